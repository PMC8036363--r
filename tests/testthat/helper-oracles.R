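# Independent brute-force oracles, deliberately written with plain loops and
# none of the package's internal kernels.

# exhaustive per-pixel minimum distance to a set of segments; returns the
# logical band mask (distance <= width AND pixel centre not inside polygon)
oracle_band <- function(nrow, ncol, res, segs, poly, width) {
  pt_seg <- function(px, py, x0, y0, x1, y1) {
    dx <- x1 - x0; dy <- y1 - y0
    l2 <- dx^2 + dy^2
    t <- if (l2 > 0) ((px - x0) * dx + (py - y0) * dy) / l2 else 0
    t <- min(max(t, 0), 1)
    sqrt((x0 + t * dx - px)^2 + (y0 + t * dy - py)^2)
  }
  in_poly <- function(px, py, vx, vy) {
    n <- length(vx)
    # boundary counts as inside
    for (i in seq_len(n)) {
      j <- if (i == 1) n else i - 1
      cr <- (vx[i] - vx[j]) * (py - vy[j]) - (vy[i] - vy[j]) * (px - vx[j])
      if (abs(cr) < 1e-9) {
        dt <- (px - vx[j]) * (vx[i] - vx[j]) + (py - vy[j]) * (vy[i] - vy[j])
        l2 <- (vx[i] - vx[j])^2 + (vy[i] - vy[j])^2
        if (dt >= -1e-9 && dt <= l2 + 1e-9) return(TRUE)
      }
    }
    inside <- FALSE
    for (i in seq_len(n)) {
      j <- if (i == 1) n else i - 1
      if ((vy[i] > py) != (vy[j] > py)) {
        xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
        if (px < xint) inside <- !inside
      }
    }
    inside
  }
  out <- matrix(FALSE, nrow, ncol)
  for (r in seq_len(nrow)) {
    for (c in seq_len(ncol)) {
      px <- (c - 0.5) * res; py <- (r - 0.5) * res
      dmin <- Inf
      for (s in seq_len(nrow(segs))) {
        d <- pt_seg(px, py, segs[s, 1], segs[s, 2], segs[s, 3], segs[s, 4])
        if (d < dmin) dmin <- d
      }
      out[r, c] <- dmin <= width && !in_poly(px, py, poly[, 1], poly[, 2])
    }
  }
  out
}

# per-candidate standardized log-rank statistic computed split by split,
# with its own Nelson-Aalen score computation
oracle_maxstat <- function(values, time, event, minprop) {
  n <- length(values)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    ch <- 0
    for (tt in sort(unique(time[event == 1]))) {
      if (tt > time[i]) break
      ch <- ch + sum(time == tt & event == 1) / sum(time >= tt)
    }
    scores[i] <- event[i] - ch
  }
  ux <- sort(unique(values))
  mids <- (ux[-length(ux)] + ux[-1]) / 2
  res <- data.frame(cut = numeric(0), stat = numeric(0))
  for (cut in mids) {
    m <- sum(values <= cut)
    if (m / n < minprop || m / n > 1 - minprop) next
    s <- sum(scores[values <= cut])
    e <- m * mean(scores)
    v <- m * (n - m) / (n * (n - 1)) * sum((scores - mean(scores))^2)
    res <- rbind(res, data.frame(cut = cut, stat = (s - e) / sqrt(v)))
  }
  res
}

# plain risk-table log-rank: observed minus expected deaths in group 1
oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group)) - 1L
  o_minus_e <- 0; v <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at <- time >= tt
    n1 <- sum(at & g == 1); n0 <- sum(at & g == 0)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & g == 1)
    nn <- n1 + n0
    o_minus_e <- o_minus_e + d1 - d * n1 / nn
    if (nn > 1) v <- v + d * (n1 / nn) * (n0 / nn) * (nn - d) / (nn - 1)
  }
  o_minus_e^2 / v
}

# small slides keep the image-level tests fast; blobs are scaled to fit and
# the minimum-object filter is scaled accordingly where used
small_slide <- function(seed, n_blobs = 2L) {
  generate_slide(slide_gen_params(
    canvas_px = c(400L, 400L), front_x_um = 140, front_amp_um = 30,
    n_blobs = n_blobs, area_meanlog = log(0.008), area_sdlog = 0.3,
    offset_um = c(40, 180), seed = seed))
}

make_cohort_df <- function(n_immature, n_other) {
  data.frame(patient_id = seq_len(n_immature + n_other),
             dr = rep(c("immature", "other"), c(n_immature, n_other)),
             stringsAsFactors = FALSE)
}
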