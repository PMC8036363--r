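test_that("diagonally touching pixels form one object under 8-connectivity", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE  # touch only at a corner
  obj <- extract_objects(m, resolution(1))
  expect_equal(nrow(obj$objects), 1L)
  expect_equal(nrow(extract_objects(matrix(FALSE, 4, 4))$objects), 0L)
})

test_that("well-separated blobs come back with their pixel-count areas", {
  res <- resolution(10)  # 100 um^2 per px
  m <- matrix(FALSE, 120, 120)
  m[2:41, 2:51] <- TRUE       # 2000 px = 0.2 mm^2
  m[60:89, 2:101] <- TRUE     # 3000 px = 0.3 mm^2
  m[95:119, 2:101] <- m[95:119, 2:101] | outer(rep(TRUE, 25), rep(TRUE, 100))
  obj <- extract_objects(m, res)
  expect_equal(sort(obj$objects$area_mm2), c(0.2, 0.25, 0.3))
})

test_that("margin features follow their arithmetic definition", {
  res <- resolution(10)
  m <- matrix(FALSE, 100, 100)
  m[2:41, 2:51] <- TRUE       # 0.2 mm^2
  m[60:89, 1:100] <- TRUE     # 0.3 mm^2
  band <- structure(list(mask = matrix(TRUE, 100, 100), width_um = 500,
                         label = "Margin1", um_per_px = 10),
                    class = "margin_band")
  feats <- compute_margin_features(extract_objects(m, res), band, "p1")
  expect_equal(feats$total_mm2, 0.5)
  expect_equal(feats$average_mm2, 0.25)
  expect_equal(feats$largest_mm2, 0.3)
  expect_equal(feats$n_objects, 2L)
  # empty intersection
  band0 <- structure(list(mask = matrix(FALSE, 100, 100), width_um = 500,
                          label = "Margin1", um_per_px = 10),
                     class = "margin_band")
  f0 <- compute_margin_features(extract_objects(m, res), band0, "p1")
  expect_equal(unlist(f0[c("total_mm2", "average_mm2", "largest_mm2", "n_objects")],
                      use.names = FALSE), c(0, 0, 0, 0))
  # resolution mismatch rejected
  band_bad <- structure(list(mask = matrix(TRUE, 100, 100), width_um = 500,
                             label = "Margin1", um_per_px = 1),
                        class = "margin_band")
  expect_error(compute_margin_features(extract_objects(m, res), band_bad),
               "resolution")
})

test_that("in-margin object area equals brute-force pixel intersection", {
  m <- matrix(FALSE, 60, 60)
  m[10:39, 10:39] <- TRUE  # one 30x30 object
  band_mask <- matrix(FALSE, 60, 60)
  band_mask[1:60, 1:24] <- TRUE  # covers the left half of the object
  band <- structure(list(mask = band_mask, width_um = 500, label = "Margin1",
                         um_per_px = 1), class = "margin_band")
  feats <- compute_margin_features(extract_objects(m), band)
  brute <- sum(m & band_mask) / 1e6
  expect_equal(feats$total_mm2, brute)
  expect_equal(attr(feats, "per_object")$area_in_margin_mm2, brute)
  expect_equal(attr(feats, "per_object")$area_mm2, sum(m) / 1e6)
})

test_that("in-margin areas are conserved and grow with nested margins", {
  s <- small_slide(seed = 41, n_blobs = 3L)
  obj <- extract_objects(s$mask, resolution(1))
  b1 <- build_margin_band(s$front, s$tumour, 100, resolution(1), dim(s$mask))
  b2 <- build_margin_band(s$front, s$tumour, 220, resolution(1), dim(s$mask))
  f1 <- compute_margin_features(obj, b1)
  f2 <- compute_margin_features(obj, b2)
  # conservation: sum of in-margin object areas equals area of mask & band
  expect_equal(f1$total_mm2, area_mm2(s$mask & b1$mask))
  expect_equal(f2$total_mm2, area_mm2(s$mask & b2$mask))
  # monotone across nested margins
  expect_lte(f1$total_mm2, f2$total_mm2)
  expect_lte(f1$largest_mm2, f2$largest_mm2)
})

test_that("Dice follows 2TP/(2TP+FP+FN) with its boundary conventions", {
  a <- matrix(FALSE, 10, 10); a[2:4, 2:4] <- TRUE
  expect_equal(dice_score(a, a)$dice, 1)
  b <- matrix(FALSE, 10, 10); b[7:9, 7:9] <- TRUE
  expect_equal(dice_score(a, b)$dice, 0)
  # TP = FP = FN = 1 px -> 2/(2+1+1) = 0.5
  gt <- matrix(FALSE, 5, 5); gt[1, 1] <- TRUE; gt[2, 2] <- TRUE
  pr <- matrix(FALSE, 5, 5); pr[1, 1] <- TRUE; pr[3, 3] <- TRUE
  rep <- dice_score(gt, pr)
  expect_equal(rep$tp_area_mm2 * 1e6, 1)
  expect_equal(rep$fp_area_mm2 * 1e6, 1)
  expect_equal(rep$fn_area_mm2 * 1e6, 1)
  expect_equal(rep$dice, 0.5)
  # both masks empty -> perfect score by convention
  e <- matrix(FALSE, 5, 5)
  expect_equal(dice_score(e, e)$dice, 1)
  expect_error(dice_score(a, matrix(FALSE, 3, 3)), "dimensions")
})

test_that("Dice is symmetric in ground truth and prediction", {
  set.seed(5)
  for (i in 1:5) {
    a <- matrix(runif(400) < 0.4, 20, 20)
    b <- matrix(runif(400) < 0.4, 20, 20)
    expect_equal(dice_score(a, b)$dice, dice_score(b, a)$dice)
  }
})

test_that("pooled Dice sums areas before applying the formula", {
  r1 <- dice_score(matrix(TRUE, 2, 2), matrix(TRUE, 2, 2))
  gt <- matrix(FALSE, 2, 2); gt[1, 1] <- TRUE
  pr <- matrix(FALSE, 2, 2); pr[2, 2] <- TRUE
  r2 <- dice_score(gt, pr)
  pooled <- aggregate_dice(list(r1, r2))
  expect_equal(pooled$dice, 2 * 4 / (2 * 4 + 1 + 1))
  expect_equal(aggregate_dice(list(r1, r2), "mean"), 0.5)
})
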