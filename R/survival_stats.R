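#' Stratified train/test split of a cohort
#'
#' Splits patients into train and test sets while preserving the composition
#' of each stratum (e.g. DR category, or outcome x DR category): within each
#' stratum, `round_half_up(n_stratum * train_frac)` patients are sampled
#' uniformly into the training set. With 528 patients of whom 125 are
#' immature and `train_frac = 0.75`, this yields 396/132 patients and 94/31
#' immature in train/test.
#'
#' @param cohort Data frame with one row per patient.
#' @param train_frac Fraction assigned to training, in (0, 1).
#' @param strata Character vector of column names defining the strata.
#' @param seed Integer seed; the same seed reproduces the same split.
#' @return A `split_result` list: integer row indices `train` and `test`,
#'   and `counts`, a per-stratum table of train/test sizes.
#' @export
stratified_split <- function(cohort, train_frac = 0.75, strata, seed = 1L) {
  stopifnot(is.data.frame(cohort))
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must lie in (0, 1)", call. = FALSE)
  if (!all(strata %in% names(cohort))) {
    stop("strata columns missing from cohort: ",
         paste(setdiff(strata, names(cohort)), collapse = ", "), call. = FALSE)
  }
  key <- interaction(cohort[strata], drop = TRUE, lex.order = TRUE)
  if (anyNA(key)) stop("missing values in strata columns", call. = FALSE)
  with_seed(seed, {
    train <- integer(0)
    levs <- levels(key)
    counts <- data.frame(stratum = levs, n = 0L, n_train = 0L, n_test = 0L)
    for (i in seq_along(levs)) {
      idx <- which(key == levs[i])
      k <- floor(length(idx) * train_frac + 0.5)  # half-up, not banker's
      take <- if (k > 0L) sort(sample(idx, k)) else integer(0)
      train <- c(train, take)
      counts$n[i] <- length(idx)
      counts$n_train[i] <- k
      counts$n_test[i] <- length(idx) - k
    }
    train <- sort(train)
    structure(list(train = train,
                   test = setdiff(seq_len(nrow(cohort)), train),
                   counts = counts),
              class = "split_result")
  })
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimates for each group, with the survival rate read off
#' at a stated horizon (the estimate is a step function; the rate reported
#' is the value of the step covering the horizon).
#'
#' @param time,event Survival outcome (months; 1 = disease-specific death).
#' @param group Group label per subject (single group if omitted).
#' @param horizon_months Horizon at which to report the survival rate
#'   (default 60); the rate at the last observed event time is reported
#'   alongside.
#' @return A `km_curves` list, one element per group: `time`, `surv`,
#'   `n_risk`, `n_event`, `surv_at_horizon`, `surv_at_last_event`.
#' @export
km_estimate <- function(time, event, group = NULL, horizon_months = 60) {
  if (any(time < 0)) stop("negative survival times", call. = FALSE)
  if (is.null(group)) group <- rep("all", length(time))
  stopifnot(length(group) == length(time))
  fit <- survival::survfit(survival::Surv(time, event) ~ g,
                           data = data.frame(time = time, event = event,
                                             g = factor(group)))
  sm <- summary(fit, censored = TRUE)
  strata <- if (is.null(sm$strata)) factor(rep("g=all", length(sm$time))) else sm$strata
  out <- lapply(levels(strata), function(s) {
    i <- strata == s
    tt <- sm$time[i]; ss <- sm$surv[i]; ev <- sm$n.event[i]
    step_at <- function(h) {
      k <- findInterval(h, tt)
      if (k == 0L) 1 else ss[k]
    }
    last_ev <- if (any(ev > 0)) max(tt[ev > 0]) else NA_real_
    list(time = tt, surv = ss, n_risk = sm$n.risk[i], n_event = ev,
         surv_at_horizon = step_at(horizon_months),
         surv_at_last_event = if (is.na(last_ev)) 1 else step_at(last_ev))
  })
  names(out) <- sub("^g=", "", levels(strata))
  structure(out, class = "km_curves", horizon_months = horizon_months)
}

#' Two-group log-rank test
#'
#' @param time,event Survival outcome.
#' @param group Two-level group label.
#' @return List with `statistic` (chi-squared, 1 df) and `p_value`
#'   (two-sided). When neither group has any event the test carries no
#'   information and `p_value = 1` by convention.
#' @export
logrank_test <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) != 2L) stop("log-rank test needs exactly two groups", call. = FALSE)
  if (any(table(g) == 0L)) stop("both groups must be non-empty", call. = FALSE)
  if (sum(event) == 0) return(list(statistic = 0, p_value = 1))
  sd <- survival::survdiff(survival::Surv(time, event) ~ g,
                           data = data.frame(time = time, event = event, g = g))
  list(statistic = unname(sd$chisq),
       p_value = unname(pchisq(sd$chisq, df = 1L, lower.tail = FALSE)))
}

#' Cox proportional-hazards fit
#'
#' Maximum partial-likelihood estimation (via the survival package; Breslow
#' ties by default, matching common clinical software) with Wald 95%
#' confidence intervals `exp(beta +/- 1.96 SE)` and two-sided Wald p-values.
#' Monotone-likelihood / separation problems are flagged rather than
#' silently returned.
#'
#' @param data Data frame containing `time`, `event` and the covariates.
#' @param covariates Character vector of covariate column names (numeric or
#'   binary-coded; ordinal stage factors should be entered as single
#'   ordinal scores).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param time_col,event_col Column names of the outcome.
#' @return A `cox_fit` object: data frame `table` (term, HR, lower, upper,
#'   p, coef, se), `loglik`, `converged`.
#' @export
cox_fit <- function(data, covariates, ties = c("breslow", "efron"),
                    time_col = "time_months", event_col = "event") {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(data), length(covariates) >= 1L,
            all(c(time_col, event_col, covariates) %in% names(data)))
  if (sum(data[[event_col]]) < 1) stop("need at least one event", call. = FALSE)
  f <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", ", event_col, ") ~ ",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(f, data = data, ties = ties)
  s <- summary(fit)
  co <- s$coefficients
  se <- co[, "se(coef)"]
  beta <- co[, "coef"]
  converged <- !anyNA(beta) && all(is.finite(se)) && all(abs(beta) < 15) &&
    all(se < 1e3)
  tab <- data.frame(term = rownames(co),
                    hr = exp(beta),
                    lower = exp(beta - 1.96 * se),
                    upper = exp(beta + 1.96 * se),
                    p = co[, "Pr(>|z|)"],
                    coef = beta,
                    se = se,
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  tab$term <- gsub("`", "", tab$term)
  structure(list(table = tab,
                 loglik = fit$loglik[2L],
                 loglik_null = fit$loglik[1L],
                 converged = converged,
                 ties = ties,
                 fit = fit),
            class = "cox_fit")
}

#' Forward-stepwise multivariate Cox model
#'
#' Builds a multivariate model by iteratively adding, among candidates not
#' yet in the model, the covariate with the smallest single-term
#' likelihood-ratio p-value, provided it is below `p_enter`; after each
#' addition any included term whose likelihood-ratio p-value (for dropping
#' it from the current model) exceeds `p_remove` is removed. Iteration stops
#' at a fixpoint. Defaults `p_enter = 0.05`, `p_remove = 0.10` mirror the
#' forward-stepwise defaults of common clinical statistics software.
#'
#' @inheritParams cox_fit
#' @param candidates Character vector of candidate covariate names.
#' @param p_enter,p_remove Entry and removal thresholds; `p_enter < p_remove`.
#' @return A `cox_stepwise` object: `selected` (ordered names), `fit` (the
#'   final [cox_fit()], or `NULL` when no candidate enters), `trace` (data
#'   frame of step, action, term, p).
#' @export
cox_forward_stepwise <- function(data, candidates, p_enter = 0.05,
                                 p_remove = 0.10,
                                 ties = c("breslow", "efron"),
                                 time_col = "time_months", event_col = "event") {
  ties <- match.arg(ties)
  stopifnot(length(candidates) >= 1L, p_enter < p_remove)
  loglik_of <- function(terms) {
    if (length(terms) == 0L) {
      fit <- survival::coxph(stats::as.formula(paste0(
        "survival::Surv(", time_col, ", ", event_col, ") ~ 1")), data = data)
      return(fit$loglik[1L])
    }
    cox_fit(data, terms, ties = ties, time_col = time_col,
            event_col = event_col)$loglik
  }
  lrt_p <- function(ll_big, ll_small) {
    pchisq(2 * (ll_big - ll_small), df = 1L, lower.tail = FALSE)
  }
  model <- character(0)
  ll_cur <- loglik_of(model)
  trace <- data.frame(step = integer(0), action = character(0),
                      term = character(0), p = numeric(0),
                      stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    step <- step + 1L
    pool <- setdiff(candidates, model)
    changed <- FALSE
    if (length(pool) > 0L) {
      p_add <- vapply(pool, function(v)
        lrt_p(loglik_of(c(model, v)), ll_cur), 0)
      if (min(p_add) < p_enter) {
        best <- pool[which.min(p_add)]
        model <- c(model, best)
        ll_cur <- loglik_of(model)
        trace <- rbind(trace, data.frame(step = step, action = "add",
                                         term = best, p = min(p_add)))
        changed <- TRUE
      }
    }
    # backward look: drop terms that no longer earn their place
    repeat {
      if (length(model) == 0L) break
      p_drop <- vapply(model, function(v)
        lrt_p(ll_cur, loglik_of(setdiff(model, v))), 0)
      worst <- which.max(p_drop)
      if (p_drop[worst] > p_remove) {
        trace <- rbind(trace, data.frame(step = step, action = "remove",
                                         term = model[worst],
                                         p = p_drop[worst]))
        model <- model[-worst]
        ll_cur <- loglik_of(model)
        changed <- TRUE
      } else break
    }
    if (!changed || step > 5L * length(candidates)) break
  }
  final <- if (length(model) > 0L) {
    cox_fit(data, model, ties = ties, time_col = time_col, event_col = event_col)
  } else NULL
  structure(list(selected = model, fit = final, trace = trace),
            class = "cox_stepwise")
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values `min_{j >= i} p_(j) * m / j`, capped at 1;
#' adjusted values are never smaller than the raw ones and preserve the raw
#' ordering.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}
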