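test_that("stratified 75/25 split reproduces the cohort arithmetic", {
  cohort <- make_cohort_df(125, 403)  # 528 patients, 125 immature
  sp <- stratified_split(cohort, 0.75, "dr", seed = 3)
  expect_equal(length(sp$train), 396L)
  expect_equal(length(sp$test), 132L)
  expect_equal(sum(cohort$dr[sp$train] == "immature"), 94L)
  expect_equal(sum(cohort$dr[sp$test] == "immature"), 31L)
  expect_setequal(c(sp$train, sp$test), seq_len(528))
  # determinism and seed sensitivity
  sp2 <- stratified_split(cohort, 0.75, "dr", seed = 3)
  expect_identical(sp$train, sp2$train)
  sp3 <- stratified_split(cohort, 0.75, "dr", seed = 4)
  expect_false(identical(sp$train, sp3$train))
  expect_error(stratified_split(cohort, 0.75, "missing_col", seed = 1),
               "missing")
})

test_that("split conserves stratum proportions within one patient", {
  set.seed(12)
  cohort <- data.frame(grp = sample(letters[1:4], 211, replace = TRUE))
  sp <- stratified_split(cohort, 0.6, "grp", seed = 8)
  for (g in letters[1:4]) {
    n_g <- sum(cohort$grp == g)
    expect_lte(abs(sum(cohort$grp[sp$train] == g) - 0.6 * n_g), 0.5 + 1e-9)
  }
})

test_that("Kaplan-Meier matches hand-computed product-limit values", {
  # 10 records with mixed censoring; risk-set products done by hand:
  # S(1)=9/10, S(2)=.9*7/9=.7, S(4)=.7*5/6, S(6)=.7*5/6*2/4, S(8)=0
  time <- c(1, 2, 2, 3, 4, 5, 6, 6, 7, 8)
  event <- c(1, 1, 1, 0, 1, 0, 1, 1, 0, 1)
  km <- km_estimate(time, event, horizon_months = 6)[["all"]]
  s_at <- function(t) km$surv[max(which(km$time <= t))]
  expect_equal(s_at(1), 0.9)
  expect_equal(s_at(2), 0.7)
  expect_equal(s_at(4), 0.7 * 5 / 6)
  expect_equal(s_at(6), 0.7 * 5 / 6 * 2 / 4)
  expect_equal(s_at(8), 0)
  expect_equal(km$surv_at_horizon, 0.7 * 5 / 6 * 2 / 4)
  # no censoring: KM equals the empirical survivor function
  km2 <- km_estimate(1:4, rep(1, 4))[["all"]]
  expect_equal(km2$surv, c(0.75, 0.5, 0.25, 0))
  # all censored: survival stays at 1
  km3 <- km_estimate(1:5, rep(0, 5))[["all"]]
  expect_true(all(km3$surv == 1))
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank test agrees with the risk-table oracle", {
  # identical groups: statistic exactly 0
  time <- rep(c(2, 4, 6, 8), 2)
  event <- rep(c(1, 1, 0, 1), 2)
  grp <- rep(c("a", "b"), each = 4)
  lr0 <- logrank_test(time, event, grp)
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  # planted strong separation: all group-A deaths precede any group-B death
  timeS <- c(1:10, 21:30)
  eventS <- rep(1, 20)
  grpS <- rep(c("a", "b"), each = 10)
  lrS <- logrank_test(timeS, eventS, grpS)
  expect_lt(lrS$p_value, 0.01)
  # small mixed fixture vs hand risk-table computation
  set.seed(77)
  tm <- sample(1:20, 14, replace = TRUE)
  ev <- rbinom(14, 1, 0.7)
  gp <- rep(c("a", "b"), 7)
  expect_equal(logrank_test(tm, ev, gp)$statistic,
               oracle_logrank(tm, ev, gp), tolerance = 1e-9)
  # no events anywhere: uninformative, p = 1 by convention
  expect_equal(logrank_test(c(1, 2, 3, 4), rep(0, 4),
                            rep(c("a", "b"), 2))$p_value, 1)
})

test_that("maxstat maximum equals brute-force enumeration on small fixtures", {
  set.seed(31)
  for (rep_i in 1:4) {
    n <- sample(20:50, 1)
    x <- round(runif(n, 0, 3), 2)           # some tied values
    t_ev <- rexp(n, 0.05 * ifelse(x > 1.5, 3, 1))
    cens <- runif(n, 0, 40)
    tm <- pmin(t_ev, cens); ev <- as.integer(t_ev <= cens)
    if (sum(ev) == 0 || length(unique(x)) < 3) next
    ms <- maxstat_cutpoint(x, tm, ev, minprop = 0.1, p_method = "none")
    ora <- oracle_maxstat(x, tm, ev, minprop = 0.1)
    expect_equal(ms$candidates, ora$cut)
    expect_equal(ms$statistics, ora$stat, tolerance = 1e-9)
    expect_equal(ms$best_cutpoint, ora$cut[which.max(abs(ora$stat))])
    expect_equal(ms$statistic, max(abs(ora$stat)), tolerance = 1e-9)
  }
})

test_that("maxstat candidates respect minprop and degenerate input is rejected", {
  x <- 1:40
  tm <- rexp(40, 0.05); ev <- rep(1L, 40)
  ms <- maxstat_cutpoint(x, tm, ev, minprop = 0.1, p_method = "none")
  frac_left <- vapply(ms$candidates, function(c) mean(x <= c), 0)
  expect_true(all(frac_left >= 0.1 & frac_left <= 0.9))
  expect_error(maxstat_cutpoint(rep(1, 10), rexp(10), rep(1L, 10)), "constant")
  expect_error(maxstat_cutpoint(1:10, rexp(10), rep(0L, 10)), "event")
})

test_that("maxstat recovers a planted cut-point with a planted hazard ratio", {
  set.seed(1204)
  recovered <- replicate(15, {
    x <- runif(200, 0, 2)                    # planted threshold at 1.0
    t_ev <- rexp(200, 0.01 * ifelse(x > 1, 3.5, 1))
    cens <- runif(200, 0, 150)
    maxstat_cutpoint(x, pmin(t_ev, cens), as.integer(t_ev <= cens),
                     p_method = "none")$best_cutpoint
  })
  # central recovery within 10% of the planted threshold on average
  expect_lt(abs(mean(recovered) - 1), 0.1)
})

test_that("maxstat permutation p is seeded and detects a planted effect", {
  set.seed(55)
  x <- runif(120, 0, 2)
  t_ev <- rexp(120, 0.01 * ifelse(x > 1, 4, 1))
  cens <- runif(120, 0, 150)
  tm <- pmin(t_ev, cens); ev <- as.integer(t_ev <= cens)
  m1 <- maxstat_cutpoint(x, tm, ev, n_perm = 500L, seed = 9)
  m2 <- maxstat_cutpoint(x, tm, ev, n_perm = 500L, seed = 9)
  expect_identical(m1$p_value, m2$p_value)
  expect_lt(m1$p_value, 0.05)
  # a marker unrelated to survival should not look significant too often
  y <- runif(120)
  expect_gt(maxstat_cutpoint(y, tm, ev, n_perm = 500L, seed = 9)$p_value, 0.001)
})

test_that("Cox fit recovers a planted log hazard ratio without bias", {
  set.seed(404)
  lhr <- replicate(60, {
    z <- rbinom(400, 1, 0.3)
    t_ev <- rexp(400, 0.01 * 3.5^z)
    cens <- runif(400, 0, 300)
    d <- data.frame(time_months = pmin(t_ev, cens),
                    event = as.integer(t_ev <= cens), z = z)
    cox_fit(d, "z")$table$coef
  })
  expect_lt(abs(mean(lhr) - log(3.5)), 0.1)
})

test_that("duplicating a dataset keeps the hazard ratio, shrinks the SE", {
  set.seed(7)
  z <- rbinom(100, 1, 0.4)
  t_ev <- rexp(100, 0.02 * 2^z)
  d <- data.frame(time_months = t_ev, event = 1L, z = z)
  f1 <- cox_fit(d, "z")
  f2 <- cox_fit(rbind(d, d), "z")
  expect_equal(f2$table$hr, f1$table$hr, tolerance = 1e-6)
  expect_lt(f2$table$se, f1$table$se)
  expect_true(f1$converged)
})

test_that("forward stepwise keeps planted effects and drops noise", {
  set.seed(2024)
  n <- 400
  z <- rbinom(n, 1, 0.3)
  noise <- rnorm(n)
  t_ev <- rexp(n, 0.01 * 3.5^z)
  cens <- runif(n, 0, 300)
  d <- data.frame(time_months = pmin(t_ev, cens),
                  event = as.integer(t_ev <= cens), z = z, noise = noise)
  sw <- cox_forward_stepwise(d, c("z", "noise"))
  expect_identical(sw$selected, "z")
  expect_equal(sw$trace$action[1], "add")
  # all-noise candidates: empty model
  d2 <- d; d2$z2 <- rnorm(n); d2$z3 <- rnorm(n)
  sw2 <- cox_forward_stepwise(d2, c("noise", "z2", "z3"))
  expect_length(sw2$selected, 0L)
  expect_null(sw2$fit)
  # single planted candidate: fixpoint equals the univariate fit
  sw3 <- cox_forward_stepwise(d, c("z", "noise"))
  uni <- cox_fit(d, "z")
  sw_single <- cox_forward_stepwise(d, "z")
  expect_equal(sw_single$fit$table$hr, uni$table$hr)
})

test_that("BH adjustment follows the step-up identities", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(6)
  p <- runif(20)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # rank order of raw p preserved in adjusted values
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  # BH rejections are a superset of Bonferroni's at the same level
  q <- 0.1
  expect_true(all(which(p.adjust(p, "bonferroni") <= q) %in% which(adj <= q)))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
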