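test_that("Kaplan-Meier estimate matches the hand product-limit", {
  # times (1, 2+, 3), events at 1 and 3
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1), rep("all", 3))
  expect_equal(km$survival[km$time == 1], 2 / 3)
  expect_equal(km$survival[km$time == 3], 0)

  # no events: survival stays at 1
  km0 <- km_estimate(c(2, 4, 6), c(0, 0, 0), rep("all", 3))
  expect_true(all(km0$survival == 1))

  # duplicating every subject leaves the curve unchanged
  set.seed(8)
  t <- rexp(30, 1 / 10); e <- rbinom(30, 1, 0.7)
  k1 <- km_estimate(t, e, rep("g", 30))
  k2 <- km_estimate(rep(t, 2), rep(e, 2), rep("g", 60))
  expect_equal(k2$survival, k1$survival)
  expect_equal(k2$time, k1$time)

  # with no censoring KM equals the empirical survival function
  t2 <- sort(rexp(50, 1 / 5))
  k3 <- km_estimate(t2, rep(1, 50), rep("g", 50))
  expect_equal(k3$survival, 1 - seq_len(50) / 50)
})

test_that("log-rank test reproduces hand oracle and survdiff", {
  # group A events at 1,2; group B events at 3,4 -> chi2 = 49/17
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr$chi2, 49 / 17, tolerance = 1e-12)
  expect_equal(lr$observed, 2)
  expect_equal(lr$expected, 5 / 6, tolerance = 1e-12)

  # two identical groups cannot differ
  t <- c(1, 3, 5, 1, 3, 5); e <- c(1, 0, 1, 1, 0, 1)
  lr0 <- logrank_test(t, e, rep(c("A", "B"), each = 3))
  expect_equal(lr0$chi2, 0)
  expect_equal(lr0$pvalue, 1)

  # label swap leaves the statistic unchanged
  set.seed(13)
  tt <- rexp(40, 1 / 8); ev <- rbinom(40, 1, 0.6)
  g <- rep(c("x", "y"), 20)
  expect_equal(logrank_test(tt, ev, g)$chi2,
               logrank_test(tt, ev, ifelse(g == "x", "y", "x"))$chi2)

  # agreement with the survival package on random censored data
  for (i in 1:20) {
    n <- sample(10:60, 1)
    tt <- rexp(n, 1 / 5)
    ev <- rbinom(n, 1, 0.7)
    g <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(g)) < 2) next
    sd <- survival::survdiff(survival::Surv(tt, ev) ~ g)
    expect_equal(logrank_test(tt, ev, g)$chi2, sd$chisq, tolerance = 1e-8)
  }

  expect_error(logrank_test(c(1, 2), c(1, 1), c("a", "a")), "two nonempty")
})

test_that("median dichotomization sends ties to the low group", {
  expect_identical(dichotomize_median(c(1, 2, 3, 4)),
                   c("low", "low", "high", "high"))
  expect_identical(dichotomize_median(c(1, 2, 2, 3)),
                   c("low", "low", "low", "high"))
  expect_error(dichotomize_median(rep(3, 5)), "degenerate")
})

test_that("univariate Cox recovers null and planted hazard ratios", {
  sim_ph <- function(n, beta, seed) {
    set.seed(seed)
    x <- rnorm(n)
    t <- rexp(n, rate = 0.01 * exp(beta * x))
    cens <- quantile(t, 0.75)
    list(x = x, time = pmin(t, cens), event = as.integer(t <= cens))
  }
  d0 <- sim_ph(500, 0, 3)
  expect_lt(abs(cox_univariate(d0$x, d0$time, d0$event)$beta), 0.15)

  d1 <- sim_ph(500, 0.7, 3)
  fit <- cox_univariate(d1$x, d1$time, d1$event)
  expect_gt(fit$beta, 0.55)
  expect_lt(fit$beta, 0.85)
  expect_true(fit$ci95[1] <= fit$hr && fit$hr <= fit$ci95[2])
  expect_lt(fit$pvalue, 1e-6)

  # shifting the covariate leaves beta unchanged
  fit2 <- cox_univariate(d1$x + 100, d1$time, d1$event)
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-8)

  expect_error(cox_univariate(d1$x, d1$time, rep(0, 500)), "no events")
})

test_that("Cox estimation bias is small across effect sizes", {
  sim_ph <- function(n, beta, seed) {
    set.seed(seed)
    x <- rnorm(n)
    t <- rexp(n, rate = 0.01 * exp(beta * x))
    cens <- quantile(t, 0.75)
    list(x = x, time = pmin(t, cens), event = as.integer(t <= cens))
  }
  for (beta in c(-0.7, 0, 0.7)) {
    est <- vapply(1:20, function(s) {
      d <- sim_ph(500, beta, 100 + s)
      cox_univariate(d$x, d$time, d$event)$beta
    }, numeric(1))
    expect_lt(abs(mean(est) - beta), 0.05)
  }
})

test_that("module risk score stratifies a planted prognostic module", {
  cfg <- sim_config(n_normal = 10, n_t1 = 75, n_t2 = 75, n_t3 = 75,
                    n_t4 = 75, n_mrna = 30, n_lncrna = 10, n_mirna = 10,
                    n_de_mrna = 4, n_de_lncrna = 3, n_de_mirna = 6,
                    n_planted_triplets = 1, survival_beta = 0.8, seed = 2)
  co <- simulate_cohort(cfg)
  tum <- co$samples[co$samples$condition == "tumor", ]
  trip <- co$truth$planted_triplets
  mir1 <- strsplit(trip$shared_mirnas, ";")[[1]][1]
  get_row <- function(cls, id) {
    lg <- normalize_log2(co$counts[[cls]])
    unclass(lg)[id, tum$sample_id]
  }
  exprs <- rbind(get_row("lncRNA", trip$lncrna_id),
                 get_row("mRNA", trip$mrna_id),
                 get_row("miRNA", mir1))
  rownames(exprs) <- c(trip$lncrna_id, trip$mrna_id, mir1)
  ms <- module_risk_score(exprs, tum$os_time, tum$os_event, seed = 5)
  expect_lt(ms$pvalue, 0.01)
  # the self-fitted high-risk group has the worse outcome by construction
  expect_identical(ms$direction, "negative")
  # risk groups partition the tumor samples nearly evenly
  expect_lte(abs(sum(ms$risk_groups == "high") -
                 sum(ms$risk_groups == "low")), 1)

  # shifting one RNA's expression changes neither scores nor groups
  exprs2 <- exprs
  exprs2[1, ] <- exprs2[1, ] + 10
  ms2 <- module_risk_score(exprs2, tum$os_time, tum$os_event, seed = 5)
  expect_equal(ms2$risk_scores, ms$risk_scores, tolerance = 1e-9)
  expect_identical(ms2$risk_groups, ms$risk_groups)
})

test_that("collinear module members are rejected by name", {
  x <- rnorm(30)
  exprs <- rbind(a = x, b = x + 1e-9 * rnorm(30), c = rnorm(30))
  tt <- rexp(30, 1 / 5)
  expect_error(module_risk_score(exprs, tt, rbinom(30, 1, 0.8)),
               "collinear.*a.*b")
})
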