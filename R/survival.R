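#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimate via [survival::survfit()], returned in a tidy
#' per-group table.
#'
#' @param times Positive follow-up times (days).
#' @param events Event indicators, 1 = death observed, 0 = censored.
#' @param groups Group labels, one per subject.
#' @return A `data.frame` with columns `group`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`.
#' @export
km_estimate <- function(times, events, groups) {
  .check_surv(times, events)
  groups <- as.character(groups)
  if (length(groups) != length(times)) stop("length mismatch")
  if (any(table(groups) == 0) || anyNA(groups)) {
    stop("every group needs at least one subject")
  }
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  if (is.null(fit$strata)) {
    grp <- rep(unique(groups), length(fit$time))
  } else {
    grp <- rep(sub("^groups=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, n_censor = fit$n.censor,
             survival = fit$surv, stringsAsFactors = FALSE)
}

.check_surv <- function(times, events) {
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop("`times` must be finite and positive")
  }
  if (!all(events %in% c(0, 1))) stop("`events` must be 0 or 1")
  invisible(NULL)
}

#' Two-group log-rank (Mantel-Haenszel) test
#'
#' Pools the 2x2 tables at each distinct event time and compares observed
#' with expected events in the first group, giving a 1-df chi-square. The
#' implementation is a direct vectorized form of the classic
#' observed-minus-expected statistic and agrees with
#' [survival::survdiff()].
#'
#' @param times Positive follow-up times.
#' @param events Event indicators (0/1).
#' @param groups Labels with exactly two distinct values, both nonempty.
#' @return List with `chi2`, `pvalue`, `observed` and `expected` (events in
#'   the first group, sorted label order).
#' @export
logrank_test <- function(times, events, groups) {
  .check_surv(times, events)
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2) stop("need exactly two nonempty groups")
  g1 <- groups == lev[1]
  st <- .logrank_chi2(times, events, g1)
  list(chi2 = st[["chi2"]],
       pvalue = stats::pchisq(st[["chi2"]], df = 1, lower.tail = FALSE),
       observed = st[["observed"]], expected = st[["expected"]])
}

# core log-rank computation on a logical group indicator; kept free of
# formula interfaces because the permutation loop calls it many times
.logrank_chi2 <- function(times, events, g1) {
  ut <- sort(unique(times[events == 1]))
  o <- e <- v <- 0
  for (tk in ut) {
    at <- times >= tk
    n1 <- sum(at & g1)
    nn <- sum(at)
    d <- sum(times == tk & events == 1)
    d1 <- sum(times == tk & events == 1 & g1)
    o <- o + d1
    e <- e + d * n1 / nn
    if (nn > 1) v <- v + d * (n1 / nn) * (1 - n1 / nn) * (nn - d) / (nn - 1)
  }
  chi2 <- if (v > 0) (o - e)^2 / v else 0
  c(chi2 = chi2, observed = o, expected = e)
}

#' Median split of an expression vector
#'
#' Values strictly above the median are labeled `"high"`, values at or
#' below it `"low"` (ties go to the low group). A constant vector cannot be
#' stratified and is an error.
#'
#' @param values Numeric vector, length >= 2.
#' @return Character vector of `"high"`/`"low"` labels.
#' @export
dichotomize_median <- function(values) {
  if (length(values) < 2) stop("need at least two subjects")
  if (anyNA(values)) stop("`values` must not contain NA")
  if (length(unique(values)) == 1) {
    stop("degenerate expression, cannot stratify")
  }
  ifelse(values > stats::median(values), "high", "low")
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Efron tie handling via
#' [survival::coxph()]; reports the log hazard ratio with its Wald test
#' and 95% confidence interval.
#'
#' @param expr Per-subject covariate (e.g. log2-normalized expression).
#' @param times Positive follow-up times.
#' @param events Event indicators (0/1), at least one event.
#' @return List (class `CoxResult`) with `beta`, `hr`, `ci95`, `pvalue`,
#'   `n_events`.
#' @export
cox_univariate <- function(expr, times, events) {
  .check_surv(times, events)
  if (sum(events) < 1) stop("no events: Cox model cannot be fit")
  if (length(unique(expr)) < 2) stop("covariate is constant")
  fit <- survival::coxph(survival::Surv(times, events) ~ expr,
                         ties = "efron")
  if (!all(is.finite(stats::coef(fit)))) {
    stop("Cox fit did not converge (", fit$iter, " iterations; ",
         "non-finite coefficient)")
  }
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  structure(list(beta = beta,
                 hr = exp(beta),
                 ci95 = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
                 pvalue = 2 * stats::pnorm(-abs(beta / se)),
                 n_events = sum(events)),
            class = "CoxResult")
}

# multivariate Cox fit without the formula machinery (hot path of the
# permutation loop); returns the coefficient vector
.fast_cox_coef <- function(X, times, events) {
  # monotone-likelihood warnings are expected in permuted refits and are
  # harmless there: the split on the linear predictor is still well defined
  fit <- suppressWarnings(
    survival::coxph.fit(X, survival::Surv(times, events),
                        strata = NULL, offset = NULL, init = NULL,
                        control = survival::coxph.control(),
                        weights = NULL, method = "efron",
                        rownames = NULL))
  co <- fit$coefficients
  co[!is.finite(co)] <- 0
  co
}

#' Module-level risk-score survival classifier
#'
#' Evaluates one ceRNA module (a lncRNA, an mRNA and a miRNA) as a joint
#' prognostic signature. The three log2-normalized expression vectors are
#' z-scored over tumor samples and fit in a multivariate Cox model; the
#' risk score is the linear predictor \eqn{\sum_i \beta_i x_i}. Patients
#' are split at the median risk score and compared by log-rank test.
#'
#' Because the score is fit and evaluated on the same patients, the
#' asymptotic log-rank p-value of the self-fitted split is anti-conservative.
#' The reported `pvalue` is therefore a permutation p-value: the whole
#' procedure (Cox fit, median split, log-rank statistic) is recomputed under
#' `n_perm` random reassignments of the survival outcomes, which makes the
#' null distribution exact by construction. The unadjusted asymptotic value
#' is kept as `pvalue_asymptotic` for reference.
#'
#' @param exprs Numeric matrix: 3 rows (lncRNA, mRNA, miRNA log2-normalized
#'   expression) x tumor samples, with rownames and colnames.
#' @param times,events Survival outcome for the same samples (days, 0/1).
#' @param module_id Identifier carried into the result.
#' @param n_perm Number of outcome permutations (default 199, so the
#'   smallest attainable p is 1/200).
#' @param seed Integer seed for the permutations.
#' @return List (class `ModuleSurvival`) with `module_id`, `betas`,
#'   `univariate` (per-RNA `CoxResult`s), `risk_scores`, `risk_groups`,
#'   `km`, `logrank_chi2`, `pvalue`, `pvalue_asymptotic`, `direction`
#'   (`"negative"` when the high-risk group fares worse).
#' @export
module_risk_score <- function(exprs, times, events, module_id = "module",
                              n_perm = 199, seed = 1) {
  if (!is.matrix(exprs) || nrow(exprs) != 3) {
    stop("`exprs` must be a 3 x samples matrix (lncRNA, mRNA, miRNA rows)")
  }
  .check_surv(times, events)
  if (ncol(exprs) != length(times)) stop("sample/outcome length mismatch")
  cc <- stats::cor(t(exprs))
  for (i in 1:2) for (j in (i + 1):3) {
    if (abs(cc[i, j]) > 0.999) {
      stop("collinear expression pair: ", rownames(exprs)[i], " and ",
           rownames(exprs)[j])
    }
  }
  X <- t(scale(t(exprs)))  # z-score each RNA over tumor samples
  Xt <- t(X)

  run_once <- function(tt, ev) {
    beta <- .fast_cox_coef(Xt, tt, ev)
    lp <- as.vector(Xt %*% beta)
    hi <- lp > stats::median(lp)
    list(beta = beta, lp = lp, hi = hi,
         stat = .logrank_chi2(tt, ev, hi))
  }
  obs <- run_once(times, events)
  chi2 <- obs$stat[["chi2"]]

  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- length(times)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    st <- run_once(times[idx], events[idx])$stat
    if (st[["chi2"]] >= chi2) exceed <- exceed + 1L
  }
  p_perm <- (1 + exceed) / (n_perm + 1)

  grp <- ifelse(obs$hi, "high", "low")
  km <- km_estimate(times, events, grp)
  # worse survival in the high-risk group = negative prognostic association
  dir <- if (obs$stat[["observed"]] >= obs$stat[["expected"]]) {
    # 'observed' counts events in the first sorted label ("high")
    "negative"
  } else {
    "positive"
  }
  uni <- lapply(seq_len(3), function(i) {
    cox_univariate(X[i, ], times, events)
  })
  names(uni) <- rownames(exprs)
  structure(list(module_id = module_id,
                 betas = stats::setNames(obs$beta, rownames(exprs)),
                 univariate = uni,
                 risk_scores = stats::setNames(obs$lp, colnames(exprs)),
                 risk_groups = stats::setNames(grp, colnames(exprs)),
                 km = km,
                 logrank_chi2 = chi2,
                 pvalue = p_perm,
                 pvalue_asymptotic = stats::pchisq(chi2, 1, lower.tail = FALSE),
                 direction = dir),
            class = "ModuleSurvival")
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng_state <- function(state) {
  if (!is.null(state)) {
    assign(".Random.seed", state, envir = globalenv())
  }
}
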