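#' Harrell's concordance index
#'
#' Fraction of comparable pairs in which the sample that fails earlier has
#' the higher risk score. A pair (i, j) is comparable when t_i < t_j and
#' sample i's event is observed; score ties are credited 0.5. C = 0.5 for
#' random scores, 1 for a perfectly discriminating model.
#'
#' @param scores numeric risk scores (higher = higher risk).
#' @param time survival/censoring times.
#' @param event event indicator (1 observed, 0 censored).
#' @return concordance index in [0, 1].
#' @export
concordance_index <- function(scores, time, event) {
  stopifnot(length(scores) == length(time), length(time) == length(event))
  dt <- outer(time, time, "<")              # t_i < t_j
  comparable <- dt & (event == 1)           # row i must have an event
  n_pairs <- sum(comparable)
  if (n_pairs == 0L) stop("no comparable pairs: concordance index undefined")
  ds <- outer(scores, scores, "-")
  concordant <- sum(comparable & ds > 0)
  tied <- sum(comparable & ds == 0)
  (concordant + 0.5 * tied) / n_pairs
}

#' Kaplan-Meier product-limit estimator
#'
#' @param time survival/censoring times.
#' @param event event indicator (1 observed, 0 censored).
#' @return object of class \code{km_curve}: data frame \code{table}
#'   (time, n_risk, n_event, n_censor, survival) over event times, and
#'   \code{survival_at(t)}, a right-continuous step-function query starting
#'   at S(0) = 1.
#' @export
kaplan_meier <- function(time, event) {
  stopifnot(length(time) >= 1L, length(time) == length(event))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  tab <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  ev <- tab[tab$n_event > 0, , drop = FALSE]
  s_fun <- if (nrow(ev)) {
    stats::stepfun(ev$time, c(1, ev$survival), right = FALSE)
  } else {
    function(t) rep(1, length(t))
  }
  structure(list(table = tab, survival_at = s_fun, n = length(time)),
            class = "km_curve")
}

#' Two-group log-rank test
#'
#' Observed-minus-expected events over the pooled event times, with the
#' hypergeometric variance; p-value from chi-square with 1 df.
#'
#' @param group two-level grouping vector.
#' @param time,event survival data.
#' @return list with \code{chisq}, \code{p_value}, \code{observed},
#'   \code{expected} (per group).
#' @export
logrank_test <- function(group, time, event) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) {
    stop("log-rank test requires exactly two non-empty groups")
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chisq <- sd$chisq
  list(chisq = chisq,
       p_value = stats::pchisq(chisq, df = 1L, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit (Breslow tie handling by default) returning, per
#' covariate, the coefficient, hazard ratio with Wald 95\% CI, and Wald
#' p-value, plus model-level likelihood-ratio and score tests.
#'
#' @param covariates data frame of per-sample covariates (one column per
#'   model term).
#' @param time,event survival data, aligned with \code{covariates} rows.
#' @param ties \code{"breslow"} (default) or \code{"efron"}.
#' @return object of class \code{cox_fit}: \code{table} (coef, hr, ci_lower,
#'   ci_upper, p_value per covariate), \code{logtest}, \code{sctest},
#'   \code{fit} (the underlying \code{coxph} object).
#' @export
cox_fit <- function(covariates, time, event, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(time)) stop("covariate rows must match samples")
  constant <- vapply(covariates, function(x) length(unique(x)) <= 1L, logical(1))
  if (any(constant)) {
    stop("constant covariate(s): ", paste(names(covariates)[constant], collapse = ", "))
  }
  dat <- cbind(covariates, .time = time, .event = event)
  fit <- survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                         ties = ties)
  if (any(!is.finite(fit$coefficients)) ||
      any(sqrt(diag(fit$var)) > 100 * (abs(fit$coefficients) + 1))) {
    stop("Cox fit did not stabilize (possible separation); coefficients: ",
         paste(format(fit$coefficients, digits = 3), collapse = ", "))
  }
  sm <- summary(fit)
  tab <- data.frame(
    term = rownames(sm$coefficients),
    coef = sm$coefficients[, "coef"],
    hr = sm$conf.int[, "exp(coef)"],
    ci_lower = sm$conf.int[, "lower .95"],
    ci_upper = sm$conf.int[, "upper .95"],
    p_value = sm$coefficients[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab,
                 logtest = unname(sm$logtest),
                 sctest = unname(sm$sctest),
                 fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("cox_fit (", nrow(x$table), " term(s)):\n", sep = "")
  print(x$table, digits = 3)
  invisible(x)
}

#' Treatment-benefit analysis stratified by predicted risk
#'
#' Restricts the cohort to stage III samples with a recorded adjuvant
#' chemotherapy (CTX) flag, splits it into low-/high-risk groups at the
#' median risk score of the full cohort, and within each risk group compares
#' treated vs untreated relapse-free survival (Kaplan-Meier curves, log-rank
#' test, univariate Cox HR for CTX). A stratum whose arms cannot support a
#' comparison (fewer than 2 samples in either arm) is skipped with a warning.
#'
#' @param scores per-sample risk scores aligned with \code{clinical} rows.
#' @param clinical clinical data frame (see \code{\link{read_clinical_table}}).
#' @return named list (\code{low_risk}, \code{high_risk}); each present
#'   stratum holds \code{n}, \code{n_ctx}, \code{km_ctx}, \code{km_no_ctx},
#'   \code{logrank}, \code{cox} (HR for CTX), or NULL when skipped.
#' @export
ctx_benefit_analysis <- function(scores, clinical) {
  clinical <- read_clinical_table(clinical)
  stopifnot(length(scores) == nrow(clinical))
  risk <- median_stratify(scores)
  keep <- clinical$stage == "III" & !is.na(clinical$ctx)
  if (!any(clinical$stage == "III")) stop("no stage III samples in the cohort")
  if (!any(keep)) stop("no stage III samples with CTX information")
  clin <- clinical[keep, , drop = FALSE]
  risk <- risk[keep]

  analyze_stratum <- function(lvl) {
    sel <- risk == lvl
    cs <- clin[sel, , drop = FALSE]
    if (sum(cs$ctx == 1) < 2L || sum(cs$ctx == 0) < 2L) {
      warning("stratum '", lvl, "' skipped: fewer than 2 samples per CTX arm")
      return(NULL)
    }
    res <- tryCatch(list(
      n = nrow(cs),
      n_ctx = sum(cs$ctx == 1),
      km_ctx = kaplan_meier(cs$time[cs$ctx == 1], cs$event[cs$ctx == 1]),
      km_no_ctx = kaplan_meier(cs$time[cs$ctx == 0], cs$event[cs$ctx == 0]),
      logrank = logrank_test(cs$ctx, cs$time, cs$event),
      cox = cox_fit(data.frame(ctx = cs$ctx), cs$time, cs$event)
    ), error = function(e) e)
    if (inherits(res, "error")) {
      # e.g. an arm with no events gives a monotone partial likelihood
      warning("stratum '", lvl, "' skipped: ", conditionMessage(res))
      return(NULL)
    }
    res
  }
  list(low_risk = analyze_stratum("low"), high_risk = analyze_stratum("high"))
}
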