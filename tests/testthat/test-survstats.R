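test_that("concordance index equals brute-force enumeration on random fixtures", {
  for (k in 1:10) {
    fx <- random_survival(40, seed = k)
    expect_identical(concordance_index(fx$scores, fx$time, fx$event),
                     cindex_bruteforce(fx$scores, fx$time, fx$event))
  }
  # against the survival package on a tie-free fixture (the package uses a
  # different convention for pairs with tied event times)
  fx <- random_survival(60, seed = 99, tie_prob = 0)
  ref <- survival::concordance(survival::Surv(fx$time, fx$event) ~ fx$scores,
                               reverse = TRUE)$concordance
  expect_equal(concordance_index(fx$scores, fx$time, fx$event), ref,
               tolerance = 1e-12)
})

test_that("perfect ranking scores C = 1 and constant scores C = 0.5", {
  expect_equal(concordance_index(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1)
  expect_equal(concordance_index(c(5, 5, 5), c(1, 2, 3), c(1, 1, 1)), 0.5)
  expect_error(concordance_index(c(1, 2), c(5, 6), c(0, 0)),
               "no comparable pairs")
})

test_that("Kaplan-Meier matches hand-computed product limits", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$table$survival[km$table$n_event > 0], c(2/3, 1/3, 0))
  # middle observation censored: risk set shrinks without a step
  km2 <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$survival_at(1), 2/3)
  expect_equal(km2$survival_at(2.5), 2/3)
  expect_equal(km2$survival_at(3), 2/3 * (1 - 1/1))
  expect_equal(km2$survival_at(0.5), 1)
  # no events: survival stays at 1
  km3 <- kaplan_meier(c(4, 5), c(0, 0))
  expect_true(all(km3$survival_at(c(0, 10)) == 1))
  # survival is non-increasing within [0, 1]
  fx <- random_survival(50, seed = 3)
  km4 <- kaplan_meier(fx$time, fx$event)
  s <- km4$table$survival
  expect_true(all(diff(s) <= 1e-12) && all(s >= 0) && all(s <= 1))
})

test_that("log-rank test is symmetric, null on identical groups, and matches a hand sum", {
  t2 <- c(1, 2, 3, 1, 2, 3); e2 <- rep(1, 6)
  lr0 <- logrank_test(rep(c("a", "b"), each = 3), t2, e2)
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)
  # separated groups: statistic from the 2x2 hypergeometric tabulation
  grp <- rep(c("a", "b"), each = 3)
  tt <- c(1, 2, 3, 10, 11, 12); ee <- rep(1, 6)
  lr <- logrank_test(grp, tt, ee)
  # hand sum: O_a = 3, E_a = 1/2 + 2/5 + 1/4, V = 9/36 + 6/25 + 3/16
  expect_equal(lr$chisq, (3 - (0.5 + 0.4 + 0.25))^2 / (0.25 + 0.24 + 0.1875),
               tolerance = 1e-12)
  # label swap leaves the statistic unchanged
  lr_sw <- logrank_test(rev(grp), tt, ee)
  expect_equal(lr_sw$chisq, lr$chisq)
  expect_error(logrank_test(rep("a", 6), tt, ee), "two non-empty groups")
})

test_that("Cox fit matches a brute-force partial-likelihood maximizer", {
  set.seed(7)
  x <- rep(c(0, 1), each = 5)
  time <- c(2, 4, 6, 8, 10, 1, 3, 5, 7, 9) + runif(10, 0, 0.1)
  event <- c(1, 1, 0, 1, 1, 1, 1, 1, 0, 1)
  fit <- cox_fit(data.frame(x = x), time, event)
  oracle <- optimize(function(b) breslow_loglik(b, x, time, event),
                     c(-5, 5), maximum = TRUE, tol = 1e-10)
  expect_equal(fit$table$coef, oracle$maximum, tolerance = 1e-6)
  expect_equal(fit$table$hr, exp(fit$table$coef))
  expect_true(fit$table$ci_lower < fit$table$hr,
              fit$table$hr < fit$table$ci_upper)
})

test_that("log-rank chi-square equals the Cox score test for a binary group", {
  # the identity holds exactly for tie-free event times
  for (k in 1:5) {
    fx <- random_survival(40, seed = k + 50, tie_prob = 0)
    grp <- rep(c(0, 1), each = 20)
    lr <- logrank_test(grp, fx$time, fx$event)
    cf <- cox_fit(data.frame(grp = grp), fx$time, fx$event)
    expect_equal(lr$chisq, cf$sctest[1], tolerance = 1e-6)
  }
})

test_that("a null binary covariate yields HR near 1", {
  set.seed(11)
  n <- 200
  time <- rexp(n, 0.1); event <- rbinom(n, 1, 0.7)
  fit <- cox_fit(data.frame(g = rep(0:1, n / 2)), time, event)
  expect_lt(abs(fit$table$coef), 0.05 + 2 * sqrt(diag(fit$fit$var)))
  expect_error(cox_fit(data.frame(g = rep(1, n)), time, event), "constant")
})

test_that("a covariate that perfectly orders events is reported as separation", {
  time <- 1:10
  event <- rep(1, 10)
  x <- 10:1  # risk score identical to reverse event order
  suppressWarnings(
    expect_error(cox_fit(data.frame(x = x), time, event), "separation"))
})

test_that("Cox recovers a known log-hazard ratio in simulation", {
  hits <- 0
  for (k in 1:50) {
    set.seed(k + 300)
    n <- 500
    x <- rnorm(n)
    t_ev <- rexp(n, rate = 0.05 * exp(0.7 * x))
    cens <- rexp(n, rate = 0.05 * 0.43)  # ~30% censoring
    time <- pmin(t_ev, cens); event <- as.integer(t_ev <= cens)
    fit <- cox_fit(data.frame(x = x), time, event)
    if (abs(fit$table$coef - 0.7) < 0.15) hits <- hits + 1
  }
  expect_gte(hits, 45)
})

test_that("the CTX analysis filters, stratifies and skips degenerate strata", {
  set.seed(21)
  n <- 80
  clin <- data.frame(sample = sprintf("s%02d", 1:n),
                     time = rexp(n, 0.05) + 1, event = rbinom(n, 1, 0.5),
                     stage = rep(c("II", "III"), n / 2), age = 65,
                     gender = "M", ctx = rbinom(n, 1, 0.5))
  scores <- rnorm(n)
  res <- suppressWarnings(ctx_benefit_analysis(scores, clin))
  for (stratum in res) {
    if (!is.null(stratum)) {
      expect_true(is.finite(stratum$cox$table$hr))
      expect_true(stratum$n_ctx >= 2)
    }
  }
  # no stage III at all: error
  clin2 <- clin; clin2$stage <- "II"
  expect_error(ctx_benefit_analysis(scores, clin2), "stage III")
  # CTX constant within a stratum: that stratum is skipped with a warning
  clin3 <- clin; clin3$ctx <- 1
  # both strata skip, so two warnings are raised
  expect_warning(
    expect_warning(res3 <- ctx_benefit_analysis(scores, clin3), "skipped"),
    "skipped")
  expect_true(is.null(res3$low_risk) && is.null(res3$high_risk))
})
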