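test_that("comparable pairs follow the censored-ranking rule", {
  # all events, distinct times: every earlier-later ordering is a pair
  p <- comparable_pairs(c(1, 2, 3), c(1, 1, 1))
  expect_equal(nrow(p), 3L)
  expect_equal(p, rbind(c(i = 1L, j = 2L), c(1L, 3L), c(2L, 3L)),
               ignore_attr = "dimnames")
  # a censored sample cannot be the earlier member
  p2 <- comparable_pairs(c(1, 2, 3), c(1, 0, 1))
  expect_equal(unname(p2), rbind(c(1L, 2L), c(1L, 3L)))
  # all censored: no pairs
  expect_equal(nrow(comparable_pairs(c(1, 2, 3), c(0, 0, 0))), 0L)
  # tied times are not comparable
  expect_equal(nrow(comparable_pairs(c(2, 2), c(1, 1))), 0L)
})

test_that("a separable one-gene ranking problem is fit to training C-index 1", {
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  X <- matrix(-time + rnorm(8, sd = 1e-3), nrow = 1,
              dimnames = list("g1", paste0("s", 1:8)))
  m <- fit_ssvm(X, time, rep(1, 8), cost = 10, sigma = 2)
  expect_equal(concordance_index(m$training_scores, time, rep(1, 8)), 1)
  # higher score = shorter survival
  expect_true(cor(m$training_scores, time, method = "spearman") < 0)
})

test_that("scoring the training set reproduces the stored training scores", {
  set.seed(1)
  X <- matrix(rnorm(200), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
  time <- rexp(20, 0.1); event <- rbinom(20, 1, 0.8)
  m <- fit_ssvm(X, time, event, cost = 1, sigma = 3)
  expect_equal(unname(predict_risk_scores(m, X)), m$training_scores,
               tolerance = 1e-10)
})

test_that("duplicating every sample leaves the fitted score function unchanged", {
  set.seed(2)
  X <- matrix(rnorm(80), nrow = 8,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
  time <- c(1.5, 3, 4.2, 5, 6.3, 7, 8.8, 9, 10.1, 12)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1, 1, 0)
  Xd <- cbind(X, X); colnames(Xd) <- paste0("d", 1:20)
  ctrl <- list(maxit = 2000L, factr = 10)
  m1 <- fit_ssvm(X, time, event, cost = 1, sigma = 2, control = ctrl)
  m2 <- fit_ssvm(Xd, c(time, time), c(event, event), cost = 1, sigma = 2,
                 control = ctrl)
  X_new <- matrix(rnorm(40), nrow = 8, dimnames = list(paste0("g", 1:8),
                                                       paste0("t", 1:5)))
  expect_lt(max(abs(predict_risk_scores(m1, X_new) -
                      predict_risk_scores(m2, X_new))), 1e-8)
})

test_that("kernel scores depend on expression only through distances", {
  set.seed(3)
  X <- matrix(rnorm(60), nrow = 6,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  time <- sort(rexp(10, 0.1)); event <- rep(1, 10)
  m <- fit_ssvm(X, time, event, cost = 1, sigma = 2)
  X_test <- matrix(rnorm(30), nrow = 6, dimnames = list(paste0("g", 1:6),
                                                        paste0("t", 1:5)))
  base <- predict_risk_scores(m, X_test)
  # adding a gene that is zero everywhere changes no distance, hence no score
  X0 <- rbind(X, g7 = 0); X_test0 <- rbind(X_test, g7 = 0)
  m0 <- fit_ssvm(X0, time, event, cost = 1, sigma = 2)
  expect_equal(predict_risk_scores(m0, X_test0), base, tolerance = 1e-8)
  # consistent gene relabeling in train and test leaves scores unchanged
  relab <- paste0("h", 1:6)
  Xr <- X; rownames(Xr) <- relab
  Xtr <- X_test; rownames(Xtr) <- relab
  mr <- fit_ssvm(Xr, time, event, cost = 1, sigma = 2)
  expect_equal(unname(predict_risk_scores(mr, Xtr)), unname(base),
               tolerance = 1e-10)
  # identical test samples get identical scores
  X_twin <- X_test[, c(1, 1)]; colnames(X_twin) <- c("a", "b")
  tw <- predict_risk_scores(m, X_twin)
  expect_identical(tw[["a"]], tw[["b"]])
})

test_that("missing test genes are imputed as zero with a warning", {
  set.seed(4)
  X <- matrix(rnorm(60), nrow = 6,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  time <- sort(rexp(10, 0.1)); event <- rep(1, 10)
  m <- fit_ssvm(X, time, event, cost = 1, sigma = 2)
  X_test <- matrix(rnorm(30), nrow = 6, dimnames = list(paste0("g", 1:6),
                                                        paste0("t", 1:5)))
  expect_warning(sc <- predict_risk_scores(m, X_test[1:4, ]), "imputed")
  X_zeroed <- X_test; X_zeroed[5:6, ] <- 0
  expect_equal(sc, predict_risk_scores(m, X_zeroed))
  expect_error(predict_risk_scores(m, matrix(0, 1, 1,
                                             dimnames = list("zz", "t"))),
               "no training gene")
})

test_that("fitting without comparable pairs is an error", {
  X <- matrix(rnorm(10), nrow = 2, dimnames = list(c("g1", "g2"), NULL))
  expect_error(fit_ssvm(X, 1:5, rep(0, 5), cost = 1, sigma = 1),
               "no comparable pairs")
})

test_that("median stratification splits below/above with median going low", {
  expect_equal(as.character(median_stratify(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(as.character(median_stratify(c(1, 2, 3))),
               c("low", "low", "high"))
  # invariant to strictly monotone transforms
  s <- c(0.3, -1.2, 2.5, 0.9, -0.4)
  expect_equal(median_stratify(s), median_stratify(exp(s)))
  expect_equal(median_stratify(s), median_stratify(rank(s)))
  expect_error(median_stratify(c(2, 2, 2)), "identical")
})

test_that("a single-cell grid is selected trivially and CV is seed-reproducible", {
  set.seed(5)
  X <- matrix(rnorm(300), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:30)))
  time <- rexp(30, 0.1); event <- rbinom(30, 1, 0.8)
  cv1 <- grid_search_cv(X, time, event, cost_grid = 1, sigma_grid = 2,
                        folds = 3, repeats = 2, seed = 7)
  expect_equal(nrow(cv1$cv_table), 1L)
  expect_equal(cv1$best$cost, 1)
  expect_equal(cv1$best$sigma, 2)
  cv2 <- grid_search_cv(X, time, event, cost_grid = 1, sigma_grid = 2,
                        folds = 3, repeats = 2, seed = 7)
  expect_identical(cv1$cv_table, cv2$cv_table)
  expect_identical(cv1$fold_cindex, cv2$fold_cindex)
})

test_that("grid ties break toward the smallest cost, then smallest sigma", {
  # all-censored-but-identical data make every cell equally (un)informative;
  # instead verify the ordering contract directly on the returned table
  set.seed(6)
  X <- matrix(rnorm(150), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:30)))
  time <- rexp(30, 0.1); event <- rbinom(30, 1, 0.8)
  cv <- grid_search_cv(X, time, event, cost_grid = c(10, 0.1),
                       sigma_grid = c(5, 0.5), folds = 3, repeats = 2,
                       seed = 8)
  expect_equal(cv$cv_table$cost, c(0.1, 0.1, 10, 10))
  expect_equal(cv$cv_table$sigma, c(0.5, 5, 0.5, 5))
  best_rows <- which(cv$cv_table$mean_cindex == max(cv$cv_table$mean_cindex))
  expect_equal(c(cv$best$cost, cv$best$sigma),
               unlist(cv$cv_table[best_rows[1], c("cost", "sigma")],
                      use.names = FALSE))
})
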