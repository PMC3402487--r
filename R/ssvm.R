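#' Comparable sample pairs under right censoring
#'
#' An ordered pair (i, j) is comparable when t_i < t_j and sample i's event
#' is observed: i demonstrably failed before j was observed to fail or be
#' censored. Pairs with tied times are not comparable.
#'
#' @param time survival/censoring times.
#' @param event event indicator (1 observed, 0 censored).
#' @return two-column integer matrix (columns \code{i}, \code{j}) of row
#'   indices; zero rows when no pair is comparable.
#' @export
comparable_pairs <- function(time, event) {
  stopifnot(length(time) == length(event))
  cmp <- outer(time, time, "<") & (event == 1)
  idx <- which(cmp, arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

# Squared Euclidean distances between rows of a (and rows of b).
.sq_dist <- function(a, b = a) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

.gauss_kernel <- function(d2, sigma) exp(-d2 / (2 * sigma^2))

# Fit ranking coefficients beta on a precomputed training kernel.
# Objective (convex, smooth): 0.5 * t(b) K b + jitter/2 * ||b||^2 +
#   (cost / n_pairs) * sum_p max(0, 1 - (u_i - u_j))^2, u = K b,
# where pairs run over comparable pairs (i shorter survival than j) so the
# fitted score increases with risk. The mean over pairs (rather than the sum)
# makes the fitted score function invariant to sample duplication.
.fit_beta <- function(K, pairs, cost, jitter = 1e-9,
                      control = list(maxit = 500L, factr = 1e4)) {
  n <- nrow(K)
  if (nrow(pairs) == 0L) stop("no comparable pairs; cannot fit the ranking model")
  pi <- pairs[, 1L]; pj <- pairs[, 2L]
  w <- cost / nrow(pairs)
  fn <- function(b) {
    u <- as.numeric(K %*% b)
    h <- pmax(0, 1 - (u[pi] - u[pj]))
    0.5 * sum(b * u) + 0.5 * jitter * sum(b^2) + w * sum(h^2)
  }
  gr <- function(b) {
    u <- as.numeric(K %*% b)
    h <- pmax(0, 1 - (u[pi] - u[pj]))
    gu <- numeric(n)
    act <- h > 0
    if (any(act)) {
      gi <- -2 * w * h[act]
      gu <- gu + .accumulate(pi[act], gi, n) + .accumulate(pj[act], -gi, n)
    }
    as.numeric(K %*% (b + gu)) + jitter * b
  }
  opt <- stats::optim(numeric(n), fn, gr, method = "L-BFGS-B",
                      control = control)
  if (!opt$convergence %in% c(0L, 1L)) {
    stop("SSVM solver failed: ", opt$message)
  }
  opt$par
}

.accumulate <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Fit a Gaussian-kernel survival SVM (ranking formulation)
#'
#' Learns a per-sample risk score u(x) = sum_k beta_k K(x_k, x) by
#' penalizing, with a smooth squared hinge, every comparable pair whose
#' score difference fails the margin u_i - u_j >= 1 (i the shorter-lived,
#' event-observed member). Higher fitted scores mean higher risk and shorter
#' expected survival. The kernel is K(x, y) = exp(-||x - y||^2 / (2 sigma^2)).
#'
#' @param X gene-by-sample expression matrix (samples in columns).
#' @param time,event survival data aligned with the columns of \code{X}.
#' @param cost penalty weight c for margin violations.
#' @param sigma Gaussian kernel width.
#' @param max_pairs cap on the number of comparable pairs; beyond it a
#'   seeded subsample is used (default 50000, rarely reached at desk scale).
#' @param pair_seed seed for the pair subsample.
#' @param control optimizer control passed to \code{stats::optim}.
#' @return object of class \code{ssvm_model}: \code{beta}, \code{cost},
#'   \code{sigma}, \code{genes}, \code{X_train}, \code{training_scores}.
#' @export
fit_ssvm <- function(X, time, event, cost = 1, sigma = 1,
                     max_pairs = 50000L, pair_seed = 1L,
                     control = list(maxit = 500L, factr = 1e4)) {
  stopifnot(is.matrix(X), ncol(X) == length(time), length(time) == length(event))
  if (anyNA(X)) stop("expression matrix contains missing values")
  pairs <- comparable_pairs(time, event)
  if (nrow(pairs) == 0L) stop("no comparable pairs; cannot fit the ranking model")
  if (nrow(pairs) > max_pairs) {
    set.seed(pair_seed)
    pairs <- pairs[sample.int(nrow(pairs), max_pairs), , drop = FALSE]
  }
  x <- t(X)
  K <- .gauss_kernel(.sq_dist(x), sigma)
  beta <- .fit_beta(K, pairs, cost, control = control)
  structure(list(beta = beta, cost = cost, sigma = sigma,
                 genes = rownames(X), X_train = X,
                 training_scores = as.numeric(K %*% beta),
                 n_pairs = nrow(pairs)),
            class = "ssvm_model")
}

#' Predict risk scores for new samples
#'
#' Test genes are matched to the training gene order; signature genes
#' missing from the test matrix are imputed as 0 (the post-z-score mean)
#' with a warning.
#'
#' @param model an \code{ssvm_model}.
#' @param X_test gene-by-sample matrix.
#' @return named numeric vector of risk scores (one per test sample).
#' @export
predict_risk_scores <- function(model, X_test) {
  stopifnot(inherits(model, "ssvm_model"), is.matrix(X_test))
  genes <- model$genes
  present <- intersect(genes, rownames(X_test))
  if (length(present) == 0L) stop("no training gene measured in the test matrix")
  if (length(present) < length(genes)) {
    warning(length(genes) - length(present),
            " training gene(s) missing in test data; imputed as 0")
  }
  Xm <- matrix(0, nrow = length(genes), ncol = ncol(X_test),
               dimnames = list(genes, colnames(X_test)))
  Xm[present, ] <- X_test[present, , drop = FALSE]
  d2 <- .sq_dist(t(Xm), t(model$X_train))
  scores <- as.numeric(.gauss_kernel(d2, model$sigma) %*% model$beta)
  stats::setNames(scores, colnames(X_test))
}

#' Cross-validated grid search over (cost, sigma)
#'
#' Evaluates every combination of the candidate cost and kernel-width values
#' by k-fold cross-validation repeated \code{repeats} times, scoring each
#' held-out fold by the concordance index, and refits the model on the full
#' data at the cell with the best mean C-index. Folds are stratified by
#' event status; ties in the grid are broken toward the smallest cost, then
#' the smallest sigma. Folds whose training part has no comparable pair, or
#' whose test part supports no C-index, are skipped with a warning.
#'
#' @param X gene-by-sample matrix.
#' @param time,event survival data.
#' @param cost_grid,sigma_grid candidate values; default 10^(-5:5) each
#'   (121 cells).
#' @param folds,repeats cross-validation layout (default 5 x 5).
#' @param seed RNG seed controlling fold assignment.
#' @param control optimizer control for the in-fold fits (looser than the
#'   final fit by default).
#' @return object of class \code{ssvm_cv}: \code{cv_table} (cost, sigma,
#'   mean_cindex, sd_cindex, n_folds), \code{fold_cindex} (cells x folds
#'   matrix), \code{best} (selected cost/sigma/mean), \code{model} (final
#'   \code{ssvm_model} refit on all samples).
#' @export
grid_search_cv <- function(X, time, event,
                           cost_grid = 10^(-5:5), sigma_grid = 10^(-5:5),
                           folds = 5L, repeats = 5L, seed = 1L,
                           control = list(maxit = 200L, factr = 1e7)) {
  stopifnot(is.matrix(X), ncol(X) == length(time))
  n <- ncol(X)
  if (sum(event == 1) < 2L) stop("too few events for cross-validation")
  cost_grid <- sort(cost_grid)
  sigma_grid <- sort(sigma_grid)
  cells <- expand.grid(sigma = sigma_grid, cost = cost_grid,
                       KEEP.OUT.ATTRS = FALSE)[, c("cost", "sigma")]
  x <- t(X)
  D2 <- .sq_dist(x)

  set.seed(seed)
  fold_of <- matrix(NA_integer_, nrow = n, ncol = repeats)
  for (rep_k in seq_len(repeats)) {
    f <- integer(n)
    for (ev in unique(event)) {
      idx <- which(event == ev)
      f[idx] <- rep_len(seq_len(folds), length(idx))[sample.int(length(idx))]
    }
    fold_of[, rep_k] <- f
  }

  n_fold_total <- folds * repeats
  fold_c <- matrix(NA_real_, nrow = nrow(cells), ncol = n_fold_total)
  col_k <- 0L
  for (rep_k in seq_len(repeats)) {
    for (fold_k in seq_len(folds)) {
      col_k <- col_k + 1L
      te <- which(fold_of[, rep_k] == fold_k)
      tr <- setdiff(seq_len(n), te)
      pairs_tr <- comparable_pairs(time[tr], event[tr])
      if (nrow(pairs_tr) == 0L) {
        warning("fold ", fold_k, " of repeat ", rep_k,
                " skipped: no comparable training pairs")
        next
      }
      test_ok <- nrow(comparable_pairs(time[te], event[te])) > 0L
      if (!test_ok) {
        warning("fold ", fold_k, " of repeat ", rep_k,
                " skipped: held-out fold supports no concordance index")
        next
      }
      for (sig_k in seq_along(sigma_grid)) {
        sigma <- sigma_grid[sig_k]
        K <- .gauss_kernel(D2, sigma)
        K_tr <- K[tr, tr, drop = FALSE]
        K_te <- K[te, tr, drop = FALSE]
        for (cost_k in seq_along(cost_grid)) {
          cost <- cost_grid[cost_k]
          row_k <- (cost_k - 1L) * length(sigma_grid) + sig_k
          beta <- tryCatch(
            .fit_beta(K_tr, pairs_tr, cost, control = control),
            error = function(e) NULL)
          if (is.null(beta)) next
          sc <- as.numeric(K_te %*% beta)
          fold_c[row_k, col_k] <- concordance_index(sc, time[te], event[te])
        }
      }
    }
  }
  if (all(is.na(fold_c))) stop("every cross-validation fold was skipped")

  cells$mean_cindex <- rowMeans(fold_c, na.rm = TRUE)
  cells$sd_cindex <- apply(fold_c, 1L, stats::sd, na.rm = TRUE)
  cells$n_folds <- rowSums(!is.na(fold_c))
  # cells are ordered by (cost, sigma) ascending; which.max takes the first
  # maximum, implementing the smallest-cost-then-smallest-sigma tie-break
  best_k <- which.max(cells$mean_cindex)
  best <- cells[best_k, ]
  model <- fit_ssvm(X, time, event, cost = best$cost, sigma = best$sigma)
  structure(list(cv_table = cells, fold_cindex = fold_c,
                 best = list(cost = best$cost, sigma = best$sigma,
                             mean_cindex = best$mean_cindex),
                 folds = folds, repeats = repeats, seed = seed,
                 model = model),
            class = "ssvm_cv")
}

#' Median split of risk scores into low-/high-risk groups
#'
#' Scores strictly above the median go to the high-risk group; scores at or
#' below the median go to the low-risk group (samples exactly at the median
#' are assigned low, a deterministic and treatment-conservative choice).
#'
#' @param scores numeric risk scores (length >= 2, not all identical).
#' @return factor with levels \code{"low"}, \code{"high"}.
#' @export
median_stratify <- function(scores) {
  stopifnot(length(scores) >= 2L)
  if (length(unique(scores)) == 1L) {
    stop("all scores identical; median stratification impossible")
  }
  med <- stats::median(scores)
  factor(ifelse(scores > med, "high", "low"), levels = c("low", "high"))
}

#' @export
print.ssvm_model <- function(x, ...) {
  cat("ssvm_model: Gaussian kernel, sigma = ", format(x$sigma),
      ", cost = ", format(x$cost), "; ", length(x$beta),
      " training samples, ", length(x$genes), " genes, ",
      x$n_pairs, " comparable pairs\n", sep = "")
  invisible(x)
}

#' @export
print.ssvm_cv <- function(x, ...) {
  cat("ssvm_cv: ", nrow(x$cv_table), " grid cells, ", x$folds, "-fold x ",
      x$repeats, " repeats\n  selected cost = ", format(x$best$cost),
      ", sigma = ", format(x$best$sigma), " (mean CV C-index ",
      round(x$best$mean_cindex, 3), ")\n", sep = "")
  invisible(x)
}
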