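#' Random walk with restart (iterative)
#'
#' Iterates p_{t+1} = (1 - r) W p_t + r p0 from p0 until the L1 change
#' between successive iterates drops below \code{tol}. With a
#' column-stochastic W the iteration conserves total probability and is a
#' contraction with factor (1 - r), so it converges geometrically; r = 0.5
#' typically converges in a few tens of iterations.
#'
#' @param network an \code{interaction_network} with W populated (see
#'   \code{\link{column_normalize}}); if W is missing it is computed.
#' @param p0 a \code{start_probabilities} object or a named numeric vector
#'   over the network nodes summing to 1.
#' @param r restart probability in (0, 1]; default 0.5.
#' @param tol L1 convergence threshold; default 1e-6.
#' @param max_iter iteration guard; default 10000.
#' @return object of class \code{walk_result}: \code{scores} (named numeric,
#'   sums to 1), \code{iterations}, \code{residual}, \code{r}.
#' @export
rwr_iterate <- function(network, p0, r = 0.5, tol = 1e-6, max_iter = 10000L) {
  W <- .get_W(network)
  p0v <- .get_p0(p0, network)
  if (r <= 0 || r > 1) stop("restart probability r must be in (0, 1]")
  p <- p0v
  for (it in seq_len(max_iter)) {
    p_new <- as.numeric((1 - r) * (W %*% p)) + r * p0v
    res <- sum(abs(p_new - p))
    p <- p_new
    if (res < tol) {
      return(structure(list(scores = stats::setNames(p, network$nodes),
                            iterations = it, residual = res, r = r),
                       class = "walk_result"))
    }
  }
  stop("random walk did not converge in ", max_iter,
       " iterations (last L1 residual ", format(res), ")")
}

#' Random walk with restart (exact linear solve)
#'
#' Solves the stationarity condition (I - (1 - r) W) p = r p0 directly.
#' Serves as an oracle for \code{\link{rwr_iterate}}; the system is
#' nonsingular for r > 0 because the spectral radius of (1 - r) W is below 1.
#'
#' @inheritParams rwr_iterate
#' @return a \code{walk_result} with \code{iterations = 0}.
#' @export
rwr_solve_exact <- function(network, p0, r = 0.5) {
  W <- .get_W(network)
  p0v <- .get_p0(p0, network)
  if (r <= 0 || r > 1) stop("restart probability r must be in (0, 1] for the exact solve")
  n <- length(p0v)
  A <- Matrix::Diagonal(n) - (1 - r) * W
  p <- as.numeric(Matrix::solve(A, r * p0v))
  structure(list(scores = stats::setNames(p, network$nodes),
                 iterations = 0L, residual = 0, r = r),
            class = "walk_result")
}

# Batched RWR: columns of P0 are independent start vectors, iterated jointly
# until every column's L1 change is below tol. Used for permutation nulls.
.rwr_iterate_matrix <- function(W, P0, r = 0.5, tol = 1e-6, max_iter = 10000L) {
  P <- P0
  for (it in seq_len(max_iter)) {
    P_new <- (1 - r) * as.matrix(W %*% P) + r * P0
    res <- max(colSums(abs(P_new - P)))
    P <- P_new
    if (res < tol) return(P)
  }
  stop("batched random walk did not converge in ", max_iter, " iterations")
}

.get_W <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  if (is.null(network$W)) network <- column_normalize(network)
  network$W
}

.get_p0 <- function(p0, network) {
  v <- if (inherits(p0, "start_probabilities")) p0$p0 else p0
  if (length(v) != length(network$nodes)) {
    stop("start-probability vector length does not match the network")
  }
  if (!is.null(names(v)) && !identical(names(v), network$nodes)) {
    stop("start-probability node order does not match the network")
  }
  if (any(v < 0) || abs(sum(v) - 1) > 1e-9) {
    stop("start probabilities must be non-negative and sum to 1")
  }
  as.numeric(v)
}

#' Write walk scores as a ranked TSV
#'
#' @param walk a \code{walk_result}.
#' @param path output path; columns gene, score, rank.
#' @export
write_walk_scores <- function(walk, path) {
  stopifnot(inherits(walk, "walk_result"))
  ord <- order(-walk$scores, names(walk$scores))
  tab <- data.frame(gene = names(walk$scores)[ord],
                    score = unname(walk$scores[ord]),
                    rank = seq_along(ord))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.walk_result <- function(x, ...) {
  cat("walk_result: ", length(x$scores), " nodes, r = ", x$r,
      ", iterations = ", x$iterations,
      ", final L1 residual = ", format(x$residual), "\n", sep = "")
  invisible(x)
}
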