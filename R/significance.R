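#' Generate a permutation null for walk scores
#'
#' Shuffles the whole start-probability vector across network nodes
#' \code{n_perm} times and runs the random walk on every permuted vector
#' (jointly, as columns of a batched iteration). Each permutation preserves
#' the multiset of start probabilities, so the null keeps the seed weight
#' profile but breaks its placement on the network.
#'
#' @param network an \code{interaction_network}.
#' @param p0 a \code{start_probabilities} object or valid named vector.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for reproducibility.
#' @param r,tol walk parameters passed to the iteration.
#' @return object of class \code{permutation_null}: \code{scores}
#'   (nodes x n_perm matrix), \code{nodes}, \code{n_perm}, \code{seed}.
#' @export
permute_start_probabilities <- function(network, p0, n_perm = 1000L,
                                        seed = 1L, r = 0.5, tol = 1e-6) {
  stopifnot(n_perm >= 1L)
  W <- .get_W(network)
  p0v <- .get_p0(p0, network)
  n <- length(p0v)
  set.seed(seed)
  P0 <- vapply(seq_len(n_perm), function(k) p0v[sample.int(n)], numeric(n))
  scores <- .rwr_iterate_matrix(W, P0, r = r, tol = tol)
  rownames(scores) <- network$nodes
  structure(list(scores = scores, nodes = network$nodes,
                 n_perm = n_perm, seed = seed, r = r),
            class = "permutation_null")
}

#' Empirical local and global p-values for walk scores
#'
#' The local p-value compares a gene's real walk score with that same gene's
#' scores across permuted-seed walks (controlling for network topology: hubs
#' have high scores under any seeding). The global p-value compares the real
#' score with the pooled scores of all genes across permutations. Both use
#' the add-one empirical rule, so p-values are never zero and lie in
#' (0, 1].
#'
#' @param real a \code{walk_result} from the observed seeds.
#' @param null a \code{permutation_null} built on the same network.
#' @return object of class \code{significance_result}: data frame
#'   \code{table} with columns gene, score, local_p, global_p, plus
#'   \code{n_perm}.
#' @export
empirical_p_values <- function(real, null) {
  stopifnot(inherits(real, "walk_result"), inherits(null, "permutation_null"))
  if (!identical(names(real$scores), null$nodes)) {
    stop("node order of the real walk does not match the permutation null")
  }
  x <- as.numeric(real$scores)
  n_perm <- null$n_perm
  local_ge <- rowSums(null$scores >= x)
  local_p <- (1 + local_ge) / (n_perm + 1)

  pooled <- sort(as.numeric(null$scores))
  n_pool <- length(pooled)
  global_ge <- n_pool - findInterval(x, pooled, left.open = TRUE)
  global_p <- (1 + global_ge) / (n_pool + 1)

  structure(list(
    table = data.frame(gene = null$nodes, score = x,
                       local_p = local_p, global_p = global_p,
                       stringsAsFactors = FALSE),
    n_perm = n_perm
  ), class = "significance_result")
}

#' Call the significant gene set from dual permutation p-values
#'
#' A gene is significant when both its local and its global p-value are
#' below \code{alpha}. The result is split by provenance into genes that
#' were seeds and genes added by the network propagation.
#'
#' @param sig_result a \code{significance_result}.
#' @param alpha dual p-value cutoff in (0, 1]; default 0.05.
#' @param seed_genes character vector of seed genes (for the provenance
#'   split); may be NULL.
#' @return object of class \code{derived_signature}: \code{genes} (sorted),
#'   \code{from_seeds}, \code{network_added}, \code{alpha}, \code{table}
#'   (per-gene table with significant + provenance columns).
#' @export
derive_signature <- function(sig_result, alpha = 0.05, seed_genes = NULL) {
  stopifnot(inherits(sig_result, "significance_result"),
            alpha > 0, alpha <= 1)
  tab <- sig_result$table
  # strict dual-p rule; alpha = 1 is the degenerate keep-everything cutoff
  # (empirical p-values are capped at 1, never above)
  tab$significant <- if (alpha >= 1) rep(TRUE, nrow(tab)) else
    tab$local_p < alpha & tab$global_p < alpha
  tab$provenance <- ifelse(tab$gene %in% seed_genes, "seed", "network_added")
  genes <- sort(tab$gene[tab$significant])
  structure(list(
    genes = genes,
    from_seeds = intersect(genes, seed_genes),
    network_added = setdiff(genes, seed_genes),
    alpha = alpha,
    table = tab
  ), class = "derived_signature")
}

#' Dice's coefficient between two gene sets
#'
#' @param a,b character vectors (treated as sets).
#' @return 2|a intersect b| / (|a| + |b|), in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L && length(b) == 0L) {
    stop("Dice's coefficient is undefined for two empty sets")
  }
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Leave-one-signature-out robustness of the derived signature
#'
#' Re-derives the significant gene set with each expression signature held
#' out in turn and reports Dice's coefficient of every hold-out set against
#' the full-evidence set.
#'
#' @param network an \code{interaction_network}.
#' @param signatures named list of gene sets (>= 2).
#' @param mutations named variant-count vector.
#' @param alpha dual p-value cutoff.
#' @param n_perm permutations per run.
#' @param seed RNG seed (the same null seed is used for every run so that
#'   set differences reflect the held-out evidence, not Monte-Carlo noise).
#' @param r,tol walk parameters.
#' @return list with \code{full} (the full \code{derived_signature}),
#'   \code{holdout_signatures} (named list of gene sets), \code{dice}
#'   (named numeric), and \code{summary} (min/mean/max of Dice).
#' @export
leave_one_signature_out <- function(network, signatures, mutations,
                                    alpha = 0.05, n_perm = 1000L, seed = 1L,
                                    r = 0.5, tol = 1e-6) {
  stopifnot(length(signatures) >= 2L)
  run_once <- function(sigs) {
    p0 <- compute_start_probabilities(network, sigs, mutations, mode = "NEM")
    real <- rwr_iterate(network, p0, r = r, tol = tol)
    null <- permute_start_probabilities(network, p0, n_perm = n_perm,
                                        seed = seed, r = r, tol = tol)
    derive_signature(empirical_p_values(real, null), alpha = alpha,
                     seed_genes = p0$seed_genes)
  }
  full <- run_once(signatures)
  holdouts <- lapply(seq_along(signatures), function(k) {
    run_once(signatures[-k])$genes
  })
  names(holdouts) <- names(signatures)
  dice <- vapply(holdouts, dice_coefficient, numeric(1), b = full$genes)
  list(full = full, holdout_signatures = holdouts, dice = dice,
       summary = c(min = min(dice), mean = mean(dice), max = max(dice)))
}

#' Write a significance table as TSV
#'
#' @param signature a \code{derived_signature}.
#' @param path output path.
#' @export
write_significance_table <- function(signature, path) {
  stopifnot(inherits(signature, "derived_signature"))
  utils::write.table(signature$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.derived_signature <- function(x, ...) {
  cat("derived_signature: ", length(x$genes), " significant gene(s) at ",
      "dual p < ", x$alpha, " (", length(x$from_seeds), " seed, ",
      length(x$network_added), " network-added)\n", sep = "")
  invisible(x)
}
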