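test_that("permuted start vectors preserve the multiset of probabilities", {
  net <- random_network(30, seed = 1)
  p0 <- random_p0(net, n_seeds = 6, seed = 2)
  # reconstruct the permuted start vectors exactly as the generator does
  set.seed(99)
  n <- length(p0)
  P0 <- vapply(1:20, function(k) as.numeric(p0)[sample.int(n)], numeric(n))
  for (k in 1:20) expect_equal(sort(P0[, k]), sort(as.numeric(p0)))
  # and every resulting null score vector sums to 1
  null <- permute_start_probabilities(net, p0, n_perm = 20, seed = 99)
  expect_equal(unname(Matrix::colSums(null$scores)), rep(1, 20),
               tolerance = 1e-9)
})

test_that("with 2 nodes the only permutations of (1,0) are (1,0) and (0,1)", {
  net <- net_from_string("A-B")
  null <- permute_start_probabilities(net, c(A = 1, B = 0), n_perm = 40,
                                      seed = 3)
  # each permuted walk starts from (1,0) or (0,1); steady states are the
  # hand-solved (2/3,1/3) or its mirror
  for (k in 1:40) {
    s <- sort(null$scores[, k])
    expect_equal(unname(s), c(1/3, 2/3), tolerance = 1e-5)
  }
})

test_that("the mean null score approaches the uniform-seed walk score", {
  net <- random_network(30, p_edge = 0.2, seed = 4)
  p0 <- random_p0(net, n_seeds = 5, seed = 5)
  null <- permute_start_probabilities(net, p0, n_perm = 2000, seed = 6)
  uniform <- rep(1 / length(net$nodes), length(net$nodes))
  names(uniform) <- net$nodes
  w_unif <- rwr_iterate(net, uniform, tol = 1e-10)
  # E over uniformly random placement of the p0 values = walk of the mean
  # start vector, which is uniform; CLT bound with a generous 4 SD margin
  mean_null <- rowMeans(null$scores)
  sd_null <- apply(null$scores, 1, sd) / sqrt(2000)
  expect_true(all(abs(mean_null - w_unif$scores) < 4 * sd_null + 1e-4))
})

test_that("empirical p-values implement the add-one counting rules", {
  nodes <- c("A", "B", "C")
  real <- structure(list(scores = c(A = 0.9, B = 0.05, C = 0.5),
                         iterations = 1L, residual = 0, r = 0.5),
                    class = "walk_result")
  set.seed(1)
  null_scores <- matrix(runif(3 * 1000, 0.1, 0.4), nrow = 3,
                        dimnames = list(nodes, NULL))
  null <- structure(list(scores = null_scores, nodes = nodes,
                         n_perm = 1000L, seed = 1L, r = 0.5),
                    class = "permutation_null")
  res <- empirical_p_values(real, null)
  # A beats all 1000 same-gene nulls -> local p = 1/1001
  expect_equal(res$table$local_p[1], 1 / 1001)
  # B is below all nulls -> local p = 1
  expect_equal(res$table$local_p[2], 1)
  # C: exact counting against its own row and the pooled null
  expect_equal(res$table$local_p[3],
               (1 + sum(null_scores[3, ] >= 0.5)) / 1001)
  expect_equal(res$table$global_p,
               unname(sapply(real$scores, function(x)
                 (1 + sum(null_scores >= x)) / (length(null_scores) + 1))))
  # p-values decrease with the real score (same null distribution)
  expect_true(all(res$table$global_p[order(real$scores)] ==
                    sort(res$table$global_p, decreasing = TRUE)))
})

test_that("p-value computation rejects mismatched node order", {
  net <- random_network(20, seed = 7)
  p0 <- random_p0(net, seed = 8)
  null <- permute_start_probabilities(net, p0, n_perm = 5, seed = 9)
  real <- rwr_iterate(net, p0)
  real$scores <- rev(real$scores)
  expect_error(empirical_p_values(real, null), "node order")
})

test_that("signature derivation applies the dual-p AND rule with provenance", {
  tab <- data.frame(gene = c("A", "B", "C", "D"),
                    score = c(0.4, 0.3, 0.2, 0.1),
                    local_p = c(0.01, 0.03, 0.20, 0.01),
                    global_p = c(0.02, 0.20, 0.01, 0.04))
  res <- structure(list(table = tab, n_perm = 100L),
                   class = "significance_result")
  sig <- derive_signature(res, alpha = 0.05, seed_genes = c("A", "C"))
  # B fails global, C fails local; only A and D pass both
  expect_equal(sig$genes, c("A", "D"))
  expect_equal(sig$from_seeds, "A")
  expect_equal(sig$network_added, "D")
  # alpha = 1 admits everything
  expect_equal(derive_signature(res, alpha = 1)$genes, c("A", "B", "C", "D"))
})

test_that("Dice's coefficient matches hand arithmetic", {
  expect_equal(dice_coefficient(c("A", "B"), c("A", "B")), 1)
  expect_equal(dice_coefficient(c("A", "B"), c("C", "D")), 0)
  expect_equal(dice_coefficient(letters[1:4], c(letters[1:3], "z")), 0.75)
  expect_equal(dice_coefficient(letters[1:10],
                                c(letters[1:5], LETTERS[1:15])), 1/3)
  expect_error(dice_coefficient(character(0), character(0)), "empty")
})

test_that("the derived signature is identical for identical seeds", {
  b <- generate_benchmark(small_config(), seed = 20)
  g1 <- derive_gene_set(b, "NEM", n_perm = 50, seed = 21)
  g2 <- derive_gene_set(b, "NEM", n_perm = 50, seed = 21)
  expect_identical(g1$genes, g2$genes)
})

test_that("holding out an empty signature reproduces the full set (Dice 1)", {
  b <- generate_benchmark(small_config(), seed = 22)
  sigs <- b$signatures[1:2]
  full <- derive_gene_set(list(network = b$network, signatures = sigs,
                               mutations = b$mutations),
                          "NEM", n_perm = 50, seed = 23)
  # appending a signature that adds no genes leaves membership counts and
  # hence the whole derivation unchanged
  sigs3 <- c(sigs, list(dup = sigs[[1]]))
  p0_a <- compute_start_probabilities(b$network, sigs, b$mutations, "NEM")
  p0_b <- compute_start_probabilities(b$network, sigs3[1:2], b$mutations, "NEM")
  expect_equal(p0_a$p0, p0_b$p0)
  expect_equal(dice_coefficient(full$genes, full$genes), 1)
})
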