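#' Configuration for the synthetic benchmark generator
#'
#' Defaults describe the emulated study conditions: a ~2000-gene scale-free
#' interactome with a planted, densely wired driver module; eight expression
#' signatures whose unique sizes follow the published collection
#' (8, 58, 26, 24, 19, 22, 34, 21 genes); a mutation catalog with Zipf-like
#' variant counts; and two independent 120-sample cohorts whose module genes
#' carry a latent prognostic signal, with roughly 30\% observed recurrences
#' and a chemotherapy benefit confined to high-risk patients (hazard ratio
#' 0.4).
#'
#' @param n_genes number of network genes.
#' @param attachment preferential-attachment edges per new node.
#' @param module_size planted driver-module size.
#' @param module_density target within-module edge density.
#' @param signature_sizes unique-gene counts of the emulated signatures.
#' @param signature_module_fraction fraction of each signature drawn from
#'   the module and its 1-hop neighborhood.
#' @param n_mutated_genes mutation-catalog size.
#' @param mutation_module_fraction fraction of mutated genes drawn from the
#'   module and its 1-hop neighborhood.
#' @param zipf_exponent variant-count distribution exponent.
#' @param n_samples samples per cohort.
#' @param beta log-hazard effect of the latent risk score.
#' @param baseline_hazard exponential baseline hazard (per month).
#' @param event_rate target fraction of observed events after censoring.
#' @param ctx_benefit_hr multiplicative hazard effect of adjuvant CTX in
#'   high-latent-risk patients (no effect in low-risk patients).
#' @param complementary split evidence channels over disjoint module halves
#'   (signatures from one half, mutations from the other)?
#' @return list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_genes = 2000L, attachment = 3L,
                             module_size = 80L, module_density = 0.10,
                             signature_sizes = c(8L, 58L, 26L, 24L, 19L,
                                                 22L, 34L, 21L),
                             signature_module_fraction = 0.5,
                             n_mutated_genes = 150L,
                             mutation_module_fraction = 0.4,
                             zipf_exponent = 2,
                             n_samples = 120L, beta = 1.0,
                             baseline_hazard = log(2) / 36,
                             event_rate = 0.30,
                             ctx_benefit_hr = 0.4,
                             complementary = FALSE) {
  cfg <- list(n_genes = n_genes, attachment = attachment,
              module_size = module_size, module_density = module_density,
              signature_sizes = signature_sizes,
              signature_module_fraction = signature_module_fraction,
              n_mutated_genes = n_mutated_genes,
              mutation_module_fraction = mutation_module_fraction,
              zipf_exponent = zipf_exponent,
              n_samples = n_samples, beta = beta,
              baseline_hazard = baseline_hazard, event_rate = event_rate,
              ctx_benefit_hr = ctx_benefit_hr,
              complementary = complementary)
  stopifnot(cfg$module_size < cfg$n_genes,
            all(cfg$signature_sizes <= cfg$n_genes),
            cfg$signature_module_fraction >= 0,
            cfg$signature_module_fraction <= 1,
            cfg$mutation_module_fraction >= 0,
            cfg$mutation_module_fraction <= 1,
            cfg$event_rate > 0, cfg$event_rate < 1)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a scale-free network with a planted driver module
#'
#' Grows a preferential-attachment backbone, then densifies a random subset
#' of \code{module_size} genes with extra within-module edges until the
#' module's internal edge density reaches the target. Gene identifiers are
#' zero-padded ("G0001", ...) so lexicographic node order is stable.
#'
#' @param config a \code{synthetic_config}.
#' @param seed RNG seed.
#' @return list with \code{network} (an \code{interaction_network}) and
#'   \code{module} (character vector of planted genes).
#' @export
generate_network <- function(config = synthetic_config(), seed = 1L) {
  set.seed(seed)
  n <- config$n_genes
  g <- igraph::sample_pa(n, m = config$attachment, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  gene_ids <- sprintf("G%0*d", nchar(as.character(n)), seq_len(n))

  module_idx <- sort(sample.int(n, config$module_size))
  # densify the module: add uniform within-module edges up to the target
  m <- config$module_size
  all_pairs <- t(utils::combn(module_idx, 2L))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  existing <- key(el[, 1L], el[, 2L])
  candidate <- !(key(all_pairs[, 1L], all_pairs[, 2L]) %in% existing)
  n_target <- ceiling(config$module_density * m * (m - 1) / 2)
  n_have <- sum(!candidate)
  if (n_target > n_have) {
    pick <- sample(which(candidate), min(n_target - n_have, sum(candidate)))
    el <- rbind(el, all_pairs[pick, , drop = FALSE])
  }

  edges <- cbind(gene_ids[el[, 1L]], gene_ids[el[, 2L]])
  net <- interaction_network(edges)
  list(network = column_normalize(net), module = gene_ids[module_idx])
}

# genes in the module plus its 1-hop network neighborhood
.module_neighborhood <- function(network, module) {
  adj <- network$adjacency
  idx <- match(module, network$nodes)
  nb <- which(Matrix::rowSums(adj[, idx, drop = FALSE]) > 0)
  sort(unique(c(module, network$nodes[nb])))
}

#' Generate evidence channels enriched in the planted module
#'
#' Each signature draws \code{signature_module_fraction} of its genes from
#' the module and its 1-hop neighborhood and the remainder uniformly from
#' the rest of the network; the mutation catalog is built the same way with
#' Zipf-distributed variant counts. With \code{complementary = TRUE} the
#' signatures sample around one half of the module and the mutations around
#' the other half, so each channel alone sees only part of the driver
#' module.
#'
#' @param config a \code{synthetic_config}.
#' @param network the generated \code{interaction_network}.
#' @param module planted module genes.
#' @param seed RNG seed.
#' @return list with \code{signatures} (named list of gene sets) and
#'   \code{mutations} (named variant-count vector).
#' @export
generate_evidence <- function(config, network, module, seed = 1L) {
  set.seed(seed)
  nodes <- network$nodes
  if (config$complementary) {
    half <- floor(length(module) / 2)
    sig_pool <- .module_neighborhood(network, module[seq_len(half)])
    mut_pool <- .module_neighborhood(network, module[(half + 1):length(module)])
  } else {
    sig_pool <- mut_pool <- .module_neighborhood(network, module)
  }

  draw_set <- function(size, pool, fraction) {
    n_in <- min(round(fraction * size), length(pool))
    inside <- sample(pool, n_in)
    outside <- sample(setdiff(nodes, pool), size - n_in)
    c(inside, outside)
  }

  signatures <- lapply(config$signature_sizes, draw_set, pool = sig_pool,
                       fraction = config$signature_module_fraction)
  names(signatures) <- sprintf("Sig_%d", seq_along(signatures))

  mut_genes <- draw_set(config$n_mutated_genes, mut_pool,
                        config$mutation_module_fraction)
  k_max <- 50L
  zipf_p <- (1:k_max)^(-config$zipf_exponent)
  counts <- sample(k_max, length(mut_genes), replace = TRUE,
                   prob = zipf_p / sum(zipf_p))
  list(signatures = signatures,
       mutations = stats::setNames(as.integer(counts), mut_genes))
}

#' Generate an expression + survival cohort driven by the planted module
#'
#' Each sample carries a standard-normal latent risk score z. Module genes
#' load on z (uniform(0.4, 1) loadings with random sign) plus unit noise;
#' all other genes are pure noise. Relapse times are exponential with hazard
#' baseline_hazard * exp(beta * z); adjuvant CTX (assigned at random to half
#' the cohort) multiplies the hazard by \code{ctx_benefit_hr} only when
#' z > 0, creating the treatment-by-risk interaction. Uniform censoring is
#' calibrated numerically so the observed event fraction matches
#' \code{event_rate} in expectation; stage III membership has
#' risk-correlated probability plogis(z).
#'
#' @param config a \code{synthetic_config}.
#' @param module planted module genes.
#' @param genes all network gene IDs (rows of the output matrix).
#' @param seed RNG seed.
#' @param sample_prefix prefix for sample IDs.
#' @param loadings optional named numeric vector of module-gene loadings on
#'   the latent risk. The gene-risk relationship is biology shared by every
#'   cohort drawn from the same mechanism, so multi-cohort designs must pass
#'   the same loadings to each cohort (as \code{\link{generate_benchmark}}
#'   does); when NULL, loadings are drawn here.
#' @return list with \code{expression} (gene-by-sample matrix),
#'   \code{clinical} (data frame with sample, time, event, stage, age,
#'   gender, ctx, latent_risk), where \code{latent_risk} is the generative
#'   truth retained for benchmarking only.
#' @export
generate_expression_survival <- function(config, module, genes, seed = 1L,
                                         sample_prefix = "S",
                                         loadings = NULL) {
  set.seed(seed)
  if (is.null(loadings)) loadings <- draw_module_loadings(module)
  n <- config$n_samples
  p <- length(genes)
  z <- stats::rnorm(n)
  expr <- matrix(stats::rnorm(p * n), nrow = p,
                 dimnames = list(genes, sprintf("%s%03d", sample_prefix,
                                                seq_len(n))))
  mod_idx <- match(intersect(names(loadings), genes), genes)
  expr[mod_idx, ] <- expr[mod_idx, ] +
    outer(loadings[match(genes[mod_idx], names(loadings))], z)

  ctx <- stats::rbinom(n, 1L, 0.5)
  hazard <- config$baseline_hazard * exp(config$beta * z) *
    ifelse(ctx == 1 & z > 0, config$ctx_benefit_hr, 1)
  t_event <- stats::rexp(n, rate = hazard)

  # choose the uniform-censoring horizon so E[fraction of observed events]
  # matches the target: P(T_i < C), C ~ U(0, cmax), is (cmax - T_i)+ / cmax
  event_frac <- function(cmax) mean(pmax(cmax - t_event, 0) / cmax)
  upper <- max(t_event) * 2
  cmax <- if (event_frac(upper) < config$event_rate) upper else {
    stats::uniroot(function(x) event_frac(x) - config$event_rate,
                   lower = min(t_event) / 100, upper = upper)$root
  }
  cens <- stats::runif(n, 0, cmax)
  time <- pmin(t_event, cens)
  event <- as.integer(t_event <= cens)
  time <- pmax(time, 0.01)  # strictly positive follow-up

  clinical <- data.frame(
    sample = colnames(expr),
    time = time,
    event = event,
    stage = ifelse(stats::runif(n) < stats::plogis(z), "III", "II"),
    age = round(stats::rnorm(n, 65, 10)),
    gender = sample(c("M", "F"), n, replace = TRUE),
    ctx = ctx,
    latent_risk = z,
    stringsAsFactors = FALSE)
  list(expression = expr, clinical = clinical)
}

#' Generate the complete synthetic benchmark
#'
#' Produces every input the pipeline consumes: the network with its planted
#' module, both evidence channels, and two independently drawn cohorts from
#' the same generative mechanism (mirroring a train-on-one / test-on-the-
#' other design).
#'
#' @param config a \code{synthetic_config}.
#' @param seed root RNG seed; sub-seeds for the network, evidence and the
#'   two cohorts are derived from it.
#' @return list of class \code{synthetic_benchmark}: \code{network},
#'   \code{module}, \code{signatures}, \code{mutations}, \code{cohort1},
#'   \code{cohort2}, \code{config}, \code{seed}.
#' @export
generate_benchmark <- function(config = synthetic_config(), seed = 1L) {
  seeds <- derive_seeds(seed, 5L)
  net <- generate_network(config, seed = seeds[1L])
  ev <- generate_evidence(config, net$network, net$module, seed = seeds[2L])
  set.seed(seeds[5L])
  loadings <- draw_module_loadings(net$module)
  co1 <- generate_expression_survival(config, net$module, net$network$nodes,
                                      seed = seeds[3L], sample_prefix = "A",
                                      loadings = loadings)
  co2 <- generate_expression_survival(config, net$module, net$network$nodes,
                                      seed = seeds[4L], sample_prefix = "B",
                                      loadings = loadings)
  structure(list(network = net$network, module = net$module,
                 signatures = ev$signatures, mutations = ev$mutations,
                 loadings = loadings, cohort1 = co1, cohort2 = co2,
                 config = config, seed = seed),
            class = "synthetic_benchmark")
}

#' Draw per-gene loadings of the driver module on the latent risk
#'
#' Uniform(0.4, 1) magnitudes with random sign, one per module gene. Uses
#' the current RNG state.
#'
#' @param module character vector of module genes.
#' @return named numeric vector.
#' @export
draw_module_loadings <- function(module) {
  stats::setNames(stats::runif(length(module), 0.4, 1.0) *
                    sample(c(-1, 1), length(module), replace = TRUE),
                  module)
}

#' Derive reproducible sub-seeds from a root seed
#'
#' Stage-level seeds are deterministic functions of the root seed so that
#' every stage's randomness is isolated and auditable. Values stay below
#' 2^31.
#'
#' @param seed root integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of length \code{n}.
#' @export
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Write all benchmark inputs in the pipeline's file formats
#'
#' Writes the edge list, signatures (GMT), mutation catalog (TSV),
#' expression matrices (TSV) and clinical tables (TSV) plus a JSON manifest
#' recording the configuration and seed.
#'
#' @param bench a \code{synthetic_benchmark}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  stopifnot(inherits(bench, "synthetic_benchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_list(bench$network, file.path(dir, "network.tsv"))
  write_gmt(bench$signatures, file.path(dir, "signatures.gmt"))
  utils::write.table(
    data.frame(gene = names(bench$mutations),
               variant_count = as.integer(bench$mutations)),
    file.path(dir, "mutations.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  for (k in 1:2) {
    co <- bench[[paste0("cohort", k)]]
    write_expression_matrix(co$expression,
                            file.path(dir, sprintf("expression_cohort%d.tsv", k)))
    utils::write.table(co$clinical,
                       file.path(dir, sprintf("clinical_cohort%d.tsv", k)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(bench$module, file.path(dir, "planted_module.txt"))
  manifest <- c(bench$config, list(seed = bench$seed))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
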