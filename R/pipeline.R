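#' Derive a gene set for a given evidence mode
#'
#' Modes \code{"NEM"}, \code{"NE"} and \code{"NM"} run the full network
#' prioritization (walk + permutation significance); \code{"union"},
#' \code{"signatures-only"} and \code{"mutations-only"} return the raw seed
#' gene sets without any propagation, serving as no-network controls.
#'
#' @param bench a \code{synthetic_benchmark} (or any list with
#'   \code{network}, \code{signatures}, \code{mutations}).
#' @param mode evidence mode.
#' @param alpha dual p-value cutoff for the walk modes.
#' @param n_perm permutations for the null.
#' @param seed RNG seed for the permutation null.
#' @param r,tol walk parameters.
#' @return list with \code{genes}, \code{mode}, and (walk modes only)
#'   \code{signature} (the \code{derived_signature}) and
#'   \code{significance} (the \code{significance_result}).
#' @export
derive_gene_set <- function(bench, mode = c("NEM", "NE", "NM", "union",
                                            "signatures-only",
                                            "mutations-only"),
                            alpha = 0.05, n_perm = 1000L, seed = 1L,
                            r = 0.5, tol = 1e-6) {
  mode <- match.arg(mode)
  sig_union <- sort(unique(unlist(bench$signatures)))
  mut_genes <- sort(names(bench$mutations))
  if (mode %in% c("NEM", "NE", "NM")) {
    p0 <- compute_start_probabilities(
      bench$network,
      signatures = if (mode %in% c("NEM", "NE")) bench$signatures else NULL,
      mutations = if (mode %in% c("NEM", "NM")) bench$mutations else NULL,
      mode = mode)
    real <- rwr_iterate(bench$network, p0, r = r, tol = tol)
    null <- permute_start_probabilities(bench$network, p0, n_perm = n_perm,
                                        seed = seed, r = r, tol = tol)
    sig_res <- empirical_p_values(real, null)
    sig <- derive_signature(sig_res, alpha = alpha, seed_genes = p0$seed_genes)
    list(genes = sig$genes, mode = mode, signature = sig,
         significance = sig_res)
  } else {
    genes <- switch(mode,
                    "union" = sort(union(sig_union, mut_genes)),
                    "signatures-only" = sig_union,
                    "mutations-only" = mut_genes)
    list(genes = genes, mode = mode)
  }
}

# z-score both cohorts independently and subset them to a gene set
.prepare_cohorts <- function(bench, genes, train_cohort = 1L) {
  test_cohort <- 3L - train_cohort
  prep <- function(co) {
    expr <- zscore_genes(co$expression)
    list(X = subset_to_signature(expr, genes), clinical = co$clinical)
  }
  list(train = prep(bench[[paste0("cohort", train_cohort)]]),
       test = prep(bench[[paste0("cohort", test_cohort)]]))
}

# train at the CV-selected cell, score the held-out cohort, and run the
# survival analytics that the run report exposes
.train_and_evaluate <- function(train, test, cost_grid, sigma_grid,
                                folds, repeats, seed) {
  cv <- grid_search_cv(train$X, train$clinical$time, train$clinical$event,
                       cost_grid = cost_grid, sigma_grid = sigma_grid,
                       folds = folds, repeats = repeats, seed = seed)
  scores <- predict_risk_scores(cv$model, test$X)
  cindex <- concordance_index(scores, test$clinical$time, test$clinical$event)
  groups <- median_stratify(scores)
  lr <- logrank_test(groups, test$clinical$time, test$clinical$event)
  cox_group <- cox_fit(data.frame(high_risk = as.integer(groups == "high")),
                       test$clinical$time, test$clinical$event)
  list(cv = cv, scores = scores, groups = groups,
       test_c_index = cindex, logrank = lr, cox_group = cox_group)
}

#' Run the full analysis pipeline on a synthetic benchmark
#'
#' Executes the complete chain: start probabilities from the evidence
#' channels, random walk with restart, permutation significance, signature
#' derivation, per-cohort expression preparation, cross-validated SSVM
#' training on one cohort, risk scoring and median stratification of the
#' other, Kaplan-Meier / log-rank / Cox analyses, and the stage III
#' chemotherapy-benefit analysis.
#'
#' @param bench a \code{synthetic_benchmark}.
#' @param mode evidence mode (see \code{\link{derive_gene_set}}).
#' @param alpha dual p-value cutoff.
#' @param n_perm permutations for the significance null.
#' @param cost_grid,sigma_grid SSVM grid (defaults: 10^(-5:5) each).
#' @param folds,repeats cross-validation layout.
#' @param seed root RNG seed for the run (permutation null, fold
#'   assignment); sub-seeds are derived deterministically.
#' @param train_cohort which cohort (1 or 2) to train on; the other is the
#'   test cohort.
#' @param r,tol walk parameters.
#' @return list of class \code{pipeline_run} with the fitted objects and a
#'   flat \code{report} list of the headline numbers (see
#'   \code{\link{pipeline_report_json}}).
#' @export
run_full_pipeline <- function(bench, mode = "NEM", alpha = 0.05,
                              n_perm = 1000L,
                              cost_grid = 10^(-5:5), sigma_grid = 10^(-5:5),
                              folds = 5L, repeats = 5L, seed = 1L,
                              train_cohort = 1L, r = 0.5, tol = 1e-6) {
  stopifnot(train_cohort %in% c(1L, 2L))
  seeds <- derive_seeds(seed, 2L)
  gs <- derive_gene_set(bench, mode = mode, alpha = alpha, n_perm = n_perm,
                        seed = seeds[1L], r = r, tol = tol)
  if (length(gs$genes) == 0L) stop("derived gene set is empty at alpha = ", alpha)
  cohorts <- .prepare_cohorts(bench, gs$genes, train_cohort = train_cohort)
  ev <- .train_and_evaluate(cohorts$train, cohorts$test, cost_grid,
                            sigma_grid, folds, repeats, seed = seeds[2L])

  test_clin <- cohorts$test$clinical
  cov_uni <- list(
    score = data.frame(score = as.numeric(scale(ev$scores))),
    age = data.frame(age = test_clin$age),
    gender = data.frame(gender_m = as.integer(test_clin$gender == "M")),
    stage = data.frame(stage_iii = as.integer(test_clin$stage == "III")))
  cox_uni <- lapply(cov_uni, function(cv) {
    tryCatch(cox_fit(cv, test_clin$time, test_clin$event)$table,
             error = function(e) NULL)
  })
  cox_multi <- tryCatch(
    cox_fit(do.call(cbind, unname(cov_uni)), test_clin$time,
            test_clin$event)$table,
    error = function(e) NULL)
  ctx <- tryCatch(
    suppressWarnings(ctx_benefit_analysis(ev$scores, test_clin)),
    error = function(e) NULL)

  km_low <- kaplan_meier(test_clin$time[ev$groups == "low"],
                         test_clin$event[ev$groups == "low"])
  km_high <- kaplan_meier(test_clin$time[ev$groups == "high"],
                          test_clin$event[ev$groups == "high"])

  report <- list(
    mode = mode,
    alpha = alpha,
    n_perm = n_perm,
    seed = seed,
    train_cohort = train_cohort,
    signature_size = length(gs$genes),
    n_from_seeds = if (!is.null(gs$signature)) length(gs$signature$from_seeds),
    n_network_added = if (!is.null(gs$signature))
      length(gs$signature$network_added),
    genes_used_train = nrow(cohorts$train$X),
    best_cost = ev$cv$best$cost,
    best_sigma = ev$cv$best$sigma,
    cv_mean_c_index = ev$cv$best$mean_cindex,
    test_c_index = ev$test_c_index,
    logrank_chisq = ev$logrank$chisq,
    logrank_p = ev$logrank$p_value,
    hr_high_vs_low = ev$cox_group$table$hr[1L],
    hr_ci_lower = ev$cox_group$table$ci_lower[1L],
    hr_ci_upper = ev$cox_group$table$ci_upper[1L],
    rfs_3yr_low = km_low$survival_at(36),
    rfs_3yr_high = km_high$survival_at(36),
    ctx_high_risk_hr = if (!is.null(ctx$high_risk))
      ctx$high_risk$cox$table$hr[1L],
    ctx_high_risk_p = if (!is.null(ctx$high_risk))
      ctx$high_risk$logrank$p_value,
    ctx_low_risk_hr = if (!is.null(ctx$low_risk))
      ctx$low_risk$cox$table$hr[1L],
    ctx_low_risk_p = if (!is.null(ctx$low_risk))
      ctx$low_risk$logrank$p_value)

  structure(list(gene_set = gs, cv = ev$cv, scores = ev$scores,
                 groups = ev$groups, logrank = ev$logrank,
                 cox_group = ev$cox_group, cox_univariate = cox_uni,
                 cox_multivariate = cox_multi, ctx = ctx,
                 km = list(low = km_low, high = km_high),
                 report = report),
            class = "pipeline_run")
}

#' Serialize a run report as canonical JSON
#'
#' The JSON is a pure function of the run's configuration and seed, so two
#' runs with the same root seed produce byte-identical reports.
#'
#' @param run a \code{pipeline_run} (or its \code{report} element).
#' @param path optional output path; when given the JSON is also written.
#' @return the JSON string, invisibly when written to a file.
#' @export
pipeline_report_json <- function(run, path = NULL) {
  report <- if (inherits(run, "pipeline_run")) run$report else run
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Compare evidence modes on identical cohorts and seeds
#'
#' Runs the pipeline once per mode (the three walk-based signatures and the
#' three no-network controls) on the same benchmark with the same seed, and
#' tabulates signature size, test C-index, log-rank p and the high- vs
#' low-risk hazard ratio. Per-mode failures are recorded and the comparison
#' continues.
#'
#' @param bench a \code{synthetic_benchmark}.
#' @param modes modes to run.
#' @param ... passed to \code{\link{run_full_pipeline}}.
#' @return data frame with one row per mode (\code{error} column for failed
#'   modes).
#' @export
run_mode_comparison <- function(bench,
                                modes = c("NEM", "NE", "NM", "union",
                                          "signatures-only",
                                          "mutations-only"),
                                ...) {
  rows <- lapply(modes, function(m) {
    res <- tryCatch(run_full_pipeline(bench, mode = m, ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(mode = m, signature_size = NA_integer_,
                 test_c_index = NA_real_, logrank_p = NA_real_,
                 hr_high_vs_low = NA_real_, error = conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      r <- res$report
      data.frame(mode = m, signature_size = r$signature_size,
                 test_c_index = r$test_c_index, logrank_p = r$logrank_p,
                 hr_high_vs_low = r$hr_high_vs_low, error = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Random-signature baseline
#'
#' Repeats the train/test evaluation with random gene sets of the same size
#' as the derived signature and reports the median test C-index and median
#' log-rank p across sets. Draws are taken from the measured genes with
#' disjoint sub-seeds.
#'
#' @param bench a \code{synthetic_benchmark}.
#' @param size gene-set size to match.
#' @param n_sets number of random sets (default 10).
#' @param seed root seed for the draws.
#' @param cost_grid,sigma_grid,folds,repeats SSVM evaluation settings.
#' @param train_cohort cohort to train on.
#' @return list with \code{per_set} data frame and \code{median_c_index},
#'   \code{median_logrank_p}.
#' @export
random_signature_baseline <- function(bench, size, n_sets = 10L, seed = 1L,
                                      cost_grid = 10^(-5:5),
                                      sigma_grid = 10^(-5:5),
                                      folds = 5L, repeats = 5L,
                                      train_cohort = 1L) {
  genes_all <- rownames(bench[[paste0("cohort", train_cohort)]]$expression)
  stopifnot(size <= length(genes_all))
  seeds <- derive_seeds(seed, n_sets + 1L)
  rows <- lapply(seq_len(n_sets), function(k) {
    set.seed(seeds[k])
    genes <- sort(sample(genes_all, size))
    cohorts <- .prepare_cohorts(bench, genes, train_cohort = train_cohort)
    ev <- .train_and_evaluate(cohorts$train, cohorts$test, cost_grid,
                              sigma_grid, folds, repeats,
                              seed = seeds[n_sets + 1L])
    data.frame(set = k, test_c_index = ev$test_c_index,
               logrank_p = ev$logrank$p_value)
  })
  per_set <- do.call(rbind, rows)
  list(per_set = per_set,
       median_c_index = stats::median(per_set$test_c_index),
       median_logrank_p = stats::median(per_set$logrank_p))
}

#' Sweep the dual p-value cutoff
#'
#' Re-derives the signature at each cutoff from one cached significance
#' result and evaluates an SSVM model per cutoff. Signature sizes are
#' non-decreasing in alpha by construction (threshold sets are nested).
#'
#' @param bench a \code{synthetic_benchmark}.
#' @param alphas cutoffs to sweep.
#' @param n_perm,seed significance-null settings.
#' @param cost_grid,sigma_grid,folds,repeats SSVM evaluation settings.
#' @param train_cohort cohort to train on.
#' @param r,tol walk parameters.
#' @return data frame with alpha, signature_size, test_c_index, logrank_p;
#'   rows whose signature cannot be trained are marked untrainable.
#' @export
alpha_sweep <- function(bench, alphas = c(0.005, 0.01, 0.05, 0.1),
                        n_perm = 1000L, seed = 1L,
                        cost_grid = 10^(-5:5), sigma_grid = 10^(-5:5),
                        folds = 5L, repeats = 5L, train_cohort = 1L,
                        r = 0.5, tol = 1e-6) {
  seeds <- derive_seeds(seed, 2L)
  gs <- derive_gene_set(bench, mode = "NEM", alpha = 1, n_perm = n_perm,
                        seed = seeds[1L], r = r, tol = tol)
  rows <- lapply(sort(alphas), function(a) {
    sig <- derive_signature(gs$significance, alpha = a,
                            seed_genes = gs$signature$table$gene[
                              gs$signature$table$provenance == "seed"])
    if (length(sig$genes) == 0L) {
      return(data.frame(alpha = a, signature_size = 0L,
                        test_c_index = NA_real_, logrank_p = NA_real_,
                        untrainable = TRUE))
    }
    res <- tryCatch({
      cohorts <- .prepare_cohorts(bench, sig$genes,
                                  train_cohort = train_cohort)
      .train_and_evaluate(cohorts$train, cohorts$test, cost_grid,
                          sigma_grid, folds, repeats, seed = seeds[2L])
    }, error = function(e) NULL)
    if (is.null(res)) {
      data.frame(alpha = a, signature_size = length(sig$genes),
                 test_c_index = NA_real_, logrank_p = NA_real_,
                 untrainable = TRUE)
    } else {
      data.frame(alpha = a, signature_size = length(sig$genes),
                 test_c_index = res$test_c_index,
                 logrank_p = res$logrank$p_value, untrainable = FALSE)
    }
  })
  do.call(rbind, rows)
}
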