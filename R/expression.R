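#' Collapse a probe-level matrix to gene level
#'
#' Probes mapping to more than one gene are eliminated. When several
#' surviving probes map to the same gene, the probe with the largest
#' interquartile range across samples is kept (the most variable probe
#' carries the most information); IQR ties are broken by lexicographic probe
#' ID for determinism.
#'
#' @param values numeric probe-by-sample matrix with unique probe rownames.
#' @param probe_to_gene two-column data frame (probe, gene); may be
#'   many-to-many.
#' @return gene-by-sample matrix with gene rownames sorted lexicographically;
#'   attribute \code{"collapse_report"} records dropped multi-gene probes and
#'   unmapped probes.
#' @export
collapse_probesets <- function(values, probe_to_gene) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  if (anyDuplicated(rownames(values))) stop("probe IDs must be unique")
  map <- data.frame(probe = as.character(probe_to_gene[[1L]]),
                    gene = as.character(probe_to_gene[[2L]]),
                    stringsAsFactors = FALSE)
  map <- unique(map)
  genes_per_probe <- table(map$probe)
  multi <- names(genes_per_probe)[genes_per_probe > 1L]
  map <- map[!(map$probe %in% multi) & map$probe %in% rownames(values), ]
  if (nrow(map) == 0L) stop("no probes remain after multi-gene elimination")

  iqr <- apply(values[map$probe, , drop = FALSE], 1L, stats::IQR, type = 7)
  map$iqr <- iqr[map$probe]
  # per gene: max IQR, ties to the lexicographically smallest probe ID
  map <- map[order(map$gene, -map$iqr, map$probe), ]
  keep <- map[!duplicated(map$gene), ]
  keep <- keep[order(keep$gene), ]
  out <- values[keep$probe, , drop = FALSE]
  rownames(out) <- keep$gene
  attr(out, "collapse_report") <- list(
    probes_in = nrow(values),
    genes_out = nrow(out),
    multi_gene_probes_dropped = length(multi),
    unmapped_probes = sum(!rownames(values) %in% probe_to_gene[[1L]]))
  out
}

#' Z-score expression rows (genes)
#'
#' Standardizes each gene row to mean 0 and unit standard deviation so that
#' expression levels are comparable across genes. Constant rows (zero SD)
#' cannot be standardized and are dropped with a warning.
#'
#' @param values gene-by-sample numeric matrix.
#' @param sd_type \code{"sample"} (n - 1 denominator, default) or
#'   \code{"population"} (n).
#' @return row-standardized matrix.
#' @export
zscore_genes <- function(values, sd_type = c("sample", "population")) {
  stopifnot(is.matrix(values))
  sd_type <- match.arg(sd_type)
  mu <- rowMeans(values)
  centered <- values - mu
  ss <- rowSums(centered^2)
  denom <- if (sd_type == "sample") ncol(values) - 1L else ncol(values)
  sds <- sqrt(ss / denom)
  constant <- sds == 0 | !is.finite(sds)
  if (all(constant)) stop("all gene rows are constant; nothing to standardize")
  if (any(constant)) {
    warning(sum(constant), " constant gene row(s) dropped before z-scoring")
    centered <- centered[!constant, , drop = FALSE]
    sds <- sds[!constant]
  }
  centered / sds
}

#' Restrict an expression matrix to a gene signature
#'
#' @param values gene-by-sample matrix (gene rownames).
#' @param signature character vector of signature genes.
#' @return matrix restricted to measured signature genes, rows in the
#'   signature's lexicographic order; attribute \code{"missing_genes"} lists
#'   signature genes absent from the matrix.
#' @export
subset_to_signature <- function(values, signature) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  signature <- sort(unique(signature))
  present <- signature[signature %in% rownames(values)]
  if (length(present) == 0L) {
    stop("no signature gene is measured in the expression matrix")
  }
  out <- values[present, , drop = FALSE]
  attr(out, "missing_genes") <- setdiff(signature, present)
  out
}

#' Read a gene-by-sample expression TSV
#'
#' First column gene IDs, header row of sample IDs.
#'
#' @param path input path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           row.names = 1L, check.names = FALSE)
  as.matrix(tab)
}

#' Write a gene-by-sample expression TSV
#'
#' @param values matrix with gene rownames and sample colnames.
#' @param path output path.
#' @export
write_expression_matrix <- function(values, path) {
  tab <- data.frame(gene = rownames(values), values, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate (and optionally read) a clinical annotation table
#'
#' Expected columns: \code{sample}, \code{time} (months, > 0), \code{event}
#' (0 censored / 1 recurrence), \code{stage} ("II"/"III"), \code{age},
#' \code{gender} ("M"/"F"), \code{ctx} (0/1/NA adjuvant chemotherapy).
#' Samples outside stages II/III are rejected: the analysis cohort excludes
#' stage I and IV disease.
#'
#' @param x a data frame, or a path to a tab-delimited file with a header.
#' @return validated data frame (stage and gender as character).
#' @export
read_clinical_table <- function(x) {
  clin <- if (is.character(x)) {
    utils::read.table(x, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                      na.strings = "NA")
  } else as.data.frame(x)
  required <- c("sample", "time", "event", "stage", "age", "gender", "ctx")
  missing_cols <- setdiff(required, names(clin))
  if (length(missing_cols)) {
    stop("clinical table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(clin$sample)) stop("duplicate sample IDs in clinical table")
  if (any(!is.finite(clin$time)) || any(clin$time <= 0)) {
    stop("survival times must be positive")
  }
  if (!all(clin$event %in% c(0, 1))) stop("event flag must be 0 or 1")
  clin$stage <- as.character(clin$stage)
  if (!all(clin$stage %in% c("II", "III"))) {
    stop("stage must be II or III (stage I/IV samples are excluded upstream)")
  }
  if (!all(is.na(clin$ctx) | clin$ctx %in% c(0, 1))) {
    stop("ctx flag must be 0, 1 or NA")
  }
  clin
}

#' Align an expression matrix and clinical table into one survival dataset
#'
#' @param values gene-by-sample matrix.
#' @param clinical a clinical data frame (see \code{\link{read_clinical_table}}).
#' @return list with \code{expression} (columns ordered as clinical rows) and
#'   \code{clinical}; samples present in only one input are dropped with a
#'   warning.
#' @export
survival_dataset <- function(values, clinical) {
  clinical <- read_clinical_table(clinical)
  common <- intersect(clinical$sample, colnames(values))
  if (length(common) == 0L) stop("no samples shared by expression and clinical data")
  dropped <- (ncol(values) - length(common)) + (nrow(clinical) - length(common))
  if (dropped > 0) warning(dropped, " sample record(s) without a match dropped")
  clinical <- clinical[match(common, clinical$sample), ]
  rownames(clinical) <- NULL
  list(expression = values[, common, drop = FALSE], clinical = clinical)
}
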