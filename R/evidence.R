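#' Read gene sets from a GMT file
#'
#' Standard GMT layout: one set per line, tab-separated fields
#' \code{name<TAB>description<TAB>gene1<TAB>gene2...}.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors (unique genes per set).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("GMT file is empty: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("malformed GMT line ", which(bad)[1L],
                     ": need name, description and >= 1 gene")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field per set (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- mapply(function(nm, genes, desc) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(sets), sets, rep_len(description, length(sets)))
  writeLines(lines, path)
  invisible(path)
}

#' Read signatures from a directory of one-gene-per-line files
#'
#' Each \code{*.txt} file is one signature named after the file.
#'
#' @param dir directory containing signature files.
#' @return named list of character vectors.
#' @export
read_signature_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (!length(files)) stop("no .txt signature files in ", dir)
  sets <- lapply(files, function(f) {
    g <- trimws(readLines(f))
    unique(g[nzchar(g)])
  })
  names(sets) <- sub("\\.txt$", "", basename(files))
  sets
}

#' Read a mutation catalog (gene, variant count) TSV
#'
#' @param path two-column tab-delimited file; a header line is detected by a
#'   non-numeric second field.
#' @return named integer vector of variant counts per gene.
#' @export
read_mutation_catalog <- function(path) {
  if (!file.exists(path)) stop("mutation catalog not found: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  header <- length(first) >= 2L && is.na(suppressWarnings(as.numeric(first[2L])))
  tab <- utils::read.table(path, sep = "\t", header = header,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("mutation catalog needs two columns (gene, count)")
  counts <- as.integer(tab[[2L]])
  if (any(is.na(counts)) || any(counts < 1L)) {
    stop("variant counts must be positive integers")
  }
  stats::setNames(counts, as.character(tab[[1L]]))
}

#' Count signature membership per gene
#'
#' A gene appearing in k of the supplied signatures gets membership count k
#' (the s_i evidence channel).
#'
#' @param signatures named list of gene sets.
#' @return named integer vector over the union of genes.
#' @export
count_signature_membership <- function(signatures) {
  stopifnot(is.list(signatures), length(signatures) >= 1L)
  if (any(lengths(signatures) == 0L)) stop("signatures must be non-empty")
  tab <- table(unlist(lapply(signatures, unique)))
  counts <- stats::setNames(as.integer(tab), names(tab))
  counts[order(names(counts))]
}

#' Compute random-walk start probabilities from evidence channels
#'
#' Maps signature-membership counts (s_i) and mutation variant counts (m_i)
#' onto the network and converts them to a start-probability vector p0. In
#' \code{"NEM"} mode each channel is normalized to total weight 1/2 over the
#' network-mapped genes and the halves are summed, so that equal total weight
#' goes to expression-signature evidence and mutation evidence; \code{"NE"}
#' and \code{"NM"} use a single channel normalized to 1. Evidence genes absent
#' from the network are dropped (they cannot seed the walk) and reported.
#'
#' @param network an \code{interaction_network}.
#' @param signatures named list of gene sets (required for NEM/NE modes), or
#'   NULL.
#' @param mutations named vector of variant counts (required for NEM/NM
#'   modes), or NULL.
#' @param mode one of \code{"NEM"}, \code{"NE"}, \code{"NM"}.
#' @return object of class \code{start_probabilities}: list with \code{p0}
#'   (named numeric over all network nodes, sums to 1), \code{mode},
#'   \code{n} (network size), and \code{channel_report} (mapped/unmapped
#'   gene counts per channel).
#' @export
compute_start_probabilities <- function(network, signatures = NULL,
                                        mutations = NULL,
                                        mode = c("NEM", "NE", "NM")) {
  stopifnot(inherits(network, "interaction_network"))
  mode <- match.arg(mode)
  nodes <- network$nodes
  n <- length(nodes)

  s_all <- if (!is.null(signatures)) count_signature_membership(signatures)
           else stats::setNames(integer(0), character(0))
  m_all <- if (!is.null(mutations)) mutations
           else stats::setNames(integer(0), character(0))
  if (length(m_all) && any(m_all < 1)) stop("mutation counts must be >= 1")

  channel_vec <- function(ev) {
    v <- stats::setNames(numeric(n), nodes)
    mapped <- intersect(names(ev), nodes)
    v[mapped] <- as.numeric(ev[mapped])
    list(v = v, mapped = length(mapped),
         unmapped = setdiff(names(ev), nodes))
  }
  use_e <- mode %in% c("NEM", "NE")
  use_m <- mode %in% c("NEM", "NM")
  if (use_e && !length(s_all)) {
    if (mode == "NE") stop("NE mode requires signatures")
    use_e <- FALSE
  }
  if (use_m && !length(m_all)) {
    if (mode == "NM") stop("NM mode requires a mutation catalog")
    use_m <- FALSE
  }

  e <- if (use_e) channel_vec(s_all) else NULL
  m <- if (use_m) channel_vec(m_all) else NULL
  e_ok <- !is.null(e) && sum(e$v) > 0
  m_ok <- !is.null(m) && sum(m$v) > 0
  if (!e_ok && !m_ok) stop("no evidence gene maps onto the network")
  if (mode == "NEM" && xor(e_ok, m_ok)) {
    warning("one evidence channel maps no genes; its weight is reassigned ",
            "to the other channel")
  }

  p0 <- stats::setNames(numeric(n), nodes)
  if (mode == "NEM" && e_ok && m_ok) {
    p0 <- 0.5 * e$v / sum(e$v) + 0.5 * m$v / sum(m$v)
  } else if (e_ok && (mode == "NE" || mode == "NEM")) {
    p0 <- e$v / sum(e$v)
  } else {
    p0 <- m$v / sum(m$v)
  }

  structure(list(
    p0 = p0,
    mode = mode,
    n = n,
    seed_genes = nodes[p0 > 0],
    channel_report = list(
      expression = if (!is.null(e)) list(mapped = e$mapped,
                                         unmapped = e$unmapped) else NULL,
      mutation = if (!is.null(m)) list(mapped = m$mapped,
                                       unmapped = m$unmapped) else NULL)
  ), class = "start_probabilities")
}

#' @export
print.start_probabilities <- function(x, ...) {
  cat("start_probabilities (mode ", x$mode, "): ", sum(x$p0 > 0),
      " seed gene(s) on ", x$n, " network nodes; sum = ",
      format(sum(x$p0)), "\n", sep = "")
  invisible(x)
}
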