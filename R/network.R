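#' Build an interaction network from an edge data frame
#'
#' Constructs the undirected, unweighted protein interaction network used by
#' the random walk. Nodes are ordered lexicographically so all downstream
#' results (score vectors, permutations) are reproducible. Isolated nodes
#' (degree 0 after cleaning) are removed because a zero column would break the
#' column-stochastic transition matrix; they are recorded in the load report.
#'
#' @param edges two-column data frame (or matrix) of gene identifiers, one
#'   interaction per row. Extra columns (e.g. a SIF interaction type) are
#'   ignored.
#' @param drop_self_loops drop rows with identical endpoints (default TRUE).
#' @param drop_duplicates drop duplicated unordered pairs (default TRUE).
#' @return an object of class \code{interaction_network} with elements
#'   \code{nodes} (character, sorted), \code{edges} (two-column character
#'   matrix, endpoints sorted within row), \code{adjacency} (sparse symmetric
#'   0/1 \code{Matrix}), \code{degree}, and \code{report} (named list of
#'   cleaning counts).
#' @export
interaction_network <- function(edges, drop_self_loops = TRUE,
                                drop_duplicates = TRUE) {
  edges <- as.matrix(edges)
  if (ncol(edges) < 2L) stop("edge input must have at least two columns")
  edges <- cbind(as.character(edges[, 1L]), as.character(edges[, 2L]))
  if (nrow(edges) == 0L) stop("edge list is empty")
  bad <- !stats::complete.cases(edges) | edges[, 1L] == "" | edges[, 2L] == ""
  if (any(bad)) {
    stop("malformed edge rows (missing endpoint) at input line(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }

  n_raw <- nrow(edges)
  n_self <- 0L
  if (drop_self_loops) {
    self <- edges[, 1L] == edges[, 2L]
    n_self <- sum(self)
    edges <- edges[!self, , drop = FALSE]
  }
  # canonical orientation so {A,B} and {B,A} collapse
  flip <- edges[, 1L] > edges[, 2L]
  edges[flip, ] <- edges[flip, 2:1]
  n_dup <- 0L
  if (drop_duplicates) {
    dup <- duplicated(paste(edges[, 1L], edges[, 2L], sep = "\r"))
    n_dup <- sum(dup)
    edges <- edges[!dup, , drop = FALSE]
  }
  if (nrow(edges) == 0L) stop("no edges remain after cleaning")

  nodes <- sort(unique(c(edges[, 1L], edges[, 2L])))
  i <- match(edges[, 1L], nodes)
  j <- match(edges[, 2L], nodes)
  adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                              dims = c(length(nodes), length(nodes)),
                              dimnames = list(nodes, nodes))
  adj@x[] <- 1  # collapse any residual multiplicity to binary

  deg <- Matrix::colSums(adj)
  # all nodes appear in >= 1 edge by construction, so no isolates here; the
  # check guards future subsetting paths
  isolated <- nodes[deg == 0]
  if (length(isolated)) {
    warning(length(isolated), " isolated node(s) removed before normalization")
    keep <- deg > 0
    nodes <- nodes[keep]
    adj <- adj[keep, keep, drop = FALSE]
    deg <- deg[keep]
  }

  structure(list(
    nodes = nodes,
    edges = edges,
    adjacency = adj,
    degree = stats::setNames(as.numeric(deg), nodes),
    W = NULL,
    report = list(nodes = length(nodes), edges = nrow(edges),
                  removed_self_loops = n_self, removed_duplicates = n_dup,
                  removed_isolated = length(isolated), input_rows = n_raw)
  ), class = "interaction_network")
}

#' Read an undirected edge list from a delimited file
#'
#' Accepts two-column tab- or whitespace-delimited text (gene, gene). A
#' three-column SIF file is accepted, with the middle interaction-type column
#' ignored.
#'
#' @param path path to the edge-list file.
#' @param drop_self_loops,drop_duplicates passed to
#'   \code{\link{interaction_network}}.
#' @param sif treat the file as 3-column SIF (node, type, node)?
#'   Default FALSE.
#' @return an \code{interaction_network}.
#' @export
read_edge_list <- function(path, drop_self_loops = TRUE,
                           drop_duplicates = TRUE, sif = FALSE) {
  if (!file.exists(path)) stop("edge list file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("edge list file is empty: ", path)
  parts <- strsplit(lines, "[\t ]+")
  need <- if (sif) 3L else 2L
  nf <- lengths(parts)
  if (any(nf < need)) {
    stop("malformed line ", which(nf < need)[1L], " in ", path,
         ": expected at least ", need, " fields")
  }
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", if (sif) 3L else 2L)
  interaction_network(cbind(a, b), drop_self_loops = drop_self_loops,
                      drop_duplicates = drop_duplicates)
}

#' Write a network's edge list to a tab-delimited file
#'
#' @param network an \code{interaction_network}.
#' @param path output path.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "interaction_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Column-normalize the adjacency matrix
#'
#' Populates the transition matrix W with W[i, j] = A[i, j] / degree(j), so
#' that every column sums to one and a random-walk step conserves total
#' probability.
#'
#' @param network an \code{interaction_network}.
#' @return the network with element \code{W} (sparse column-stochastic
#'   \code{Matrix}) filled in.
#' @export
column_normalize <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  deg <- Matrix::colSums(network$adjacency)
  if (any(deg == 0)) stop("network has isolated nodes; rebuild before normalizing")
  network$W <- network$adjacency %*% Matrix::Diagonal(x = 1 / deg)
  dimnames(network$W) <- dimnames(network$adjacency)
  network
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("interaction_network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  r <- x$report
  cat("  cleaned: ", r$removed_self_loops, " self-loop(s), ",
      r$removed_duplicates, " duplicate(s), ",
      r$removed_isolated, " isolated node(s)\n", sep = "")
  if (!is.null(x$W)) cat("  transition matrix W: column-normalized\n")
  invisible(x)
}
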