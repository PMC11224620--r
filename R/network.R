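#' Construct a functional gene interaction network
#'
#' A functional network is a symmetric gene-by-gene matrix of posterior
#' probabilities in \[0, 1\] that two genes act in a common cellular process
#' in a given cell type. Self-weights are stored as 1 by convention but are
#' never used in any statistic: every operation in this package excludes
#' self-edges.
#'
#' @param weights numeric square matrix with values in \[0, 1\]. Must be
#'   symmetric. The diagonal is overwritten with 1.
#' @param genes character vector of unique, non-empty gene identifiers, one
#'   per row of `weights`. Defaults to `rownames(weights)`. Identifiers are
#'   case-sensitive opaque strings; no symbol mapping is performed.
#' @return an object of class `functional_network`: a list with elements
#'   `genes` (character) and `weights` (named symmetric matrix).
#' @examples
#' w <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' w["A", "B"] <- w["B", "A"] <- 0.9
#' net <- functional_network(w)
#' net_weight(net, "A", "B")
#' @export
functional_network <- function(weights, genes = rownames(weights)) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop_modhub("`weights` must be a numeric matrix")
  if (nrow(weights) != ncol(weights))
    stop_modhub("`weights` must be square (got %d x %d)", nrow(weights), ncol(weights))
  if (is.null(genes)) stop_modhub("gene identifiers are required (rownames or `genes`)")
  genes <- as.character(genes)
  if (length(genes) != nrow(weights))
    stop_modhub("length(genes) != nrow(weights)")
  if (anyDuplicated(genes)) stop_modhub("duplicate gene identifiers: %s",
    paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (any(!nzchar(genes)) || anyNA(genes)) stop_modhub("gene identifiers must be non-empty")
  if (anyNA(weights)) stop_modhub("weights contain NA")
  if (any(weights < 0) || any(weights > 1))
    stop_modhub("weights outside [0, 1]")
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 0, check.attributes = FALSE)))
    stop_modhub("`weights` is not symmetric")
  diag(weights) <- 1
  dimnames(weights) <- list(genes, genes)
  structure(list(genes = genes, weights = weights), class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  off <- x$weights[upper.tri(x$weights)]
  cat(sprintf("Functional network: %d genes, %d unordered pairs\n",
              length(x$genes), length(off)))
  cat(sprintf("  edge weights (excl. diagonal): min %.4g, mean %.4g, max %.4g\n",
              min(off), mean(off), max(off)))
  cat("  genes: ", paste(utils::head(x$genes, 6), collapse = ", "),
      if (length(x$genes) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.functional_network <- function(x) dim(x$weights)

#' Edge weight between two genes
#'
#' @param net a [functional_network()].
#' @param a,b gene identifiers present in the network.
#' @return the posterior probability weight of the undirected edge (a, b).
#' @export
net_weight <- function(net, a, b) {
  stopifnot(inherits(net, "functional_network"))
  miss <- setdiff(c(a, b), net$genes)
  if (length(miss)) stop_modhub("gene(s) not in network: %s", paste(miss, collapse = ", "))
  net$weights[a, b]
}

#' Read a functional network from disk
#'
#' Two dialects are supported. `edge_list`: a headerless 3-column TSV of
#' `gene_a  gene_b  weight` rows describing an undirected graph; pairs not
#' listed default to weight 0, and a pair listed in both orientations must
#' carry the same weight. `dense_matrix`: a TSV whose first row and first
#' column hold gene identifiers and whose body is the full symmetric matrix.
#'
#' @param path path to the file.
#' @param format `"edge_list"` or `"dense_matrix"`.
#' @return a [functional_network()].
#' @seealso [write_network()]
#' @export
read_network <- function(path, format = c("edge_list", "dense_matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_modhub("file not found: %s", path)
  if (format == "edge_list") read_network_edge_list(path) else read_network_dense(path)
}

read_network_edge_list <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          colClasses = c("character", "character", "character"),
                          col.names = c("a", "b", "w"), fill = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) != 3L) stop_modhub("edge list must have 3 columns")
  w <- suppressWarnings(as.numeric(df$w))
  if (anyNA(w)) stop_modhub("malformed edge-list row: non-numeric weight (row %d)",
                            which(is.na(w))[1])
  if (any(w < 0 | w > 1)) stop_modhub("edge weight outside [0, 1] (row %d)",
                                      which(w < 0 | w > 1)[1])
  if (any(df$a == df$b)) stop_modhub("self-edge not allowed (row %d)", which(df$a == df$b)[1])
  genes <- unique(c(rbind(df$a, df$b)))   # order of first appearance
  n <- length(genes)
  W <- matrix(0, n, n, dimnames = list(genes, genes))
  ia <- match(df$a, genes); ib <- match(df$b, genes)
  ## canonical unordered key to detect duplicates / asymmetric re-listings
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  key <- (lo - 1) * n + hi
  if (anyDuplicated(key)) {
    for (k in unique(key[duplicated(key)])) {
      ws <- w[key == k]
      if (length(unique(ws)) > 1L)
        stop_modhub("asymmetric edge: pair (%s, %s) listed with different weights",
                    genes[(k - 1) %/% n + 1], genes[(k - 1) %% n + 1])
    }
  }
  W[cbind(ia, ib)] <- w
  W[cbind(ib, ia)] <- w
  functional_network(W, genes)
}

read_network_dense <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          row.names = NULL, check.names = FALSE,
                          stringsAsFactors = FALSE)
  genes <- as.character(df[[1]])
  header <- colnames(df)[-1]
  if (anyDuplicated(header)) stop_modhub("duplicate gene in dense header")
  M <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(M)) stop_modhub("dense matrix body must be numeric")
  if (!identical(genes, header))
    stop_modhub("dense matrix row and column gene identifiers differ")
  rownames(M) <- genes
  functional_network(M, genes)
}

#' Write a functional network to disk
#'
#' The edge-list dialect serializes nonzero-weight unordered pairs with 6
#' decimal places; pairs absent from the file read back as weight 0, so a
#' gene all of whose edges are 0 does not survive an edge-list round trip
#' (use the dense format for such networks). The dense dialect writes the
#' full matrix at 17 significant digits and round-trips exactly.
#'
#' @inheritParams read_network
#' @param net a [functional_network()].
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edge_list", "dense_matrix")) {
  stopifnot(inherits(net, "functional_network"))
  format <- match.arg(format)
  if (format == "edge_list") {
    ut <- which(upper.tri(net$weights), arr.ind = TRUE)
    w <- net$weights[ut]
    keep <- round(w, 6) > 0
    lines <- sprintf("%s\t%s\t%.6f",
                     net$genes[ut[keep, 1]], net$genes[ut[keep, 2]], w[keep])
    writeLines(lines, path)
  } else {
    body <- apply(net$weights, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
    writeLines(c(paste(c("gene", net$genes), collapse = "\t"),
                 paste(net$genes, body, sep = "\t")), path)
  }
  invisible(path)
}
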