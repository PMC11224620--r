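#' Construct a differential-expression (DEG) table
#'
#' Per-gene differential-expression records in the shape produced by DESeq2
#' and similar tools: a signed log2 fold change, a nominal p-value and a
#' Benjamini-Hochberg adjusted p-value (FDR). If `padj` is missing it is
#' computed with [bh_adjust()] over the non-missing p-values.
#'
#' @param gene character vector of unique gene identifiers.
#' @param log2fc signed log2 fold changes.
#' @param pvalue nominal p-values in \[0, 1\] (NA allowed).
#' @param padj adjusted p-values in \[0, 1\] (NA allowed), or NULL to compute
#'   them by Benjamini-Hochberg over the non-missing `pvalue`s.
#' @return a `data.frame` of class `deg_table` with columns
#'   `gene`, `log2fc`, `pvalue`, `padj`.
#' @export
deg_table <- function(gene, log2fc, pvalue, padj = NULL) {
  gene <- as.character(gene)
  if (anyDuplicated(gene))
    stop_modhub("duplicate gene rows: %s",
                paste(utils::head(unique(gene[duplicated(gene)]), 5), collapse = ", "))
  if (any(!nzchar(gene)) || anyNA(gene)) stop_modhub("empty gene identifier")
  log2fc <- as.numeric(log2fc); pvalue <- as.numeric(pvalue)
  if (length(log2fc) != length(gene) || length(pvalue) != length(gene))
    stop_modhub("gene, log2fc, pvalue must have equal length")
  bad <- !is.na(pvalue) & (pvalue < 0 | pvalue > 1)
  if (any(bad)) stop_modhub("pvalue outside [0, 1] for gene %s", gene[bad][1])
  if (is.null(padj)) {
    padj <- rep(NA_real_, length(gene))
    ok <- !is.na(pvalue)
    padj[ok] <- bh_adjust(pvalue[ok])
  } else {
    padj <- as.numeric(padj)
    if (length(padj) != length(gene)) stop_modhub("padj length mismatch")
    bad <- !is.na(padj) & (padj < 0 | padj > 1)
    if (any(bad)) stop_modhub("padj outside [0, 1] for gene %s", gene[bad][1])
  }
  structure(data.frame(gene = gene, log2fc = log2fc, pvalue = pvalue,
                       padj = padj, stringsAsFactors = FALSE),
            class = c("deg_table", "data.frame"))
}

#' Read a DEG table from a TSV file
#'
#' Expects a header containing at least `gene`, `log2fc` and `pvalue`
#' (case-insensitive); `padj` is optional and computed by [bh_adjust()] over
#' the non-missing p-values when absent. Extra columns are ignored.
#'
#' @param path path to the TSV file.
#' @return a [deg_table()].
#' @export
read_deg_table <- function(path) {
  if (!file.exists(path)) stop_modhub("file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  cols <- tolower(colnames(df))
  need <- c("gene", "log2fc", "pvalue")
  miss <- setdiff(need, cols)
  if (length(miss)) stop_modhub("missing required column(s): %s", paste(miss, collapse = ", "))
  pick <- function(nm) df[[which(cols == nm)[1]]]
  num <- function(nm) {
    x <- pick(nm)
    y <- suppressWarnings(as.numeric(x))
    if (any(is.na(y) & !is.na(x) & !(x %in% c("NA", ""))))
      stop_modhub("non-numeric values in column '%s'", nm)
    y
  }
  deg_table(gene = pick("gene"), log2fc = num("log2fc"), pvalue = num("pvalue"),
            padj = if ("padj" %in% cols) num("padj") else NULL)
}

#' Write a DEG table as TSV
#'
#' @param degs a [deg_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(degs, path) {
  stopifnot(inherits(degs, "deg_table"))
  utils::write.table(degs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Differential-expression calls at a threshold
#'
#' Applies the package-wide thresholding convention: significance is judged
#' on the adjusted p-value (`padj < cutoff`, default 0.05); the nominal
#' p-value is used only on explicit request (`threshold = "pvalue"`), the
#' fallback used for weak-signal perturbation arms. Genes whose thresholded
#' statistic is missing are excluded from the universe rather than treated
#' as non-significant, to avoid padding the null group with untested genes.
#'
#' @param degs a [deg_table()].
#' @param threshold `"padj"` (default) or `"pvalue"`.
#' @param cutoff significance cutoff, default 0.05.
#' @return a named logical vector over the tested universe (genes with a
#'   non-missing thresholded statistic): TRUE for significant genes.
#' @export
deg_calls <- function(degs, threshold = c("padj", "pvalue"), cutoff = 0.05) {
  stopifnot(inherits(degs, "deg_table"))
  threshold <- match.arg(threshold)
  stat <- degs[[threshold]]
  ok <- !is.na(stat)
  stats::setNames(stat[ok] < cutoff, degs$gene[ok])
}
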