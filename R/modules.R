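#' Construct a gene module
#'
#' A named set of gene identifiers, e.g. a disease-vulnerability module
#' produced by an upstream network association study.
#'
#' @param name module name (non-empty string).
#' @param members character vector of gene identifiers; duplicates are
#'   collapsed.
#' @return an object of class `gene_module` with fields `name` and `members`.
#' @export
gene_module <- function(name, members) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_modhub("module name must be a non-empty string")
  members <- as.character(members)
  members <- members[nzchar(members) & !is.na(members)]
  members <- unique(members)
  if (!length(members)) stop_modhub("module '%s' has no members", name)
  structure(list(name = name, members = members), class = "gene_module")
}

#' @export
print.gene_module <- function(x, ...) {
  cat(sprintf("Gene module '%s': %d members\n", x$name, length(x$members)))
  cat("  ", paste(utils::head(x$members, 8), collapse = ", "),
      if (length(x$members) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated; column 1 is the set name,
#' column 2 a free-text description (ignored), columns 3+ the member genes.
#' Duplicate genes within one line are collapsed with a warning; duplicate
#' set names across lines are an error.
#'
#' @param path path to a GMT file.
#' @return a named list of [gene_module()] objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_modhub("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop_modhub("GMT line %d has fewer than 3 columns", i)
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes))
      warning(sprintf("GMT set '%s': duplicate genes collapsed", f[1]), call. = FALSE)
    out[[i]] <- gene_module(f[1], genes)
    nms[i] <- f[1]
  }
  if (anyDuplicated(nms))
    stop_modhub("duplicate set names in GMT: %s",
                paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(out) <- nms
  out
}

#' Write gene modules in GMT format
#'
#' @param modules a [gene_module()] or list of them.
#' @param path output path.
#' @param description description field written as column 2.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(modules, path, description = "na") {
  if (inherits(modules, "gene_module")) modules <- list(modules)
  lines <- vapply(modules, function(m)
    paste(c(m$name, description, m$members), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
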