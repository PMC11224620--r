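#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment. Output is order-invariant
#' (adjusted values permute with their inputs) and each adjusted value lies
#' in \[p, 1\].
#'
#' @param pvalues numeric vector of p-values in \[0, 1\] (no NA).
#' @return adjusted p-values, same order and length.
#' @export
bh_adjust <- function(pvalues) {
  pvalues <- as.numeric(pvalues)
  if (anyNA(pvalues)) stop_modhub("bh_adjust: NA p-value")
  if (any(pvalues < 0 | pvalues > 1)) stop_modhub("bh_adjust: p-value outside [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' One-sided rank-sum test of DEG connectivity to a hub
#'
#' Tests whether genes called differentially expressed after perturbing a
#' hub are more strongly connected to that hub in the functional network
#' than non-DEG genes — the key validation that the network's connectivity
#' predictions carry over to a real perturbation. The universe is the set
#' of genes present in both the network and the DEG table (hub excluded;
#' genes with a missing thresholded statistic excluded). Connectivity is
#' the edge weight to the hub; the alternative is one-sided, "DEG genes
#' have greater connectivity".
#'
#' The exact rank-sum distribution is used when both groups have at most
#' `exact_max` members (via the null Wilcoxon distribution when there are
#' no ties, or full enumeration of group assignments when there are);
#' otherwise the normal approximation with tie and continuity correction.
#'
#' @param net a [functional_network()].
#' @param hub gene identifier of the perturbed hub (in the network).
#' @param degs a [deg_table()].
#' @param threshold,cutoff passed to [deg_calls()]; default `padj < 0.05`.
#' @param exact_max group-size ceiling for the exact test (default 20).
#' @return a list of class `deg_connectivity_test`: `p.value`, `statistic`
#'   (rank-sum statistic W of the DEG group), `n_deg`, `n_nondeg`,
#'   `median_deg`, `median_nondeg` (median connectivity per group),
#'   `method` ("exact", "exact_ties" or "normal_approx"), and the
#'   threshold settings.
#' @export
deg_connectivity_test <- function(net, hub, degs,
                                  threshold = c("padj", "pvalue"), cutoff = 0.05,
                                  exact_max = 20) {
  stopifnot(inherits(net, "functional_network"), inherits(degs, "deg_table"))
  threshold <- match.arg(threshold)
  if (!hub %in% net$genes) stop_modhub("hub '%s' not in network", hub)
  calls <- deg_calls(degs, threshold, cutoff)
  universe <- setdiff(intersect(net$genes, names(calls)), hub)
  if (!length(universe)) stop_modhub("no overlap between network and DEG table")
  is_deg <- calls[universe]
  w <- net$weights[universe, hub]
  x <- w[is_deg]; y <- w[!is_deg]
  if (!length(x)) stop_modhub("empty comparison group: no DEGs at %s < %g", threshold, cutoff)
  if (!length(y)) stop_modhub("empty comparison group: all genes are DEGs")
  rk <- rank(c(x, y))
  W <- sum(rk[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  n1 <- length(x); n2 <- length(y)
  if (n1 <= exact_max && n2 <= exact_max) {
    if (!ties) {
      method <- "exact"
      p <- stats::pwilcox(W - 1, n1, n2, lower.tail = FALSE)
    } else if (choose(n1 + n2, n1) <= 2e5) {
      method <- "exact_ties"
      p <- rank_sum_enum_p(c(x, y), n1, W)
    } else {
      method <- "normal_approx"
      p <- suppressWarnings(stats::wilcox.test(x, y, alternative = "greater",
                                               exact = FALSE, correct = TRUE)$p.value)
    }
  } else {
    method <- "normal_approx"
    p <- suppressWarnings(stats::wilcox.test(x, y, alternative = "greater",
                                             exact = FALSE, correct = TRUE)$p.value)
  }
  structure(list(p.value = p, statistic = W, n_deg = n1, n_nondeg = n2,
                 median_deg = stats::median(x), median_nondeg = stats::median(y),
                 method = method, threshold = threshold, cutoff = cutoff,
                 exact_max = exact_max, hub = hub),
            class = "deg_connectivity_test")
}

## Exact one-sided rank-sum p under ties: enumerate every assignment of n1
## of the pooled values to the first group and count rank sums >= observed.
rank_sum_enum_p <- function(pooled, n1, W_obs) {
  rk <- rank(pooled)
  offset <- n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  Ws <- colSums(matrix(rk[combos], nrow = n1)) - offset
  mean(Ws >= W_obs - 1e-9)
}

#' @export
print.deg_connectivity_test <- function(x, ...) {
  cat("One-sided Wilcoxon rank-sum test: DEG connectivity to hub\n")
  cat(sprintf("  hub %s; DEGs at %s < %g\n", x$hub, x$threshold, x$cutoff))
  cat(sprintf("  n = %d DEG vs %d non-DEG; median connectivity %.4g vs %.4g\n",
              x$n_deg, x$n_nondeg, x$median_deg, x$median_nondeg))
  cat(sprintf("  W = %g, p = %.4g (%s)\n", x$statistic, x$p.value, x$method))
  invisible(x)
}

#' One-sided Fisher's exact test of gene-set overlap
#'
#' Hypergeometric upper-tail test of whether two gene sets overlap more
#' than expected by chance within a common universe:
#' `p = P(X >= |A intersect B|)` with X hypergeometric.
#'
#' @param setA,setB character vectors of gene identifiers. Elements outside
#'   the universe are dropped with a warning.
#' @param universe character vector of gene identifiers, at least 4.
#' @param alternative only `"greater"` (enrichment) is supported.
#' @return a list of class `overlap_test`: `table` (2x2 counts: in-both,
#'   A-only, B-only, neither), `overlap`, `odds_ratio` (sample odds ratio;
#'   0.5 Haldane correction applied, and flagged via `haldane`, only when a
#'   cell is 0), `p.value`, `universe_size`.
#' @export
fisher_overlap <- function(setA, setB, universe, alternative = "greater") {
  alternative <- match.arg(alternative, "greater")
  universe <- unique(as.character(universe))
  if (length(universe) < 4L) stop_modhub("universe must contain at least 4 genes")
  dropA <- setdiff(setA, universe); dropB <- setdiff(setB, universe)
  if (length(dropA) || length(dropB))
    warning(sprintf("%d setA / %d setB gene(s) outside universe dropped",
                    length(dropA), length(dropB)), call. = FALSE)
  A <- intersect(unique(setA), universe)
  B <- intersect(unique(setB), universe)
  if (!length(A)) stop_modhub("setA empty after intersecting with universe")
  if (!length(B)) stop_modhub("setB empty after intersecting with universe")
  N <- length(universe)
  a <- length(intersect(A, B))
  b <- length(A) - a
  cc <- length(B) - a
  d <- N - a - b - cc
  p <- stats::phyper(a - 1, length(A), N - length(A), length(B), lower.tail = FALSE)
  haldane <- any(c(a, b, cc, d) == 0)
  h <- if (haldane) 0.5 else 0
  or <- ((a + h) * (d + h)) / ((b + h) * (cc + h))
  structure(list(table = matrix(c(a, b, cc, d), 2, 2,
                                dimnames = list(inA = c("yes", "no"), inB = c("yes", "no"))),
                 overlap = a, odds_ratio = or, haldane = haldane,
                 p.value = p, universe_size = N, alternative = alternative),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat("Fisher's exact test (one-sided, enrichment)\n")
  cat(sprintf("  overlap %d of universe %d; odds ratio %.4g%s; p = %.4g\n",
              x$overlap, x$universe_size, x$odds_ratio,
              if (x$haldane) " (Haldane-corrected)" else "", x$p.value))
  invisible(x)
}

#' Signed overlap of two DEG tables
#'
#' Compares differential-expression calls between two perturbation
#' experiments (e.g. in vitro and in vivo arms of the same silencing),
#' stratified by direction of change: up-regulated DEGs of table A against
#' up-regulated DEGs of table B, likewise for down-regulated, and a
#' combined test on the full DEG sets. Genes significant in both tables
#' with opposite signs are reported as discordant.
#'
#' The universe is the set of genes tested (non-missing thresholded
#' statistic) in both tables.
#'
#' @param degA,degB [deg_table()] objects, thresholded identically.
#' @param threshold,cutoff passed to [deg_calls()].
#' @return a list of class `signed_overlap`: `up` and `down`
#'   ([fisher_overlap()] results per direction), `combined` (full DEG sets),
#'   `discordant` (character vector of opposite-sign genes), `universe_size`.
#' @export
signed_overlap <- function(degA, degB, threshold = c("padj", "pvalue"),
                           cutoff = 0.05) {
  threshold <- match.arg(threshold)
  callsA <- deg_calls(degA, threshold, cutoff)
  callsB <- deg_calls(degB, threshold, cutoff)
  universe <- intersect(names(callsA), names(callsB))
  if (length(universe) < 4L) stop_modhub("fewer than 4 genes tested in both tables")
  lfcA <- stats::setNames(degA$log2fc, degA$gene)[universe]
  lfcB <- stats::setNames(degB$log2fc, degB$gene)[universe]
  sigA <- universe[callsA[universe]]
  sigB <- universe[callsB[universe]]
  upA <- sigA[lfcA[sigA] > 0]; dnA <- sigA[lfcA[sigA] < 0]
  upB <- sigB[lfcB[sigB] > 0]; dnB <- sigB[lfcB[sigB] < 0]
  discordant <- union(intersect(upA, dnB), intersect(dnA, upB))
  safe_fisher <- function(A, B) {
    if (!length(A) || !length(B)) return(NULL)
    fisher_overlap(A, B, universe)
  }
  structure(list(up = safe_fisher(upA, upB),
                 down = safe_fisher(dnA, dnB),
                 combined = safe_fisher(sigA, sigB),
                 discordant = discordant,
                 n_sigA = length(sigA), n_sigB = length(sigB),
                 universe_size = length(universe),
                 threshold = threshold, cutoff = cutoff),
            class = "signed_overlap")
}

#' @export
print.signed_overlap <- function(x, ...) {
  cat(sprintf("Signed DEG overlap (universe %d; %s < %g)\n",
              x$universe_size, x$threshold, x$cutoff))
  fmt <- function(nm, t) {
    if (is.null(t)) cat(sprintf("  %s: not testable (empty set)\n", nm))
    else cat(sprintf("  %s: overlap %d, p = %.4g\n", nm, t$overlap, t$p.value))
  }
  fmt("up/up   ", x$up); fmt("down/down", x$down); fmt("combined ", x$combined)
  cat(sprintf("  discordant genes: %d\n", length(x$discordant)))
  invisible(x)
}

#' Cumulative rank-enrichment curve of DEGs along hub connectivity
#'
#' Ranks the tested universe by connectivity to the hub (edge weight,
#' descending, competition ranks, ties broken by gene identifier for
#' display order) and reports, at each rank cutoff k, the cumulative DEG
#' count among the top k and the enrichment fold
#' `(hits/k) / (m/N)` over the random expectation, where m is the total
#' DEG count and N the universe size. The fold at k = N is exactly 1 by
#' construction. DEG rank positions are returned as the "rug".
#'
#' @inheritParams deg_connectivity_test
#' @param cutoff_grid `"auto"` evaluates every rank when N <= 5000 and 200
#'   log-spaced cutoffs otherwise; `"all"` forces every rank.
#' @return a data.frame of class `enrichment_curve` with columns
#'   `k`, `hits`, `fold`, `expected` (constant 1); attributes `rug`
#'   (competition ranks of the DEGs), `n_universe`, `n_deg`, `hub`.
#' @export
rank_enrichment_curve <- function(net, hub, degs,
                                  threshold = c("padj", "pvalue"), cutoff = 0.05,
                                  cutoff_grid = c("auto", "all")) {
  stopifnot(inherits(net, "functional_network"), inherits(degs, "deg_table"))
  threshold <- match.arg(threshold)
  cutoff_grid <- match.arg(cutoff_grid)
  if (!hub %in% net$genes) stop_modhub("hub '%s' not in network", hub)
  calls <- deg_calls(degs, threshold, cutoff)
  universe <- setdiff(intersect(net$genes, names(calls)), hub)
  if (!length(universe)) stop_modhub("no overlap between network and DEG table")
  is_deg <- calls[universe]
  if (!any(is_deg)) stop_modhub("no DEGs at %s < %g", threshold, cutoff)
  w <- net$weights[universe, hub]
  ord <- order(-w, universe)
  N <- length(universe); m <- sum(is_deg)
  hits_all <- cumsum(is_deg[ord])
  if (cutoff_grid == "all" || N <= 5000) {
    ks <- seq_len(N)
  } else {
    ks <- sort(unique(c(round(exp(seq(log(1), log(N), length.out = 200))), N)))
  }
  fold <- (hits_all[ks] / ks) / (m / N)
  rug <- competition_rank(w)[is_deg]
  structure(data.frame(k = as.integer(ks), hits = as.integer(hits_all[ks]),
                       fold = fold, expected = 1),
            class = c("enrichment_curve", "data.frame"),
            rug = sort(rug), n_universe = N, n_deg = m, hub = hub,
            threshold = threshold, cutoff = cutoff)
}

#' @export
print.enrichment_curve <- function(x, ...) {
  cat(sprintf("Rank-enrichment curve: %d DEGs in universe of %d (hub %s)\n",
              attr(x, "n_deg"), attr(x, "n_universe"), attr(x, "hub")))
  show <- x[x$k %in% c(10, 50, 100, 500, attr(x, "n_universe")), , drop = FALSE]
  if (nrow(show)) print.data.frame(show, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
plot.enrichment_curve <- function(x, ...) {
  graphics::plot(x$k, x$fold, type = "l", log = "x", col = "steelblue4", lwd = 2,
                 xlab = "rank cutoff k (by connectivity to hub)",
                 ylab = "enrichment fold over random", ...)
  graphics::abline(h = 1, lty = 2)
  graphics::rug(attr(x, "rug"))
  invisible(x)
}
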