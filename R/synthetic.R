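#' Parameters of the planted-module network simulator
#'
#' The generator emulates the statistical shape of a cell-type-specific
#' functional network and of the perturbation RNA-seq results downstream
#' analyses consume: a symmetric matrix of posterior-probability edge
#' weights containing one module with elevated internal connectivity and
#' one hub gene with elevated connectivity to that module, plus
#' DESeq2-shaped DEG tables in which the probability that a gene responds
#' to silencing of the hub increases with its network connectivity to the
#' hub.
#'
#' Edge weights are Beta-distributed to respect the \[0, 1\] posterior
#' semantics. Background pairs draw from `background_beta`, module-internal
#' pairs from `module_beta`, hub-module pairs from `hub_beta`. The defaults
#' (Beta(1,9), Beta(4,6), Beta(6,4): means 0.1, 0.4, 0.6) give a clearly
#' planted but not trivially separable module. Differential expression of
#' gene g after perturbing the hub follows
#' `P(DE_g) = plogis(de_intercept + de_slope * w(hub, g))`; with the
#' defaults (-3, 6) a background gene is DE with probability ~0.09 and a
#' strongly connected gene (w = 0.8) with probability ~0.86. DE genes draw
#' `pvalue = 10^-U(lo, hi)` and `|log2fc| ~ N(lfc_de)` with random sign;
#' null genes draw uniform p-values and `log2fc ~ N(0, lfc_null_sd)`.
#'
#' @param n_genes number of genes (default 2000).
#' @param module_size planted module size (default 100).
#' @param background_beta,module_beta,hub_beta Beta shape pairs `(a, b)`
#'   for background, module-internal and hub-module edge weights. The
#'   module mean may not fall below the background mean (equality is
#'   allowed, which yields the fully exchangeable null network).
#' @param de_intercept,de_slope logit-scale intercept and slope (per unit
#'   edge weight) of the DE probability model. `de_slope = 0` gives the
#'   calibration null in which DE labels are independent of connectivity.
#' @param lfc_de mean and sd of `|log2fc|` for DE genes (log2 units).
#' @param lfc_null_sd sd of the null log2 fold changes.
#' @param p_de_exponent_range `(lo, hi)`: DE p-values are `10^-U(lo, hi)`.
#' @param hub_in_module place the hub inside the module (default FALSE:
#'   the hub is a regulator of, not a member of, the module).
#' @param seed master integer seed; all draws derive from it via
#'   [stream_seed()] (separate streams for network edges, DE labels and
#'   noise, so components can be redrawn independently).
#' @return a validated list of class `generator_params`.
#' @export
generator_params <- function(n_genes = 2000, module_size = 100,
                             background_beta = c(1, 9),
                             module_beta = c(4, 6),
                             hub_beta = c(6, 4),
                             de_intercept = -3, de_slope = 6,
                             lfc_de = c(2, 0.5), lfc_null_sd = 0.25,
                             p_de_exponent_range = c(2, 8),
                             hub_in_module = FALSE,
                             seed = 1) {
  p <- list(n_genes = as.integer(n_genes), module_size = as.integer(module_size),
            background_beta = as.numeric(background_beta),
            module_beta = as.numeric(module_beta), hub_beta = as.numeric(hub_beta),
            de_intercept = as.numeric(de_intercept), de_slope = as.numeric(de_slope),
            lfc_de = as.numeric(lfc_de), lfc_null_sd = as.numeric(lfc_null_sd),
            p_de_exponent_range = as.numeric(p_de_exponent_range),
            hub_in_module = isTRUE(hub_in_module), seed = as.integer(seed))
  if (!is_count(p$n_genes) || !is_count(p$module_size))
    stop_modhub("n_genes and module_size must be integers")
  if (p$n_genes <= p$module_size) stop_modhub("n_genes must exceed module_size")
  if (p$module_size < 3L) stop_modhub("module_size must be at least 3")
  for (nm in c("background_beta", "module_beta", "hub_beta")) {
    b <- p[[nm]]
    if (length(b) != 2L || any(!is.finite(b)) || any(b <= 0))
      stop_modhub("%s must be two positive shape parameters", nm)
  }
  bmean <- function(b) b[1] / (b[1] + b[2])
  if (bmean(p$module_beta) < bmean(p$background_beta))
    stop_modhub("module_beta mean must not fall below background_beta mean")
  if (length(p$lfc_de) != 2L || p$lfc_de[2] < 0 || p$lfc_null_sd < 0)
    stop_modhub("invalid log2fc parameters")
  r <- p$p_de_exponent_range
  if (length(r) != 2L || r[1] >= r[2] || r[1] < 0)
    stop_modhub("p_de_exponent_range must be (lo, hi) with 0 <= lo < hi")
  structure(p, class = "generator_params")
}

#' @export
print.generator_params <- function(x, ...) {
  bmean <- function(b) b[1] / (b[1] + b[2])
  cat(sprintf("Planted-module generator: %d genes, module %d, hub %s module\n",
              x$n_genes, x$module_size, if (x$hub_in_module) "inside" else "outside"))
  cat(sprintf("  edge means: background %.2f, module %.2f, hub-module %.2f\n",
              bmean(x$background_beta), bmean(x$module_beta), bmean(x$hub_beta)))
  cat(sprintf("  P(DE) = plogis(%g + %g w); seed %d\n",
              x$de_intercept, x$de_slope, x$seed))
  invisible(x)
}

#' Generate a planted-module functional network
#'
#' Draws a symmetric Beta-weighted network per the [generator_params()]
#' model: background weights for every unordered pair, overwritten by
#' module-Beta draws for module-internal pairs and hub-Beta draws for
#' hub-module pairs. Gene identifiers are `g0001, g0002, ...`; the hub is
#' the first gene and the module the following `module_size` genes (first
#' `module_size` including the hub when `hub_in_module`). Fully
#' reproducible from `params$seed` (network stream).
#'
#' @param params a [generator_params()].
#' @return a list with `network` (a [functional_network()]) and `truth`
#'   (partial ground truth: `module` as a [gene_module()] named
#'   `"PLANTED"`, `hub`, `params`).
#' @export
generate_network <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  n <- params$n_genes
  genes <- sprintf("g%0*d", max(4L, nchar(n)), seq_len(n))
  hub <- genes[1]
  mod <- if (params$hub_in_module) genes[seq_len(params$module_size)]
         else genes[1 + seq_len(params$module_size)]
  W <- with_seed(stream_seed(params$seed, "network"), {
    W <- matrix(0, n, n)
    iu <- upper.tri(W)
    W[iu] <- stats::rbeta(sum(iu), params$background_beta[1], params$background_beta[2])
    mi <- match(mod, genes)
    sub <- W[mi, mi]
    su <- upper.tri(sub)
    sub[su] <- stats::rbeta(sum(su), params$module_beta[1], params$module_beta[2])
    W[mi, mi] <- sub
    tgt <- setdiff(mi, 1L)   # hub-module pairs (self excluded when hub is a member)
    W[1, tgt] <- stats::rbeta(length(tgt), params$hub_beta[1], params$hub_beta[2])
    W[lower.tri(W)] <- 0
    W <- W + t(W)
    dimnames(W) <- list(genes, genes)
    W
  })
  truth <- list(module = gene_module("PLANTED", mod), hub = hub, params = params)
  list(network = functional_network(W, genes), truth = truth)
}

## Realize a DEG table from fixed truth labels/signs with a given noise seed.
## `active` marks which truth-DE genes are expressed as DE in this table.
realize_degs <- function(net, truth, params, noise_seed, active = NULL) {
  genes <- setdiff(net$genes, truth$hub)
  de <- truth$de_labels[genes]
  if (!is.null(active)) de <- de & active[genes]
  sgn <- truth$de_signs[genes]
  lo <- params$p_de_exponent_range[1]; hi <- params$p_de_exponent_range[2]
  with_seed(noise_seed, {
    pv <- numeric(length(genes)); lfc <- numeric(length(genes))
    nde <- sum(de)
    pv[de] <- 10^(-stats::runif(nde, lo, hi))
    lfc[de] <- sgn[de] * abs(stats::rnorm(nde, params$lfc_de[1], params$lfc_de[2]))
    pv[!de] <- stats::runif(sum(!de))
    lfc[!de] <- stats::rnorm(sum(!de), 0, params$lfc_null_sd)
    ## the hub itself: strong knockdown signal
    deg_table(gene = c(genes, truth$hub),
              log2fc = c(lfc, -params$lfc_de[1]),
              pvalue = c(pv, 10^(-hi)))
  })
}

#' Generate a perturbation DEG table from a planted network
#'
#' Simulates silencing of the planted hub: each gene g (hub excluded) is
#' differentially expressed with probability
#' `plogis(de_intercept + de_slope * w(hub, g))` (label stream), DE and
#' null genes then draw p-values and log2 fold changes per
#' [generator_params()] (noise stream), and `padj` is the
#' Benjamini-Hochberg adjustment over all p-values. The hub itself is
#' written with a large negative log2 fold change (knockdown).
#'
#' @param net the network from [generate_network()].
#' @param truth the (partial) truth from [generate_network()].
#' @param params the same [generator_params()].
#' @return a list with `degs` (a [deg_table()]) and `truth` completed with
#'   `de_labels` and `de_signs` (named over all non-hub genes).
#' @export
generate_perturbation_degs <- function(net, truth, params) {
  stopifnot(inherits(net, "functional_network"), inherits(params, "generator_params"))
  if (!truth$hub %in% net$genes) stop_modhub("hub not in network")
  genes <- setdiff(net$genes, truth$hub)
  w <- net$weights[genes, truth$hub]
  pr <- stats::plogis(params$de_intercept + params$de_slope * w)
  lab <- with_seed(stream_seed(params$seed, "labels"), {
    de <- stats::runif(length(genes)) < pr
    sgn <- sample(c(-1, 1), length(genes), replace = TRUE)
    list(de = de, sgn = sgn)
  })
  truth$de_labels <- stats::setNames(lab$de, genes)
  truth$de_signs <- stats::setNames(lab$sgn, genes)
  degs <- realize_degs(net, truth, params, stream_seed(params$seed, "noise"))
  list(degs = degs, truth = truth)
}

#' Generate a pair of DEG tables sharing ground truth
#'
#' Emulates two arms of the same perturbation (e.g. in vitro and in vivo):
#' both tables share the DE labels and signs fixed in `truth`, with
#' independent noise realizations of p-values and fold changes. The second
#' table is optionally attenuated: a fraction of its DE genes reverts to
#' null, emulating a weaker in-vivo signal.
#'
#' @inheritParams generate_perturbation_degs
#' @param truth a completed truth (from [generate_perturbation_degs()]).
#' @param seed2 integer seed for the second table's noise (and the choice
#'   of attenuated genes).
#' @param attenuation fraction of DE genes reverted to null in the second
#'   table, in \[0, 1\] (default 0.5).
#' @return a list with `degsA`, `degsB` ([deg_table()]s) and `reverted`
#'   (identifiers of DE genes nulled in table B).
#' @export
generate_paired_degs <- function(net, truth, params, seed2, attenuation = 0.5) {
  stopifnot(inherits(params, "generator_params"))
  if (is.null(truth$de_labels)) stop_modhub("truth lacks de_labels; run generate_perturbation_degs first")
  if (!is.numeric(attenuation) || attenuation < 0 || attenuation > 1)
    stop_modhub("attenuation must be in [0, 1]")
  degsA <- realize_degs(net, truth, params, stream_seed(params$seed, "noise"))
  de_genes <- names(truth$de_labels)[truth$de_labels]
  reverted <- with_seed(stream_seed(seed2, "attenuation"), {
    k <- round(attenuation * length(de_genes))
    if (k > 0) sample(de_genes, k) else character(0)
  })
  active <- stats::setNames(rep(TRUE, length(truth$de_labels)), names(truth$de_labels))
  active[reverted] <- FALSE
  degsB <- realize_degs(net, truth, params, stream_seed(seed2, "noise"), active)
  list(degsA = degsA, degsB = degsB, reverted = sort(reverted))
}

#' Simulate a complete planted-hub study
#'
#' Convenience wrapper: generates the network, the perturbation DEG table
#' and (optionally) a paired second table from one [generator_params()].
#'
#' @param params a [generator_params()].
#' @param paired also generate a second, attenuated DEG table.
#' @param seed2 noise seed for the second table (default `params$seed + 1`).
#' @param attenuation see [generate_paired_degs()].
#' @return a list with `network`, `module`, `hub`, `truth`, `degs`, and
#'   when `paired`, `degs2` and `reverted`.
#' @export
simulate_study <- function(params = generator_params(), paired = FALSE,
                           seed2 = params$seed + 1L, attenuation = 0.5) {
  g <- generate_network(params)
  d <- generate_perturbation_degs(g$network, g$truth, params)
  out <- list(network = g$network, module = d$truth$module, hub = d$truth$hub,
              truth = d$truth, degs = d$degs)
  if (paired) {
    p <- generate_paired_degs(g$network, d$truth, params, seed2, attenuation)
    out$degs2 <- p$degsB
    out$reverted <- p$reverted
  }
  out
}
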