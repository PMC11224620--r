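## Core statistic: per-gene module-connectivity z-score.
##
## For gene g and module M, let xbar_g be the mean posterior probability
## between g and the genes of M (g itself excluded if it is a member), and
## let mu_g and sigma_g be the mean and sample standard deviation of the
## posterior probabilities between g and every other gene in the network.
## Then
##     z = (xbar_g - mu_g) / (sigma_g / sqrt(n)),   n = effective module size,
## i.e. xbar_g standardized against what a random module of n genes would
## give under g's genome-wide connectivity distribution. High z means g is
## more strongly connected to the module than g's general connectivity
## pattern predicts — the signature of a candidate module regulator.

## Vectorized scoring of a set of genes; shared by the exported functions.
## Returns a data.frame with columns gene, xbar, mu, sigma, n, z, flag.
score_genes <- function(net, module, which_genes, min_module_size,
                        z_denominator) {
  W <- net$weights
  genes <- net$genes
  n_genes <- length(genes)
  mod <- intersect(module$members, genes)
  dropped <- setdiff(module$members, genes)
  if (length(dropped))
    warning(sprintf("module '%s': %d member(s) absent from network dropped",
                    module$name, length(dropped)), call. = FALSE)
  idx <- match(which_genes, genes)
  in_mod <- which_genes %in% mod
  mod_idx <- match(mod, genes)

  dW <- diag(W)
  rs  <- rowSums(W)  - dW                       # sum over h != g
  rs2 <- rowSums(W^2) - dW^2
  nref <- n_genes - 1
  mu <- rs / nref
  v <- (rs2 - rs^2 / nref) / (nref - 1)
  sigma <- sqrt(pmax(v, 0))

  s_mod <- rowSums(W[, mod_idx, drop = FALSE])
  n_eff <- ifelse(in_mod, length(mod) - 1L, length(mod))
  xbar <- (s_mod[idx] - ifelse(in_mod, dW[idx], 0)) / n_eff

  denom <- switch(z_denominator,
                  se = sigma[idx] / sqrt(n_eff),
                  sd_over_n = sigma[idx] / n_eff)
  z <- (xbar - mu[idx]) / denom

  flag <- rep("", length(idx))
  flag[sigma[idx] < 1e-14] <- "degenerate_sigma"
  flag[n_eff < min_module_size] <- "module_too_small"
  z[nzchar(flag)] <- NA_real_
  data.frame(gene = which_genes, xbar = xbar, mu = mu[idx], sigma = sigma[idx],
             n = as.integer(n_eff), z = z, flag = flag,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Module-connectivity z-score of a single gene
#'
#' Standardizes the mean posterior probability between `gene` and the module
#' members against the gene's genome-wide connectivity distribution. See
#' [rank_module_hubs()] for the network-wide ranking built on this score.
#'
#' @param net a [functional_network()].
#' @param module a [gene_module()]. Members absent from the network are
#'   dropped with a warning; if `gene` is itself a member it is excluded from
#'   the module mean. The effective module must retain at least
#'   `min_module_size` genes.
#' @param gene gene identifier present in the network.
#' @param min_module_size minimum effective module size (default 3).
#' @param z_denominator `"se"` (default) divides the centred mean by
#'   `sigma/sqrt(n)`, the standard error of a mean of `n` draws — the choice
#'   that makes z comparable across module sizes; `"sd_over_n"` divides by
#'   `sigma/n`.
#' @return a list of class `connectivity_z` with fields `gene`, `xbar`
#'   (mean weight to the module), `mu`, `sigma` (mean and sample sd of the
#'   gene's weights to all other network genes), `n` (effective module
#'   size), `z`, and `z_denominator`.
#' @examples
#' net <- example_network5()
#' module_connectivity_z(net, gene_module("M", c("B", "C")), "A",
#'                       min_module_size = 2)
#' @export
module_connectivity_z <- function(net, module, gene, min_module_size = 3,
                                  z_denominator = c("se", "sd_over_n")) {
  stopifnot(inherits(net, "functional_network"), inherits(module, "gene_module"))
  z_denominator <- match.arg(z_denominator)
  if (length(gene) != 1L || !gene %in% net$genes)
    stop_modhub("gene '%s' not in network", as.character(gene)[1])
  r <- score_genes(net, module, gene, min_module_size, z_denominator)
  if (r$flag == "module_too_small")
    stop_modhub("effective module size %d below min_module_size = %d", r$n, min_module_size)
  if (r$flag == "degenerate_sigma")
    stop_modhub("degenerate connectivity distribution for '%s': sigma = 0, z undefined", gene)
  structure(list(gene = r$gene, xbar = r$xbar, mu = r$mu, sigma = r$sigma,
                 n = r$n, z = r$z, z_denominator = z_denominator),
            class = "connectivity_z")
}

#' @export
print.connectivity_z <- function(x, ...) {
  cat(sprintf("Module connectivity of '%s': z = %.4f (denominator sigma/%s)\n",
              x$gene, x$z, if (x$z_denominator == "se") "sqrt(n)" else "n"))
  cat(sprintf("  xbar = %.4f, mu = %.4f, sigma = %.4f, n = %d\n",
              x$xbar, x$mu, x$sigma, x$n))
  invisible(x)
}

#' Rank all network genes by module-connectivity z-score
#'
#' The central fit of the package: scores every eligible gene in the network
#' against a module with [module_connectivity_z()] and returns the
#' genome-wide hub ranking. The top-ranked gene is the strongest candidate
#' regulator of the module.
#'
#' Module members are scored by default (each against the module minus
#' itself). Genes with a degenerate (zero-variance) connectivity
#' distribution, or for which the effective module is too small, are not
#' ranked; they are kept in the table with a `flag` and sort last.
#'
#' @inheritParams module_connectivity_z
#' @param include_module_members score module members too (default TRUE).
#' @return an object of class `hub_ranking`: a data.frame with columns
#'   `gene, xbar, mu, sigma, n, z, rank, flag`, ordered by `z` descending
#'   (ties broken by gene identifier; `rank` is the 1-based competition
#'   rank, tied z share the minimum rank). Attributes record the module,
#'   settings and network size.
#' @examples
#' sim <- simulate_study(generator_params(n_genes = 120, module_size = 12,
#'                                        seed = 1))
#' fit <- rank_module_hubs(sim$network, sim$module)
#' head(as.data.frame(fit))
#' @export
rank_module_hubs <- function(net, module, include_module_members = TRUE,
                             min_module_size = 3,
                             z_denominator = c("se", "sd_over_n")) {
  stopifnot(inherits(net, "functional_network"), inherits(module, "gene_module"))
  z_denominator <- match.arg(z_denominator)
  cand <- net$genes
  if (!include_module_members) cand <- setdiff(cand, module$members)
  res <- score_genes(net, module, cand, min_module_size, z_denominator)
  ok <- !nzchar(res$flag)
  res$rank <- NA_integer_
  if (any(ok)) res$rank[ok] <- competition_rank(res$z[ok])
  ## display order: z desc, gene id asc; flagged genes last (by gene id)
  ord <- order(!ok, -ifelse(ok, res$z, -Inf), res$gene)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  structure(res,
            class = c("hub_ranking", "data.frame"),
            module = module$name,
            module_size = sum(module$members %in% net$genes),
            n_genes = length(net$genes),
            n_ranked = sum(ok),
            include_module_members = include_module_members,
            min_module_size = min_module_size,
            z_denominator = z_denominator,
            module_members = intersect(module$members, net$genes))
}

#' @export
print.hub_ranking <- function(x, top = 10, ...) {
  cat(sprintf("Hub ranking against module '%s' (%d members in network)\n",
              attr(x, "module"), attr(x, "module_size")))
  cat(sprintf("  %d of %d genes ranked; z denominator sigma/%s\n",
              attr(x, "n_ranked"), nrow(x),
              if (attr(x, "z_denominator") == "se") "sqrt(n)" else "n"))
  n_flag <- sum(nzchar(x$flag))
  if (n_flag) cat(sprintf("  %d gene(s) flagged (degenerate sigma or module too small)\n", n_flag))
  print.data.frame(utils::head(x, top), digits = 4)
  invisible(x)
}

#' @export
summary.hub_ranking <- function(object, top = 5, ...) {
  mem <- attr(object, "module_members")
  nonmod <- object[!(object$gene %in% mem) & !nzchar(object$flag), , drop = FALSE]
  out <- list(module = attr(object, "module"),
              n_genes = attr(object, "n_genes"),
              n_ranked = attr(object, "n_ranked"),
              n_flagged = sum(nzchar(object$flag)),
              top = utils::head(object[!nzchar(object$flag), ], top),
              top_non_member = utils::head(nonmod, top),
              z_denominator = attr(object, "z_denominator"))
  class(out) <- "summary.hub_ranking"
  out
}

#' @export
print.summary.hub_ranking <- function(x, ...) {
  cat(sprintf("Module '%s': %d/%d genes ranked, %d flagged\n",
              x$module, x$n_ranked, x$n_genes, x$n_flagged))
  cat("Top genes overall:\n")
  print.data.frame(x$top, digits = 4)
  cat("Top non-member genes (candidate regulators):\n")
  print.data.frame(x$top_non_member, digits = 4)
  invisible(x)
}

#' @export
plot.hub_ranking <- function(x, highlight = NULL, ...) {
  ok <- !nzchar(x$flag)
  graphics::plot(x$rank[ok], x$z[ok], log = "x", pch = 16, cex = 0.5,
                 xlab = "rank", ylab = "module-connectivity z",
                 main = sprintf("Hub ranking: module '%s'", attr(x, "module")), ...)
  if (!is.null(highlight)) {
    i <- which(x$gene %in% highlight & ok)
    graphics::points(x$rank[i], x$z[i], col = "red3", pch = 16)
    graphics::text(x$rank[i], x$z[i], x$gene[i], pos = 4, col = "red3", cex = 0.8)
  }
  invisible(x)
}

#' Connectivity rank of one gene among all partners of another
#'
#' Answers "how close a functional partner of `target` is `query`?": the
#' edge weight between the two genes, and the competition rank of that
#' weight among the weights of every other network gene to `target`.
#'
#' @param net a [functional_network()].
#' @param query,target distinct gene identifiers present in the network.
#' @return a list of class `pair_rank` with fields `query`, `target`,
#'   `weight`, `rank` (1-based competition rank of `query` among all genes
#'   g != target, by weight to `target`, descending) and `total`
#'   (number of genes ranked, i.e. network size minus one).
#' @export
pair_connectivity_rank <- function(net, query, target) {
  stopifnot(inherits(net, "functional_network"))
  miss <- setdiff(c(query, target), net$genes)
  if (length(miss)) stop_modhub("gene(s) not in network: %s", paste(miss, collapse = ", "))
  if (identical(query, target)) stop_modhub("query and target must differ")
  others <- setdiff(net$genes, target)
  w <- net$weights[others, target]
  wq <- net$weights[query, target]
  structure(list(query = query, target = target, weight = wq,
                 rank = as.integer(sum(w > wq) + 1L), total = length(others)),
            class = "pair_rank")
}

#' @export
print.pair_rank <- function(x, ...) {
  cat(sprintf("%s -- %s: weight %.4g, ranked %d out of %d partners of %s\n",
              x$query, x$target, x$weight, x$rank, x$total, x$target))
  invisible(x)
}

#' Five-gene toy network used in examples
#'
#' Gene A's weights to B, C, D, E are 0.9, 0.8, 0.1, 0.2; the remaining
#' pairs carry small fixed weights. Handy for illustrating the z-score
#' arithmetic by hand.
#' @return a [functional_network()] over genes A..E.
#' @export
example_network5 <- function() {
  g <- c("A", "B", "C", "D", "E")
  W <- matrix(0, 5, 5, dimnames = list(g, g))
  W["A", c("B", "C", "D", "E")] <- c(0.9, 0.8, 0.1, 0.2)
  W["B", c("C", "D", "E")] <- c(0.30, 0.20, 0.10)
  W["C", c("D", "E")] <- c(0.15, 0.25)
  W["D", "E"] <- 0.05
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  functional_network(W)
}
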