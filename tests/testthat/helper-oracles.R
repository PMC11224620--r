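## Independent brute-force oracles, deliberately naive: element-by-element
## loops and direct enumeration, never sharing code with the package paths
## they check.

## z-score by exhaustive per-element arithmetic.
oracle_z <- function(net, module_members, gene, denominator = "se") {
  genes <- net$genes
  W <- net$weights
  mod <- intersect(module_members, genes)
  mod <- setdiff(mod, gene)
  xs <- numeric(0)
  for (m in mod) xs <- c(xs, W[gene, m])
  xbar <- sum(xs) / length(xs)
  ref <- numeric(0)
  for (h in genes) if (h != gene) ref <- c(ref, W[gene, h])
  mu <- sum(ref) / length(ref)
  sigma <- sqrt(sum((ref - mu)^2) / (length(ref) - 1))
  n <- length(mod)
  den <- if (denominator == "se") sigma / sqrt(n) else sigma / n
  list(xbar = xbar, mu = mu, sigma = sigma, n = n, z = (xbar - mu) / den)
}

## One-sided hypergeometric tail by explicit choose-product summation.
oracle_fisher_p <- function(N, nA, nB, overlap) {
  ks <- overlap:min(nA, nB)
  ks <- ks[ks >= max(0, nA + nB - N)]
  sum(choose(nA, ks) * choose(N - nA, nB - ks)) / choose(N, nB)
}

## Exact one-sided rank-sum p by enumerating every assignment of the pooled
## values into a group of size n1.
oracle_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  rk <- rank(pooled)
  W_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  Ws <- apply(combos, 2, function(i) sum(rk[i]) - n1 * (n1 + 1) / 2)
  mean(Ws >= W_obs - 1e-9)
}

## BH step-up by the textbook recipe: p(i) * n / i, cumulative min from the
## largest rank, capped at 1, mapped back to input order.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

## Random symmetric [0,1]-weighted network over n genes.
random_network <- function(n, seed, letters_ids = FALSE) {
  set.seed(seed)
  ids <- if (letters_ids) paste0("G", seq_len(n)) else sprintf("r%03d", seq_len(n))
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  W[upper.tri(W)] <- runif(n * (n - 1) / 2)
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  functional_network(W, ids)
}

## Small DEG table with given significant genes (padj-driven).
make_deg_table <- function(genes, sig_genes, lfc = NULL) {
  sig <- genes %in% sig_genes
  deg_table(gene = genes,
            log2fc = if (is.null(lfc)) ifelse(sig, 2, 0.1) else lfc,
            pvalue = ifelse(sig, 1e-6, 0.9),
            padj = ifelse(sig, 1e-4, 0.95))
}

small_params <- function(seed = 1, ...) {
  generator_params(n_genes = 200, module_size = 20, seed = seed, ...)
}
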