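test_that("z-score matches hand arithmetic on the five-gene example", {
  net <- example_network5()
  ## A's weights: B 0.9, C 0.8, D 0.1, E 0.2; module {B, C}
  r <- module_connectivity_z(net, gene_module("M", c("B", "C")), "A",
                             min_module_size = 2)
  expect_equal(r$xbar, 0.85)
  expect_equal(r$mu, 0.5)
  expect_equal(r$sigma, sd(c(0.9, 0.8, 0.1, 0.2)))
  expect_equal(r$n, 2L)
  expect_equal(r$z, 0.35 / (sd(c(0.9, 0.8, 0.1, 0.2)) / sqrt(2)))
  expect_equal(r$z, 1.2124, tolerance = 1e-4)

  ## module == the whole reference population -> z exactly 0
  r0 <- module_connectivity_z(net, gene_module("M", c("B", "C", "D", "E")), "A")
  expect_equal(r0$xbar, r0$mu)
  expect_equal(r0$z, 0)

  ## sd_over_n denominator scales z by sqrt(n)
  r2 <- module_connectivity_z(net, gene_module("M", c("B", "C")), "A",
                              min_module_size = 2, z_denominator = "sd_over_n")
  expect_equal(r2$z, r$z * sqrt(2))
})

test_that("degenerate and invalid inputs error informatively", {
  g <- c("A", "B", "C", "D", "E")
  W <- matrix(0.5, 5, 5, dimnames = list(g, g))
  net <- functional_network(W)
  expect_error(module_connectivity_z(net, gene_module("M", c("B", "C", "D")), "A"),
               "degenerate")
  net5 <- example_network5()
  expect_error(module_connectivity_z(net5, gene_module("M", c("B", "C")), "Z"),
               "not in network")
  expect_error(module_connectivity_z(net5, gene_module("M", c("B", "C")), "A",
                                     min_module_size = 3),
               "below min_module_size")
  ## members absent from the network are dropped with a warning
  expect_warning(
    r <- module_connectivity_z(net5, gene_module("M", c("B", "C", "nope")), "A",
                               min_module_size = 2),
    "absent")
  expect_equal(r$n, 2L)
})

test_that("vectorized scoring equals the brute-force oracle on random instances", {
  for (seed in 1:8) {
    n <- sample(8:50, 1)
    net <- random_network(n, seed = 1000 + seed)
    msz <- sample(3:max(3, n %/% 3), 1)
    module <- gene_module("M", sample(net$genes, msz))
    fit <- rank_module_hubs(net, module)
    for (gene in sample(net$genes, 5)) {
      o <- oracle_z(net, module$members, gene)
      row <- fit[fit$gene == gene, ]
      if (o$n < 3) {
        expect_match(row$flag, "module_too_small")
      } else {
        expect_equal(row$z, o$z, tolerance = 1e-12)
        expect_equal(row$xbar, o$xbar, tolerance = 1e-12)
        expect_equal(row$sigma, o$sigma, tolerance = 1e-12)
      }
    }
  }
})

test_that("ranking is deterministic, competition-ranked, module members scored minus self", {
  net <- random_network(30, seed = 7)
  module <- gene_module("M", net$genes[1:6])
  fit <- rank_module_hubs(net, module)
  expect_s3_class(fit, "hub_ranking")
  expect_equal(nrow(fit), 30)
  expect_equal(sort(fit$rank), sort(rank(-fit$z, ties.method = "min")))
  expect_true(all(diff(fit$z) <= 1e-15))                 # sorted by z descending
  expect_equal(fit$n[match(net$genes[1], fit$gene)], 5L) # member scored vs module minus itself
  expect_equal(fit$n[match(net$genes[10], fit$gene)], 6L)
  ## member exclusion matches the single-gene path
  r <- module_connectivity_z(net, module, net$genes[1])
  expect_equal(fit$z[match(net$genes[1], fit$gene)], r$z)
  ## excluding members removes exactly the member rows
  fit2 <- rank_module_hubs(net, module, include_module_members = FALSE)
  expect_equal(nrow(fit2), 24)
  expect_false(any(module$members %in% fit2$gene))
  ## same input twice -> identical object
  expect_identical(as.data.frame(fit), as.data.frame(rank_module_hubs(net, module)))
})

test_that("degenerate genes are flagged, never ranked, and sort last", {
  g <- sprintf("q%02d", 1:10)
  set.seed(5)
  W <- matrix(0, 10, 10, dimnames = list(g, g))
  W[upper.tri(W)] <- runif(45)
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  W[1, -1] <- 0.4; W[-1, 1] <- 0.4          # gene 1: zero-variance connectivity
  net <- functional_network(W, g)
  fit <- rank_module_hubs(net, gene_module("M", g[4:8]))
  row <- fit[fit$gene == "q01", ]
  expect_equal(row$flag, "degenerate_sigma")
  expect_true(is.na(row$rank))
  expect_equal(fit$gene[nrow(fit)], "q01")   # flagged genes sort last
  expect_equal(attr(fit, "n_ranked"), 9)
})

test_that("a network too small to host any module yields an all-flagged ranking", {
  W <- matrix(c(1, 0.3, 0.3, 1), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  net <- functional_network(W)
  expect_warning(fit <- rank_module_hubs(net, gene_module("M", c("A", "B", "C"))),
                 "absent")
  expect_true(all(nzchar(fit$flag)))
  expect_equal(attr(fit, "n_ranked"), 0)
  expect_true(all(is.na(fit$rank)))
})

test_that("pair connectivity rank sorts partners of the target", {
  net <- example_network5()
  ## partners of A by weight: B 0.9 > C 0.8 > E 0.2 > D 0.1
  pr <- pair_connectivity_rank(net, "C", "A")
  expect_equal(pr$weight, 0.8)
  expect_equal(pr$rank, 2L)
  expect_equal(pr$total, 4L)
  expect_equal(pair_connectivity_rank(net, "B", "A")$rank, 1L)
  expect_error(pair_connectivity_rank(net, "A", "A"), "differ")
  expect_error(pair_connectivity_rank(net, "A", "Z"), "not in network")
  ## brute-force oracle on a random network
  net2 <- random_network(25, seed = 99)
  for (i in 1:5) {
    qt <- sample(net2$genes, 2)
    pr <- pair_connectivity_rank(net2, qt[1], qt[2])
    w <- sapply(setdiff(net2$genes, qt[2]), function(g) net2$weights[g, qt[2]])
    expect_equal(pr$rank, as.integer(sum(sort(w, decreasing = TRUE) > pr$weight) + 1))
    expect_equal(pr$total, 24L)
  }
})

test_that("monotonicity: raising a gene-module weight never lowers that gene's z", {
  set.seed(21)
  for (rep in 1:5) {
    net <- random_network(20, seed = 300 + rep)
    module <- gene_module("M", net$genes[2:7])
    gene <- net$genes[10]
    z0 <- module_connectivity_z(net, module, gene)$z
    m <- sample(module$members, 1)
    W <- net$weights
    W[gene, m] <- W[m, gene] <- min(1, W[gene, m] + runif(1, 0.05, 0.3))
    z1 <- module_connectivity_z(functional_network(W), module, gene)$z
    expect_gte(z1, z0 - 1e-12)
  }
})
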