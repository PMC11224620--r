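test_that("BH adjustment matches the step-up recipe and is order-invariant", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.5, 7)), rep(0.5, 7))
  expect_error(bh_adjust(c(0.1, 1.2)), "outside")

  set.seed(11)
  for (i in 1:10) {
    p <- runif(sample(2:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-14)
    expect_true(all(adj >= p - 1e-15 & adj <= 1))
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])   # order invariance
  }
})

test_that("DEG connectivity rank-sum: exact enumeration cases", {
  g <- c("H", "w1", "w2", "l1", "l2")
  W <- matrix(0.5, 5, 5, dimnames = list(g, g))
  W["H", c("w1", "w2", "l1", "l2")] <- c(0.9, 0.8, 0.1, 0.2)
  W[, "H"] <- W["H", ]
  net <- functional_network(W)
  degs <- make_deg_table(g[-1], c("w1", "w2"))

  r <- deg_connectivity_test(net, "H", degs)
  expect_equal(r$p.value, 1 / 6)           # most extreme of C(4,2) assignments
  expect_equal(r$n_deg, 2); expect_equal(r$n_nondeg, 2)
  expect_equal(r$median_deg, 0.85)
  expect_match(r$method, "^exact")

  ## identical connectivity multisets: no separation, p >= 0.5
  W2 <- W
  W2["H", c("w1", "w2", "l1", "l2")] <- c(0.3, 0.7, 0.3, 0.7)
  W2[, "H"] <- W2["H", ]
  r2 <- deg_connectivity_test(functional_network(W2), "H", degs)
  expect_gte(r2$p.value, 0.5)

  ## empty comparison groups error
  expect_error(deg_connectivity_test(net, "H", make_deg_table(g[-1], g[-1])),
               "empty comparison group")
  expect_error(deg_connectivity_test(net, "H", make_deg_table(g[-1], character(0))),
               "empty comparison group")
  expect_error(deg_connectivity_test(net, "nope", degs), "not in network")
})

test_that("rank-sum exact mode equals assignment enumeration; approx stays close", {
  set.seed(31)
  for (rep in 1:12) {
    n1 <- sample(5:6, 1); n2 <- sample(5:7, 1)
    while (n1 + n2 > 12) n2 <- n2 - 1
    n <- n1 + n2 + 1
    ids <- c("H", sprintf("t%02d", seq_len(n1 + n2)))
    W <- matrix(0, n, n, dimnames = list(ids, ids))
    W[upper.tri(W)] <- if (rep %% 2) runif(n * (n - 1) / 2)
                       else sample(seq(0, 1, 0.1), n * (n - 1) / 2, replace = TRUE)
    W[lower.tri(W)] <- t(W)[lower.tri(W)]
    net <- functional_network(W, ids)
    sig <- sample(ids[-1], n1)
    degs <- make_deg_table(ids[-1], sig)

    r <- deg_connectivity_test(net, "H", degs)
    x <- W[sig, "H"]; y <- W[setdiff(ids[-1], sig), "H"]
    expect_equal(r$p.value, oracle_wilcox_p(x, y), tolerance = 1e-12)

    r_apx <- deg_connectivity_test(net, "H", degs, exact_max = 0)
    expect_equal(r_apx$method, "normal_approx")
    ## tie-free instances: the corrected normal tail tracks the exact one
    if (rep %% 2) expect_lt(abs(r_apx$p.value - r$p.value), 0.01)
  }
})

test_that("Fisher overlap matches the hypergeometric tail and handles edge cases", {
  u <- sprintf("u%02d", 1:20)
  A <- u[1:5]; B <- c(u[1:5], u[6:8])    # overlap 5, |A|=5, |B|=8
  r <- fisher_overlap(A, B, u)
  expect_equal(r$p.value, choose(15, 3) / choose(20, 8))
  expect_equal(r$overlap, 5)
  expect_equal(sum(r$table), 20)
  expect_true(r$haldane)   # A-only cell is 0

  ## zero overlap: full upper tail, p = 1
  r0 <- fisher_overlap(u[1:5], u[6:10], u)
  expect_equal(r0$p.value, 1)
  ## degenerate margins: A == B == universe
  r1 <- fisher_overlap(u, u, u)
  expect_equal(r1$overlap, 20)
  expect_equal(r1$p.value, 1)

  expect_warning(fisher_overlap(c(A, "zzz"), B, u), "outside universe")
  expect_error(suppressWarnings(fisher_overlap("zzz", B, u)), "empty")
  expect_error(fisher_overlap(A, B, u[1:3]), "at least 4")
})

test_that("Fisher tail equals choose-product enumeration across universes up to 30", {
  for (N in c(4, 7, 12, 19, 30)) {
    u <- sprintf("x%02d", seq_len(N))
    for (nA in unique(c(1, N %/% 3, N %/% 2, N - 1))) {
      for (nB in unique(c(1, N %/% 2, N - 1))) {
        for (ov in unique(c(max(0, nA + nB - N), min(nA, nB) %/% 2, min(nA, nB)))) {
          A <- u[seq_len(nA)]
          B <- c(u[seq_len(ov)], if (nB > ov) u[nA + seq_len(nB - ov)])
          if (ov == 0) B <- u[nA + seq_len(nB)]
          if (max(0, nA + nB - N) > ov) next
          r <- suppressWarnings(fisher_overlap(A, B, u))
          expect_equal(r$p.value, oracle_fisher_p(N, nA, length(unique(B)), r$overlap),
                       tolerance = 1e-13)
        }
      }
    }
  }
})

test_that("signed overlap stratifies by direction and reports discordance", {
  genes <- sprintf("s%02d", 1:40)
  sig <- genes[1:10]
  lfc <- ifelse(genes %in% genes[1:5], 2, ifelse(genes %in% genes[6:10], -2, 0.05))
  dA <- make_deg_table(genes, sig, lfc = lfc)
  dB <- make_deg_table(genes, sig, lfc = lfc)

  r <- signed_overlap(dA, dB)
  expect_equal(r$up$overlap, 5)
  expect_equal(r$down$overlap, 5)
  expect_equal(r$combined$overlap, 10)
  expect_length(r$discordant, 0)
  expect_lt(r$combined$p.value, 1e-6)

  ## same DEGs, all signs flipped: direction overlaps vanish, discordance total
  dBflip <- make_deg_table(genes, sig, lfc = -lfc)
  rf <- signed_overlap(dA, dBflip)
  expect_equal(rf$up$overlap, 0)
  expect_equal(rf$down$overlap, 0)
  expect_length(rf$discordant, 10)
  expect_equal(rf$combined$overlap, 10)   # unsigned overlap unaffected
})

test_that("enrichment curve: closure, trivial folds, rug, grids", {
  g <- c("H", sprintf("e%02d", 1:10))
  W <- matrix(0, 11, 11, dimnames = list(g, g))
  W["H", g[-1]] <- seq(1, 0.1, length.out = 10)   # e01 highest ... e10 lowest
  W[, "H"] <- W["H", ]
  W[2:11, 2:11][upper.tri(matrix(0, 10, 10))] <- 0.01
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  net <- functional_network(W, g)

  degs <- make_deg_table(g[-1], c("e01", "e02"))   # DEGs at ranks 1-2
  cv <- rank_enrichment_curve(net, "H", degs)
  expect_equal(cv$fold[cv$k == 2], (2 / 2) / (2 / 10))   # = 5
  expect_equal(cv$fold[cv$k == 10], 1)                   # exact closure at k = N
  expect_equal(attr(cv, "rug"), c(1L, 2L))
  expect_true(all(diff(cv$hits) >= 0))
  expect_true(all(cv$hits <= pmin(cv$k, attr(cv, "n_deg"))))

  degs2 <- make_deg_table(g[-1], c("e09", "e10"))  # DEGs at the bottom
  cv2 <- rank_enrichment_curve(net, "H", degs2)
  expect_equal(cv2$fold[cv2$k == 8], 0)
  expect_equal(cv2$fold[cv2$k == 10], 1)

  expect_error(rank_enrichment_curve(net, "H", make_deg_table(g[-1], character(0))),
               "no DEGs")

  ## log-spaced grid on a larger universe still closes at N
  net2 <- random_network(60, seed = 13)
  degs3 <- make_deg_table(net2$genes[-1], sample(net2$genes[-1], 12))
  cvL <- rank_enrichment_curve(net2, net2$genes[1], degs3, cutoff_grid = "auto")
  expect_equal(cvL$fold[nrow(cvL)], 1)
  expect_equal(cvL$k[nrow(cvL)], 59L)
})
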