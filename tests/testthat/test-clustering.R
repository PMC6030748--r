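test_that("K = 1 gives full membership and the sampler is seed-stable", {
  fx <- sample_pop(20, c(`100` = 0.5, `102` = 0.5), 3)
  gt <- toy_table(fx$a1, fx$a2, rep("P", 20))
  fit <- admixture_gibbs(gt, 1, iters = 300, burnin = 100, seed = 2)
  expect_true(all(fit$Q == 1))
  f1 <- admixture_gibbs(gt, 2, iters = 300, burnin = 100, seed = 5)
  f2 <- admixture_gibbs(gt, 2, iters = 300, burnin = 100, seed = 5)
  expect_identical(f1$Q, f2$Q)
})

test_that("fully separated populations are recovered at K = 2", {
  n <- 25
  a <- matrix(rep(c(100L, 120L), each = n), ncol = 1)[, rep(1, 10)]
  gt <- toy_table(a, a, rep(c("A", "B"), each = n))
  fit <- admixture_gibbs(gt, 2, iters = 1500, burnin = 400, seed = 5)
  own <- pmax(fit$Q[, 1], fit$Q[, 2])
  expect_gt(min(own), 0.95)
  # the two populations occupy different clusters
  expect_gt(abs(mean(fit$Q[1:n, 1]) - mean(fit$Q[n + 1:n, 1])), 0.9)
  # Q rows are proper proportions
  expect_equal(unname(rowSums(fit$Q)), rep(1, 2 * n), tolerance = 1e-12)
})

test_that("individuals with no genotypes are excluded with a warning", {
  fx <- sample_pop(10, c(`100` = 0.5, `102` = 0.5), 2)
  a1 <- rbind(fx$a1, NA); a2 <- rbind(fx$a2, NA)
  gt <- toy_table(a1, a2, rep("P", 11))
  expect_warning(fit <- admixture_gibbs(gt, 2, iters = 200, burnin = 50,
                                        seed = 1),
                 "excluded")
  expect_equal(nrow(fit$Q), 10L)
})

test_that("replicate lnP estimates agree within the replicate spread", {
  fx <- study_fx()
  gt <- subset_geno(fx$genotypes, pops = c("DAN4", "VIS1", "ODR1"))
  lps <- vapply(1:4, function(r)
    admixture_gibbs(gt, 2, iters = 1200, burnin = 400, seed = 40 + r)$lnP,
    numeric(1))
  expect_lt(abs(lps[1] - lps[2]), 3 * sd(lps) + 1e-8)
})

test_that("Evanno's delta-K picks a constructed kink and rejects bad input", {
  Ks <- 1:5
  # lnP exactly linear in K -> deltaK 0 everywhere defined
  lin <- matrix(rep(-1000 + 50 * Ks, 2), ncol = 2)
  rownames(lin) <- Ks
  lin <- lin + matrix(c(0.5, -0.5), 5, 2, byrow = TRUE)  # nonzero sd
  dk <- delta_k_series(lin, Ks)
  expect_equal(dk$deltaK[2:4], rep(0, 3), tolerance = 1e-9)
  expect_true(all(is.na(dk$deltaK[c(1, 5)])))
  # kink at K = 3: closed-form second difference / sd
  m <- c(-2000, -1500, -1200, -1150, -1100)
  kink <- matrix(rep(m, 2), ncol = 2) + matrix(c(1, -1), 5, 2, byrow = TRUE)
  rownames(kink) <- Ks
  dk2 <- delta_k_series(kink, Ks)
  expect_equal(dk2$K[which.max(dk2$deltaK)], 3)
  expect_equal(dk2$deltaK[3],
               abs(m[4] - 2 * m[3] + m[2]) / sd(kink[3, ]))
  # zero replicate spread flagged as infinite
  zero <- matrix(rep(m, 2), ncol = 2); rownames(zero) <- Ks
  expect_true(is.infinite(delta_k_series(zero, Ks)$deltaK[3]))
  # a single replicate cannot support delta-K
  gt <- toy_table(matrix(c(100L, 102L, 100L, 104L)),
                  matrix(c(100L, 102L, 102L, 104L)), rep("P", 4))
  expect_error(scan_k(gt, 1:3, replicates = 1L, iters = 100, burnin = 10),
               "replicate")
  expect_error(scan_k(gt, c(1, 3), replicates = 2L), "contiguous")
})

test_that("greedy run alignment undoes label switching", {
  set.seed(6)
  Q <- matrix(rgamma(40 * 3, 1), 40); Q <- Q / rowSums(Q)
  swapped <- Q[, c(3, 1, 2)]
  al <- align_runs(list(Q, swapped))
  expect_equal(al$runs[[2]], Q, ignore_attr = TRUE)
  expect_equal(al$G, c(1, 1))
  expect_equal(al$mean_Q, Q, ignore_attr = TRUE)
  # aligning a run with itself is the identity
  al2 <- align_runs(list(Q, Q))
  expect_equal(al2$runs[[2]], Q, ignore_attr = TRUE)
  expect_error(align_runs(list(Q, Q[, 1:2])), "share")
})

test_that("greedy alignment equals the exhaustive optimum for small K", {
  set.seed(11)
  for (K in 2:4) {
    Q1 <- matrix(rgamma(30 * K, 1), 30); Q1 <- Q1 / rowSums(Q1)
    Q2 <- matrix(rgamma(30 * K, 1), 30); Q2 <- Q2 / rowSums(Q2)
    al <- align_runs(list(Q1, Q2))
    # brute force over all permutations of Q2's columns
    perms <- hydropop:::.all_perms(K)
    gbest <- max(apply(perms, 1, function(pp)
      hydropop:::.g_similarity(Q2[, pp, drop = FALSE], Q1)))
    gal <- hydropop:::.g_similarity(al$runs[[2]], Q1)
    expect_equal(gal, gbest)
  }
})

test_that("correspondence analysis matches an independent decomposition", {
  set.seed(3)
  a1 <- matrix(sample(c(100L, 102L, 104L), 40 * 4, TRUE), ncol = 4)
  a2 <- matrix(sample(c(100L, 102L, 104L), 40 * 4, TRUE), ncol = 4)
  gt <- toy_table(a1, a2, rep(c("A", "B"), each = 20))
  f <- fca(gt, n_axes = 2)
  # oracle: MASS::corresp on the same indicator matrix
  X <- do.call(cbind, lapply(1:4, function(j)
    sapply(c(100, 102, 104), function(a)
      (gt$a1[, j] == a) + (gt$a2[, j] == a))))
  co <- MASS::corresp(X, nf = 2)
  # principal coordinates agree up to axis sign
  for (ax in 1:2) {
    v1 <- f$ind_coords[, ax]
    v2 <- co$rscore[, ax] * co$cor[ax]
    expect_lt(min(max(abs(v1 - v2)), max(abs(v1 + v2))), 1e-8)
  }
  # duplicated individuals land on identical coordinates
  gt2 <- toy_table(rbind(a1, a1[1, , drop = FALSE]),
                   rbind(a2, a2[1, , drop = FALSE]),
                   c(rep(c("A", "B"), each = 20), "A"))
  f2 <- fca(gt2)
  expect_equal(unname(f2$ind_coords[41, ]), unname(f2$ind_coords[1, ]),
               tolerance = 1e-10)
  # two fixed-difference populations separate with zero within-pop spread
  af <- matrix(rep(c(100L, 120L), each = 10), ncol = 1)[, c(1, 1)]
  gtf <- toy_table(af, af, rep(c("A", "B"), each = 10))
  ff <- fca(gtf, n_axes = 1)
  expect_equal(sd(ff$ind_coords[1:10, 1]), 0, tolerance = 1e-12)
  expect_gt(abs(ff$pop_centroids["A", 1] - ff$pop_centroids["B", 1]), 0.5)
  # monomorphic-only tables are rejected
  gm <- toy_table(matrix(100L, 5, 2), matrix(100L, 5, 2), rep("P", 5))
  expect_error(fca(gm), "polymorphic")
})

test_that("the fixture's Czech Oder populations join the Danube-side cluster", {
  gt <- study_fx()$genotypes
  fit <- admixture_gibbs(gt, 2, iters = 2000, burnin = 500, seed = 42)
  qbar <- rowsum(fit$Q, gt$pop)
  qbar <- qbar / as.vector(table(gt$pop)[rownames(qbar)])
  dan <- c("DAN1", "DAN2", paste0("DAN", 4:10))
  dan_cl <- which.max(colMeans(qbar[dan, ]))
  expect_gt(min(qbar[abc_groups()$CZODER, dan_cl]), 0.5)
  expect_lt(qbar["ODR4", dan_cl], 0.5)
  expect_lt(qbar["VIS1", dan_cl], 0.5)
  # FCA places CZODER with the Danube populations, not with POLRIV
  f <- fca(gt)
  ax <- f$pop_centroids[, 1]
  d_to <- function(p, set) abs(ax[p] - mean(ax[set]))
  for (p in abc_groups()$CZODER)
    expect_lt(d_to(p, dan), d_to(p, abc_groups()$POLRIV))
})
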