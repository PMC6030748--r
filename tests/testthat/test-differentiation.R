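test_that("Weir-Cockerham theta matches independent symbolic evaluation", {
  # pop A: (1,1),(1,2),(2,2),(1,2); pop B: (1,1),(1,1),(1,2),(1,1)
  a1 <- matrix(c(100L, 100L, 102L, 100L, 100L, 100L, 100L, 100L))
  a2 <- matrix(c(100L, 102L, 102L, 102L, 100L, 100L, 102L, 100L))
  gt <- toy_table(a1, a2, rep(c("A", "B"), each = 4))
  th <- pairwise_fst(gt, "A", "B")
  # direct evaluation of the 1984 estimator for two alleles
  ni <- c(4, 4); r <- 2; nbar <- 4
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  p <- c(4 / 8, 7 / 8)        # freq of allele 100 in A, B
  h <- c(2 / 4, 1 / 4)        # het proportion per pop
  pbar <- sum(ni * p) / (r * nbar)
  s2 <- sum(ni * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  expect_equal(th, (2 * a) / (2 * (a + b + cc)))   # both alleles symmetric
})

test_that("theta hits its boundary cases", {
  fixed <- toy_table(matrix(c(rep(100L, 8), rep(110L, 8))),
                     matrix(c(rep(100L, 8), rep(110L, 8))),
                     rep(c("A", "B"), each = 8))
  expect_equal(pairwise_fst(fixed, "A", "B"), 1)
  expect_equal(pairwise_rst(fixed, "A", "B"), 1)
  # two samples from one panmictic pool: mean theta ~ 0
  set.seed(5)
  ths <- replicate(100, {
    fx <- sample_pop(30, c(`100` = 0.4, `102` = 0.3, `104` = 0.3), 3)
    pairwise_fst(toy_table(fx$a1, fx$a2, rep(c("A", "B"), 15)), "A", "B")
  })
  expect_lt(abs(mean(ths)), 2 * sd(ths) / sqrt(100))
})

test_that("theta and rho respect their invariances", {
  set.seed(8)
  fxa <- sample_pop(20, c(`100` = 0.6, `102` = 0.25, `104` = 0.15), 2)
  fxb <- sample_pop(20, c(`100` = 0.2, `102` = 0.3, `104` = 0.5), 2)
  gt <- toy_table(rbind(fxa$a1, fxb$a1), rbind(fxa$a2, fxb$a2),
                  rep(c("A", "B"), each = 20))
  th0 <- pairwise_fst(gt, "A", "B")
  # theta invariant under allele relabeling (identity only matters)
  swap <- function(m) { m2 <- m; m2[m == 100L] <- 104L; m2[m == 104L] <- 100L; m2 }
  gt_sw <- toy_table(swap(rbind(fxa$a1, fxb$a1)), swap(rbind(fxa$a2, fxb$a2)),
                     rep(c("A", "B"), each = 20))
  expect_equal(pairwise_fst(gt_sw, "A", "B"), th0)
  # rho invariant under adding a constant to all sizes at a locus
  rho0 <- pairwise_rst(gt, "A", "B")
  gt_shift <- toy_table(rbind(fxa$a1, fxb$a1) + 20L,
                        rbind(fxa$a2, fxb$a2) + 20L,
                        rep(c("A", "B"), each = 20))
  expect_equal(pairwise_rst(gt_shift, "A", "B"), rho0)
})

test_that("R_ST equals a direct ANOVA on repeat counts", {
  set.seed(9)
  fxa <- sample_pop(15, c(`100` = 0.5, `104` = 0.3, `110` = 0.2))
  fxb <- sample_pop(15, c(`100` = 0.1, `104` = 0.2, `110` = 0.7))
  gt <- toy_table(rbind(fxa$a1, fxb$a1), rbind(fxa$a2, fxb$a2),
                  rep(c("A", "B"), each = 15))
  rho <- pairwise_rst(gt, "A", "B")
  # oracle: one-way ANOVA variance components on gene-copy repeat counts
  x <- (c(gt$a1, gt$a2) - 100L) / 2
  lab <- rep(gt$pop, 2)
  ni <- table(lab); N <- sum(ni); r <- 2
  means <- tapply(x, lab, mean)
  ssb <- sum(ni * (means - mean(x))^2)
  ssw <- sum((x - means[lab])^2)
  msb <- ssb / (r - 1); msw <- ssw / (N - r)
  n0 <- (N - sum(ni^2) / N) / (r - 1)
  sb <- (msb - msw) / n0
  expect_equal(rho, sb / (sb + msw))
})

test_that("the F_ST permutation test behaves at its extremes", {
  fixed <- toy_table(matrix(c(rep(100L, 8), rep(110L, 8))),
                     matrix(c(rep(100L, 8), rep(110L, 8))),
                     rep(c("A", "B"), each = 8))
  r <- fst_permutation_test(fixed, "A", "B", n_perm = 99, seed = 1)
  expect_equal(r$p, 1 / 100)
  r2 <- fst_permutation_test(fixed, "A", "B", n_perm = 99, seed = 1)
  expect_identical(r, r2)   # deterministic given seed
})

test_that("allele-size permutation keeps R_ST fixed for exchangeable sizes", {
  # equally-spaced alleles whose sizes are a random relabeling: the
  # observed R_ST must sit inside the permutation distribution's support
  set.seed(10)
  fxa <- sample_pop(20, c(`100` = 0.7, `102` = 0.2, `104` = 0.1), 2)
  fxb <- sample_pop(20, c(`100` = 0.1, `102` = 0.2, `104` = 0.7), 2)
  gt <- toy_table(rbind(fxa$a1, fxb$a1), rbind(fxa$a2, fxb$a2),
                  rep(c("A", "B"), each = 20))
  r <- allele_size_permutation_test(gt, n_perm = 199, seed = 2)
  expect_true(r$ci[1] <= r$ci[2])
  expect_true(r$p >= 1 / 200 && r$p <= 1)
  # mutation-driven divergence (large size gap between pops, five loci)
  big <- toy_table(matrix(rep(c(rep(100L, 15), rep(120L, 15)), 5), ncol = 5),
                   matrix(rep(c(rep(102L, 15), rep(122L, 15)), 5), ncol = 5),
                   rep(c("A", "B"), each = 15))
  rb <- allele_size_permutation_test(big, n_perm = 199, seed = 3)
  expect_lt(rb$p, 0.05)
})

test_that("AMOVA components reproduce a brute-force SSD decomposition", {
  set.seed(9)
  n <- 8
  pops <- rep(c("P1", "P2", "P3", "P4"), each = n)
  a1 <- matrix(sample(c(100L, 102L, 104L), 4 * n * 2, TRUE), ncol = 2)
  a2 <- matrix(sample(c(100L, 102L, 104L), 4 * n * 2, TRUE), ncol = 2)
  miss <- matrix(runif(4 * n * 2) < 0.1, ncol = 2)
  a1[miss] <- NA; a2[miss] <- NA
  gt <- toy_table(a1, a2, pops)
  gs <- grouping_scheme(unique(pops), c("G1", "G1", "G2", "G2"))
  am <- amova(gt, gs, n_perm = 0)
  brute <- vapply(1:2, function(j) {
    copies <- c(gt$a1[, j], gt$a2[, j]); lab <- rep(gt$pop, 2)
    ok <- !is.na(copies); copies <- copies[ok]; lab <- lab[ok]
    D <- outer(copies, copies, "!=") * 1
    ssd <- function(sel) { k <- sum(sel); if (k == 0) 0 else sum(D[sel, sel]) / 2 / k }
    wp <- sum(vapply(unique(lab), function(p) ssd(lab == p), numeric(1)))
    wg <- sum(vapply(list(c("P1", "P2"), c("P3", "P4")),
                     function(g) ssd(lab %in% g), numeric(1)))
    tot <- ssd(rep(TRUE, length(lab)))
    c(ag = tot - wg, ap = wg - wp, wp = wp)
  }, numeric(3))
  expect_equal(unname(am$ssd), unname(rowSums(brute)))
  # disjoint fixed groups: F_CT -> 1
  af <- matrix(c(rep(100L, 16), rep(110L, 16)), ncol = 1)
  gtf <- toy_table(af, af, pops)
  expect_equal(amova(gtf, gs, n_perm = 0)$FCT, 1)
  # panmictic pool: mean F_CT ~ 0 over replicates
  set.seed(12)
  fcts <- replicate(60, {
    fx <- sample_pop(4 * n, c(`100` = 0.4, `102` = 0.35, `104` = 0.25), 2)
    amova(toy_table(fx$a1, fx$a2, pops), gs, n_perm = 0)$FCT
  })
  expect_lt(abs(mean(fcts)), 2.5 * sd(fcts) / sqrt(60))
  # errors: fewer than two groups
  expect_error(amova(gt, grouping_scheme(unique(pops), rep("G", 4))),
               "groups")
})

test_that("isolation-by-distance recovers a constructed linear signal", {
  n <- 7
  pops <- paste0("P", 1:n)
  set.seed(3)
  y <- matrix(runif(n * n, 0.05, 0.4), n); y <- (y + t(y)) / 2; diag(y) <- 0
  dimnames(y) <- list(pops, pops)
  f <- y / (1 + y)                      # so f/(1-f) = y exactly
  dm <- exp(y); diag(dm) <- 0           # ln(distance) == y + noise-free
  gs <- grouping_scheme(pops, rep("G", n), dist = dm)
  r <- ibd_regression(f, gs, n_perm = 199, seed = 4)
  expect_equal(r$mantel_r, 1, tolerance = 1e-10)
  expect_equal(r$p, 1 / 200, tolerance = 1e-9)
  expect_equal(r$slope, 1, tolerance = 1e-8)
  # permuting population order leaves slope and r unchanged
  ord <- sample(pops)
  gs2 <- grouping_scheme(ord, rep("G", n), dist = dm[ord, ord])
  r2 <- ibd_regression(f[ord, ord], gs2, n_perm = 199, seed = 4)
  expect_equal(r2$slope, r$slope)
  expect_equal(r2$mantel_r, r$mantel_r)
})

test_that("pairwise matrices cover every unordered pair of the fixture", {
  gt <- study_fx()$genotypes
  pm <- pairwise_matrices(gt)
  expect_equal(sum(!is.na(pm$fst[upper.tri(pm$fst)])), 351L)
  expect_equal(sum(!is.na(pm$rst[upper.tri(pm$rst)])), 351L)
  expect_true(isTRUE(all.equal(pm$fst, t(pm$fst))))
})

test_that("the fixture carries the translocation and watershed signals", {
  fx <- study_fx()
  gt <- fx$genotypes
  # CZODER is closer to its source (NMORAV) than to its own watershed
  f_trans <- mean(outer(abc_groups()$CZODER, abc_groups()$NMORAV,
                        Vectorize(function(a, b) pairwise_fst(gt, a, b))))
  f_balt <- mean(outer(abc_groups()$CZODER, abc_groups()$POLRIV,
                       Vectorize(function(a, b) pairwise_fst(gt, a, b))))
  expect_lt(f_trans, f_balt)
  # removing the mismatched populations strengthens the watershed signal
  apops <- amova_populations()
  am_all <- amova(subset_geno(gt, pops = apops), fx$grouping, n_perm = 0)
  am_red <- amova(subset_geno(gt,
                              pops = setdiff(apops, mismatched_populations())),
                  fx$grouping, n_perm = 0)
  expect_gt(am_red$FCT, am_all$FCT)
})
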