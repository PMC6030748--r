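test_that("no mutation means one allele everywhere", {
  s <- scenario(data.frame(name = "A", n = 20, ne = 100))
  gt <- simulate_coalescent(s, mutation_model(mean_rate = 1e-12,
                                              rate_shape = Inf),
                            5, seed = 1)
  expect_equal(length(unique(c(gt$a1, gt$a2))), 1L)
  expect_equal(heterozygosity(gt, "A")$He, rep(0, 5))
})

test_that("a split at time zero leaves no differentiation", {
  s <- scenario(data.frame(name = c("A", "B"), n = c(50, 50),
                           ne = c(1000, 1000)),
                data.frame(time = 0, type = "origin", pop = "B", src1 = "A",
                           src2 = NA, rate = NA, ne = NA))
  gt <- simulate_coalescent(s, mutation_model(rate_shape = Inf), 50, seed = 3)
  expect_lt(abs(pairwise_fst(gt, "A", "B")), 0.02)
})

test_that("strict-SMM equilibrium heterozygosity matches the closed form", {
  # E[He] = 1 - 1/sqrt(1 + 8 N mu) for the unbounded one-step model
  N <- 1000; mu <- 5e-4; L <- 500
  s <- scenario(data.frame(name = "A", n = 50, ne = N))
  gt <- simulate_coalescent(s, mutation_model(mean_rate = mu, p_geom = 0,
                                              allele_range = 80L,
                                              rate_shape = Inf),
                            L, seed = 7)
  he <- vapply(seq_len(L), function(j) {
    al <- c(gt$a1[, j], gt$a2[, j])
    p <- table(al) / length(al)
    1 - sum(p^2)
  }, numeric(1))
  expected <- 1 - 1 / sqrt(1 + 8 * N * mu)
  se <- sd(he) / sqrt(L)
  expect_lt(abs(mean(he) - expected), 3 * se)
})

test_that("simulation is deterministic given the seed", {
  s <- study_scenario()
  g1 <- simulate_coalescent(s, mutation_model(), 4, seed = 9)
  g2 <- simulate_coalescent(s, mutation_model(), 4, seed = 9)
  expect_identical(g1$a1, g2$a1)
  expect_identical(g1$a2, g2$a2)
  g3 <- simulate_coalescent(s, mutation_model(), 4, seed = 10)
  expect_false(identical(g1$a1, g3$a1))
})

test_that("expected F_ST increases with split time", {
  mean_fst <- function(t) {
    s <- scenario(data.frame(name = c("A", "B"), n = c(30, 30),
                             ne = c(500, 500)),
                  data.frame(time = t, type = "origin", pop = "B",
                             src1 = "A", src2 = NA, rate = NA, ne = NA))
    mean(vapply(1:8, function(r)
      pairwise_fst(simulate_coalescent(s, mutation_model(rate_shape = Inf),
                                       20, seed = 100 * t + r), "A", "B"),
      numeric(1)))
  }
  f <- vapply(c(0, 50, 500), mean_fst, numeric(1))
  expect_true(f[1] < f[2] && f[2] < f[3])
})

test_that("scenarios without a common root are rejected before simulating", {
  expect_error(
    scenario(data.frame(name = c("A", "B"), n = c(5, 5), ne = c(100, 100))),
    "no common root")
  expect_error(
    scenario(data.frame(name = "A", n = 5, ne = 100),
             data.frame(time = -1, type = "origin", pop = "A", src1 = "A",
                        src2 = NA, rate = NA, ne = NA)),
    "times")
})

test_that("zero-rate admixture is distributionally a pure split", {
  base <- data.frame(name = c("C", "A", "B", "ANC"), n = c(25, 25, 25, 0),
                     ne = c(500, 500, 500, 1000))
  anc <- data.frame(time = 1000, type = "origin", pop = c("A", "B"),
                    src1 = "ANC", src2 = NA, rate = NA, ne = NA)
  s_adm <- scenario(base, rbind(
    data.frame(time = 100, type = "admix", pop = "C", src1 = "A", src2 = "B",
               rate = 0, ne = NA), anc))
  s_pure <- scenario(base, rbind(
    data.frame(time = 100, type = "origin", pop = "C", src1 = "B", src2 = NA,
               rate = NA, ne = NA), anc))
  groups <- list(C = "C", A = "A", B = "B")
  mut <- mutation_model(rate_shape = Inf)
  st <- function(s, r) summary_statistics(
    simulate_coalescent(s, mut, 15, seed = r), groups)
  m_adm <- rowMeans(vapply(1:12, function(r) st(s_adm, r), numeric(18)))
  m_pure <- rowMeans(vapply(13:24, function(r) st(s_pure, r), numeric(18)))
  # identical generative law: replicate means agree loosely everywhere
  expect_lt(max(abs(m_adm - m_pure) / pmax(abs(m_pure), 0.05)), 0.35)
  # and the admixture-specific signal (C's F_ST to each source) agrees
  expect_lt(abs(m_adm[["FST_C_A"]] - m_pure[["FST_C_A"]]), 0.05)
  expect_lt(abs(m_adm[["FST_C_B"]] - m_pure[["FST_C_B"]]), 0.05)
})

test_that("nuisance overlay behaves at its extremes and in between", {
  fx <- sample_pop(40, c(`100` = 0.4, `102` = 0.3, `104` = 0.3), 2)
  gt <- toy_table(fx$a1, fx$a2, rep("P", 40))
  same <- apply_nuisance(gt, nuisance_model(), seed = 1)
  expect_identical(same$a1, gt$a1)
  gone <- apply_nuisance(gt, nuisance_model(
    null_freq = c(L1 = 1, L2 = 1)), seed = 1)
  expect_true(all(is.na(gone$a1)))
  # a null frequency inflates apparent homozygosity
  set.seed(2)
  fx2 <- sample_pop(500, c(`100` = 0.5, `102` = 0.5), 1)
  gt2 <- toy_table(fx2$a1, fx2$a2, rep("P", 500))
  withn <- apply_nuisance(gt2, nuisance_model(null_freq = c(L1 = 0.2)),
                          seed = 3)
  expect_gt(mean(withn$a1 == withn$a2, na.rm = TRUE),
            mean(gt2$a1 == gt2$a2))
})

test_that("the study fixture matches the sampling design", {
  fx <- study_fx()
  gt <- fx$genotypes
  expect_equal(length(gt$ind), 688L)
  expect_equal(length(populations(gt)), 27L)
  sizes <- vapply(abc_groups(), function(g) sum(gt$pop %in% g), integer(1))
  expect_equal(unname(sizes[c("CZELBE", "NMORAV", "CZODER", "WMORAV",
                              "POLRIV")]),
               c(86L, 175L, 85L, 56L, 75L))
  expect_equal(length(fx$alignment$seq), 83L)
  # determinism: same seed, bitwise identical files
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_genepop(make_study_fixture(5)$genotypes, f1)
  write_genepop(make_study_fixture(5)$genotypes, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("scenario configurations round-trip through YAML", {
  f <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("populations:",
               "  - {name: A, n: 10, ne: 500}",
               "  - {name: B, n: 10, ne: 300}",
               "events:",
               "  - {time: 100, type: origin, pop: B, src1: A}",
               "mutation: {mean_rate: 1.0e-3, p_geom: 0.1}"), f)
  cfg <- read_scenario_config(f)
  expect_equal(cfg$scenario$populations$ne, c(500, 300))
  expect_equal(cfg$scenario$events$type, "origin")
  expect_equal(cfg$mutation$mean_rate, 1e-3)
  expect_equal(cfg$mutation$p_geom, 0.1)
})
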