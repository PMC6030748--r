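test_that("summary statistics match direct hand computation", {
  # X: hom(100), het(100,102); Y: hom(102), hom(104)
  a1 <- matrix(c(100L, 100L, 102L, 104L), ncol = 1)
  a2 <- matrix(c(100L, 102L, 102L, 104L), ncol = 1)
  gt <- toy_table(a1, a2, c("X", "X", "Y", "Y"))
  ss <- summary_statistics(gt, list(X = "X", Y = "Y"))
  expect_equal(unname(ss["A_X"]), 2)
  expect_equal(unname(ss["A_Y"]), 2)
  # unbiased gene diversity on 4 copies of X: (4/3)(1 - (3/4)^2 - (1/4)^2)
  expect_equal(unname(ss["H_X"]), (4 / 3) * (1 - (3 / 4)^2 - (1 / 4)^2))
  # repeat counts X: 0,0,0,1 -> var = 1/4; Y: 1,1,2,2 -> var = 1/3
  expect_equal(unname(ss["V_X"]), var(c(0, 0, 0, 1)))
  expect_equal(unname(ss["V_Y"]), var(c(1, 1, 2, 2)))
  # DAS: pair ps = {0, 0, .5, 0} -> 1 - 0.125
  expect_equal(unname(ss["DAS_X_Y"]), 1 - mean(c(0, 0, 0.5, 0)))
  # (delta mu)^2 on repeat scale: (0.25 - 1.5)^2
  expect_equal(unname(ss["DMU2_X_Y"]), (0.25 - 1.5)^2)
})

test_that("summary statistics hit degenerate baselines", {
  # monomorphic data
  gm <- toy_table(matrix(100L, 8, 2), matrix(100L, 8, 2),
                  rep(c("A", "B"), 4))
  sm <- summary_statistics(gm, list(A = "A", B = "B"))
  expect_equal(unname(sm[c("A_A", "H_A", "V_A", "DMU2_A_B")]), c(1, 0, 0, 0))
  # two identical groups: FST ~ 0, DMU2 = 0
  fx <- sample_pop(40, c(`100` = 0.5, `102` = 0.3, `104` = 0.2), 4)
  gt <- toy_table(fx$a1, fx$a2, rep(c("A", "B"), 20))
  ss <- summary_statistics(gt, list(A = "A", B = "B"))
  expect_lt(abs(ss[["FST_A_B"]]), 0.08)
  expect_lt(ss[["DMU2_A_B"]], 0.2)
  expect_error(summary_statistics(gt, list(A = "A", Z = "nope")),
               "non-empty")
})

toy_models <- function() {
  prior <- data.frame(param = c("N1", "N2", "NANC", "t"),
                      min = c(100, 100, 100, 10), max = c(2000, 2000, 2000, 200))
  mk <- function(tmul) function(theta)
    scenario(data.frame(name = c("P1", "P2", "ANC"), n = c(25, 25, 0),
                        ne = c(theta[[1]], theta[[2]], theta[[3]])),
             data.frame(time = theta[[4]] * tmul, type = "origin",
                        pop = "P1", src1 = "P2", src2 = NA, rate = NA,
                        ne = NA))
  list(recent = abc_model("recent", prior, mk(1)),
       old = abc_model("old", prior, mk(20)))
}

test_that("reference tables are seed-deterministic and prior-faithful", {
  m <- toy_models()
  loci <- locus_set(sprintf("L%02d", 1:6), 2)
  mut <- mutation_model(p_geom = 0.22)
  groups <- list(P1 = "P1", P2 = "P2")
  expect_equal(nrow(build_reference(list(), groups, 0, mut, loci)), 0L)
  r1 <- build_reference(m, groups, 150, mut, loci, seed = 4)
  r2 <- build_reference(m, groups, 150, mut, loci, seed = 4)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 300L)
  # parameter marginals match their uniform priors (KS, alpha = 0.01)
  ks <- stats::ks.test(r1$par_t[r1$scenario == "recent"], "punif", 10, 200)
  expect_gt(ks$p.value, 0.01)
  expect_true(all(r1$par_N1 >= 100 & r1$par_N1 <= 2000))
})

test_that("model choice is symmetric for indistinguishable scenarios", {
  m <- toy_models()
  same <- list(abc_model("s1", m$recent$prior, m$recent$builder),
               abc_model("s2", m$recent$prior, m$recent$builder))
  loci <- locus_set(sprintf("L%02d", 1:6), 2)
  mut <- mutation_model(p_geom = 0.22)
  groups <- list(P1 = "P1", P2 = "P2")
  ref <- build_reference(same, groups, 400, mut, loci, seed = 6)
  set.seed(60)
  th <- c(N1 = 500, N2 = 500, NANC = 500, t = 100)
  gt <- simulate_coalescent(m$recent$builder(th), mut, 6, seed = 99,
                            loci = loci)
  obs <- summary_statistics(gt, groups)
  mc <- suppressWarnings(model_choice(ref, obs, tolerance = 0.2))
  expect_equal(sum(mc$posterior), 1)
  expect_lt(max(abs(mc$posterior - 0.5)), 0.25)
  # a reference covering a single scenario is refused
  one <- ref[ref$scenario == "s1", ]
  expect_error(model_choice(one, obs), "2 scenarios")
})

test_that("rejection counts and logistic posteriors agree when separated", {
  m <- toy_models()
  loci <- locus_set(sprintf("L%02d", 1:8), 2)
  mut <- mutation_model(p_geom = 0.22)
  groups <- list(P1 = "P1", P2 = "P2")
  ref <- build_reference(m, groups, 1500, mut, loci, seed = 8)
  th <- c(N1 = 800, N2 = 800, NANC = 800, t = 100)
  gt <- simulate_coalescent(m$recent$builder(th), mut, 8, seed = 123,
                            loci = loci)
  obs <- summary_statistics(gt, groups)
  mc <- suppressWarnings(model_choice(ref, obs, tolerance = 0.05))
  i <- which(mc$scenario == "recent")
  expect_equal(mc$posterior[i], mc$rejection[i], tolerance = 0.2)
  expect_gt(mc$posterior[i], 0.5)
})

test_that("parameter estimation reproduces the prior at full tolerance", {
  m <- toy_models()$recent
  loci <- locus_set(sprintf("L%02d", 1:6), 2)
  mut <- mutation_model(p_geom = 0.22)
  ref <- build_reference(list(m), list(P1 = "P1", P2 = "P2"), 600, mut,
                         loci, seed = 10)
  th <- c(N1 = 700, N2 = 700, NANC = 700, t = 50)
  gt <- simulate_coalescent(m$builder(th), mut, 6, seed = 77, loci = loci)
  obs <- summary_statistics(gt, list(P1 = "P1", P2 = "P2"))
  pe <- estimate_parameters(ref, obs, tolerance = 1, adjust = FALSE)
  # the unadjusted full-tolerance posterior of t is its U(10, 200) prior
  expect_equal(pe$summary$median[pe$summary$param == "t"], 105,
               tolerance = 0.12)
  ks <- stats::ks.test(pe$samples[, "t"], "punif", 10, 200)
  expect_gt(ks$p.value, 0.01)
  # the regression adjustment does not inflate the posterior
  pa <- estimate_parameters(ref, obs, tolerance = 0.1, adjust = TRUE)
  pr <- estimate_parameters(ref, obs, tolerance = 0.1, adjust = FALSE)
  expect_lte(var(pa$samples[, "t"]), var(pr$samples[, "t"]) * 1.05)
})

test_that("model checking enforces a disjoint held-out set and calibrates", {
  m <- toy_models()$recent
  loci <- locus_set(sprintf("L%02d", 1:6), 2)
  mut <- mutation_model(p_geom = 0.22)
  groups <- list(P1 = "P1", P2 = "P2")
  ref <- build_reference(list(m), groups, 500, mut, loci, seed = 12)
  th <- c(N1 = 600, N2 = 600, NANC = 600, t = 80)
  gt <- simulate_coalescent(m$builder(th), mut, 6, seed = 55, loci = loci)
  obs <- summary_statistics(gt, groups)
  fit_stats <- one_sample_stats(groups)
  held <- setdiff(names(obs), fit_stats)
  pe <- estimate_parameters(ref, obs, tolerance = 0.05,
                            stats_use = fit_stats)
  expect_error(model_check(m, pe, obs, groups, heldout = names(obs),
                           fitted_stats = fit_stats, mut = mut, loci = loci),
               "overlap")
  expect_error(model_check(m, pe, obs, groups, heldout = held,
                           fitted_stats = fit_stats, mut = mut, loci = loci,
                           n_ppc = 0), "positive")
  ck <- model_check(m, pe, obs, groups, heldout = held,
                    fitted_stats = fit_stats, mut = mut, loci = loci,
                    n_ppc = 60, seed = 3)
  # data generated by the fitted model itself should not be extreme
  expect_true(all(ck$tail_p > 0.01))
})

test_that("the Czech Oder group is traced to its Morava source", {
  fx <- study_fx()
  mut <- mutation_model(p_geom = 0.22)
  obs <- summary_statistics(
    pool_groups(fx$genotypes, abc_groups()[c("CZODER", "NMORAV", "POLRIV")]),
    czoder_groups())
  ref <- build_reference(czoder_models(), czoder_groups(), 600, mut,
                         study_loci(), seed = 55)
  mc <- suppressWarnings(model_choice(ref, obs, tolerance = 0.05))
  expect_equal(mc$scenario[which.max(mc$posterior)], "pure_nmorav")
})

test_that("fixture admixture time and bottleneck size are recovered in CI", {
  mut <- mutation_model(p_geom = 0.22)
  adm <- sazava_models()[[1]]
  ref <- build_reference(list(adm), sazava_groups(), 10000, mut,
                         study_loci(), seed = 303)
  cover_t <- 0L; cover_n <- 0L
  for (r in 1:20) {
    fx <- make_study_fixture(100L + r)
    obs <- summary_statistics(
      pool_groups(fx$genotypes, abc_groups()[c("SAZAVA", "CZELBE", "WMORAV")]),
      sazava_groups())
    s <- estimate_parameters(ref, obs, tolerance = 0.01)$summary
    t_ci <- s[s$param == "t_adm", ]; n_ci <- s[s$param == "N_bot", ]
    if (t_ci$lo95 <= 229 && t_ci$hi95 >= 229) cover_t <- cover_t + 1L
    if (n_ci$lo95 <= 69 && n_ci$hi95 >= 69) cover_n <- cover_n + 1L
  }
  expect_gte(cover_t, 16L)    # >= 80% of 20 replicate fixtures
  expect_gte(cover_n, 16L)
})

test_that("the study scenario families build valid scenarios", {
  for (fam in list(sazava_models(), czoder_models())) {
    expect_length(fam, 3L)
    pr <- fam[[1]]$prior
    set.seed(20)
    for (m in fam) {
      repeat {
        th <- stats::setNames(stats::runif(nrow(pr), pr$min, pr$max),
                              pr$param)
        sc <- m$builder(th)
        if (!is.null(sc)) break
      }
      expect_s3_class(sc, "scenario")
      expect_equal(sum(sc$populations$n), switch(fam[[1]]$name,
        admix_elbe_wmorav = 168L, pure_nmorav = 335L))
    }
  }
})
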