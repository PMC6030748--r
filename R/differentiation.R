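## ---- Weir-Cockerham theta ----

# per-locus variance components a (among populations), b (among individuals
# within populations), c (within individuals), summed over alleles, for the
# individuals selected by `labels` (population label per row; NA rows and
# missing genotypes excluded per locus).
.wc_locus_components <- function(a1, a2, labels) {
  ok <- !is.na(a1) & !is.na(labels)
  a1 <- a1[ok]; a2 <- a2[ok]; lab <- labels[ok]
  pops <- unique(lab)
  r <- length(pops)
  if (r < 2L) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  pi_ <- match(lab, pops)
  ni <- tabulate(pi_, nbins = r)
  if (any(ni < 1L) || sum(ni) < 3L) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  alleles <- sort(unique(c(a1, a2)))
  A <- length(alleles)
  if (A < 2L) return(c(a = 0, b = 0, c = 0))
  i1 <- match(a1, alleles); i2 <- match(a2, alleles)
  # allele copy counts per pop x allele
  cnt <- matrix(0, r, A)
  idx <- (i1 - 1L) * r + pi_
  t1 <- tabulate(idx, nbins = r * A)
  idx <- (i2 - 1L) * r + pi_
  t2 <- tabulate(idx, nbins = r * A)
  cnt <- matrix(t1 + t2, r, A)
  p <- cnt / (2 * ni)
  # heterozygote counts per pop x allele (individual het and carries allele)
  het <- i1 != i2
  hcnt <- matrix(0, r, A)
  if (any(het)) {
    hidx <- c((i1[het] - 1L) * r + pi_[het], (i2[het] - 1L) * r + pi_[het])
    hcnt <- matrix(tabulate(hidx, nbins = r * A), r, A)
  }
  h <- hcnt / ni
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(ni * p) / (r * nbar)
  s2 <- colSums(ni * (p - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(ni * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = sum(a), b = sum(b), c = sum(cc))
}

.wc_theta_from_matrices <- function(a1, a2, labels) {
  comp <- vapply(seq_len(ncol(a1)),
                 function(j) .wc_locus_components(a1[, j], a2[, j], labels),
                 numeric(3))
  sa <- sum(comp[1, ], na.rm = TRUE)
  st <- sum(comp[1, ] + comp[2, ] + comp[3, ], na.rm = TRUE)
  if (st == 0) return(NA_real_)
  sa / st
}

#' Pairwise Weir-Cockerham F_ST
#'
#' Multi-locus theta as the ratio of summed variance components
#' `sum(a) / sum(a+b+c)` across loci; missing genotypes are excluded per
#' locus. May be slightly negative in weakly differentiated pairs.
#'
#' @param x a [genotype_table()].
#' @param popA,popB population labels.
#' @return theta (numeric scalar; `NA` if no shared polymorphic locus).
#' @export
pairwise_fst <- function(x, popA, popB) {
  keep <- x$pop %in% c(popA, popB)
  .wc_theta_from_matrices(x$a1[keep, , drop = FALSE],
                          x$a2[keep, , drop = FALSE], x$pop[keep])
}

#' Global multi-locus Weir-Cockerham theta
#' @param x a [genotype_table()].
#' @param pops populations to include (default all).
#' @return theta.
#' @export
global_fst <- function(x, pops = NULL) {
  if (is.null(pops)) pops <- populations(x)
  keep <- x$pop %in% pops
  .wc_theta_from_matrices(x$a1[keep, , drop = FALSE],
                          x$a2[keep, , drop = FALSE], x$pop[keep])
}

#' Permutation test for pairwise F_ST > 0
#'
#' Individuals are permuted between the two populations holding sample
#' sizes fixed; `p = (1 + #(theta_perm >= theta_obs)) / (n_perm + 1)`.
#'
#' @param x a [genotype_table()].
#' @param popA,popB population labels.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `theta`, `p`, `n_perm`.
#' @export
fst_permutation_test <- function(x, popA, popB, n_perm = 1000L, seed = 1L) {
  keep <- x$pop %in% c(popA, popB)
  a1 <- x$a1[keep, , drop = FALSE]; a2 <- x$a2[keep, , drop = FALSE]
  lab <- x$pop[keep]
  obs <- .wc_theta_from_matrices(a1, a2, lab)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(lab)
    if (.wc_theta_from_matrices(a1, a2, perm) >= obs) hits <- hits + 1L
  }
  list(theta = obs, p = (1 + hits) / (n_perm + 1), n_perm = n_perm)
}

## ---- R_ST (allele-size variance components) ----

# two-level ANOVA on allele-size values (repeat counts), gene copies as
# units, returning per-locus components (between, within)
.rst_locus_components <- function(v1, v2, labels) {
  ok <- !is.na(v1)
  x <- c(v1[ok], v2[ok]); lab <- rep(labels[ok], 2L)
  pops <- unique(lab)
  r <- length(pops)
  if (r < 2L) return(c(b = NA_real_, w = NA_real_))
  pi_ <- match(lab, pops)
  ni <- tabulate(pi_, nbins = r)
  N <- sum(ni)
  gm <- mean(x)
  means <- vapply(seq_len(r), function(i) mean(x[pi_ == i]), numeric(1))
  ssb <- sum(ni * (means - gm)^2)
  ssw <- sum((x - means[pi_])^2)
  if (N <= r) return(c(b = NA_real_, w = NA_real_))
  msb <- ssb / (r - 1)
  msw <- ssw / (N - r)
  n0 <- (N - sum(ni^2) / N) / (r - 1)
  c(b = (msb - msw) / n0, w = msw)
}

.rst_from_matrices <- function(r1, r2, labels) {
  comp <- vapply(seq_len(ncol(r1)),
                 function(j) .rst_locus_components(r1[, j], r2[, j], labels),
                 numeric(2))
  sb <- sum(comp[1, ], na.rm = TRUE)
  st <- sum(comp[1, ] + comp[2, ], na.rm = TRUE)
  if (st == 0) return(NA_real_)
  sb / st
}

#' Pairwise (or global) R_ST
#'
#' F_ST analogue on allele sizes: variance components of repeat counts
#' between vs within populations, pooled across loci by summing components.
#'
#' @param x a [genotype_table()].
#' @param popA,popB population labels; when both `NULL` all populations
#'   enter a global estimate.
#' @return rho (numeric scalar).
#' @export
pairwise_rst <- function(x, popA = NULL, popB = NULL) {
  rc <- repeat_counts(x)
  keep <- if (is.null(popA)) rep(TRUE, length(x$pop)) else x$pop %in% c(popA, popB)
  .rst_from_matrices(rc$r1[keep, , drop = FALSE],
                     rc$r2[keep, , drop = FALSE], x$pop[keep])
}

#' Allele-size permutation test (R_ST vs pR_ST)
#'
#' Permutes allele sizes among allelic states within each locus (allelic
#' identities and their frequencies are kept; only the size attached to
#' each state is shuffled) and recomputes R_ST. Under pure drift the
#' observed R_ST is a draw from this distribution; R_ST above it indicates
#' stepwise mutations contribute to the differentiation.
#'
#' @param x a [genotype_table()].
#' @param pops populations to include (>= 2; default all).
#' @param n_perm number of size permutations.
#' @param seed integer seed.
#' @return list: `rst_obs`, `prst_mean`, `ci` (2.5/97.5% of the permuted
#'   distribution), `p` (one-sided, add-one convention).
#' @export
allele_size_permutation_test <- function(x, pops = NULL, n_perm = 9000L,
                                         seed = 1L) {
  if (is.null(pops)) pops <- populations(x)
  if (length(pops) < 2L) stop("need at least 2 populations", call. = FALSE)
  keep <- x$pop %in% pops
  rc <- repeat_counts(x)
  r1 <- rc$r1[keep, , drop = FALSE]; r2 <- rc$r2[keep, , drop = FALSE]
  lab <- x$pop[keep]
  L <- ncol(r1)
  # state index per copy and per-locus state-size tables
  states <- vector("list", L); s1 <- r1; s2 <- r2
  for (j in seq_len(L)) {
    states[[j]] <- sort(unique(c(r1[, j], r2[, j])))
    s1[, j] <- match(r1[, j], states[[j]])
    s2[, j] <- match(r2[, j], states[[j]])
  }
  obs <- .rst_from_matrices(r1, r2, lab)
  set.seed(seed)
  prst <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    p1 <- s1; p2 <- s2
    for (j in seq_len(L)) {
      sz <- sample(states[[j]])
      p1[, j] <- sz[s1[, j]]
      p2[, j] <- sz[s2[, j]]
    }
    prst[b] <- .rst_from_matrices(p1, p2, lab)
  }
  list(rst_obs = obs, prst_mean = mean(prst),
       ci = stats::quantile(prst, c(0.025, 0.975), names = FALSE),
       p = (1 + sum(prst >= obs)) / (n_perm + 1), n_perm = n_perm)
}

## ---- hierarchical AMOVA ----

# per-locus allele count matrix (population x allele)
.pop_allele_counts <- function(x, j, pops) {
  a1 <- x$a1[, j]; a2 <- x$a2[, j]
  ok <- !is.na(a1) & x$pop %in% pops
  alleles <- sort(unique(c(a1[ok], a2[ok])))
  r <- length(pops); A <- length(alleles)
  cnt <- matrix(0, r, A, dimnames = list(pops, alleles))
  if (!A) return(cnt)
  pi_ <- match(x$pop[ok], pops)
  i1 <- match(a1[ok], alleles); i2 <- match(a2[ok], alleles)
  cnt <- matrix(tabulate((i1 - 1L) * r + pi_, nbins = r * A) +
                tabulate((i2 - 1L) * r + pi_, nbins = r * A),
                r, A, dimnames = list(pops, alleles))
  cnt
}

# SSD of a pooled set of copies with allele counts `cnt` under the 0/1 metric
.ssd01 <- function(cnt) {
  N <- sum(cnt)
  if (N == 0) return(0)
  (N^2 - sum(cnt^2)) / (2 * N)
}

# three-level variance components for one locus given the population x
# allele count matrix and the group assignment of populations
.amova_locus <- function(cnt, grp) {
  Ni <- rowSums(cnt)
  use <- Ni > 0
  cnt <- cnt[use, , drop = FALSE]; grp <- grp[use]; Ni <- Ni[use]
  P <- nrow(cnt); G <- length(unique(grp))
  N <- sum(Ni)
  if (P < 2L || G < 2L || N == 0) return(rep(NA_real_, 6))
  ssd_wp <- sum(apply(cnt, 1, .ssd01))
  grp_cnt <- rowsum(cnt, grp)
  ssd_wg <- sum(apply(grp_cnt, 1, .ssd01))
  ssd_tot <- .ssd01(colSums(cnt))
  ssd_ap <- ssd_wg - ssd_wp
  ssd_ag <- ssd_tot - ssd_wg
  df_wp <- N - P; df_ap <- P - G; df_ag <- G - 1
  Ng <- rowsum(Ni, grp)[, 1]
  sum_ni2_over_ng <- sum(tapply(Ni^2, grp, sum) / Ng)
  n1 <- (N - sum_ni2_over_ng) / df_ap
  n2 <- (sum_ni2_over_ng - sum(Ni^2) / N) / df_ag
  n3 <- (N - sum(Ng^2) / N) / df_ag
  ms_wp <- ssd_wp / df_wp
  ms_ap <- ssd_ap / df_ap
  ms_ag <- ssd_ag / df_ag
  sc <- ms_wp
  sb <- (ms_ap - sc) / n1
  sa <- (ms_ag - sc - n2 * sb) / n3
  c(sa = sa, sb = sb, sc = sc, ssd_ag = ssd_ag, ssd_ap = ssd_ap, ssd_wp = ssd_wp)
}

#' Hierarchical AMOVA (group / population / within-population)
#'
#' Three-level analysis of molecular variance on microsatellite allele
#' frequencies: allele copies are the units and the different-allele (0/1)
#' metric is used, so sums of squares reduce to allele-count identities.
#' Variance components are computed per locus and summed; `F_CT` is the
#' among-group fraction of total variance. Its significance is assessed by
#' permuting whole populations among groups.
#'
#' @param x a [genotype_table()].
#' @param grouping a [grouping_scheme()] covering all populations of `x`
#'   that should enter (populations absent from the scheme are dropped).
#' @param n_perm permutations of populations among groups.
#' @param seed integer seed.
#' @return list with variance components (`sigma_a`, `sigma_b`, `sigma_c`),
#'   `FCT`, `FSC`, `FST`, permutation `p_fct`, and the SSD table.
#' @export
amova <- function(x, grouping, n_perm = 10000L, seed = 1L) {
  pops <- intersect(grouping$populations, unique(x$pop))
  grp <- unname(grouping$group[pops])
  if (length(unique(grp)) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(!table(grp) >= 1L)) stop("each group needs >= 1 population", call. = FALSE)
  L <- nrow(x$loci)
  cnts <- lapply(seq_len(L), function(j) .pop_allele_counts(x, j, pops))
  comp_all <- vapply(cnts, .amova_locus, numeric(6), grp = grp)
  sa <- sum(comp_all[1, ], na.rm = TRUE)
  sb <- sum(comp_all[2, ], na.rm = TRUE)
  sc <- sum(comp_all[3, ], na.rm = TRUE)
  tot <- sa + sb + sc
  fct <- sa / tot
  obs <- fct
  hits <- 0L
  if (n_perm > 0) {
    set.seed(seed)
    for (b in seq_len(n_perm)) {
      pg <- sample(grp)
      comp <- vapply(cnts, .amova_locus, numeric(6), grp = pg)
      fperm <- sum(comp[1, ], na.rm = TRUE) /
        sum(comp[1, ] + comp[2, ] + comp[3, ], na.rm = TRUE)
      if (!is.na(fperm) && fperm >= obs) hits <- hits + 1L
    }
  }
  list(sigma_a = sa, sigma_b = sb, sigma_c = sc,
       FCT = fct, FSC = sb / (sb + sc), FST = (sa + sb) / tot,
       p_fct = if (n_perm > 0) (1 + hits) / (n_perm + 1) else NA_real_,
       ssd = rowSums(comp_all[4:6, , drop = FALSE], na.rm = TRUE),
       n_perm = n_perm)
}

## ---- pairwise matrices and isolation by distance ----

#' Pairwise F_ST and R_ST matrices with permutation p-values
#'
#' @param x a [genotype_table()].
#' @param n_perm permutations per pair for the F_ST test (0 skips testing).
#' @param n_perm_rst allele-size permutations per pair (0 skips).
#' @param seed integer seed.
#' @return list of symmetric matrices: `fst`, `rst`, `p_fst`, `p_rst`.
#' @export
pairwise_matrices <- function(x, n_perm = 0L, n_perm_rst = 0L, seed = 1L) {
  pops <- populations(x)
  P <- length(pops)
  fst <- rst <- pf <- pr <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  diag(fst) <- diag(rst) <- 0
  k <- 0L
  for (i in seq_len(P - 1L)) for (j in seq(i + 1L, P)) {
    k <- k + 1L
    fst[i, j] <- fst[j, i] <- pairwise_fst(x, pops[i], pops[j])
    rst[i, j] <- rst[j, i] <- pairwise_rst(x, pops[i], pops[j])
    if (n_perm > 0) {
      pf[i, j] <- pf[j, i] <-
        fst_permutation_test(x, pops[i], pops[j], n_perm, seed + k)$p
    }
    if (n_perm_rst > 0) {
      pr[i, j] <- pr[j, i] <-
        allele_size_permutation_test(x, c(pops[i], pops[j]), n_perm_rst,
                                     seed + k)$p
    }
  }
  list(fst = fst, rst = rst, p_fst = pf, p_rst = pr)
}

#' Isolation by distance: linearised F_ST against ln distance
#'
#' Regresses `F_ST / (1 - F_ST)` on the natural log of pairwise distance
#' and tests the matrix correlation with a Mantel permutation test.
#'
#' @param fst symmetric pairwise F_ST matrix (dimnames = populations).
#' @param grouping a [grouping_scheme()] carrying the distance matrix (km).
#' @param pops subset of populations to analyse (default: all shared).
#' @param n_perm Mantel permutations.
#' @param seed integer seed.
#' @return list with `slope`, `intercept`, `mantel_r`, `p`, `n_pairs`.
#' @export
ibd_regression <- function(fst, grouping, pops = NULL, n_perm = 1000L,
                           seed = 1L) {
  if (is.null(pops)) pops <- intersect(rownames(fst), grouping$populations)
  f <- fst[pops, pops]
  d <- grouping$dist[pops, pops]
  if (any(d[upper.tri(d)] <= 0))
    stop("all pairwise distances must be > 0", call. = FALSE)
  if (any(f[upper.tri(f)] >= 1)) {
    warning("pairs with F_ST = 1 excluded (transform undefined)")
  }
  y <- f / (1 - f)
  y[f >= 1] <- NA_real_
  ut <- upper.tri(f)
  usable <- ut & f < 1
  fit <- stats::lm(y[usable] ~ log(d[usable]))
  set.seed(seed)
  mt <- vegan::mantel(stats::as.dist(y), stats::as.dist(log(d)),
                      permutations = n_perm, na.rm = TRUE)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       mantel_r = unname(mt$statistic), p = mt$signif,
       n_pairs = sum(usable))
}
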