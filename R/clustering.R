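#' Bayesian admixture clustering (Gibbs sampler)
#'
#' Individual-based clustering under the admixture model with correlated
#' allele frequencies: each cluster's frequencies are Dirichlet-distributed
#' around ancestral frequencies (Dirichlet(`lambda`) prior) with a
#' per-cluster drift parameter F, each individual has membership
#' proportions Q with a symmetric Dirichlet(alpha) prior, and alpha moves
#' by a Metropolis random walk with a uniform(0, 10) prior. Missing allele
#' copies are dropped from the likelihood. `lnP` is the standard harmonic
#' estimator `mean(logL) - var(logL)/2` over post-burn-in sweeps.
#'
#' @param x a [genotype_table()].
#' @param K number of clusters (>= 1).
#' @param iters total Gibbs sweeps.
#' @param burnin sweeps discarded before accumulating posterior means.
#' @param lambda Dirichlet parameter of the ancestral frequency prior.
#' @param seed integer seed; the run is deterministic given it.
#' @param alpha_max upper bound of the uniform prior on alpha.
#' @param alpha_step Metropolis step s.d. for alpha.
#' @return an `admixture_fit`: `K`, `Q` (posterior mean memberships,
#'   individuals x K), `P` (cluster x locus allele frequencies), `lnP`,
#'   `trace` (per-sweep log-likelihood), `alpha`, `F`.
#' @export
admixture_gibbs <- function(x, K, iters = 20000L, burnin = 5000L, lambda = 1,
                            seed = 1L, alpha_max = 10, alpha_step = 0.025) {
  stopifnot(K >= 1L, iters > burnin)
  all_missing <- rowSums(!is.na(x$a1)) == 0L
  if (any(all_missing)) {
    warning(sprintf("%d individual(s) with no genotypes excluded",
                    sum(all_missing)))
    x <- genotype_table(x$a1[!all_missing, , drop = FALSE],
                        x$a2[!all_missing, , drop = FALSE],
                        x$ind[!all_missing], x$pop[!all_missing],
                        x$loci, validate = FALSE)
  }
  L <- nrow(x$loci)
  alleles <- lapply(seq_len(L), function(j)
    sort(unique(c(x$a1[, j], x$a2[, j]))))
  idx <- function(m) vapply(seq_len(L), function(j) {
    v <- match(m[, j], alleles[[j]]) - 1L
    v[is.na(v)] <- -1L
    v
  }, integer(nrow(m)))
  x1 <- idx(x$a1); x2 <- idx(x$a2)
  if (nrow(x$a1) == 1L) { x1 <- matrix(x1, 1L); x2 <- matrix(x2, 1L) }
  nA <- vapply(alleles, length, integer(1))
  set.seed(seed)
  res <- admixture_gibbs_cpp(x1, x2, nA, as.integer(K), as.integer(iters),
                             as.integer(burnin), lambda, alpha_max, alpha_step)
  tr <- as.numeric(res$logl)
  lnP <- mean(tr) - stats::var(tr) / 2
  Q <- res$Q
  dimnames(Q) <- list(x$ind, paste0("k", seq_len(K)))
  structure(list(K = K, Q = Q, P = res$P, lnP = lnP, trace = tr,
                 alpha = res$alpha, F = as.numeric(res$F),
                 pop = x$pop, loci = x$loci$name),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture_fit: K = %d, %d individuals, lnP = %.1f\n",
              x$K, nrow(x$Q), x$lnP))
  invisible(x)
}

#' Scan cluster numbers and compute Evanno's delta-K
#'
#' Runs replicate Gibbs chains for each K in `Ks` and summarises
#' `ln Pr(X|K)`; delta-K at interior K is
#' `|mean lnP(K+1) - 2 mean lnP(K) + mean lnP(K-1)| / sd(lnP(K))`
#' (undefined at the smallest and largest K; reported `Inf` with a flag
#' when the replicate spread is zero).
#'
#' @param x a [genotype_table()].
#' @param Ks contiguous integer vector of cluster numbers.
#' @param replicates chains per K (>= 2 for delta-K).
#' @param iters,burnin per-chain Gibbs controls.
#' @param seed integer seed; chain r of K uses a seed derived from it.
#' @return data.frame per K: `K`, `mean_lnP`, `sd_lnP`, `deltaK`,
#'   `sd_zero` flag; the full lnP matrix as attribute `lnP`.
#' @export
scan_k <- function(x, Ks, replicates = 3L, iters = 4000L, burnin = 1000L,
                   seed = 1L) {
  if (any(diff(sort(Ks)) != 1L)) stop("Ks must be contiguous", call. = FALSE)
  if (replicates < 2L)
    stop("delta-K needs >= 2 replicates (replicate SD undefined)", call. = FALSE)
  Ks <- sort(Ks)
  lnP <- matrix(NA_real_, length(Ks), replicates,
                dimnames = list(Ks, NULL))
  for (ki in seq_along(Ks)) for (r in seq_len(replicates)) {
    fit <- admixture_gibbs(x, Ks[ki], iters = iters, burnin = burnin,
                           seed = seed + 1000L * ki + r)
    lnP[ki, r] <- fit$lnP
  }
  delta_k_series(lnP, Ks)
}

#' Delta-K from a matrix of replicate lnP values
#'
#' @param lnP matrix (K values x replicates) of `ln Pr(X|K)` estimates.
#' @param Ks the K value of each row.
#' @return data.frame as in [scan_k()].
#' @export
delta_k_series <- function(lnP, Ks = as.integer(rownames(lnP))) {
  m <- rowMeans(lnP)
  s <- apply(lnP, 1, stats::sd)
  nK <- length(Ks)
  dk <- rep(NA_real_, nK)
  flag <- rep(FALSE, nK)
  if (nK >= 3L) for (i in 2:(nK - 1L)) {
    num <- abs(m[i + 1] - 2 * m[i] + m[i - 1])
    if (s[i] == 0) { dk[i] <- Inf; flag[i] <- TRUE }
    else dk[i] <- num / s[i]
  }
  out <- data.frame(K = Ks, mean_lnP = m, sd_lnP = s, deltaK = dk,
                    sd_zero = flag, row.names = NULL)
  attr(out, "lnP") <- lnP
  out
}

## ---- replicate alignment (greedy, CLUMPP-style) ----

# similarity between two membership matrices after no permutation:
# G = 1 - ||Q1 - Q2||_F / sqrt(2 n)  (0 when rows are disjoint unit vectors)
.g_similarity <- function(Q1, Q2) {
  1 - sqrt(sum((Q1 - Q2)^2)) / sqrt(2 * nrow(Q1))
}

.all_perms <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- .all_perms(k - 1L)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

# best column permutation of Q (exhaustive for K <= 7, greedy column
# matching above) maximizing similarity to `ref`
.best_perm <- function(Q, ref) {
  K <- ncol(Q)
  if (K <= 7L) {
    perms <- .all_perms(K)
    best <- perms[1, ]; bg <- -Inf
    for (r in seq_len(nrow(perms))) {
      g <- .g_similarity(Q[, perms[r, ], drop = FALSE], ref)
      if (g > bg) { bg <- g; best <- perms[r, ] }
    }
    best
  } else {
    # greedy: repeatedly match the closest (column, reference column) pair
    cost <- matrix(0, K, K)
    for (i in seq_len(K)) for (j in seq_len(K))
      cost[i, j] <- sum((Q[, i] - ref[, j])^2)
    perm <- integer(K)
    free_i <- seq_len(K); free_j <- seq_len(K)
    while (length(free_i)) {
      sub <- cost[free_i, free_j, drop = FALSE]
      w <- which(sub == min(sub), arr.ind = TRUE)[1, ]
      perm[free_j[w[2]]] <- free_i[w[1]]
      free_i <- free_i[-w[1]]; free_j <- free_j[-w[2]]
    }
    perm
  }
}

#' Align replicate admixture runs (greedy label matching)
#'
#' Cluster labels are arbitrary in each run (label switching). Runs are
#' processed greedily: each run after the first is column-permuted to
#' maximize the similarity score `G = 1 - normalized Frobenius distance`
#' against the running average of the already-aligned runs, then averaged
#' in. Exhaustive over permutations for K <= 7.
#'
#' @param runs list of Q matrices (or `admixture_fit` objects) sharing
#'   individuals and K.
#' @return list with `mean_Q`, the aligned `runs`, and `G` (similarity of
#'   each aligned run to the final mean).
#' @export
align_runs <- function(runs) {
  Qs <- lapply(runs, function(r) if (inherits(r, "admixture_fit")) r$Q else r)
  K <- ncol(Qs[[1]]); n <- nrow(Qs[[1]])
  for (q in Qs) if (ncol(q) != K || nrow(q) != n)
    stop("runs must share individuals and K", call. = FALSE)
  aligned <- list(Qs[[1]])
  running <- Qs[[1]]
  for (r in seq_along(Qs)[-1]) {
    perm <- .best_perm(Qs[[r]], running)
    qa <- Qs[[r]][, perm, drop = FALSE]
    colnames(qa) <- colnames(Qs[[1]])
    aligned[[r]] <- qa
    running <- Reduce(`+`, aligned) / length(aligned)
  }
  meanQ <- Reduce(`+`, aligned) / length(aligned)
  G <- vapply(aligned, .g_similarity, numeric(1), Q2 = meanQ)
  list(mean_Q = meanQ, runs = aligned, G = G)
}

## ---- factorial correspondence analysis ----

#' Factorial correspondence analysis of allele-count profiles
#'
#' Individuals are coded as 0/1/2 counts over all (locus, allele) columns,
#' missing genotypes mean-imputed per column, and a correspondence analysis
#' (chi-square metric SVD of the standardized profile matrix) is computed.
#'
#' @param x a [genotype_table()].
#' @param n_axes number of leading axes to return.
#' @return list with `ind_coords` (individuals x axes, principal
#'   coordinates), `pop_centroids`, `inertia`, `explained` (fraction per
#'   axis), and the column profile matrix dimensions.
#' @export
fca <- function(x, n_axes = 2L) {
  L <- nrow(x$loci)
  cols <- list()
  poly <- 0L
  for (j in seq_len(L)) {
    al <- sort(unique(c(x$a1[, j], x$a2[, j])))
    al <- al[!is.na(al)]
    if (length(al) >= 2L) poly <- poly + 1L
    for (a in al) {
      v <- (x$a1[, j] == a) + (x$a2[, j] == a)
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      cols[[paste0(x$loci$name[j], ".", a)]] <- v
    }
  }
  if (poly < 2L) stop("need >= 2 polymorphic loci", call. = FALSE)
  X <- do.call(cbind, cols)
  keep <- apply(X, 2, function(v) stats::var(v) > 0)
  X <- X[, keep, drop = FALSE]
  N <- X / sum(X)
  r <- rowSums(N); cc <- colSums(N)
  S <- (N - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(S)
  pos <- sv$d > 1e-10
  d <- sv$d[pos]
  n_axes <- min(n_axes, sum(pos))
  coords <- sweep(sv$u[, seq_len(n_axes), drop = FALSE], 1, sqrt(r), `/`) %*%
    diag(d[seq_len(n_axes)], n_axes)
  rownames(coords) <- x$ind
  colnames(coords) <- paste0("axis", seq_len(n_axes))
  cents <- rowsum(coords, x$pop)
  cents <- cents / as.vector(table(x$pop)[rownames(cents)])
  list(ind_coords = coords, pop_centroids = cents,
       inertia = d^2, explained = d[seq_len(n_axes)]^2 / sum(d^2))
}
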