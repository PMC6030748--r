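#' Observed and unbiased expected heterozygosity
#'
#' `Ho` is the fraction of non-missing genotypes that are heterozygous;
#' `He` is Nei's unbiased estimator `2n/(2n-1) * (1 - sum p_a^2)` with `n`
#' the number of genotyped individuals at the locus.
#'
#' @param x a [genotype_table()].
#' @param population population label.
#' @return data.frame with one row per locus: `locus`, `n`, `A` (allele
#'   count), `Ho`, `He` (`NA` where no individual is genotyped).
#' @export
heterozygosity <- function(x, population) {
  keep <- x$pop == population
  out <- data.frame(locus = x$loci$name, n = NA_integer_, A = NA_integer_,
                    Ho = NA_real_, He = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(nrow(x$loci))) {
    a1 <- x$a1[keep, j]; a2 <- x$a2[keep, j]
    ok <- !is.na(a1)
    n <- sum(ok)
    out$n[j] <- n
    if (n == 0L) next                       # undefined, left NA
    out$Ho[j] <- mean(a1[ok] != a2[ok])
    p <- table(c(a1[ok], a2[ok])) / (2 * n)
    out$A[j] <- length(p)
    out$He[j] <- if (n > 1) (2 * n / (2 * n - 1)) * (1 - sum(p^2))
                 else 1 - sum(p^2)
  }
  out
}

#' Rarefaction allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies: `AR = sum_a [1 - choose(2n - c_a, g)/choose(2n, g)]`, the
#' hypergeometric rarefaction used to standardise allele counts across
#' unequal sample sizes. The default `g = 18` genes corresponds to a
#' minimum sample size of 9 diploid individuals.
#'
#' @param x a [genotype_table()].
#' @param population population label.
#' @param g rarefaction size in gene copies.
#' @return data.frame per locus: `locus`, `n`, `A`, `AR` (`NA`, flagged in
#'   `defined`, where `2n < g`).
#' @export
allelic_richness <- function(x, population, g = 18L) {
  keep <- x$pop == population
  out <- data.frame(locus = x$loci$name, n = NA_integer_, A = NA_integer_,
                    AR = NA_real_, defined = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(nrow(x$loci))) {
    al <- c(x$a1[keep, j], x$a2[keep, j])
    al <- al[!is.na(al)]
    n2 <- length(al)
    out$n[j] <- n2 %/% 2L
    if (n2 == 0L) next
    cnt <- table(al)
    out$A[j] <- length(cnt)
    if (n2 < g) next                         # undefined at this g
    out$AR[j] <- sum(1 - exp(lchoose(n2 - cnt, g) - lchoose(n2, g)))
    out$defined[j] <- TRUE
  }
  out
}

## ---- Hardy-Weinberg exact test (Levene conditional distribution) ----

# log probability of a genotype configuration given allele counts:
# log[ n! 2^H prod(m_a!) / (prod n_ab! (2n)!) ]
# cnt is upper-triangular: diagonal = homozygote counts, upper = heterozygotes
.levene_logprob <- function(cnt) {
  n <- sum(cnt)
  het <- sum(cnt[upper.tri(cnt)])
  m <- rowSums(cnt) + colSums(cnt)           # copies: 2*diag + hets touching a
  lgamma(n + 1) + het * log(2) + sum(lgamma(m + 1)) -
    sum(lgamma(cnt[upper.tri(cnt, diag = TRUE)] + 1)) - lgamma(2 * n + 1)
}

# enumerate all configurations for 2 or 3 alleles with fixed allele counts,
# returning the vector of log probabilities
.enumerate_levene <- function(m) {
  k <- length(m)
  out <- numeric(0)
  if (k == 2L) {
    hmax <- min(m)
    hs <- seq(m[1] %% 2L, hmax, by = 2L)
    for (h in hs) {
      cnt <- matrix(0, 2, 2)
      cnt[1, 2] <- h
      cnt[1, 1] <- (m[1] - h) / 2
      cnt[2, 2] <- (m[2] - h) / 2
      out <- c(out, .levene_logprob(cnt))
    }
  } else if (k == 3L) {
    for (n12 in 0:min(m[1], m[2])) for (n13 in 0:min(m[1] - n12, m[3])) {
      r1 <- m[1] - n12 - n13
      if (r1 < 0 || r1 %% 2) next
      for (n23 in 0:min(m[2] - n12, m[3] - n13)) {
        r2 <- m[2] - n12 - n23; r3 <- m[3] - n13 - n23
        if (r2 < 0 || r3 < 0 || r2 %% 2 || r3 %% 2) next
        cnt <- matrix(0, 3, 3)
        cnt[1, 2] <- n12; cnt[1, 3] <- n13; cnt[2, 3] <- n23
        diag(cnt) <- c(r1, r2, r3) / 2
        out <- c(out, .levene_logprob(cnt))
      }
    }
  } else stop("enumeration supports at most 3 alleles", call. = FALSE)
  out
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Exact probability test under the Levene conditional distribution of
#' genotype configurations given allele counts: the p-value sums the
#' probabilities of all configurations no more probable than the observed
#' one. Full enumeration is used for up to 3 alleles and n <= 100;
#' otherwise a Metropolis chain over configurations (allele-swapping
#' proposals) estimates the p-value, with a batch-means standard error.
#'
#' @param genotype_counts symmetric k x k matrix of genotype counts
#'   (unordered pairs; only the upper triangle including the diagonal is
#'   used).
#' @param method `"auto"`, `"enumeration"` or `"mcmc"`.
#' @param mc_params list with `dememorization`, `batches`, `iter_per_batch`.
#' @param seed integer seed for the Markov chain.
#' @return list with `p`, `se` (`NA` for enumeration), `method`, and
#'   `no_test` flag (monomorphic input, p = 1).
#' @export
hwe_exact_test <- function(genotype_counts,
                           method = c("auto", "enumeration", "mcmc"),
                           mc_params = list(dememorization = 10000,
                                            batches = 100,
                                            iter_per_batch = 5000),
                           seed = 1L) {
  method <- match.arg(method)
  cnt <- as.matrix(genotype_counts)
  # fold to upper-triangular form (diag = homozygotes, upper = heterozygotes)
  sym <- isTRUE(all.equal(unname(cnt), unname(t(cnt))))
  ut <- matrix(0, nrow(cnt), ncol(cnt))
  diag(ut) <- diag(cnt)
  ut[upper.tri(ut)] <- if (sym) cnt[upper.tri(cnt)] else
    cnt[upper.tri(cnt)] + t(cnt)[upper.tri(cnt)]
  cnt <- ut
  m <- as.integer(rowSums(cnt) + colSums(cnt))  # copies per allele
  # drop absent alleles
  present <- m > 0L
  cnt <- cnt[present, present, drop = FALSE]
  m <- m[present]
  k <- length(m)
  n <- sum(cnt[upper.tri(cnt, diag = TRUE)])
  if (k < 2L)
    return(list(p = 1, se = NA_real_, method = "none", no_test = TRUE))
  if (method == "auto")
    method <- if (k <= 3L && n <= 100L) "enumeration" else "mcmc"
  obs <- .levene_logprob(cnt)
  if (method == "enumeration") {
    lp <- .enumerate_levene(m)
    pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
    p <- sum(pr[lp <= obs + 1e-9])
    return(list(p = p, se = NA_real_, method = "enumeration", no_test = FALSE))
  }
  # Metropolis chain: swap one allele copy between two random genotypes
  set.seed(seed)
  ut <- which(upper.tri(cnt, diag = TRUE), arr.ind = TRUE)
  # expand genotypes of individuals
  g1 <- rep(ut[, 1], cnt[ut]); g2 <- rep(ut[, 2], cnt[ut])
  cur <- obs
  nbatch <- mc_params$batches
  hits <- numeric(nbatch)
  total_iter <- mc_params$dememorization + nbatch * mc_params$iter_per_batch
  cm <- cnt
  for (it in seq_len(total_iter)) {
    i <- sample.int(n, 2L)
    # alleles to swap: one copy from each individual
    ai <- if (stats::runif(1) < 0.5) g1[i[1]] else g2[i[1]]
    bj <- if (stats::runif(1) < 0.5) g1[i[2]] else g2[i[2]]
    if (ai != bj) {
      o1 <- sort(c(g1[i[1]], g2[i[1]])); o2 <- sort(c(g1[i[2]], g2[i[2]]))
      keep1 <- if (o1[1] == ai) o1[2] else o1[1]
      keep2 <- if (o2[1] == bj) o2[2] else o2[1]
      n1 <- sort(c(keep1, bj)); n2 <- sort(c(keep2, ai))
      # telescoped change in log pi, pi propto 2^H / prod(n_ab!)
      delta <- 0
      delta <- delta + log(cm[o1[1], o1[2]]); cm[o1[1], o1[2]] <- cm[o1[1], o1[2]] - 1L
      delta <- delta + log(cm[o2[1], o2[2]]); cm[o2[1], o2[2]] <- cm[o2[1], o2[2]] - 1L
      cm[n1[1], n1[2]] <- cm[n1[1], n1[2]] + 1L; delta <- delta - log(cm[n1[1], n1[2]])
      cm[n2[1], n2[2]] <- cm[n2[1], n2[2]] + 1L; delta <- delta - log(cm[n2[1], n2[2]])
      dh <- (n1[1] != n1[2]) + (n2[1] != n2[2]) -
            (o1[1] != o1[2]) - (o2[1] != o2[2])
      # Hastings: selecting a given allele from a heterozygote has
      # probability 1/2, from a homozygote 1; the correction 2^-dh cancels
      # the 2^dh of the target, so only the factorial part decides
      if (log(stats::runif(1)) < delta) {
        g1[i[1]] <- n1[1]; g2[i[1]] <- n1[2]
        g1[i[2]] <- n2[1]; g2[i[2]] <- n2[2]
        cur <- cur + dh * log(2) + delta
      } else {                               # revert counts
        cm[n1[1], n1[2]] <- cm[n1[1], n1[2]] - 1L
        cm[n2[1], n2[2]] <- cm[n2[1], n2[2]] - 1L
        cm[o1[1], o1[2]] <- cm[o1[1], o1[2]] + 1L
        cm[o2[1], o2[2]] <- cm[o2[1], o2[2]] + 1L
      }
    }
    if (it > mc_params$dememorization) {
      b <- (it - mc_params$dememorization - 1L) %/% mc_params$iter_per_batch + 1L
      hits[b] <- hits[b] + (cur <= obs + 1e-9)
    }
  }
  ph <- hits / mc_params$iter_per_batch
  list(p = mean(ph), se = stats::sd(ph) / sqrt(nbatch), method = "mcmc",
       no_test = FALSE)
}

#' Genotype-count matrix for one locus in one population
#'
#' @param x a [genotype_table()].
#' @param population population label.
#' @param locus locus name or index.
#' @return symmetric matrix of genotype counts, dimnames = allele sizes.
#' @export
genotype_count_matrix <- function(x, population, locus) {
  j <- if (is.character(locus)) match(locus, x$loci$name) else locus
  keep <- x$pop == population & !is.na(x$a1[, j])
  a1 <- x$a1[keep, j]; a2 <- x$a2[keep, j]
  al <- sort(unique(c(a1, a2)))
  k <- length(al)
  cnt <- matrix(0L, k, k, dimnames = list(al, al))
  if (k == 0L) return(cnt)
  i1 <- match(a1, al); i2 <- match(a2, al)
  for (q in seq_along(i1)) cnt[i1[q], i2[q]] <- cnt[i1[q], i2[q]] + 1L
  cnt
}

#' EM estimate of the null-allele frequency at a locus
#'
#' Maximum-likelihood estimate under Hardy-Weinberg proportions with one
#' non-amplifying allele: apparent homozygotes are treated as a mixture of
#' true homozygotes and visible/null heterozygotes (Dempster-type EM).
#' With `include_missing = TRUE`, missing genotypes are counted as null
#' homozygotes; otherwise the likelihood conditions on a visible genotype
#' and the unseen null-homozygote class is augmented inside the EM.
#'
#' @param x a [genotype_table()].
#' @param population population label.
#' @param locus locus name or index.
#' @param tol convergence tolerance on successive null-frequency estimates.
#' @param max_iter maximum EM iterations.
#' @param include_missing count missing genotypes as null homozygotes.
#' @return list with `null_hat`, `iterations`, `converged`, and the visible
#'   allele-frequency estimates `p`.
#' @export
estimate_null_alleles <- function(x, population, locus, tol = 1e-8,
                                  max_iter = 20000L, include_missing = FALSE) {
  j <- if (is.character(locus)) match(locus, x$loci$name) else locus
  keep <- x$pop == population
  a1 <- x$a1[keep, j]; a2 <- x$a2[keep, j]
  miss <- sum(is.na(a1))
  ok <- !is.na(a1)
  if (sum(ok) < 5L) stop("fewer than 5 genotyped individuals", call. = FALSE)
  a1 <- a1[ok]; a2 <- a2[ok]
  al <- sort(unique(c(a1, a2)))
  k <- length(al)
  i1 <- match(a1, al); i2 <- match(a2, al)
  n_obs <- length(i1)
  hom <- i1 == i2
  hom_counts <- tabulate(i1[hom], nbins = k)
  het_counts <- matrix(0, k, k)
  for (q in which(!hom)) het_counts[i1[q], i2[q]] <- het_counts[i1[q], i2[q]] + 1
  het_al <- tabulate(c(i1[!hom], i2[!hom]), nbins = k)

  p <- tabulate(c(i1, i2), nbins = k) / (2 * n_obs)
  pN <- 0.05
  p <- p * (1 - pN)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # E-step: split apparent homozygotes aa into true aa vs a-null
    denom <- p^2 + 2 * p * pN
    w_true <- ifelse(denom > 0, p^2 / denom, 1)
    exp_null_from_hom <- sum(hom_counts * (1 - w_true))   # one null copy each
    n_nn <- if (include_missing) miss
            else if (pN < 1) n_obs * pN^2 / (1 - pN^2) else 0
    n_tot <- n_obs + n_nn
    copies_a <- het_al + 2 * hom_counts * w_true + hom_counts * (1 - w_true)
    copies_null <- exp_null_from_hom + 2 * n_nn
    tot <- sum(copies_a) + copies_null
    p_new <- copies_a / tot
    pN_new <- copies_null / tot
    # boundary MLEs (pN -> 0) are approached sublinearly; an estimate below
    # tol is treated as converged to the boundary
    done <- abs(pN_new - pN) < tol || pN_new < tol
    p <- p_new; pN <- pN_new
    if (done) { converged <- TRUE; break }
  }
  if (!converged) {
    e <- simpleError(sprintf("EM did not converge in %d iterations", max_iter))
    e$last <- list(null_hat = pN, p = stats::setNames(p, al))
    stop(e)
  }
  list(null_hat = pN, iterations = it, converged = TRUE,
       p = stats::setNames(p, al))
}

#' Per-population, per-locus diversity table
#'
#' @param x a [genotype_table()].
#' @param g rarefaction size in gene copies.
#' @param hwe compute the exact Hardy-Weinberg p-value per cell.
#' @param seed seed for any Markov-chain HWE estimates.
#' @return data.frame keyed by (population, locus) with `n`, `A`, `Ho`,
#'   `He`, `AR`, `null_hat` and optionally `p_hwe`.
#' @export
diversity_table <- function(x, g = 18L, hwe = FALSE, seed = 1L) {
  res <- list()
  for (p in populations(x)) {
    h <- heterozygosity(x, p)
    ar <- allelic_richness(x, p, g = g)
    d <- data.frame(population = p, h, AR = ar$AR, null_hat = NA_real_,
                    stringsAsFactors = FALSE)
    for (j in seq_len(nrow(x$loci))) {
      nh <- tryCatch(
        estimate_null_alleles(x, p, j)$null_hat,
        error = function(e) NA_real_)
      d$null_hat[j] <- nh
      if (hwe) {
        cm <- genotype_count_matrix(x, p, j)
        d$p_hwe[j] <- hwe_exact_test(cm, seed = seed)$p
      }
    }
    res[[p]] <- d
  }
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}
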