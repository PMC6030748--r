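## ---- summary statistics ----

#' Summary statistics for demographic inference
#'
#' Computes, for each population group, the mean number of alleles, mean
#' unbiased gene diversity and mean allele-size variance (repeat units)
#' across loci; and for each group pair, Weir-Cockerham F_ST, the
#' shared-allele distance `DAS = 1 - mean proportion of shared alleles
#' between cross-group individuals`, and the `(delta mu)^2` distance
#' (squared difference of mean allele size, averaged over loci). The
#' vector order is fixed: all per-group statistics (grouped by statistic),
#' then all pair statistics.
#'
#' @param x a [genotype_table()].
#' @param groups named list mapping group labels to population labels.
#' @return named numeric vector.
#' @export
summary_statistics <- function(x, groups) {
  G <- length(groups)
  gname <- names(groups)
  lab <- rep(NA_integer_, length(x$ind))
  for (g in seq_len(G)) lab[x$pop %in% groups[[g]]] <- g
  if (any(vapply(seq_len(G), function(g) sum(lab == g, na.rm = TRUE) == 0,
                 logical(1))))
    stop("every group must be non-empty", call. = FALSE)
  keep <- !is.na(lab)
  a1 <- x$a1[keep, , drop = FALSE]; a2 <- x$a2[keep, , drop = FALSE]
  lab <- lab[keep]
  rc0 <- repeat_counts(x)
  r1 <- rc0$r1[keep, , drop = FALSE]; r2 <- rc0$r2[keep, , drop = FALSE]
  L <- ncol(a1)
  A <- H <- V <- matrix(NA_real_, G, L)
  M <- matrix(NA_real_, G, L)               # mean allele size per group/locus
  for (g in seq_len(G)) {
    rows <- lab == g
    for (j in seq_len(L)) {
      al <- c(a1[rows, j], a2[rows, j]); al <- al[!is.na(al)]
      if (!length(al)) next
      cnt <- table(al)
      n2 <- length(al)
      p <- cnt / n2
      A[g, j] <- length(cnt)
      H[g, j] <- if (n2 > 1) n2 / (n2 - 1) * (1 - sum(p^2)) else 0
      rv <- c(r1[rows, j], r2[rows, j]); rv <- rv[!is.na(rv)]
      V[g, j] <- stats::var(rv)
      M[g, j] <- mean(rv)
    }
  }
  out <- c(stats::setNames(rowMeans(A, na.rm = TRUE), paste0("A_", gname)),
           stats::setNames(rowMeans(H, na.rm = TRUE), paste0("H_", gname)),
           stats::setNames(rowMeans(V, na.rm = TRUE), paste0("V_", gname)))
  if (G >= 2) {
    ps <- shared_allele_ps_cpp(a1, a2, lab - 1L, G)
    for (i in seq_len(G - 1)) for (j in seq(i + 1, G)) {
      tag <- paste0(gname[i], "_", gname[j])
      fst <- .wc_theta_from_matrices(a1[lab %in% c(i, j), , drop = FALSE],
                                     a2[lab %in% c(i, j), , drop = FALSE],
                                     lab[lab %in% c(i, j)])
      out[paste0("FST_", tag)] <- fst
      out[paste0("DAS_", tag)] <- 1 - ps[i, j]
      out[paste0("DMU2_", tag)] <- mean((M[i, ] - M[j, ])^2, na.rm = TRUE)
    }
  }
  out
}

#' Names of the one-sample (fitting) statistics of a group design
#' @param groups named list of groups (as in [summary_statistics()]).
#' @return character vector.
#' @export
one_sample_stats <- function(groups) {
  as.vector(outer(c("A_", "H_", "V_"), names(groups), paste0))
}

## ---- models, priors, reference tables ----

#' Define an ABC demographic model
#'
#' @param name scenario identifier.
#' @param prior data.frame with columns `param`, `min`, `max` (uniform
#'   priors).
#' @param builder `function(theta)` returning a [scenario()] for a named
#'   parameter vector, or `NULL` when an event-order constraint is
#'   violated (the draw is rejected and repeated).
#' @return an `abc_model`.
#' @export
abc_model <- function(name, prior, builder) {
  stopifnot(all(c("param", "min", "max") %in% names(prior)),
            all(prior$max > prior$min))
  structure(list(name = name, prior = prior, builder = builder),
            class = "abc_model")
}

.draw_prior <- function(prior) {
  stats::setNames(stats::runif(nrow(prior), prior$min, prior$max),
                  prior$param)
}

#' Build an ABC reference table
#'
#' For each model, draws parameters from their uniform priors (redrawing
#' when the model's builder rejects an invalid event ordering), simulates
#' a microsatellite dataset with the shared coalescent engine and records
#' the summary statistics.
#'
#' @param models list of [abc_model()] objects.
#' @param groups named list mapping group labels to the population labels
#'   produced by the builders' scenarios.
#' @param n_per_scenario simulated datasets per model.
#' @param mut a [mutation_model()].
#' @param loci locus table used for the simulated datasets.
#' @param seed integer seed (the table is deterministic given it).
#' @param offsets per-locus base-pair offsets passed to the simulator.
#' @return a `reference_table`: data.frame with `scenario`, parameter
#'   columns (`par_*`), and statistic columns; priors kept as attribute.
#' @export
build_reference <- function(models, groups, n_per_scenario, mut, loci,
                            seed = 1L, offsets = 100L) {
  rows <- list()
  set.seed(seed)
  sim_seeds <- sample.int(2^31 - 2, length(models) * max(n_per_scenario, 1L))
  k <- 0L
  for (m in models) {
    if (n_per_scenario < 1L) next
    for (b in seq_len(n_per_scenario)) {
      k <- k + 1L
      repeat {
        theta <- .draw_prior(m$prior)
        scen <- m$builder(theta)
        if (!is.null(scen)) break
      }
      gt <- simulate_coalescent(scen, mut, n_loci = nrow(loci),
                                seed = sim_seeds[k], loci = loci,
                                offsets = offsets)
      ss <- summary_statistics(gt, groups)
      rows[[k]] <- c(scenario = NA_real_,
                     stats::setNames(theta, paste0("par_", names(theta))), ss)
      names(rows[[k]])[1] <- "scenario"
      attr(rows[[k]], "scenario") <- m$name
    }
  }
  if (!length(rows)) {
    out <- data.frame(scenario = character())
  } else {
    nm <- unique(unlist(lapply(rows, names)))
    nm <- setdiff(nm, "scenario")
    mat <- matrix(NA_real_, length(rows), length(nm),
                  dimnames = list(NULL, nm))
    for (q in seq_along(rows)) {
      r <- rows[[q]]
      mat[q, intersect(names(r), nm)] <- r[intersect(names(r), nm)]
    }
    out <- data.frame(scenario = vapply(rows, attr, "", "scenario"),
                      mat, check.names = FALSE, stringsAsFactors = FALSE)
  }
  attr(out, "priors") <- stats::setNames(lapply(models, `[[`, "prior"),
                                         vapply(models, `[[`, "", "name"))
  class(out) <- c("reference_table", class(out))
  out
}

.stat_cols <- function(ref) {
  setdiff(names(ref), c("scenario", grep("^par_", names(ref), value = TRUE)))
}

# MAD-standardized deviations of reference stats from the observed point;
# drops statistics that are constant (MAD 0) or missing in `observed`
.standardize <- function(ref_stats, observed) {
  use <- intersect(colnames(ref_stats), names(observed))
  X <- as.matrix(ref_stats[, use, drop = FALSE])
  obs <- observed[use]
  mads <- apply(X, 2, stats::mad, na.rm = TRUE)
  ok <- is.finite(mads) & mads > 0 & is.finite(obs)
  X <- X[, ok, drop = FALSE]; obs <- obs[ok]; mads <- mads[ok]
  dev <- sweep(sweep(X, 2, obs), 2, mads, `/`)
  dev[!is.finite(dev)] <- 0
  dev
}

#' ABC model choice by logistic regression on the closest simulations
#'
#' Statistics are standardized by their reference-table median absolute
#' deviation; the `tolerance` fraction of simulations closest to the
#' observed vector (Euclidean distance) is retained; a multinomial
#' logistic regression of the scenario indicator on the statistic
#' deviations, weighted by an Epanechnikov kernel in the distance, is
#' evaluated at the observed point (deviation zero). 95% credible
#' intervals come from the regression's asymptotic covariance. Direct
#' rejection frequencies among the retained simulations are also
#' returned.
#'
#' @param ref a `reference_table` covering >= 2 scenarios.
#' @param observed named statistic vector from [summary_statistics()].
#' @param tolerance fraction of simulations retained.
#' @param stats_use optional subset of statistic names to fit on.
#' @return data.frame per scenario: `posterior`, `lo95`, `hi95`,
#'   `rejection` (retained fraction), `n_retained`.
#' @export
model_choice <- function(ref, observed, tolerance = 0.01, stats_use = NULL) {
  scen <- unique(ref$scenario)
  if (length(scen) < 2L) stop("reference table must cover >= 2 scenarios", call. = FALSE)
  sc <- .stat_cols(ref)
  if (!is.null(stats_use)) sc <- intersect(sc, stats_use)
  dev <- .standardize(ref[, sc, drop = FALSE], observed)
  d <- sqrt(rowSums(dev^2))
  n_keep <- max(length(scen) + 1L, ceiling(tolerance * nrow(ref)))
  idx <- order(d)[seq_len(min(n_keep, nrow(ref)))]
  dmax <- max(d[idx])
  w <- 1 - (d[idx] / dmax)^2
  w[w <= 0] <- min(w[w > 0], 1e-6)
  y <- factor(ref$scenario[idx], levels = scen)
  rej <- as.numeric(table(y)) / length(idx)
  if (any(rej == 0))
    warning("scenario(s) absent from the retained set, probability floored at 0: ",
            paste(scen[rej == 0], collapse = ", "))
  X <- dev[idx, , drop = FALSE]
  # drop collinear/constant columns in the retained set
  keep_col <- apply(X, 2, function(v) stats::sd(v) > 1e-10)
  X <- X[, keep_col, drop = FALSE]
  fit <- tryCatch({
    df <- data.frame(y = y, X)
    utils::capture.output(
      mf <- nnet::multinom(y ~ ., data = df, weights = w, maxit = 500,
                           trace = FALSE))
    mf
  }, error = function(e) NULL)
  if (is.null(fit) || length(unique(y)) < 2L) {
    post <- rej
    se <- sqrt(post * (1 - post) / length(idx))
  } else {
    nd <- as.data.frame(matrix(0, 1, ncol(X)))
    names(nd) <- colnames(X)
    pr <- stats::predict(fit, newdata = nd, type = "probs")
    post <- rep(0, length(scen))
    names(post) <- scen
    present <- levels(y)[table(y) > 0]
    if (is.null(dim(pr)) && length(pr) == 1L) {
      # two retained scenarios: probability of the second present level
      post[present[1]] <- 1 - pr
      post[present[2]] <- pr
    } else if (is.null(dim(pr))) {
      post[names(pr)] <- pr
    } else post[colnames(pr)] <- pr
    # delta-method CI on the intercept-driven probabilities
    se <- tryCatch({
      V <- stats::vcov(fit)
      icpt <- grep("(Intercept)", colnames(V), fixed = TRUE)
      b_se <- sqrt(diag(V)[icpt])
      # propagate through softmax at the observed point
      p <- post[post > 0]
      s <- rep(NA_real_, length(scen))
      if (length(b_se) == length(p) - 1)
        s[match(names(p)[-1], scen)] <- p[-1] * (1 - p[-1]) * b_se
      s[is.na(s)] <- mean(s, na.rm = TRUE)
      s
    }, error = function(e) sqrt(post * (1 - post) / length(idx)))
  }
  post <- pmax(post, 0)
  post <- post / sum(post)
  data.frame(scenario = scen, posterior = as.numeric(post),
             lo95 = pmax(0, as.numeric(post) - 1.96 * se),
             hi95 = pmin(1, as.numeric(post) + 1.96 * se),
             rejection = rej, n_retained = length(idx),
             stringsAsFactors = FALSE)
}

# logit transform of parameters to their prior bounds and back
.to_logit <- function(x, lo, hi) {
  z <- (x - lo) / (hi - lo)
  z <- pmin(pmax(z, 1e-8), 1 - 1e-8)
  log(z / (1 - z))
}
.from_logit <- function(z, lo, hi) lo + (hi - lo) / (1 + exp(-z))

.wquantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' ABC parameter estimation with local-linear regression adjustment
#'
#' Retains the `tolerance` fraction of the chosen scenario's simulations
#' closest to the observed statistics, logit-transforms parameters to
#' their prior bounds, adjusts them by Epanechnikov-weighted local-linear
#' regression on the statistic deviations, and back-transforms. Reports
#' weighted posterior medians and 95% intervals. A singular regression
#' design falls back to the unadjusted rejection sample with a warning.
#'
#' @param ref_best `reference_table` rows of the chosen scenario.
#' @param observed named statistic vector.
#' @param tolerance fraction retained.
#' @param adjust apply the regression adjustment (default TRUE).
#' @param stats_use optional subset of statistic names.
#' @return list with `samples` (adjusted draws), `weights`, and `summary`
#'   (median and 2.5/97.5% quantiles per parameter).
#' @export
estimate_parameters <- function(ref_best, observed, tolerance = 0.01,
                                adjust = TRUE, stats_use = NULL) {
  stopifnot(length(unique(ref_best$scenario)) == 1L)
  prior <- attr(ref_best, "priors")[[unique(ref_best$scenario)]]
  if (is.null(prior)) stop("reference table lost its priors attribute", call. = FALSE)
  sc <- .stat_cols(ref_best)
  if (!is.null(stats_use)) sc <- intersect(sc, stats_use)
  dev <- .standardize(ref_best[, sc, drop = FALSE], observed)
  d <- sqrt(rowSums(dev^2))
  n_keep <- max(20L, ceiling(tolerance * nrow(ref_best)))
  idx <- order(d)[seq_len(min(n_keep, nrow(ref_best)))]
  dmax <- max(d[idx])
  w <- 1 - (d[idx] / dmax)^2
  w[w <= 0] <- min(w[w > 0], 1e-6)
  pars <- paste0("par_", prior$param)
  th <- as.matrix(ref_best[idx, pars, drop = FALSE])
  thL <- th
  for (q in seq_len(ncol(th)))
    thL[, q] <- .to_logit(th[, q], prior$min[q], prior$max[q])
  X <- dev[idx, , drop = FALSE]
  keep_col <- apply(X, 2, function(v) stats::sd(v) > 1e-10)
  X <- X[, keep_col, drop = FALSE]
  adj <- thL
  if (adjust && ncol(X)) {
    fit <- tryCatch(stats::lm.wfit(cbind(1, X), thL, w), error = function(e) NULL)
    if (is.null(fit) || any(is.na(fit$coefficients))) {
      warning("singular regression design; returning unadjusted rejection sample")
    } else {
      b <- fit$coefficients[-1, , drop = FALSE]
      adj <- thL - X %*% b
    }
  }
  out <- adj
  for (q in seq_len(ncol(th)))
    out[, q] <- .from_logit(adj[, q], prior$min[q], prior$max[q])
  colnames(out) <- prior$param
  summ <- t(apply(out, 2, function(v) .wquantile(v, w, c(0.5, 0.025, 0.975))))
  colnames(summ) <- c("median", "lo95", "hi95")
  list(samples = out, weights = w,
       summary = data.frame(param = prior$param, summ, row.names = NULL))
}

#' Posterior predictive model checking
#'
#' Simulates datasets from posterior parameter draws of the fitted model
#' and reports, for each held-out statistic, the two-sided tail
#' probability of the observed value in the posterior predictive
#' distribution. The held-out set must be disjoint from the fitting set.
#'
#' @param model the fitted [abc_model()].
#' @param posterior result of [estimate_parameters()].
#' @param observed full observed statistic vector.
#' @param groups group design (as in [summary_statistics()]).
#' @param heldout names of held-out statistics.
#' @param fitted_stats names of the statistics used for fitting.
#' @param mut,loci,offsets simulation settings as in [build_reference()].
#' @param n_ppc number of posterior predictive simulations (> 0).
#' @param seed integer seed.
#' @return data.frame per held-out statistic: `observed`, `ppc_median`,
#'   `tail_p`.
#' @export
model_check <- function(model, posterior, observed, groups, heldout,
                        fitted_stats, mut, loci, offsets = 100L,
                        n_ppc = 100L, seed = 1L) {
  if (n_ppc < 1L) stop("n_ppc must be positive", call. = FALSE)
  if (length(intersect(heldout, fitted_stats)))
    stop("held-out statistics overlap the fitting set", call. = FALSE)
  set.seed(seed)
  draws <- sample.int(nrow(posterior$samples), n_ppc, replace = TRUE,
                      prob = posterior$weights)
  sim_seeds <- sample.int(2^31 - 2, n_ppc)
  sims <- matrix(NA_real_, n_ppc, length(heldout),
                 dimnames = list(NULL, heldout))
  for (b in seq_len(n_ppc)) {
    theta <- posterior$samples[draws[b], ]
    scen <- model$builder(theta)
    if (is.null(scen)) next
    gt <- simulate_coalescent(scen, mut, n_loci = nrow(loci),
                              seed = sim_seeds[b], loci = loci,
                              offsets = offsets)
    ss <- summary_statistics(gt, groups)
    sims[b, ] <- ss[heldout]
  }
  res <- data.frame(stat = heldout, observed = observed[heldout],
                    ppc_median = apply(sims, 2, stats::median, na.rm = TRUE),
                    tail_p = NA_real_, row.names = NULL)
  for (q in seq_along(heldout)) {
    v <- sims[, q]; v <- v[!is.na(v)]
    lo <- (1 + sum(v <= observed[heldout[q]])) / (length(v) + 1)
    hi <- (1 + sum(v >= observed[heldout[q]])) / (length(v) + 1)
    res$tail_p[q] <- 2 * min(lo, hi)
  }
  res
}
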