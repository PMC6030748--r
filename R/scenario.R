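#' Demographic scenario
#'
#' A scenario lists sampled and unsampled (stem/ancestral) populations with
#' present-day diploid effective sizes, and a time-ordered event program.
#' Times are generations before present; with the generation time fixed at
#' one year, years and generations coincide.
#'
#' Event types:
#' * `origin(pop, src, time)` — looking forward, `pop` was founded from
#'   `src` at `time`; looking backward its lineages merge into `src`.
#' * `admix(pop, src1, src2, rate, time)` — `pop` founded at `time` by
#'   admixture, a lineage tracing to `src1` with probability `rate` and to
#'   `src2` otherwise.
#' * `ne_change(pop, ne, time)` — for times older than `time` (backward),
#'   the effective size of `pop` is `ne`; successive events build a
#'   piecewise-constant size history (e.g. founding bottlenecks).
#'
#' @param populations data.frame with columns `name`, `n` (sampled diploid
#'   individuals, 0 for stems), `ne` (present-day diploid effective size).
#' @param events data.frame with columns `time`, `type`
#'   (`"origin"|"admix"|"ne_change"`), `pop`, `src1`, `src2`, `rate`, `ne`
#'   (unused fields `NA`).
#' @return an object of class `scenario`.
#' @export
scenario <- function(populations, events = NULL) {
  stopifnot(all(c("name", "n", "ne") %in% names(populations)))
  if (anyDuplicated(populations$name)) stop("duplicate population name", call. = FALSE)
  if (any(populations$ne < 1)) stop("Ne must be >= 1", call. = FALSE)
  if (any(populations$n < 0)) stop("sample sizes must be >= 0", call. = FALSE)
  if (is.null(events))
    events <- data.frame(time = numeric(), type = character(),
                         pop = character(), src1 = character(),
                         src2 = character(), rate = numeric(), ne = numeric(),
                         stringsAsFactors = FALSE)
  for (col in c("src1", "src2")) if (!col %in% names(events)) events[[col]] <- NA_character_
  for (col in c("rate", "ne")) if (!col %in% names(events)) events[[col]] <- NA_real_
  if (any(events$time < 0)) stop("event times must be >= 0", call. = FALSE)
  bad_r <- events$type == "admix" & (is.na(events$rate) | events$rate < 0 | events$rate > 1)
  if (any(bad_r)) stop("admixture rate must be in [0,1]", call. = FALSE)
  events <- events[order(events$time), , drop = FALSE]
  obj <- structure(list(populations = populations, events = events),
                   class = "scenario")
  validate_scenario(obj)
  obj
}

#' Check that every lineage can reach a single root
#'
#' Replays the event program backward in time over the set of populations
#' that carry samples; exactly one population must remain active when the
#' program ends.
#'
#' @param x a [scenario()].
#' @return `x` invisibly; error if no common root is reachable.
#' @export
validate_scenario <- function(x) {
  pops <- x$populations$name
  alive <- pops[x$populations$n > 0]
  ev <- x$events
  for (k in seq_len(nrow(ev))) {
    e <- ev[k, ]
    if (!e$type %in% c("origin", "admix", "ne_change"))
      stop("unknown event type: ", e$type, call. = FALSE)
    if (!e$pop %in% pops) stop("event names unknown population: ", e$pop, call. = FALSE)
    if (e$type %in% c("origin", "admix")) {
      if (!e$src1 %in% pops) stop("unknown source population: ", e$src1, call. = FALSE)
      if (e$type == "admix" && !e$src2 %in% pops)
        stop("unknown source population: ", e$src2, call. = FALSE)
      if (e$pop %in% alive) {
        alive <- setdiff(alive, e$pop)
        alive <- union(alive, e$src1)
        if (e$type == "admix") alive <- union(alive, e$src2)
      }
    }
  }
  if (length(alive) > 1)
    stop("scenario has no common root: populations ",
         paste(alive, collapse = ", "), " never merge", call. = FALSE)
  invisible(x)
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("scenario: %d populations (%d sampled), %d events\n",
              nrow(x$populations), sum(x$populations$n > 0), nrow(x$events)))
  invisible(x)
}

#' Generalized stepwise mutation model
#'
#' Microsatellite mutations change the repeat count by a geometrically
#' distributed number of units (parameter `p_geom`; 0 gives the strict
#' one-step model), reflected into a bounded set of contiguous allele
#' states. Per-locus rates are drawn from a Gamma distribution with shape
#' `rate_shape` around `mean_rate` (`rate_shape = Inf` fixes all loci to
#' `mean_rate`).
#'
#' @param mean_rate mean mutation rate per locus per generation.
#' @param p_geom geometric parameter of the mutation step size, in [0,1).
#' @param allele_range number of contiguous allele states.
#' @param rate_shape Gamma shape of the across-locus rate distribution.
#' @return an object of class `mutation_model`.
#' @export
mutation_model <- function(mean_rate = 5e-4, p_geom = 0, allele_range = 40L,
                           rate_shape = 2) {
  stopifnot(mean_rate > 0, p_geom >= 0, p_geom < 1, allele_range >= 2)
  structure(list(mean_rate = mean_rate, p_geom = p_geom,
                 allele_range = as.integer(allele_range),
                 rate_shape = rate_shape),
            class = "mutation_model")
}

#' Simulate diploid microsatellite genotypes under a scenario
#'
#' Each locus is an independent coalescent genealogy under the scenario's
#' demography; generalized-stepwise mutations are dropped on branches and
#' the allele state at each tip is the root state plus the accumulated
#' steps, reflected into the allele range. States are reported in base
#' pairs as `offset + motif * state`.
#'
#' @param scen a [scenario()].
#' @param mut a [mutation_model()].
#' @param n_loci number of loci.
#' @param seed integer seed; the simulation is deterministic given it.
#' @param loci optional locus table ([locus_set()]); defaults to `n_loci`
#'   dinucleotide loci named `L01`, `L02`, ...
#' @param offsets per-locus base-pair offset of state 0 (default 100).
#' @param mu optional per-locus mutation rates overriding the draw from
#'   `mut`.
#' @return a [genotype_table()].
#' @export
simulate_coalescent <- function(scen, mut, n_loci, seed = 1L, loci = NULL,
                                offsets = 100L, mu = NULL) {
  validate_scenario(scen)
  if (is.null(loci))
    loci <- locus_set(sprintf("L%02d", seq_len(n_loci)), 2L)
  stopifnot(nrow(loci) == n_loci)
  offsets <- rep_len(as.integer(offsets), n_loci)
  set.seed(seed)
  if (is.null(mu)) {
    mu <- if (is.finite(mut$rate_shape))
      stats::rgamma(n_loci, shape = mut$rate_shape,
                    scale = mut$mean_rate / mut$rate_shape)
    else rep(mut$mean_rate, n_loci)
  }
  mu <- rep_len(mu, n_loci)
  pops <- scen$populations
  idx <- stats::setNames(seq_len(nrow(pops)) - 1L, pops$name)
  ev <- scen$events
  em <- matrix(0, nrow(ev), 7)
  if (nrow(ev)) {
    em[, 1] <- ev$time
    em[, 2] <- match(ev$type, c("origin", "admix", "ne_change")) - 1L
    em[, 3] <- idx[ev$pop]
    em[, 4] <- ifelse(is.na(ev$src1), -1, idx[ev$src1])
    em[, 5] <- ifelse(is.na(ev$src2), -1, idx[ev$src2])
    em[, 6] <- ifelse(is.na(ev$rate), 0, ev$rate)
    em[, 7] <- ifelse(is.na(ev$ne), 0, ev$ne)
  }
  res <- sim_coalescent_cpp(as.integer(pops$n), as.numeric(pops$ne), em,
                            mu, mut$p_geom, mut$allele_range)
  keep <- pops$n > 0
  pop_of <- rep(pops$name[keep], pops$n[keep])
  ids <- unlist(lapply(pops$name[keep], function(p)
    sprintf("%s_%02d", p, seq_len(pops$n[pops$name == p]))))
  bp <- function(s) sweep(sweep(s, 2, loci$motif, `*`), 2, offsets, `+`)
  genotype_table(bp(res$s1), bp(res$s2), ids, pop_of, loci, validate = FALSE)
}

#' Nuisance overlay: null alleles and random missing genotypes
#'
#' @param null_freq named numeric vector, null-allele frequency per locus
#'   (unnamed loci default 0).
#' @param missing_rate probability a genotype is dropped at random.
#' @return an object of class `nuisance_model`.
#' @export
nuisance_model <- function(null_freq = numeric(), missing_rate = 0) {
  stopifnot(all(null_freq >= 0 & null_freq <= 1),
            missing_rate >= 0, missing_rate <= 1)
  structure(list(null_freq = null_freq, missing_rate = missing_rate),
            class = "nuisance_model")
}

#' Apply null alleles and missing data to a genotype table
#'
#' Each allele copy is independently replaced by a non-amplifying allele
#' with its locus' null frequency: a heterozygote with one null copy
#' appears as a homozygote for the visible allele, a null/null genotype
#' becomes missing. Additional genotypes are then set missing at random.
#'
#' @param x a [genotype_table()].
#' @param nuis a [nuisance_model()].
#' @param seed integer seed.
#' @return a new `geno_table`.
#' @export
apply_nuisance <- function(x, nuis, seed = 1L) {
  set.seed(seed)
  a1 <- x$a1; a2 <- x$a2
  n <- nrow(a1)
  for (j in seq_len(ncol(a1))) {
    nf <- nuis$null_freq[x$loci$name[j]]
    if (is.na(nf) || !length(nf)) nf <- 0
    if (nf > 0) {
      z1 <- stats::runif(n) < nf
      z2 <- stats::runif(n) < nf
      both <- z1 & z2
      a1[z2 & !z1, j] <- a1[z2 & !z1, j]       # visible copy kept
      a2[z2 & !z1, j] <- a1[z2 & !z1, j]
      a1[z1 & !z2, j] <- a2[z1 & !z2, j]
      a2[z1 & !z2, j] <- a2[z1 & !z2, j]
      a1[both, j] <- NA_integer_; a2[both, j] <- NA_integer_
    }
  }
  if (nuis$missing_rate > 0) {
    drop <- matrix(stats::runif(length(a1)) < nuis$missing_rate, nrow = n)
    a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
  }
  genotype_table(a1, a2, x$ind, x$pop, x$loci, validate = FALSE)
}

#' Read a scenario and mutation model from a YAML configuration
#'
#' Keys mirror the constructor fields: `populations:` (list of
#' `{name, n, ne}`), `events:` (list of `{time, type, pop, src1, src2,
#' rate, ne}`), optional `mutation: {mean_rate, p_geom, allele_range,
#' rate_shape}`.
#'
#' @param path YAML file.
#' @return list with elements `scenario` and `mutation`.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pops <- do.call(rbind, lapply(cfg$populations, function(p)
    data.frame(name = p$name, n = as.integer(p$n %||% 0),
               ne = as.numeric(p$ne), stringsAsFactors = FALSE)))
  evs <- if (length(cfg$events)) do.call(rbind, lapply(cfg$events, function(e)
    data.frame(time = as.numeric(e$time), type = e$type, pop = e$pop,
               src1 = e$src1 %||% NA_character_,
               src2 = e$src2 %||% NA_character_,
               rate = as.numeric(e$rate %||% NA),
               ne = as.numeric(e$ne %||% NA), stringsAsFactors = FALSE)))
  else NULL
  m <- cfg$mutation
  mut <- mutation_model(mean_rate = m$mean_rate %||% 5e-4,
                        p_geom = m$p_geom %||% 0,
                        allele_range = m$allele_range %||% 40L,
                        rate_shape = m$rate_shape %||% 2)
  list(scenario = scenario(pops, evs), mutation = mut)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
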