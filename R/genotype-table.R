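#' Describe a microsatellite locus
#'
#' A locus is identified by its name and the length in base pairs of its
#' repeat motif. Allele calls are stored in base pairs; statistics that
#' operate on repeat counts (R_ST, the stepwise mutation model) convert
#' through the motif length, using the minimum observed allele size at the
#' locus as the offset.
#'
#' @param name character locus identifier.
#' @param motif_length integer, base pairs per repeat unit (>= 1).
#' @return A one-row `data.frame` with columns `name` and `motif`.
#' @export
locus <- function(name, motif_length) {
  stopifnot(is.character(name), length(name) == 1L)
  motif_length <- as.integer(motif_length)
  if (is.na(motif_length) || motif_length < 1L)
    stop("motif_length must be an integer >= 1", call. = FALSE)
  data.frame(name = name, motif = motif_length, stringsAsFactors = FALSE)
}

#' Build a locus table
#'
#' @param names character vector of locus names.
#' @param motif_lengths integer vector (recycled if length 1) of motif
#'   lengths in base pairs.
#' @return `data.frame` with columns `name`, `motif`.
#' @export
locus_set <- function(names, motif_lengths = 2L) {
  motif_lengths <- rep_len(as.integer(motif_lengths), length(names))
  if (anyNA(motif_lengths) || any(motif_lengths < 1L))
    stop("all motif lengths must be integers >= 1", call. = FALSE)
  if (anyDuplicated(names)) stop("duplicate locus names", call. = FALSE)
  data.frame(name = as.character(names), motif = motif_lengths,
             stringsAsFactors = FALSE)
}

#' Diploid genotype table
#'
#' Container for diploid microsatellite calls: for each individual and locus
#' an unordered pair of allele sizes in base pairs, or missing (both alleles
#' `NA`; half-calls are not representable). Populations are carried as a
#' label per individual.
#'
#' @param allele1,allele2 integer matrices (individuals x loci) of allele
#'   sizes in base pairs; `NA` marks a missing genotype and must appear in
#'   both matrices at the same cells.
#' @param individuals character vector of unique individual identifiers.
#' @param populations character vector assigning each individual to a
#'   population.
#' @param loci locus table from [locus_set()].
#' @param validate check allele congruence with motif lengths.
#' @return An object of class `geno_table`.
#' @export
genotype_table <- function(allele1, allele2, individuals, populations, loci,
                           validate = TRUE) {
  allele1 <- as.matrix(allele1); allele2 <- as.matrix(allele2)
  storage.mode(allele1) <- "integer"; storage.mode(allele2) <- "integer"
  dimnames(allele1) <- dimnames(allele2) <- NULL
  n <- length(individuals)
  stopifnot(nrow(allele1) == n, nrow(allele2) == n,
            ncol(allele1) == nrow(loci), ncol(allele2) == nrow(loci),
            length(populations) == n)
  if (anyDuplicated(individuals))
    stop("duplicate individual identifiers", call. = FALSE)
  if (!identical(is.na(allele1), is.na(allele2)))
    stop("half-missing genotypes are not representable: both alleles must be NA together",
         call. = FALSE)
  # store unordered pairs canonically as (min, max)
  lo <- pmin(allele1, allele2); hi <- pmax(allele1, allele2)
  bad <- which(!is.na(lo) & lo <= 0L)
  if (length(bad))
    stop("allele sizes must be positive integers", call. = FALSE)
  obj <- structure(
    list(a1 = lo, a2 = hi,
         ind = as.character(individuals),
         pop = as.character(populations),
         loci = loci),
    class = "geno_table")
  dimnames(obj$a1) <- dimnames(obj$a2) <- list(obj$ind, loci$name)
  if (validate) validate_geno_table(obj)
  obj
}

validate_geno_table <- function(x) {
  for (j in seq_len(nrow(x$loci))) {
    al <- c(x$a1[, j], x$a2[, j])
    al <- al[!is.na(al)]
    if (!length(al)) next
    m <- x$loci$motif[j]
    r <- (al - min(al)) %% m
    if (any(r != 0L)) {
      bad <- sort(unique(al[r != 0L]))
      stop(sprintf("locus %s: alleles %s not congruent modulo motif length %d",
                   x$loci$name[j], paste(bad, collapse = ","), m),
           call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.geno_table <- function(x, ...) {
  cat(sprintf("geno_table: %d individuals, %d loci, %d populations\n",
              length(x$ind), nrow(x$loci), length(unique(x$pop))))
  invisible(x)
}

#' @export
dim.geno_table <- function(x) c(length(x$ind), nrow(x$loci))

#' Population labels of a genotype table
#' @param x a `geno_table`.
#' @return character vector of distinct population labels in order of first
#'   appearance.
#' @export
populations <- function(x) unique(x$pop)

#' Subset a genotype table by population and/or locus
#'
#' @param x a `geno_table`.
#' @param pops population labels to keep (default all).
#' @param loci locus names to keep (default all).
#' @return A `geno_table` restricted to the selection.
#' @export
subset_geno <- function(x, pops = NULL, loci = NULL) {
  keep_i <- if (is.null(pops)) seq_along(x$ind) else which(x$pop %in% pops)
  keep_j <- if (is.null(loci)) seq_len(nrow(x$loci)) else
    match(loci, x$loci$name)
  if (anyNA(keep_j)) stop("unknown locus name", call. = FALSE)
  genotype_table(x$a1[keep_i, keep_j, drop = FALSE],
                 x$a2[keep_i, keep_j, drop = FALSE],
                 x$ind[keep_i], x$pop[keep_i],
                 x$loci[keep_j, , drop = FALSE], validate = FALSE)
}

#' Allele counts for one locus
#'
#' @param x a `geno_table`.
#' @param locus locus name or index.
#' @param pop optional population label; default pools all individuals.
#' @return named integer vector of allele-copy counts, names = allele sizes.
#' @export
allele_counts <- function(x, locus, pop = NULL) {
  j <- if (is.character(locus)) match(locus, x$loci$name) else locus
  keep <- if (is.null(pop)) TRUE else x$pop == pop
  al <- c(x$a1[keep, j], x$a2[keep, j])
  al <- al[!is.na(al)]
  tab <- table(al)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Convert allele sizes to repeat counts
#'
#' Subtracts the per-locus offset (minimum observed allele size) and divides
#' by the motif length, so alleles become small non-negative integers on the
#' repeat-count scale used by R_ST and the stepwise mutation model.
#'
#' @param x a `geno_table`.
#' @return list with integer matrices `r1`, `r2` (repeat counts, `NA` for
#'   missing) and the per-locus `offset` used.
#' @export
repeat_counts <- function(x) {
  r1 <- x$a1; r2 <- x$a2
  offs <- integer(nrow(x$loci))
  for (j in seq_len(nrow(x$loci))) {
    al <- c(r1[, j], r2[, j])
    offs[j] <- if (all(is.na(al))) 0L else min(al, na.rm = TRUE)
    r1[, j] <- (r1[, j] - offs[j]) %/% x$loci$motif[j]
    r2[, j] <- (r2[, j] - offs[j]) %/% x$loci$motif[j]
  }
  list(r1 = r1, r2 = r2, offset = offs)
}

#' Combine genotype tables over the same loci
#' @param ... `geno_table` objects sharing an identical locus table.
#' @return a single `geno_table`.
#' @export
rbind_geno <- function(...) {
  xs <- list(...)
  loci <- xs[[1]]$loci
  for (x in xs) stopifnot(identical(x$loci, loci))
  genotype_table(do.call(rbind, lapply(xs, `[[`, "a1")),
                 do.call(rbind, lapply(xs, `[[`, "a2")),
                 unlist(lapply(xs, `[[`, "ind")),
                 unlist(lapply(xs, `[[`, "pop")),
                 loci, validate = FALSE)
}
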