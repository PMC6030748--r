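## ---- study-design constants ----

# sampling design: population, microsatellite sample size, mtDNA subset
# size, basin, watershed group and approximate site coordinates
.study_design <- function() {
  d <- read.table(header = TRUE, text = "
pop     n  n_mt basin   watershed lat    lon
DAN1   45  0    danube  black     48.780 17.016
DAN2   34  1    danube  black     48.693 16.999
DAN3   15  4    danube  black     47.883 17.500
DAN4   24  2    danube  black     49.029 17.392
DAN5   24  2    danube  black     49.046 17.468
DAN6   25  2    danube  black     49.340 17.345
DAN7   23  2    danube  black     49.433 17.339
DAN8   24  2    danube  black     49.041 16.616
DAN9    9  2    danube  black     49.127 16.330
DAN10  23  2    danube  black     49.209 15.991
DAN11  21  5    danube  black     48.899 22.391
DAN12  25  5    danube  black     47.364 19.823
RHI1   27  5    rhine   north     51.788  6.371
RHI2   25  5    rhine   north     50.283  8.796
RHI3   22  3    rhine   north     51.785  6.334
NET    16  5    rhine   north     51.626  4.586
ELB1   46  3    elbe    north     50.297 14.481
ELB2   22  3    elbe    north     50.101 15.158
ELB3   26  3    elbe    north     49.841 14.681
ELB4   18  3    elbe    north     50.033 15.616
ODR1   36  3    oder    baltic    49.890 18.307
ODR2   27  3    oder    baltic    49.753 18.282
ODR3   22  3    oder    baltic    49.617 17.920
ODR4   22  5    oder    baltic    51.031 16.999
VIS1   29  3    vistula baltic    52.617 18.478
VIS2   24  0    vistula baltic    52.550 19.583
ITA    34  4    po      po        45.403  8.740
LICH    0  3    oder    baltic    52.339 18.358
", stringsAsFactors = FALSE)
  d
}

#' The 12-locus marker panel of the study design
#'
#' Twelve microsatellites with a 4-bp motif for Rser11 and 2-bp motifs
#' elsewhere; Rser04 and Rser13 are the hyper-variable loci and Rser04 /
#' Rser09 the loci carrying null alleles in the emulated design.
#'
#' @return a locus table as from [locus_set()].
#' @export
study_loci <- function() {
  nm <- c("Rser01", "Rser02", "Rser03", "Rser04", "Rser05", "Rser06",
          "Rser07", "Rser09", "Rser10", "Rser11", "Rser13", "Rhca03")
  locus_set(nm, ifelse(nm == "Rser11", 4L, 2L))
}

#' Reduced 9-locus set (hyper-variable and null-allele loci removed)
#' @return character vector of locus names.
#' @export
reduced_locus_set <- function() {
  setdiff(study_loci()$name, c("Rser04", "Rser09", "Rser13"))
}

#' Populations entering the three-watershed AMOVA
#'
#' The watershed contrast uses populations close to the divides: the Elbe
#' basin (ELB1-ELB4), the Czech/Slovak Danube tributaries (DAN1, DAN2,
#' DAN4-DAN10) and the Oder basin (ODR1-ODR4).
#'
#' @return character vector of population labels.
#' @export
amova_populations <- function() {
  c(paste0("ELB", 1:4), "DAN1", "DAN2", paste0("DAN", 4:10),
    paste0("ODR", 1:4))
}

#' Populations mismatched with their watershed
#'
#' The admixed Sazava population and the three upper-Oder populations whose
#' genotypes cluster with the Danube basin.
#'
#' @return character vector of population labels.
#' @export
mismatched_populations <- function() c("ELB3", "ODR1", "ODR2", "ODR3")

#' Pooled population groups used in the demographic inference
#' @return named list of population-label vectors.
#' @export
abc_groups <- function() {
  list(SAZAVA = "ELB3",
       CZELBE = c("ELB1", "ELB2", "ELB4"),
       WMORAV = c("DAN8", "DAN9", "DAN10"),
       CZODER = c("ODR1", "ODR2", "ODR3"),
       POLRIV = c("ODR4", "VIS1", "VIS2"),
       NMORAV = c("DAN1", "DAN2", paste0("DAN", 4:7)))
}

## ---- fixture scenario ----

#' Demographic scenario underlying the study fixture
#'
#' Encodes the fixture's history: two glacial refugia (western and eastern
#' stems), colonisation of the three watershed stems, fine-scale splits of
#' the 27 sampled populations, the recent admixture origin of the Sazava
#' population (229 generations ago, 61.3% from the western Morava stem,
#' founding bottleneck Ne = 69 for 6 generations) and the translocation
#' origin of the Czech Oder populations (stem founded from the Morava stem
#' 130 generations ago through a bottleneck of Ne = 50).
#'
#' @return a [scenario()].
#' @export
study_scenario <- function() {
  d <- .study_design()
  d <- d[d$n > 0, ]
  stems <- data.frame(
    name = c("ROOT", "WEST", "EAST", "DANUBE", "TISZA", "MORAV", "DYJE",
             "NORTH", "RHINE", "ELBE", "BALTIC", "CZODER_S"),
    n = 0L,
    ne = c(10000, 8000, 4000, 6000, 4000, 2500, 2000,
           1200, 1000, 1000, 1500, 600),
    stringsAsFactors = FALSE)
  pop_ne <- c(DAN1 = 800, DAN2 = 900, DAN3 = 3000, DAN4 = 1200, DAN5 = 1000,
              DAN6 = 900, DAN7 = 1100, DAN8 = 1000, DAN9 = 500, DAN10 = 700,
              DAN11 = 2500, DAN12 = 2200, RHI1 = 700, RHI2 = 1200,
              RHI3 = 600, NET = 120, ELB1 = 900, ELB2 = 1000, ELB3 = 800,
              ELB4 = 300, ODR1 = 400, ODR2 = 250, ODR3 = 250, ODR4 = 800,
              VIS1 = 150, VIS2 = 400, ITA = 400)
  samp <- data.frame(name = d$pop, n = d$n, ne = unname(pop_ne[d$pop]),
                     stringsAsFactors = FALSE)
  pops <- rbind(stems, samp)
  ev <- function(time, type, pop, src1 = NA, src2 = NA, rate = NA, ne = NA)
    data.frame(time = time, type = type, pop = pop, src1 = src1, src2 = src2,
               rate = rate, ne = ne, stringsAsFactors = FALSE)
  events <- rbind(
    # deep structure
    ev(9000, "origin", "WEST", "ROOT"),
    ev(9000, "origin", "EAST", "ROOT"),
    ev(6000, "origin", "DANUBE", "WEST"),
    ev(3000, "origin", "TISZA", "DANUBE"),
    ev(3000, "origin", "BALTIC", "EAST"),
    ev(2500, "origin", "MORAV", "DANUBE"),
    ev(2500, "origin", "DYJE", "DANUBE"),
    ev(1500, "admix", "NORTH", "DANUBE", "EAST", rate = 0.5),
    ev(1200, "origin", "RHINE", "NORTH"),
    ev(1200, "origin", "ELBE", "NORTH"),
    # sampled populations
    ev(250, "origin", "DAN1", "MORAV"),
    ev(250, "origin", "DAN2", "MORAV"),
    ev(400, "origin", "DAN3", "DANUBE"),
    ev(150, "origin", "DAN4", "MORAV"),
    ev(150, "origin", "DAN5", "MORAV"),
    ev(200, "origin", "DAN6", "MORAV"),
    ev(150, "origin", "DAN7", "MORAV"),
    ev(250, "origin", "DAN8", "DYJE"),
    ev(300, "origin", "DAN9", "DYJE"),
    ev(300, "origin", "DAN10", "DYJE"),
    ev(400, "origin", "DAN11", "TISZA"),
    ev(400, "origin", "DAN12", "TISZA"),
    ev(60,  "origin", "ITA", "TISZA"),
    ev(300, "origin", "RHI1", "RHINE"),
    ev(300, "admix", "RHI2", "RHINE", "EAST", rate = 0.6),
    ev(300, "origin", "RHI3", "RHINE"),
    ev(600, "origin", "NET", "RHINE"),
    ev(200, "origin", "ELB1", "ELBE"),
    ev(200, "origin", "ELB2", "ELBE"),
    ev(300, "origin", "ELB4", "ELBE"),
    # Sazava: recent admixture with founding bottleneck
    ev(223, "ne_change", "ELB3", ne = 69),
    ev(229, "admix", "ELB3", "DYJE", "ELBE", rate = 0.613),
    # Czech Oder: translocation from the Morava stem through a bottleneck
    ev(110, "ne_change", "CZODER_S", ne = 50),
    ev(130, "origin", "CZODER_S", "MORAV"),
    ev(60, "origin", "ODR1", "CZODER_S"),
    ev(60, "origin", "ODR2", "CZODER_S"),
    ev(60, "origin", "ODR3", "CZODER_S"),
    # Polish rivers: old Baltic-stem splits
    ev(1200, "origin", "ODR4", "BALTIC"),
    ev(1500, "origin", "VIS1", "BALTIC"),
    ev(1200, "origin", "VIS2", "BALTIC"))
  scenario(pops, events)
}

## ---- mtDNA fixture ----

# two-lineage alignment: a star-like western haplogroup plus a small
# eastern haplogroup about 30 substitutions away, infinite-sites style
.study_mtdna <- function(seed, len = 1124L) {
  set.seed(seed)
  d <- .study_design()
  d <- d[d$n_mt > 0, ]
  west_core <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  mutate_at <- function(s, sites) {
    for (i in sites) s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1)
    s
  }
  east_sites <- sample(len, 30)
  east_core <- mutate_at(west_core, east_sites)
  free <- setdiff(seq_len(len), east_sites)
  # star-like western haplogroup: core plus derived haplotypes 1-2 steps out
  west_h <- list(west_core)
  for (i in 1:9) west_h[[i + 1]] <-
    mutate_at(west_core, sample(free, sample(1:2, 1)))
  east_h <- list(east_core,
                 mutate_at(east_core, sample(free, 1)),
                 mutate_at(east_core, sample(free, 2)))
  eastern_pops <- c("VIS1", "ODR4", "LICH")
  seqs <- character(0); pops <- character(0)
  for (r in seq_len(nrow(d))) {
    p <- d$pop[r]; nm <- d$n_mt[r]
    n_east <- if (p %in% eastern_pops) nm else if (p == "RHI2") 2L else 0L
    for (q in seq_len(nm)) {
      if (q <= n_east) {
        h <- east_h[[sample.int(length(east_h), 1, prob = c(0.7, 0.2, 0.1))]]
      } else {
        h <- west_h[[sample.int(length(west_h), 1,
                                prob = c(0.55, rep(0.05, 9)))]]
      }
      seqs <- c(seqs, paste(h, collapse = ""))
      pops <- c(pops, p)
    }
  }
  names(seqs) <- sprintf("%s_mt%02d", pops, stats::ave(seq_along(pops), pops,
                                                       FUN = seq_along))
  seq_alignment(seqs, pops)
}

#' Generate the full study fixture
#'
#' Emits a 27-population microsatellite dataset (688 individuals, 12 loci)
#' simulated under [study_scenario()], overlays null alleles on Rser04
#' (6.9%) and Rser09 (7.9%) and ~4% random missing genotypes, and builds
#' the accompanying metadata (watershed groups, coordinates) and an
#' 83-sequence, 1124-bp two-lineage mtDNA alignment with a star-like
#' western haplogroup. Deterministic given `seed`.
#'
#' @param seed integer seed.
#' @param nuisance apply the null-allele/missing overlay (default TRUE).
#' @return list with `genotypes` (a [genotype_table()]), `grouping`
#'   (a [grouping_scheme()]), `alignment` (a [seq_alignment()]), and
#'   `scenario`.
#' @export
make_study_fixture <- function(seed = 1L, nuisance = TRUE) {
  scen <- study_scenario()
  loci <- study_loci()
  mu <- ifelse(loci$name %in% c("Rser04", "Rser13"), 4e-3, 5e-4)
  offsets <- ifelse(loci$name == "Rser11", 150L, 100L)
  mut <- mutation_model(mean_rate = 5e-4, p_geom = 0.22, allele_range = 40L)
  gt <- simulate_coalescent(scen, mut, n_loci = nrow(loci), seed = seed,
                            loci = loci, offsets = offsets, mu = mu)
  if (nuisance) {
    nuis <- nuisance_model(null_freq = c(Rser04 = 0.069, Rser09 = 0.079),
                           missing_rate = 0.035)
    gt <- apply_nuisance(gt, nuis, seed = seed + 1L)
  }
  d <- .study_design()
  ds <- d[d$n > 0, ]
  grouping <- grouping_scheme(ds$pop, ds$watershed,
                              coords = data.frame(lat = ds$lat, lon = ds$lon))
  aln <- .study_mtdna(seed + 2L)
  list(genotypes = gt, grouping = grouping, alignment = aln, scenario = scen)
}
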