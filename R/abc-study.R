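## ---- study scenario families for the demographic inference ----

.read_priors <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(rbind, lapply(cfg$params, function(p)
    data.frame(param = p$name, min = p$min, max = p$max,
               stringsAsFactors = FALSE)))
}

# three-group skeleton: focal population founded from / admixed between two
# source groups, with a founding bottleneck; sources split from a common
# ancestor further back
.three_group_builder <- function(focal, srcA, srcB, nf, nA, nB,
                                 mode = c("admix", "pureA", "pureB")) {
  mode <- match.arg(mode)
  function(theta) {
    t_f <- theta[[5]]; t_anc <- theta[[6]]
    d_bot <- theta[[9]]
    if (t_anc <= t_f || d_bot >= t_f) return(NULL)
    pops <- data.frame(
      name = c(focal, srcA, srcB, "ANC"),
      n = c(nf, nA, nB, 0L),
      ne = c(theta[[1]], theta[[2]], theta[[3]], theta[[4]]),
      stringsAsFactors = FALSE)
    ev <- list(
      data.frame(time = t_f - d_bot, type = "ne_change", pop = focal,
                 src1 = NA, src2 = NA, rate = NA, ne = theta[[8]],
                 stringsAsFactors = FALSE),
      if (mode == "admix")
        data.frame(time = t_f, type = "admix", pop = focal,
                   src1 = srcA, src2 = srcB, rate = theta[[7]], ne = NA,
                   stringsAsFactors = FALSE)
      else
        data.frame(time = t_f, type = "origin", pop = focal,
                   src1 = if (mode == "pureA") srcA else srcB,
                   src2 = NA, rate = NA, ne = NA, stringsAsFactors = FALSE),
      data.frame(time = t_anc, type = "origin", pop = srcA,
                 src1 = "ANC", src2 = NA, rate = NA, ne = NA,
                 stringsAsFactors = FALSE),
      data.frame(time = t_anc, type = "origin", pop = srcB,
                 src1 = "ANC", src2 = NA, rate = NA, ne = NA,
                 stringsAsFactors = FALSE))
    scenario(pops, do.call(rbind, ev))
  }
}

#' Scenario family for the origin of the Sazava population
#'
#' Three competing models for the SAZAVA group (pooled with its sources
#' CZELBE and WMORAV): admixture between CZELBE and WMORAV, pure CZELBE
#' origin, and pure WMORAV origin, each with a founding bottleneck.
#' Priors are uniform with bounds read from an editable YAML file.
#'
#' @param config path of the prior configuration (default: the file
#'   shipped with the package).
#' @param n sample sizes per group (named vector with SAZAVA, CZELBE,
#'   WMORAV; defaults to the study design).
#' @return list of three [abc_model()] objects.
#' @export
sazava_models <- function(config = system.file("extdata", "sazava_priors.yml",
                                               package = "hydropop"),
                          n = c(SAZAVA = 26L, CZELBE = 86L, WMORAV = 56L)) {
  prior <- .read_priors(config)
  list(
    abc_model("admix_elbe_wmorav", prior,
              .three_group_builder("SAZAVA", "WMORAV", "CZELBE",
                                   n[["SAZAVA"]], n[["WMORAV"]],
                                   n[["CZELBE"]], "admix")),
    abc_model("pure_elbe", prior,
              .three_group_builder("SAZAVA", "WMORAV", "CZELBE",
                                   n[["SAZAVA"]], n[["WMORAV"]],
                                   n[["CZELBE"]], "pureB")),
    abc_model("pure_wmorav", prior,
              .three_group_builder("SAZAVA", "WMORAV", "CZELBE",
                                   n[["SAZAVA"]], n[["WMORAV"]],
                                   n[["CZELBE"]], "pureA")))
}

#' Scenario family for the origin of the Czech Oder populations
#'
#' Three competing models for the CZODER group against its candidate
#' sources NMORAV (Black Sea watershed, translocation hypothesis) and
#' POLRIV (Baltic watershed, natural colonisation): pure NMORAV origin,
#' pure POLRIV origin, and admixture.
#'
#' @param config path of the prior configuration YAML.
#' @param n sample sizes per group.
#' @return list of three [abc_model()] objects.
#' @export
czoder_models <- function(config = system.file("extdata", "czoder_priors.yml",
                                               package = "hydropop"),
                          n = c(CZODER = 85L, NMORAV = 175L, POLRIV = 75L)) {
  prior <- .read_priors(config)
  list(
    abc_model("pure_nmorav", prior,
              .three_group_builder("CZODER", "NMORAV", "POLRIV",
                                   n[["CZODER"]], n[["NMORAV"]],
                                   n[["POLRIV"]], "pureA")),
    abc_model("pure_polriv", prior,
              .three_group_builder("CZODER", "NMORAV", "POLRIV",
                                   n[["CZODER"]], n[["NMORAV"]],
                                   n[["POLRIV"]], "pureB")),
    abc_model("admix_nmorav_polriv", prior,
              .three_group_builder("CZODER", "NMORAV", "POLRIV",
                                   n[["CZODER"]], n[["NMORAV"]],
                                   n[["POLRIV"]], "admix")))
}

#' Group design matching the builders of [sazava_models()]
#' @return named list for [summary_statistics()].
#' @export
sazava_groups <- function() list(SAZAVA = "SAZAVA", CZELBE = "CZELBE",
                                 WMORAV = "WMORAV")

#' Group design matching the builders of [czoder_models()]
#' @return named list for [summary_statistics()].
#' @export
czoder_groups <- function() list(CZODER = "CZODER", NMORAV = "NMORAV",
                                 POLRIV = "POLRIV")

#' Pool fixture populations into the inference groups
#'
#' Relabels the populations of a genotype table by their pooled group
#' (e.g. ELB1/ELB2/ELB4 -> CZELBE) and drops individuals outside the
#' design, so the observed statistics are computed on the same footing as
#' the simulated ones.
#'
#' @param x a [genotype_table()].
#' @param groups named list mapping group label to population labels.
#' @return a [genotype_table()] whose populations are the group labels.
#' @export
pool_groups <- function(x, groups) {
  lab <- rep(NA_character_, length(x$ind))
  for (g in names(groups)) lab[x$pop %in% groups[[g]]] <- g
  keep <- !is.na(lab)
  genotype_table(x$a1[keep, , drop = FALSE], x$a2[keep, , drop = FALSE],
                 x$ind[keep], lab[keep], x$loci, validate = FALSE)
}
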