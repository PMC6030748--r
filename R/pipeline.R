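#' Default pipeline configuration
#'
#' @param seed global seed; every stochastic stage derives its seed from it.
#' @param out_dir output directory.
#' @param stages stages to run, in dependency order, among
#'   `"simulate"`, `"diversity"`, `"diff"`, `"structure"`, `"network"`,
#'   `"abc"`.
#' @return a named list understood by [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1L, out_dir = "hydropop_out",
                            stages = c("simulate", "diversity", "diff",
                                       "structure", "network", "abc")) {
  list(
    seed = seed, out_dir = out_dir, stages = stages,
    input = list(genepop = NULL, metadata = NULL, fasta = NULL),
    diversity = list(g = 18L, hwe = FALSE),
    diff = list(n_perm_fst = 100L, n_perm_rst = 0L, n_perm_amova = 1000L,
                mismatched = mismatched_populations(),
                amova_pops = amova_populations(),
                ibd_pops = paste0("DAN", 1:10)),
    structure = list(Ks = 2:4, replicates = 2L, iters = 2000L,
                     burnin = 500L, final_K = 2L),
    abc = list(n_per_scenario = 500L, tolerance = 0.05, families = "sazava"),
    mutation = list(mean_rate = 5e-4, p_geom = 0.22, allele_range = 40L))
}

.write_tsv <- function(df, path, seed) {
  con <- file(path, "w")
  writeLines(sprintf("# hydropop %s seed=%s",
                     as.character(utils::packageVersion("hydropop")), seed),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on either the built-in
#' synthetic study fixture (stage `"simulate"`) or user-supplied files
#' (Genepop genotypes, metadata, FASTA alignment), writing per-stage TSV
#' outputs, a log with versions/seed/timings, and a consolidated summary.
#' A stage failure aborts with the stage name; outputs of completed stages
#' are retained.
#'
#' @param config list from [pipeline_config()] (or a YAML file path whose
#'   keys override the defaults).
#' @return invisibly, a list with the per-stage results and output paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) {
    user <- yaml::read_yaml(config)
    config <- utils::modifyList(pipeline_config(), user)
  }
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "pipeline_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat(sprintf("hydropop %s\nseed: %d\nstages: %s\n",
              as.character(utils::packageVersion("hydropop")), cfg$seed,
              paste(cfg$stages, collapse = ", ")),
      file = log_path)
  res <- list(paths = character())
  stage <- function(name, fun) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    t0 <- Sys.time()
    out <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    logf("stage %-10s %.1fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    out
  }

  # ---- data ----
  dat <- stage("simulate", function() {
    fx <- make_study_fixture(cfg$seed)
    write_genepop(fx$genotypes, file.path(cfg$out_dir, "genotypes.gen"))
    write_metadata(fx$grouping, file.path(cfg$out_dir, "metadata.tsv"))
    write_fasta_alignment(fx$alignment, file.path(cfg$out_dir, "cytb.fasta"))
    fx
  })
  if (is.null(dat)) {
    if (is.null(cfg$input$genepop))
      stop("no input: enable the simulate stage or provide input files",
           call. = FALSE)
    gt <- read_genepop(cfg$input$genepop, loci = study_loci())
    grouping <- if (!is.null(cfg$input$metadata))
      read_metadata(cfg$input$metadata) else NULL
    aln <- if (!is.null(cfg$input$fasta))
      read_fasta_alignment(cfg$input$fasta) else NULL
    dat <- list(genotypes = gt, grouping = grouping, alignment = aln)
  }
  gt <- dat$genotypes
  res$data <- dat

  # ---- diversity ----
  res$diversity <- stage("diversity", function() {
    dv <- diversity_table(gt, g = cfg$diversity$g, hwe = cfg$diversity$hwe,
                          seed = cfg$seed)
    .write_tsv(dv, file.path(cfg$out_dir, "diversity.tsv"), cfg$seed)
    red <- reduced_locus_set()
    means <- do.call(rbind, lapply(populations(gt), function(p) {
      dd <- dv[dv$population == p, ]
      data.frame(population = p,
                 Ho_12 = mean(dd$Ho, na.rm = TRUE),
                 He_12 = mean(dd$He, na.rm = TRUE),
                 AR_12 = mean(dd$AR, na.rm = TRUE),
                 Ho_9 = mean(dd$Ho[dd$locus %in% red], na.rm = TRUE),
                 He_9 = mean(dd$He[dd$locus %in% red], na.rm = TRUE),
                 AR_9 = mean(dd$AR[dd$locus %in% red], na.rm = TRUE))
    }))
    .write_tsv(means, file.path(cfg$out_dir, "diversity_means.tsv"), cfg$seed)
    list(table = dv, means = means)
  })

  # ---- differentiation ----
  res$diff <- stage("diff", function() {
    pm <- pairwise_matrices(gt, n_perm = cfg$diff$n_perm_fst,
                            n_perm_rst = cfg$diff$n_perm_rst,
                            seed = cfg$seed)
    # joint matrix layout: F_ST above the diagonal, R_ST below
    tab2 <- pm$fst
    tab2[lower.tri(tab2)] <- pm$rst[lower.tri(pm$rst)]
    .write_tsv(data.frame(population = rownames(tab2), round(tab2, 4),
                          check.names = FALSE),
               file.path(cfg$out_dir, "fst_rst_matrix.tsv"), cfg$seed)
    out <- list(matrices = pm)
    if (!is.null(dat$grouping)) {
      apops <- intersect(cfg$diff$amova_pops, populations(gt))
      am_all <- amova(subset_geno(gt, pops = apops), dat$grouping,
                      n_perm = cfg$diff$n_perm_amova, seed = cfg$seed)
      keep <- setdiff(apops, cfg$diff$mismatched)
      am_red <- amova(subset_geno(gt, pops = keep), dat$grouping,
                      n_perm = cfg$diff$n_perm_amova, seed = cfg$seed)
      am <- data.frame(
        analysis = c("all_populations", "mismatched_removed"),
        FCT = c(am_all$FCT, am_red$FCT),
        FSC = c(am_all$FSC, am_red$FSC),
        FST = c(am_all$FST, am_red$FST),
        p_FCT = c(am_all$p_fct, am_red$p_fct))
      .write_tsv(am, file.path(cfg$out_dir, "amova.tsv"), cfg$seed)
      out$amova <- list(all = am_all, reduced = am_red)
      ibd_pops <- intersect(cfg$diff$ibd_pops, populations(gt))
      if (length(ibd_pops) >= 4 && !is.null(dat$grouping$dist)) {
        ib <- ibd_regression(pm$fst, dat$grouping, pops = ibd_pops,
                             seed = cfg$seed)
        out$ibd <- ib
        .write_tsv(data.frame(slope = ib$slope, intercept = ib$intercept,
                              mantel_r = ib$mantel_r, p = ib$p),
                   file.path(cfg$out_dir, "ibd.tsv"), cfg$seed)
      }
    }
    out
  })

  # ---- clustering ----
  res$structure <- stage("structure", function() {
    sk <- scan_k(gt, cfg$structure$Ks, replicates = cfg$structure$replicates,
                 iters = cfg$structure$iters, burnin = cfg$structure$burnin,
                 seed = cfg$seed)
    .write_tsv(sk, file.path(cfg$out_dir, "delta_k.tsv"), cfg$seed)
    K <- cfg$structure$final_K
    runs <- lapply(seq_len(cfg$structure$replicates), function(r)
      admixture_gibbs(gt, K, iters = cfg$structure$iters,
                      burnin = cfg$structure$burnin,
                      seed = cfg$seed + 500L * r))
    al <- align_runs(runs)
    qdf <- data.frame(individual = rownames(al$mean_Q),
                      population = gt$pop, al$mean_Q, check.names = FALSE)
    .write_tsv(qdf, file.path(cfg$out_dir, sprintf("q_matrix_K%d.tsv", K)),
               cfg$seed)
    png_path <- file.path(cfg$out_dir, sprintf("structure_K%d.png", K))
    grDevices::png(png_path, width = 1200, height = 300)
    graphics::barplot(t(al$mean_Q), col = seq_len(K) + 1, border = NA,
                      space = 0, names.arg = rep("", nrow(al$mean_Q)),
                      main = sprintf("admixture proportions, K = %d", K))
    grDevices::dev.off()
    fc <- fca(gt)
    .write_tsv(data.frame(population = rownames(fc$pop_centroids),
                          fc$pop_centroids),
               file.path(cfg$out_dir, "fca_centroids.tsv"), cfg$seed)
    list(scan = sk, aligned = al, fca = fc)
  })

  # ---- haplotype network ----
  res$network <- stage("network", function() {
    if (is.null(dat$alignment)) return(NULL)
    hs <- collapse_haplotypes(dat$alignment)
    net <- median_joining(hs)
    write_network(net, file.path(cfg$out_dir, "network_edges.tsv"),
                  file.path(cfg$out_dir, "network.gml"))
    .write_tsv(data.frame(haplotype = rownames(hs$pop_counts),
                          freq = hs$freq, hs$pop_counts, check.names = FALSE),
               file.path(cfg$out_dir, "haplotypes.tsv"), cfg$seed)
    list(haplotypes = hs, network = net)
  })

  # ---- demographic inference ----
  res$abc <- stage("abc", function() {
    mut <- mutation_model(cfg$mutation$mean_rate, cfg$mutation$p_geom,
                          cfg$mutation$allele_range)
    loci <- study_loci()
    out <- list()
    for (fam in cfg$abc$families) {
      models <- if (fam == "sazava") sazava_models() else czoder_models()
      groups <- if (fam == "sazava") sazava_groups() else czoder_groups()
      pools <- if (fam == "sazava")
        abc_groups()[c("SAZAVA", "CZELBE", "WMORAV")]
      else abc_groups()[c("CZODER", "NMORAV", "POLRIV")]
      obs_gt <- pool_groups(gt, pools)
      obs <- summary_statistics(obs_gt, stats::setNames(as.list(names(pools)),
                                                        names(pools)))
      ref <- build_reference(models, groups, cfg$abc$n_per_scenario, mut,
                             loci, seed = cfg$seed + 77L)
      mc <- model_choice(ref, obs, tolerance = cfg$abc$tolerance)
      best <- mc$scenario[which.max(mc$posterior)]
      rb <- ref[ref$scenario == best, ]
      attr(rb, "priors") <- attr(ref, "priors")
      pe <- estimate_parameters(rb, obs, tolerance = cfg$abc$tolerance)
      .write_tsv(mc, file.path(cfg$out_dir, sprintf("abc_%s_models.tsv", fam)),
                 cfg$seed)
      .write_tsv(pe$summary,
                 file.path(cfg$out_dir, sprintf("abc_%s_params.tsv", fam)),
                 cfg$seed)
      out[[fam]] <- list(model_choice = mc, best = best, params = pe)
    }
    jsonlite::write_json(
      lapply(out, function(o) list(best = o$best,
                                   posterior = o$model_choice)),
      file.path(cfg$out_dir, "abc_results.json"), auto_unbox = TRUE,
      digits = NA)
    out
  })

  # ---- consolidated summary ----
  summ <- list(seed = cfg$seed,
               n_individuals = length(gt$ind),
               n_populations = length(populations(gt)),
               n_pairs = length(populations(gt)) *
                 (length(populations(gt)) - 1) / 2)
  if (!is.null(res$diff$amova)) {
    summ$FCT_all <- res$diff$amova$all$FCT
    summ$FCT_reduced <- res$diff$amova$reduced$FCT
  }
  if (!is.null(res$abc))
    summ$abc_best <- lapply(res$abc, `[[`, "best")
  jsonlite::write_json(summ, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("done")
  invisible(res)
}
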