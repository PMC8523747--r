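#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML file (or an equivalent R list) with a
#' mandatory `seed`, an output directory, stage toggles, and either a
#' `simulate` block (synthetic cohort parameters) or input paths to a
#' beta matrix, sample metadata and probe manifest.  Referenced files
#' are checked for existence up front, before any compute.
#'
#' @param config Path to a YAML file or a named list.
#' @return The validated configuration list.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$seed))
    stop("the configuration must set a seed")
  if (is.null(config$out_dir)) config$out_dir <- "clonmeth_out"
  config$stages <- modifyList(
    list(qc = TRUE, ewas = TRUE, select = TRUE, enrich = TRUE,
         motifs = FALSE, predict = FALSE), config$stages %||% list())
  for (p in unlist(config$inputs)) {
    if (!file.exists(p)) stop("input file does not exist: ", p)
  }
  if (isTRUE(config$stages$motifs) && is.null(config$simulate) &&
      is.null(config$inputs$fasta))
    stop("motifs stage requires a FASTA input")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sidecar <- function(path, params, seed, inputs = character()) {
  meta <- list(parameters = params,
               software = paste0("clonmeth ",
                                 as.character(packageVersion("clonmeth"))),
               seed = seed,
               input_checksums = if (length(inputs))
                 as.list(tools::md5sum(inputs)) else list(),
               created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
}

#' QQ plot of EWAS P values
#' @param p_values P values.
#' @param path Output PNG path.
#' @export
plot_qq <- function(p_values, path) {
  grDevices::png(path, width = 600, height = 600)
  on.exit(grDevices::dev.off())
  n <- length(p_values)
  exp_p <- -log10((seq_len(n) - 0.5) / n)
  obs_p <- -log10(sort(p_values))
  plot(exp_p, obs_p, pch = 20, cex = 0.5,
       xlab = "Expected -log10(P)", ylab = "Observed -log10(P)",
       main = sprintf("lambda = %.2f", genomic_inflation(p_values)))
  graphics::abline(0, 1, col = "red")
  invisible(path)
}

#' Volcano plot of an EWAS table
#' @param ewas_table EWAS table.
#' @param cutoff Optional significance cutoff drawn as a dashed line.
#' @param path Output PNG path.
#' @export
plot_volcano <- function(ewas_table, cutoff = NULL, path) {
  grDevices::png(path, width = 700, height = 600)
  on.exit(grDevices::dev.off())
  sig <- if (!is.null(cutoff)) ewas_table$p_value <= cutoff else FALSE
  col <- ifelse(sig & ewas_table$direction > 0, "red",
                ifelse(sig, "blue", "grey50"))
  plot(ewas_table$estimate, -log10(ewas_table$p_value), pch = 20,
       cex = 0.5, col = col, xlab = "Effect estimate (M units)",
       ylab = "-log10(P)")
  if (!is.null(cutoff))
    graphics::abline(h = -log10(cutoff), lty = 2)
  invisible(path)
}

#' Directionality-curve plot
#' @param curve A [directionality_curve()] result.
#' @param min_proportion Proportion rule drawn as a dashed line.
#' @param path Output PNG path.
#' @export
plot_directionality <- function(curve, min_proportion = 0.95, path) {
  grDevices::png(path, width = 700, height = 500)
  on.exit(grDevices::dev.off())
  plot(-log10(curve$cutoff), curve$proportion, type = "l", col = "red",
       xlab = "-log10(P cutoff)", ylab = "Directional proportion")
  graphics::abline(h = min_proportion, lty = 2)
  invisible(path)
}

#' Run the analysis pipeline end to end
#'
#' Executes the configured stages in order — simulate (or load), QC,
#' EWAS, threshold selection, enrichment, motifs, predictor — writing
#' every table as TSV with a JSON sidecar (parameters, package version,
#' seed, input checksums) plus QQ/volcano/directionality plots.
#'
#' @param config A configuration accepted by [read_pipeline_config()].
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config) {
  config <- read_pipeline_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  # --- inputs: synthetic by default -------------------------------------
  if (!is.null(config$simulate) || is.null(config$inputs)) {
    simcfg <- config$simulate %||% list()
    n_probes <- simcfg$n_probes %||% 20000
    ann <- make_annotation(n_probes = n_probes, seed = seed)
    design_args <- simcfg[setdiff(names(simcfg), "n_probes")]
    design <- do.call(sim_design, c(design_args, list(seed = seed + 1)))
    refs <- make_reference_profiles(ann, design$cell_types,
                                    seed = seed + 2)
    sim <- simulate_cohort(design, ann, refs)
    cohort <- sim$cohort
    write_cohort(sim, file.path(out, "simulated"))
    write_annotation(ann, file.path(out, "simulated"))
  } else {
    beta <- read_matrix_tsv(config$inputs$beta)
    meta <- utils::read.delim(config$inputs$metadata)
    manifest <- utils::read.delim(config$inputs$manifest)
    cohort <- structure(list(beta = beta, M = beta_to_m(beta),
                             samples = meta, cell_fractions = NULL),
                        class = "methylation_cohort")
    ann <- list(probes = manifest,
                cell_types = config$cell_types %||% character())
    class(ann) <- "probe_annotation"
  }

  # --- qc ---------------------------------------------------------------
  if (isTRUE(config$stages$qc)) {
    screen <- pca_outlier_screen(cohort$M,
                                 n_components = config$qc$n_components %||% 7,
                                 z_max = config$qc$z_max %||% 6)
    keep <- !screen$flagged
    cohort$beta <- cohort$beta[, keep, drop = FALSE]
    cohort$M <- cohort$M[, keep, drop = FALSE]
    cohort$samples <- cohort$samples[keep, , drop = FALSE]
    if (!is.null(cohort$cell_fractions))
      cohort$cell_fractions <- cohort$cell_fractions[keep, , drop = FALSE]
    cohort$M <- batch_center(cohort$M, cohort$samples$batch)
    write_tsv(screen, file.path(out, "qc_outlier_screen.tsv"))
    sidecar(file.path(out, "qc_outlier_screen.tsv"),
            config$qc %||% list(), seed)
  }

  # --- ewas + site selection -------------------------------------------
  results <- list()
  if (isTRUE(config$stages$ewas)) {
    gene <- config$ewas$exposure %||% "TET2"
    des <- ewas_design(
      exposure = gene,
      covariates = config$ewas$covariates %||% c("age", "sex", "batch"),
      n_pcs = config$ewas$n_pcs %||% 4,
      grouping = config$ewas$grouping %||% "pair")
    tab <- run_ewas(cohort, des)
    results$ewas <- tab
    write_tsv(tab, file.path(out, "ewas.tsv"))
    sidecar(file.path(out, "ewas.tsv"),
            list(exposure = gene, lambda = genomic_inflation(tab$p_value)),
            seed)
    plot_qq(tab$p_value, file.path(out, "qq.png"))

    if (isTRUE(config$stages$select)) {
      hs <- select_hyper_set(tab,
                             direction = config$select$direction %||% 1,
                             min_proportion =
                               config$select$min_proportion %||% 0.95,
                             fallback_k = config$select$fallback_k %||% 2000,
                             source = gene)
      results$hyper_set <- hs
      write_tsv(data.frame(probe_id = hs$probe_ids),
                file.path(out, "hyper_set.tsv"))
      sidecar(file.path(out, "hyper_set.tsv"),
              list(rule = hs$rule, cutoff = hs$cutoff, k = hs$k), seed)
      plot_volcano(tab, hs$cutoff, file.path(out, "volcano.png"))
      plot_directionality(directionality_curve(tab, hs$direction),
                          path = file.path(out, "directionality.png"))

      if (isTRUE(config$stages$enrich) && length(ann$cell_types)) {
        ct <- ann$cell_types[1]
        states <- data.frame(probe_id = ann$probes$probe_id,
                             state = ann$probes[[paste0("state_", ct)]],
                             island_relation = ann$probes$island_relation)
        comp <- composition_enrichment(hs, states, "state")
        isl <- composition_enrichment(hs, states, "island_relation")
        results$state_enrichment <- comp
        write_tsv(comp, file.path(out, "state_enrichment.tsv"))
        write_tsv(isl, file.path(out, "island_enrichment.tsv"))
        sidecar(file.path(out, "state_enrichment.tsv"),
                list(cell_type = ct), seed)
      }
    }
  }

  # --- predictor --------------------------------------------------------
  if (isTRUE(config$stages$predict) && !is.null(results$hyper_set)) {
    gene <- config$ewas$exposure %||% "TET2"
    ids <- results$hyper_set$probe_ids
    Xp <- t(cohort$M[ids, , drop = FALSE])
    yp <- as.numeric(cohort$samples[[gene]])
    rep <- loocv_predict(Xp, yp, enet_spec(
      alpha = config$predict$alpha %||% 0.5))
    pred <- data.frame(sample_id = cohort$samples$sample_id,
                       probability = rep$probabilities,
                       predicted = rep$predicted, truth = yp)
    write_tsv(pred, file.path(out, "predictions.tsv"))
    sidecar(file.path(out, "predictions.tsv"),
            list(sensitivity = rep$sensitivity,
                 specificity = rep$specificity), seed)
    results$prediction <- rep
  }

  invisible(out)
}
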