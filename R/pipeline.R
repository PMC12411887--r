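#' Run the full SIAM analysis pipeline
#'
#' Executes simulate -> filter -> cluster/correct/classify -> flux partition
#' -> normalize/ordinate/PERMANOVA -> multiblock sPLS-DA -> report, writing
#' each stage's outputs (CSV/JSON) to `config$outdir` before the next stage
#' begins. Every stage draws its randomness from a seed derived from the root
#' seed, and the run manifest records the config, per-stage seeds, output
#' checksums, wall-clock times and warnings; re-running with the same config
#' reproduces identical checksums.
#'
#' @param config A [run_config()].
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
#' @examples
#' \donttest{
#' cfg <- run_config(seed = 1, n_species = 40, n_permutations = 99)
#' man <- run_pipeline(cfg)
#' names(man$stages)
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "siam_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config),
                   version = as.character(packageVersion("siampeat")),
                   stages = list())
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    warns <- character()
    files <- withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
      }),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    manifest$stages[[name]] <<- list(
      seed = stage_seed(config$seed, name),
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3),
      files = as.list(tools::md5sum(files)),
      warnings = warns
    )
  }

  out <- function(...) file.path(config$outdir, ...)

  run_stage("simulate", function() {
    sd_sim <- stage_seed(config$seed, "simulate")
    state$design <- sample_design()
    state$species <- generate_species(
      config$n_species, origin_mix = unlist(config$origin_mix),
      enrichment = config$enrichment, enrichment_sd = config$enrichment_sd,
      seed = sd_sim
    )
    sim <- generate_feature_table(
      state$species, state$design,
      dynamics = do.call(dynamics_config, config$dynamics),
      noise = do.call(noise_config, config$noise),
      seed = sd_sim + 1L
    )
    state$table <- sim$table
    state$truth <- sim$truth
    state$nmr <- generate_nmr_block(
      config$n_nmr_metabolites, state$design,
      labeled_fraction = config$nmr_labeled_fraction, seed = sd_sim + 2L
    )
    state$flux <- simulate_flux_series(
      do.call(flux_config, config$flux), seed = sd_sim + 3L
    )
    cfg_echo <- config
    cfg_echo$outdir <- "." # keep the echoed config portable and run-invariant
    write_run_config(cfg_echo, out("run_config.yaml"))
    write_feature_table(state$table, out("feature_table.csv"))
    write_metadata(state$design, out("metadata.csv"))
    readr::write_csv(state$nmr$concentrations, out("nmr_concentrations.csv"))
    write_flux_table(state$flux$observations, out("flux.csv"))
    readr::write_csv(state$truth$feature_map, out("truth_feature_map.csv"))
    readr::write_csv(state$flux$truth, out("truth_flux.csv"))
    jsonlite::write_json(
      list(labeled_species = state$truth$labeled_species,
           species = state$truth$species),
      out("truth_species.json"), auto_unbox = TRUE, digits = NA
    )
    out(c("run_config.yaml", "feature_table.csv", "metadata.csv",
          "nmr_concentrations.csv", "flux.csv", "truth_feature_map.csv",
          "truth_flux.csv", "truth_species.json"))
  })

  run_stage("filter", function() {
    state$filtered <- filter_features(
      state$table, min_mass = config$min_mass, max_mass = config$max_mass,
      min_intensity = config$min_intensity, min_snr = config$min_snr
    )
    if (nrow(state$filtered) == 0) stop("empty feature set")
    write_feature_table(state$filtered, out("filtered_features.csv"))
    out("filtered_features.csv")
  })

  run_stage("detect", function() {
    cl <- cluster_isotopologues(state$filtered, rt_tol = config$rt_tol,
                                mass_tol_ppm = config$mass_tol_ppm)
    state$clusters <- analyze_clusters(cl, min_incorporation = config$min_incorporation)
    flat <- state$clusters |>
      dplyr::select("cluster_id", "base_feature_id", "n_members",
                    "n_carbon_est", "enrichment_at_pct", "diagnostic_ratio",
                    "label_call")
    readr::write_csv(flat, out("clusters.csv"))
    state$detection <- summarize_detection(state$clusters)
    readr::write_csv(state$detection, out("detection_summary.csv"))
    jsonlite::write_json(state$detection, out("detection_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    out(c("clusters.csv", "detection_summary.csv", "detection_summary.json"))
  })

  run_stage("partition", function() {
    state$partition <- partition_series(state$flux$observations,
                                        r_litter = config$r_litter)
    readr::write_csv(state$partition$per_day, out("flux_partition.csv"))
    readr::write_csv(state$partition$cumulative, out("flux_cumulative.csv"))
    out(c("flux_partition.csv", "flux_cumulative.csv"))
  })

  run_stage("ordinate", function() {
    sd_ord <- stage_seed(config$seed, "ordinate")
    m <- cluster_abundance_matrix(state$clusters) |>
      median_normalize() |>
      pareto_scale()
    state$scaled <- m
    d <- manhattan_distance(m)
    state$pcoa <- pcoa(d)
    state$hclust <- hierarchical_cluster(d, linkage = config$linkage)
    dsg <- state$design[match(colnames(m), state$design$sample_id), ]
    grp <- paste(dsg$treatment, dsg$timepoint, sep = "_")
    state$permanova <- list(
      sample_type = permanova(d, dsg$treatment, config$n_permutations,
                              seed = sd_ord, factor_name = "treatment"),
      time = permanova(d, dsg$timepoint, config$n_permutations,
                       seed = sd_ord + 1L, factor_name = "timepoint"),
      group = permanova(d, grp, config$n_permutations,
                        seed = sd_ord + 2L, factor_name = "treatment_timepoint")
    )
    coords <- tibble::as_tibble(state$pcoa$coordinates, rownames = "sample_id")
    readr::write_csv(coords, out("pcoa_coordinates.csv"))
    readr::write_csv(tibble::tibble(eigenvalue = state$pcoa$eigenvalues),
                     out("pcoa_eigenvalues.csv"))
    readr::write_csv(
      tibble::as_tibble(state$hclust$merge, .name_repair = ~ c("left", "right")) |>
        dplyr::mutate(height = state$hclust$height),
      out("hclust_merges.csv")
    )
    perm_tbl <- purrr::map_dfr(state$permanova, function(p) {
      tibble::tibble(factor = p$factor_name, pseudo_f = p$pseudo_f,
                     p_value = p$p_value, n_permutations = p$n_permutations)
    })
    readr::write_csv(perm_tbl, out("permanova.csv"))
    out(c("pcoa_coordinates.csv", "pcoa_eigenvalues.csv", "hclust_merges.csv",
          "permanova.csv"))
  })

  run_stage("discriminate", function() {
    dsg <- state$design
    keep_samples <- dsg$sample_id[dsg$treatment %in% c("PO", "PL")]
    drop_constant <- function(x) x[, apply(x, 2, sd) > 0, drop = FALSE]
    ms <- drop_constant(t(state$scaled[, keep_samples, drop = FALSE]))
    nmr_raw <- abundance_matrix(state$nmr$concentrations) |>
      median_normalize() |>
      pareto_scale()
    nmr <- drop_constant(t(nmr_raw[, keep_samples, drop = FALSE]))
    classes <- dsg$treatment[match(keep_samples, dsg$sample_id)]
    state$model <- fit_multiblock_splsda(
      list(ms = ms, nmr = nmr), classes,
      keep_per_block = config$keep_per_block,
      n_components = config$n_components,
      design_weight = config$design_weight
    )
    state$discriminants <- rank_discriminants(state$model, 1)
    state$lfc <- log2_fold_change(cluster_abundance_matrix(state$clusters), dsg)
    readr::write_csv(state$discriminants, out("discriminant_features.csv"))
    scores <- purrr::imap_dfr(state$model$scores, function(s, block) {
      tibble::as_tibble(s, rownames = "sample_id") |>
        dplyr::mutate(block = block, .before = 1)
    })
    readr::write_csv(scores, out("splsda_scores.csv"))
    readr::write_csv(state$lfc, out("log2_fold_change.csv"))
    out(c("discriminant_features.csv", "splsda_scores.csv",
          "log2_fold_change.csv"))
  })

  run_stage("report", function() {
    results <- list(
      detection = state$detection,
      partition = state$partition,
      pcoa = state$pcoa,
      permanova = state$permanova,
      discriminants = state$discriminants,
      lfc = state$lfc
    )
    write_report(results, out("report.md"))
    out(c("report.md", "report.json"))
  })

  manifest$stages <- manifest$stages[PIPELINE_STAGES[PIPELINE_STAGES %in% names(manifest$stages)]]
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
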