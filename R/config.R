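#' Build a pipeline run configuration
#'
#' Collects every tunable of the end-to-end pipeline in one serializable
#' object. Filter thresholds default to the standard feature-detection
#' settings (100--1200 Da, 2e6 minimum intensity, S/N > 3, 5 ppm); the litter
#' end-member ratio defaults to the 52.4 at-% bulk litter enrichment.
#'
#' @param seed Root seed; per-stage seeds are derived from it (see
#'   [stage_seed()]).
#' @param outdir Output directory of [run_pipeline()].
#' @param n_species Number of synthetic molecular species.
#' @param origin_mix Origin-pool proportions for [generate_species()].
#' @param enrichment Litter per-carbon 13C probability.
#' @param enrichment_sd Between-species enrichment SD.
#' @param dynamics,noise,flux Lists of overrides for [dynamics_config()],
#'   [noise_config()], [flux_config()].
#' @param n_nmr_metabolites,nmr_labeled_fraction NMR block settings.
#' @param min_mass,max_mass,min_intensity,min_snr Feature filters.
#' @param rt_tol,mass_tol_ppm Clustering tolerances.
#' @param min_incorporation Label-call threshold.
#' @param r_litter Litter end-member atom fraction for flux partitioning.
#' @param n_permutations PERMANOVA permutations.
#' @param linkage Hierarchical clustering linkage.
#' @param keep_per_block,n_components,design_weight sPLS-DA settings.
#' @return A list of class `"siam_config"`.
#' @export
run_config <- function(seed = 1,
                       outdir = tempfile("siam_run_"),
                       n_species = 120,
                       origin_mix = c(litter = 0.35, peat_native = 0.3,
                                      microbial_product = 0.2, peat_primed = 0.15),
                       enrichment = 0.524,
                       enrichment_sd = 0,
                       dynamics = list(),
                       noise = list(),
                       flux = list(),
                       n_nmr_metabolites = 45,
                       nmr_labeled_fraction = 0.4,
                       min_mass = 100, max_mass = 1200,
                       min_intensity = 2e6, min_snr = 3,
                       rt_tol = 0.2, mass_tol_ppm = 5,
                       min_incorporation = 0.02,
                       r_litter = 0.524,
                       n_permutations = 999,
                       linkage = "average",
                       keep_per_block = c(20, 6),
                       n_components = 2,
                       design_weight = 0.1) {
  cfg <- list(
    seed = as.integer(seed), outdir = outdir, n_species = n_species,
    origin_mix = as.list(origin_mix), enrichment = enrichment,
    enrichment_sd = enrichment_sd,
    dynamics = utils::modifyList(unclass(dynamics_config()), dynamics),
    noise = utils::modifyList(unclass(noise_config()), noise),
    flux = utils::modifyList(unclass(flux_config()), flux),
    n_nmr_metabolites = n_nmr_metabolites,
    nmr_labeled_fraction = nmr_labeled_fraction,
    min_mass = min_mass, max_mass = max_mass,
    min_intensity = min_intensity, min_snr = min_snr,
    rt_tol = rt_tol, mass_tol_ppm = mass_tol_ppm,
    min_incorporation = min_incorporation,
    r_litter = r_litter, n_permutations = n_permutations,
    linkage = linkage, keep_per_block = keep_per_block,
    n_components = n_components, design_weight = design_weight
  )
  structure(cfg, class = "siam_config")
}

#' Serialize / restore a run configuration (YAML)
#'
#' Round-trips losslessly: `read_run_config(write_run_config(cfg, p))` equals
#' `cfg`.
#'
#' @param config A `"siam_config"`.
#' @param path File path.
#' @return The config (read) or `path` invisibly (write).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(run_config()), raw)
  cfg$seed <- as.integer(cfg$seed)
  cfg$keep_per_block <- as.numeric(unlist(cfg$keep_per_block))
  cfg$flux$days <- as.numeric(unlist(cfg$flux$days))
  structure(cfg, class = "siam_config")
}

PIPELINE_STAGES <- c("simulate", "filter", "detect", "partition",
                     "ordinate", "discriminate", "report")

#' Derive a per-stage seed from the root seed
#'
#' All randomness flows from the single root seed; each pipeline stage gets a
#' deterministic derived seed so stages stay reproducible when re-run in
#' isolation.
#'
#' @param root Root integer seed.
#' @param stage Stage name among `r toString(PIPELINE_STAGES)` or an integer
#'   index.
#' @return Integer seed below 2^31.
#' @export
stage_seed <- function(root, stage) {
  idx <- if (is.character(stage)) match(stage, PIPELINE_STAGES) else as.integer(stage)
  if (is.na(idx)) stop("unknown stage: ", stage)
  as.integer((as.numeric(root) * 7919 + idx * 104729) %% 2147483647)
}
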