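#' Filter an LC-MS feature table
#'
#' Applies the standard feature-detection thresholds: neutral mass within
#' \[`min_mass`, `max_mass`\] Da (inclusive on both ends), maximum per-sample
#' intensity at least `min_intensity`, and signal-to-noise strictly greater
#' than `min_snr`. Row order is preserved; an empty table is returned empty.
#'
#' @param table Feature table (tibble with `feature_id`, `neutral_mass`,
#'   `rt_min`, `snr`, then sample intensity columns).
#' @param min_mass,max_mass Mass window in Da (defaults 100 and 1200).
#' @param min_intensity Minimum of the per-feature maximum intensity
#'   (default 2e6).
#' @param min_snr Signal-to-noise threshold; features must exceed it
#'   (default 3).
#' @return The filtered feature table.
#' @export
#' @examples
#' sp <- generate_species(10, seed = 1)
#' sim <- generate_feature_table(sp, seed = 1)
#' nrow(filter_features(sim$table))
filter_features <- function(table, min_mass = 100, max_mass = 1200,
                            min_intensity = 2e6, min_snr = 3) {
  if (any(c(min_mass, max_mass, min_intensity, min_snr) < 0)) {
    stop("thresholds must be non-negative")
  }
  if (nrow(table) == 0) return(table)
  inten <- feature_intensities(table)
  max_int <- apply(inten, 1, max)
  keep <- table$neutral_mass >= min_mass & table$neutral_mass <= max_mass &
    max_int >= min_intensity & table$snr > min_snr
  table[keep, , drop = FALSE]
}

# Intensity sub-matrix of a feature table (rows = features, cols = samples).
#' @noRd
feature_intensities <- function(table) {
  meta <- c("feature_id", "neutral_mass", "rt_min", "snr")
  m <- as.matrix(table[, setdiff(names(table), meta), drop = FALSE])
  rownames(m) <- table$feature_id
  m
}
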