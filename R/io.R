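#' Render feature ids from mass and retention time
#'
#' Feature ids follow the `MW_<mass>@RT_<rt>` convention of metabolomics
#' feature exports, with 5 decimals for mass and 3 for retention time.
#'
#' @param mass Neutral monoisotopic mass in Da.
#' @param rt Retention time in minutes.
#' @return Character vector of ids.
#' @export
#' @examples
#' make_feature_id(328.22503, 37.539)
make_feature_id <- function(mass, rt) {
  sprintf("MW_%.5f@RT_%.3f", mass, rt)
}

#' Parse feature ids back into mass and retention time
#'
#' @param ids Character vector of `MW_<mass>@RT_<rt>` ids.
#' @return A tibble with `feature_id`, `mass`, `rt`.
#' @export
#' @examples
#' parse_feature_id("MW_328.22503@RT_37.539")
parse_feature_id <- function(ids) {
  m <- regmatches(ids, regexec("^MW_([0-9]+\\.?[0-9]*)@RT_([0-9]+\\.?[0-9]*)$", ids))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) {
    stop("malformed feature id(s): ",
         paste(utils::head(ids[bad], 5), collapse = ", "))
  }
  tibble::tibble(
    feature_id = ids,
    mass = vapply(m, function(x) as.numeric(x[2]), numeric(1)),
    rt = vapply(m, function(x) as.numeric(x[3]), numeric(1))
  )
}

#' Write / read the canonical feature table CSV
#'
#' Comma-separated, UTF-8, header row mandatory; columns `feature_id`,
#' `neutral_mass`, `rt_min`, `snr`, then one intensity column per sample. On
#' read, ids are parsed and cross-checked against the explicit mass/RT
#' columns; a mismatch beyond id print precision (5 decimals for mass, 3 for
#' RT) is an error, as are duplicate ids and negative intensities.
#'
#' @param table Feature table tibble.
#' @param path File path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the tibble.
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  table <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("feature_id", "neutral_mass", "rt_min", "snr")
  if (!all(needed %in% names(table))) {
    stop("feature table must have columns ", paste(needed, collapse = ", "))
  }
  if (anyDuplicated(table$feature_id)) {
    stop("duplicate feature ids: ",
         paste(unique(table$feature_id[duplicated(table$feature_id)])[1:3],
               collapse = ", "))
  }
  parsed <- parse_feature_id(table$feature_id)
  mism <- abs(parsed$mass - table$neutral_mass) > 0.6e-5 |
    abs(parsed$rt - table$rt_min) > 0.6e-3
  if (any(mism)) {
    stop("feature id / column mismatch beyond print precision in row(s): ",
         paste(utils::head(which(mism), 5), collapse = ", "))
  }
  inten <- feature_intensities(table)
  if (any(inten < 0)) stop("negative intensities in feature table")
  table
}

#' Write / read the sample metadata CSV
#'
#' @param design Sample design tibble.
#' @param path File path.
#' @return The design tibble (read) or `path` invisibly (write).
#' @export
write_metadata <- function(design, path) {
  readr::write_csv(design, path)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  design <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_design(design)
  design
}

#' Write / read the CO2 flux observation CSV
#'
#' Columns `jar_id`, `treatment`, `label_status`, `day`, `f_net`, `r_net`,
#' with the flux unit carried in a `#`-comment header line and never silently
#' converted.
#'
#' @param observations Flux observation tibble.
#' @param path File path.
#' @param unit Flux unit string recorded in the header.
#' @return The observations tibble (read; the unit is in attribute `unit`)
#'   or `path` invisibly (write).
#' @export
write_flux_table <- function(observations, path,
                             unit = "umol CO2 g-1 dry peat d-1") {
  writeLines(paste0("# unit: ", unit), path)
  readr::write_csv(observations, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_flux_table
#' @export
read_flux_table <- function(path) {
  first <- readLines(path, n = 1)
  unit <- sub("^# unit: ", "", first)
  obs <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  stopifnot(all(c("jar_id", "treatment", "label_status", "day",
                  "f_net", "r_net") %in% names(obs)))
  if (any(obs$f_net < 0) || any(obs$r_net < 0 | obs$r_net > 1)) {
    stop("flux table violates f_net >= 0 or 0 <= r_net <= 1")
  }
  attr(obs, "unit") <- unit
  obs
}
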