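TIMEPOINT_DAYS <- c(T0 = 0, T1 = 7, T2 = 18, T3 = 40)

#' Map incubation timepoint labels to days
#'
#' Timepoints T0--T3 correspond to incubation days 0, 7, 18 and 40; this codec
#' is the single place where that mapping lives.
#'
#' @param timepoint Character vector of labels among `"T0".."T3"`.
#' @return Integer vector of days since the start of the incubation.
#' @export
#' @examples
#' timepoint_to_day(c("T0", "T1", "T3"))
timepoint_to_day <- function(timepoint) {
  bad <- setdiff(unique(timepoint), names(TIMEPOINT_DAYS))
  if (length(bad) > 0) {
    stop("unknown timepoint label(s): ", paste(bad, collapse = ", "))
  }
  unname(TIMEPOINT_DAYS[timepoint])
}

#' Build the incubation sample design
#'
#' Constructs the sample metadata table for a litter-amendment incubation:
#' litter-only (LO) jars exist only at T0, peat-only (PO) jars are never
#' isotopically labeled, and peat+litter (PL) jars run through all timepoints.
#' Each treatment x timepoint combination carries `replicates` jars; for LO
#' and PL the replicate pair is one labeled and one unlabeled jar (labeled and
#' unlabeled amendments are treated as analytical replicates downstream,
#' because 13C substitution does not alter chemistry).
#'
#' @param replicates Jars per treatment x timepoint x label status
#'   (default 2).
#' @param timepoints Timepoint labels to include for PO/PL.
#' @return A tibble with columns `sample_id`, `treatment`, `label_status`,
#'   `timepoint`, `day`, `replicate`. With the defaults: 4 LO samples at T0,
#'   2 PO and 4 PL samples per timepoint (labeled and unlabeled amendments
#'   each in duplicate), 28 samples in all.
#' @export
#' @examples
#' sample_design()
sample_design <- function(replicates = 2, timepoints = c("T0", "T1", "T2", "T3")) {
  stopifnot(replicates >= 1, all(timepoints %in% names(TIMEPOINT_DAYS)))
  grid <- dplyr::bind_rows(
    tidyr::expand_grid(treatment = "LO", timepoint = intersect("T0", timepoints),
                       label_status = c("labeled", "unlabeled"),
                       replicate = seq_len(replicates)),
    tidyr::expand_grid(treatment = "PO", timepoint = timepoints,
                       label_status = "unlabeled",
                       replicate = seq_len(replicates)),
    tidyr::expand_grid(treatment = "PL", timepoint = timepoints,
                       label_status = c("labeled", "unlabeled"),
                       replicate = seq_len(replicates))
  )
  grid |>
    dplyr::mutate(
      day = timepoint_to_day(.data$timepoint),
      sample_id = sprintf("%s_%s_%s_R%d", .data$treatment, .data$timepoint,
                          dplyr::if_else(.data$label_status == "labeled", "lab", "unl"),
                          .data$replicate)
    ) |>
    dplyr::select("sample_id", "treatment", "label_status", "timepoint",
                  "day", "replicate") |>
    dplyr::arrange(.data$treatment, .data$timepoint, .data$label_status,
                   .data$replicate)
}

# Validate a design tibble against the structural invariants.
#' @noRd
check_design <- function(design) {
  stopifnot(is.data.frame(design), nrow(design) > 0)
  needed <- c("sample_id", "treatment", "label_status", "timepoint", "day")
  missing <- setdiff(needed, names(design))
  if (length(missing) > 0) {
    stop("design is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(design$sample_id)) stop("duplicate sample_id in design")
  if (any(design$treatment == "LO" & design$timepoint != "T0")) {
    stop("LO samples may exist only at T0")
  }
  if (any(design$treatment == "PO" & design$label_status != "unlabeled")) {
    stop("PO samples must be unlabeled")
  }
  invisible(design)
}
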