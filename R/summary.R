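#' Round half-up
#'
#' Rounds halves away from zero (the convention used when reporting detection
#' percentages), unlike base [round()] which rounds halves to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
#' @examples
#' round_half_up(32.1875, 2) # 32.19
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

#' Summarize feature detection and annotation counts
#'
#' Produces the per-category counts and percentages of a detection run, each
#' percentage computed as `100 * count / n_features_total` and rounded half-up
#' to 2 decimals.
#'
#' @param clusters Analyzed cluster table from [analyze_clusters()], or NULL
#'   when supplying counts directly.
#' @param annotation_counts Named integer vector of additional category counts
#'   (annotation categories are pass-through labels supplied by the caller).
#' @param n_features_total Total feature count; defaults to the number of
#'   features across all clusters.
#' @param n_labeled Number of labeled features; defaults to the number of
#'   features in clusters with a positive label call.
#' @return A tibble with columns `category`, `count`, `pct`.
#' @export
#' @examples
#' summarize_detection(n_features_total = 320, n_labeled = 164,
#'                     annotation_counts = c(annotated = 103))
summarize_detection <- function(clusters = NULL, annotation_counts = integer(),
                                n_features_total = NULL, n_labeled = NULL) {
  if (!is.null(clusters)) {
    if (is.null(n_features_total)) n_features_total <- sum(clusters$n_members)
    if (is.null(n_labeled)) n_labeled <- sum(clusters$n_members[clusters$label_call])
  }
  if (is.null(n_features_total) || n_features_total == 0) {
    stop("n_features_total must be a positive count")
  }
  counts <- c(labeled = as.integer(n_labeled), annotation_counts)
  if (any(counts > n_features_total)) {
    stop("category counts cannot exceed n_features_total")
  }
  tibble::tibble(
    category = c("total", names(counts)),
    count = c(n_features_total, unname(counts)),
    pct = round_half_up(100 * c(n_features_total, unname(counts)) / n_features_total, 2)
  )
}
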