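#' Write the human-readable summary report and its JSON twin
#'
#' Renders a markdown-style text document with one section per pipeline
#' stage (detection summary, flux partition and priming, ordination,
#' PERMANOVA, discriminant features, fold changes); stages absent from
#' `results` are marked "not run". A machine-readable JSON twin with the same
#' content is written next to it.
#'
#' @param results Named list with any of `detection`, `partition`, `pcoa`,
#'   `permanova`, `discriminants`, `lfc`.
#' @param path Path of the markdown report; the JSON twin replaces the
#'   extension with `.json`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  if (length(results) == 0 || all(vapply(results, is.null, logical(1)))) {
    stop("at least one stage's results must be present")
  }
  lines <- c("# SIAM pipeline report", "")
  json <- list()

  fmt_tbl <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) formatC(x, format = "g", digits = 6))
    header <- paste(names(df), collapse = " | ")
    sep <- paste(rep("---", ncol(df)), collapse = " | ")
    rows <- apply(df, 1, paste, collapse = " | ")
    c(paste("|", header, "|"), paste("|", sep, "|"), paste("|", rows, "|"))
  }

  section <- function(title, content) {
    lines <<- c(lines, paste("##", title), "", content, "")
  }

  if (!is.null(results$detection)) {
    det <- results$detection |>
      dplyr::mutate(pct = sprintf("%.2f", .data$pct))
    section("Detection summary", fmt_tbl(det))
    json$detection <- results$detection
  } else section("Detection summary", "not run")

  if (!is.null(results$partition)) {
    section("Flux partition (per jar-day)", fmt_tbl(results$partition$per_day))
    section("Cumulative fluxes", fmt_tbl(results$partition$cumulative))
    json$partition <- list(per_day = results$partition$per_day,
                           cumulative = results$partition$cumulative)
  } else section("Flux partition", "not run")

  if (!is.null(results$pcoa)) {
    coords <- tibble::as_tibble(results$pcoa$coordinates, rownames = "sample_id")
    keep <- c("sample_id", utils::head(setdiff(names(coords), "sample_id"), 2))
    section("Ordination (PCoA, first two axes)", fmt_tbl(coords[, keep]))
    json$pcoa <- list(
      coordinates = coords,
      prop_var = results$pcoa$prop_var,
      eigenvalues = results$pcoa$eigenvalues
    )
  } else section("Ordination", "not run")

  if (!is.null(results$permanova)) {
    perm <- purrr::map_dfr(results$permanova, function(p) {
      tibble::tibble(factor = p$factor_name, pseudo_f = p$pseudo_f,
                     p_value = p$p_value, n_permutations = p$n_permutations)
    })
    section("PERMANOVA", fmt_tbl(perm))
    json$permanova <- perm
  } else section("PERMANOVA", "not run")

  if (!is.null(results$discriminants)) {
    section("Discriminant features (component 1)", fmt_tbl(results$discriminants))
    json$discriminants <- results$discriminants
  } else section("Discriminant features", "not run")

  if (!is.null(results$lfc)) {
    section("Log2 fold changes vs PO at T0 (head)",
            fmt_tbl(utils::head(results$lfc, 20)))
    json$lfc <- results$lfc
  } else section("Log2 fold changes", "not run")

  writeLines(lines, path)
  jsonlite::write_json(json, sub("\\.[a-z]+$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
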