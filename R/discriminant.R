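#' Fit a multiblock sparse PLS-DA across data blocks
#'
#' Couples several abundance blocks (e.g. LC-MS features and NMR metabolite
#' concentrations measured on the same samples) to a binary class outcome in
#' an N-integration framework: classes are dummy-coded as an outcome block,
#' each data block's loading vectors are updated to maximize covariance with
#' the outcome scores plus `design_weight` times the covariance with the
#' other data blocks' scores, sparsity keeps only the `keep_per_block`
#' largest-magnitude loadings per component, and blocks are deflated by
#' regression on their own scores between components. Backed by
#' [mixOmics::block.splsda()]; blocks are centered and unit-variance scaled
#' internally, and initialization is the leading singular vector of each
#' block's cross-covariance with the outcome, so the fit is deterministic.
#'
#' @param blocks Named list of matrices, samples x features, sharing row
#'   (sample) order.
#' @param classes Binary class labels (e.g. `"PO"`/`"PL"`), one per sample;
#'   each class needs at least 2 samples.
#' @param keep_per_block Integer vector (one per block) of features retained
#'   per component (default `c(20, 6)` for an MS + NMR pair).
#' @param n_components Number of components (default 2).
#' @param design_weight Coupling between data blocks in \[0, 1\]; the coupling
#'   to the outcome block is fixed at 1 (default 0.1).
#' @param max_iter,tol Convergence controls of the iterative update.
#' @return An object of class `"siam_splsda"`: list with `loadings` and
#'   `scores` per block per component, `keep_per_block`, `explained_variance`
#'   (block-wise redundancy), `classes`, `design_weight`, and the underlying
#'   `fit`.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 10); colnames(x) <- paste0("f", 1:20)
#' y <- rep(c("PO", "PL"), each = 5)
#' x[y == "PL", 1:3] <- x[y == "PL", 1:3] + 3
#' m <- fit_multiblock_splsda(list(ms = x), y, keep_per_block = 3,
#'                            n_components = 1)
#' rank_discriminants(m, 1)
fit_multiblock_splsda <- function(blocks, classes,
                                  keep_per_block = c(20, 6),
                                  n_components = 2,
                                  design_weight = 0.1,
                                  max_iter = 100, tol = 1e-6) {
  stopifnot(is.list(blocks), length(blocks) >= 1)
  if (is.null(names(blocks))) names(blocks) <- paste0("block", seq_along(blocks))
  n <- nrow(blocks[[1]])
  if (!all(vapply(blocks, nrow, integer(1)) == n)) {
    stop("all blocks must share the same samples")
  }
  classes <- factor(classes)
  if (nlevels(classes) != 2) stop("classes must be binary")
  if (any(table(classes) < 2)) stop("degenerate design: a class has < 2 samples")
  if (length(keep_per_block) == 1) {
    keep_per_block <- rep(keep_per_block, length(blocks))
  }
  stopifnot(length(keep_per_block) == length(blocks), all(keep_per_block >= 1))

  keepX <- lapply(seq_along(blocks), function(b) {
    rep(min(keep_per_block[b], ncol(blocks[[b]])), n_components)
  })
  names(keepX) <- names(blocks)
  design <- matrix(design_weight, length(blocks), length(blocks))
  diag(design) <- 0

  zero_var <- lapply(blocks, function(b) apply(b, 2, sd) == 0)
  if (any(unlist(zero_var))) {
    stop("zero-variance feature(s) in block(s) ",
         paste(names(blocks)[vapply(zero_var, any, logical(1))], collapse = ", "),
         "; drop constant features before fitting")
  }
  fit <- suppressMessages(mixOmics::block.splsda(
    X = blocks, Y = classes, ncomp = n_components, keepX = keepX,
    design = design, max.iter = max_iter, tol = tol, near.zero.var = FALSE
  ))

  data_blocks <- names(blocks)
  structure(
    list(loadings = fit$loadings[data_blocks],
         scores = fit$variates[data_blocks],
         keep_per_block = setNames(keep_per_block, data_blocks),
         explained_variance = lapply(fit$prop_expl_var[data_blocks], unname),
         classes = classes,
         design_weight = design_weight,
         n_components = n_components,
         fit = fit),
    class = "siam_splsda"
  )
}

#' Rank discriminant features of a fitted model
#'
#' Collects the nonzero loadings of one component across all data blocks and
#' orders them by absolute loading, descending; ties break alphabetically by
#' feature id so the ranking is deterministic and invariant to block order.
#'
#' @param model A `"siam_splsda"` fit.
#' @param component Component index.
#' @return A tibble `feature_id`, `block`, `loading`, ordered by
#'   `abs(loading)` descending.
#' @export
rank_discriminants <- function(model, component = 1) {
  if (component < 1 || component > model$n_components) {
    stop("component out of range")
  }
  purrr::imap_dfr(model$loadings, function(L, block) {
    v <- L[, component]
    keep <- v != 0
    tibble::tibble(feature_id = rownames(L)[keep], block = block,
                   loading = unname(v[keep]))
  }) |>
    dplyr::arrange(dplyr::desc(abs(.data$loading)), .data$feature_id)
}

#' Log2 fold-change trajectories relative to a reference group
#'
#' Expresses each feature's mean abundance per treatment x timepoint as a
#' log2 fold change relative to its mean in the reference group (peat-only at
#' T0 by default). A pseudocount of half the smallest nonzero value in the
#' matrix keeps ratios defined at true zeros.
#'
#' @param m Abundance matrix (features x samples), raw scale.
#' @param design Sample design matching the columns of `m`.
#' @param ref_treatment,ref_timepoint Reference group (defaults PO at T0).
#' @param pseudocount Added to numerator and denominator means; default
#'   `NULL` = half the smallest nonzero value of `m`.
#' @return A tibble `feature_id`, `treatment`, `timepoint`, `log2fc` (one row
#'   per feature x group x timepoint), with the reference definition in
#'   attributes.
#' @export
log2_fold_change <- function(m, design, ref_treatment = "PO",
                             ref_timepoint = "T0", pseudocount = NULL) {
  design <- design[match(colnames(m), design$sample_id), ]
  if (anyNA(design$sample_id)) stop("design does not cover all samples")
  ref_cols <- design$treatment == ref_treatment & design$timepoint == ref_timepoint
  if (!any(ref_cols)) stop("reference group is empty")
  if (is.null(pseudocount)) {
    nz <- m[m > 0]
    pseudocount <- if (length(nz) > 0) min(nz) / 2 else 0
  }
  ref_mean <- rowMeans(m[, ref_cols, drop = FALSE])
  if (pseudocount == 0 && any(ref_mean == 0)) {
    stop("undefined ratio: zero reference mean with zero pseudocount")
  }
  groups <- unique(design[, c("treatment", "timepoint")])
  out <- purrr::pmap_dfr(groups, function(treatment, timepoint) {
    cols <- design$treatment == treatment & design$timepoint == timepoint
    gm <- rowMeans(m[, cols, drop = FALSE])
    tibble::tibble(
      feature_id = rownames(m), treatment = treatment, timepoint = timepoint,
      log2fc = log2((gm + pseudocount) / (ref_mean + pseudocount))
    )
  })
  attr(out, "reference") <- list(treatment = ref_treatment,
                                 timepoint = ref_timepoint,
                                 pseudocount = pseudocount)
  out
}
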