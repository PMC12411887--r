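#' Extract a features x samples abundance matrix from a table
#'
#' Drops the identifier and feature-metadata columns (`neutral_mass`,
#' `rt_min`, `snr`, `mass`) and returns the numeric intensity block as a
#' matrix in `raw` normalization state, rows named by the identifier column.
#'
#' @param table Feature or metabolite table (first column = identifier).
#' @return Numeric matrix (features x samples) with attribute `norm_state`.
#' @export
abundance_matrix <- function(table) {
  meta <- intersect(names(table), c("neutral_mass", "rt_min", "snr", "mass"))
  m <- as.matrix(table[, setdiff(names(table)[-1], meta), drop = FALSE])
  rownames(m) <- table[[1]]
  if (any(m < 0)) stop("raw abundances must be non-negative")
  attr(m, "norm_state") <- "raw"
  m
}

# Internal: check/advance normalization state raw -> median_normalized -> pareto_scaled
#' @noRd
norm_state <- function(m) attr(m, "norm_state") %||% "raw"

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Median-normalize samples
#'
#' Divides each sample (column) by the median of its nonzero values, then
#' multiplies by the grand median of those per-sample medians so the matrix
#' keeps its original scale. Zeros are kept as true zeros (absence below
#' detection is not imputed).
#'
#' @param m Raw abundance matrix (features x samples).
#' @return Matrix in `median_normalized` state.
#' @export
median_normalize <- function(m) {
  if (norm_state(m) != "raw") stop("median_normalize expects a raw matrix")
  meds <- apply(m, 2, function(x) {
    nz <- x[x > 0]
    if (length(nz) == 0) return(NA_real_)
    median(nz)
  })
  if (any(is.na(meds))) {
    stop("degenerate sample(s) with all-zero abundances: ",
         paste(colnames(m)[is.na(meds)], collapse = ", "))
  }
  out <- sweep(m, 2, meds, "/") * median(meds)
  attr(out, "norm_state") <- "median_normalized"
  out
}

#' Pareto-scale features
#'
#' Centers each feature (row) and divides by the square root of its sample
#' standard deviation (n - 1 denominator). Pareto scaling shrinks dynamic
#' range less aggressively than unit-variance scaling, keeping some weight on
#' high-abundance features. Constant features map to all zeros.
#'
#' @param m Median-normalized abundance matrix.
#' @return Matrix in `pareto_scaled` state (may contain negatives).
#' @export
pareto_scale <- function(m) {
  if (norm_state(m) != "median_normalized") {
    stop("pareto_scale expects a median-normalized matrix")
  }
  ctr <- m - rowMeans(m)
  s <- apply(m, 1, sd)
  scl <- ifelse(s > 0, sqrt(s), 1) # constant rows stay centered at 0
  out <- ctr / scl
  attr(out, "norm_state") <- "pareto_scaled"
  out
}

#' Manhattan distances between samples
#'
#' `D[i, j] = sum_f |x_fi - x_fj]` over the feature rows.
#'
#' @param m Abundance matrix (features x samples), any normalization state.
#' @return A `dist` object over samples.
#' @export
manhattan_distance <- function(m) {
  dist(t(m), method = "manhattan")
}

#' Principal coordinate analysis
#'
#' Classical metric scaling of a distance matrix: Gower double-centering of
#' -D^2/2 followed by eigendecomposition; coordinates are eigenvectors scaled
#' by the square roots of the positive eigenvalues. Negative eigenvalues
#' (possible for non-Euclidean distances such as Manhattan) are reported but
#' excluded from the variance proportions; no Cailliez correction is applied.
#'
#' @param d A `dist` object or symmetric zero-diagonal matrix.
#' @return An object of class `"siam_pcoa"`: list with `coordinates` (samples
#'   x axes), `eigenvalues` (all, decreasing), `prop_var` (over positive
#'   eigenvalues), `method`.
#' @export
#' @examples
#' x <- matrix(rnorm(20), 5)
#' p <- pcoa(dist(x))
#' p$prop_var
pcoa <- function(d) {
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (!isSymmetric(unname(m)) || any(diag(m) != 0)) {
      stop("input must be a symmetric, zero-diagonal distance matrix")
    }
    d <- stats::as.dist(m)
  }
  n <- attr(d, "Size")
  fit <- cmdscale(d, k = n - 1, eig = TRUE)
  eig <- fit$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig))
  coords <- fit$points[, seq_len(sum(pos)), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(
    list(coordinates = coords,
         eigenvalues = eig,
         prop_var = eig[pos] / sum(eig[pos]),
         method = "pcoa"),
    class = "siam_pcoa"
  )
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of a sample distance matrix; the linkage default
#' is average (UPGMA). Ties in merge heights follow [stats::hclust()]'s
#' deterministic lowest-index order.
#'
#' @param d A `dist` object over samples.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return An `hclust` object (merge list with heights).
#' @export
hierarchical_cluster <- function(d, linkage = "average") {
  if (attr(d, "Size") < 2) stop("need at least 2 samples to cluster")
  hclust(d, method = linkage)
}

#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: the pseudo-F statistic is
#' computed from among- and within-group sums of squared distances
#' (Anderson's distance-based formulation, via [vegan::adonis2()]), and the
#' p-value from random permutations of the group labels with the add-one
#' estimator `p = (1 + #(F_perm >= F_obs)) / (1 + n_permutations)`, so p is
#' never exactly 0.
#'
#' @param d A `dist` object over samples.
#' @param groups Factor (or coercible) of group labels, one per sample.
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Optional integer seed for reproducible permutations.
#' @param factor_name Name recorded for the grouping factor.
#' @return An object of class `"siam_permanova"`: list with `pseudo_f`,
#'   `p_value`, `n_permutations`, `seed`, `factor_name`, `df`.
#' @export
#' @examples
#' x <- matrix(rnorm(40), 4, 10)
#' permanova(dist(t(x), "manhattan"), c("a", "a", "b", "b"),
#'           n_permutations = 99, seed = 1)$p_value
permanova <- function(d, groups, n_permutations = 999, seed = NULL,
                      factor_name = deparse(substitute(groups))) {
  groups <- factor(groups)
  n <- attr(d, "Size")
  if (length(groups) != n) stop("groups length must match the distance matrix")
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  fit <- with_seed_if(seed, {
    vegan::adonis2(d ~ groups, permutations = n_permutations)
  })
  structure(
    list(pseudo_f = fit$F[1],
         p_value = fit$`Pr(>F)`[1],
         n_permutations = n_permutations,
         seed = seed,
         factor_name = factor_name,
         df = fit$Df[1]),
    class = "siam_permanova"
  )
}
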