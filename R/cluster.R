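#' Group features into isotopologue clusters
#'
#' In a SIAM experiment the labeled isotopologues of a compound co-elute with
#' their unlabeled counterpart and sit at exact mass shifts of k * 1.0033548
#' Da (the 13C-12C mass difference). Clustering is greedy agglomeration:
#' features are scanned in increasing mass order; the lowest-mass unassigned
#' feature seeds a cluster (its k = 0 candidate), and every unassigned feature
#' whose retention time lies within `rt_tol` of the seed and whose mass
#' difference is within `mass_tol_ppm` (relative to the feature's mass) of an
#' integer multiple k * 1.0033548, 1 <= k <= `max_k`, is attached at that k.
#' If several k values are compatible the one with the smallest ppm error
#' wins; each feature joins at most one cluster; features matching nothing
#' become singleton (k = 0 only) clusters.
#'
#' @param table Filtered feature table.
#' @param rt_tol Retention-time pairing window in minutes (default 0.2, tight
#'   relative to a 70-min gradient).
#' @param mass_tol_ppm Mass tolerance in ppm (default 5).
#' @param max_k Largest heavy-atom shift considered (default 60, generous for
#'   masses up to 1200 Da).
#' @return A tibble with one row per cluster: `cluster_id`,
#'   `base_feature_id`, `n_members`, a `members` list-column of tibbles
#'   (`feature_id`, `k`, `neutral_mass`, `rt_min`, `intensity` summed over
#'   samples), and a `sample_intensities` list-column of members x samples
#'   matrices.
#' @export
#' @examples
#' sp <- generate_species(5, seed = 1)
#' sim <- generate_feature_table(sp, seed = 1)
#' cl <- cluster_isotopologues(filter_features(sim$table))
#' cl$n_members
cluster_isotopologues <- function(table, rt_tol = 0.2, mass_tol_ppm = 5,
                                  max_k = 60) {
  if (rt_tol <= 0) stop("rt_tol must be > 0")
  if (nrow(table) == 0) stop("empty feature set")
  ord <- order(table$neutral_mass)
  mass <- table$neutral_mass[ord]
  rt <- table$rt_min[ord]
  ids <- table$feature_id[ord]
  inten <- feature_intensities(table)[ord, , drop = FALSE]
  total_int <- rowSums(inten)

  n <- length(mass)
  assigned <- rep(FALSE, n)
  clusters <- vector("list", n)
  n_cl <- 0
  for (i in seq_len(n)) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    member_idx <- i
    member_k <- 0L
    cand <- which(!assigned & abs(rt - rt[i]) <= rt_tol & mass > mass[i])
    for (j in cand) {
      dm <- mass[j] - mass[i]
      k <- round(dm / C13_MASS_SHIFT)
      if (k < 1 || k > max_k) next
      err <- abs(dm - k * C13_MASS_SHIFT)
      if (err <= mass_tol_ppm * 1e-6 * mass[j]) {
        # k already distinct by construction? two features can land on the
        # same k (duplicate isotopologue); keep the first (lower mass error
        # order is scan order) and leave the other to seed its own cluster
        if (k %in% member_k) next
        member_idx <- c(member_idx, j)
        member_k <- c(member_k, as.integer(k))
        assigned[j] <- TRUE
      }
    }
    n_cl <- n_cl + 1
    clusters[[n_cl]] <- list(
      members = tibble::tibble(
        feature_id = ids[member_idx], k = member_k,
        neutral_mass = mass[member_idx], rt_min = rt[member_idx],
        intensity = total_int[member_idx]
      ),
      sample_intensities = inten[member_idx, , drop = FALSE]
    )
  }
  clusters <- clusters[seq_len(n_cl)]
  tibble::tibble(
    cluster_id = sprintf("cl%04d", seq_len(n_cl)),
    base_feature_id = vapply(clusters, function(cl) cl$members$feature_id[1],
                             character(1)),
    n_members = vapply(clusters, function(cl) nrow(cl$members), integer(1)),
    members = lapply(clusters, `[[`, "members"),
    sample_intensities = lapply(clusters, `[[`, "sample_intensities")
  )
}
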