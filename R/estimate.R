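#' Estimate the carbon count of an isotopologue cluster
#'
#' Grid-searches integer carbon counts chemically consistent with the neutral
#' mass (between mass/30 and mass/12 carbons; the observed largest heavy-atom
#' shift imposes a hard lower bound). For each candidate the observed envelope
#' is natural-abundance corrected and the residual of the best-fitting
#' binomial envelope (uniform labeling at the envelope-mean probability) is
#' computed; the candidate with the smallest residual wins, with ties broken
#' toward the smallest carbon count. A raw deconvolution residual cannot
#' discriminate carbon counts (any count at least as large as the observed
#' maximum shift fits the data), so identifiability comes from the binomial
#' shape constraint of the uniform-labeling model.
#'
#' @param f_obs Observed envelope proportions over k = 0.. (gaps as 0).
#' @param mass Neutral monoisotopic mass of the base (k = 0) feature, in Da.
#' @param p_nat Natural 13C abundance.
#' @return Integer carbon count estimate.
#' @export
#' @examples
#' env <- binomial_envelope(6, 0.524)
#' estimate_n_carbon(forward_convolve(env, 6) , 180.063)
estimate_n_carbon <- function(f_obs, mass, p_nat = 0.0107) {
  if (mass <= 0) stop("mass must be > 0")
  hi <- floor(mass / 12)
  if (hi < 1) stop("mass below one carbon (non-organic mass)")
  max_k_obs <- max(c(0L, which(f_obs > 0) - 1L))
  f_obs <- f_obs[seq_len(max_k_obs + 1)] # drop trailing zero padding
  lo <- max(1L, floor(mass / 30), max_k_obs)
  if (lo > hi) {
    stop("observed heavy-atom shifts exceed the carbon capacity of mass ", mass)
  }
  f_obs <- f_obs / sum(f_obs)
  best_nc <- lo
  best_res <- Inf
  for (nc in lo:hi) {
    f_corr <- natural_abundance_correct(pad_envelope(f_obs, nc), nc, p_nat)
    p_hat <- sum((0:nc) * f_corr) / nc
    res <- sum((f_corr - dbinom(0:nc, nc, p_hat))^2)
    if (res < best_res - 1e-12) {
      best_res <- res
      best_nc <- nc
    }
  }
  as.integer(best_nc)
}

#' Fractional 13C enrichment of a corrected envelope
#'
#' The mean heavy-atom count of the tracer-only envelope divided by the
#' carbon count, in atom percent: `100 * sum(k * f_corr_k) / n_carbon`.
#'
#' @param f_corr Corrected envelope proportions (sum to 1).
#' @param n_carbon Carbon count (>= 1).
#' @return Enrichment in atom percent, in \[0, 100\].
#' @export
#' @examples
#' estimate_enrichment(binomial_envelope(6, 0.5), 6) # 50
estimate_enrichment <- function(f_corr, n_carbon) {
  if (n_carbon < 1) stop("n_carbon must be >= 1")
  if (abs(sum(f_corr) - 1) > 1e-6) stop("f_corr must sum to 1")
  100 * sum((seq_along(f_corr) - 1) * f_corr) / n_carbon
}

#' Classify a cluster as isotopically labeled
#'
#' The diagnostic ratio is the corrected envelope mass above k = 0 (the
#' fraction of molecules carrying at least one tracer atom). A cluster is
#' called labeled when that ratio reaches `min_incorporation` and the cluster
#' has at least two members (a lone feature carries no envelope evidence).
#'
#' @param f_corr Corrected envelope proportions.
#' @param n_members Number of features in the cluster.
#' @param min_incorporation Minimum excess heavy fraction (default 0.02).
#' @return A list with `label_call` (logical) and `diagnostic_ratio`.
#' @export
classify_labeled <- function(f_corr, n_members, min_incorporation = 0.02) {
  ratio <- sum(f_corr[-1])
  list(label_call = ratio >= min_incorporation && n_members >= 2,
       diagnostic_ratio = ratio)
}

#' Compound-level abundance matrix from isotopologue clusters
#'
#' Sums the member isotopologue intensities of each cluster per sample,
#' giving one abundance row per compound. At the compound level, labeled and
#' unlabeled jars are true analytical replicates (the tracer only
#' redistributes intensity across a compound's isotopologues), so this is
#' the matrix the multivariate and discriminant stages should see.
#'
#' @param clusters Cluster table from [cluster_isotopologues()].
#' @return Numeric matrix (clusters x samples), rows named by `cluster_id`,
#'   in `raw` normalization state.
#' @export
cluster_abundance_matrix <- function(clusters) {
  m <- do.call(rbind, lapply(clusters$sample_intensities, colSums))
  rownames(m) <- clusters$cluster_id
  attr(m, "norm_state") <- "raw"
  m
}

# Least-squares fit of a pure natural-abundance envelope to the observed
# isotopologue proportions, over a carbon-count grid. Both model and data are
# restricted to the observed k support and renormalized, so truncation of the
# high-k tail by the intensity threshold does not bias the fit.
#' @noRd
fit_natural_envelope <- function(ks, f_at_ks, nc_max, p_nat) {
  f <- f_at_ks / sum(f_at_ks)
  lo <- max(1L, max(ks))
  best_nc <- lo; best_sse <- Inf
  for (nc in lo:max(lo, nc_max)) {
    b <- dbinom(ks, nc, p_nat)
    s <- sum(b)
    if (s <= 0) next
    sse <- sum((f - b / s)^2)
    if (sse < best_sse - 1e-15) {
      best_sse <- sse
      best_nc <- nc
    }
  }
  list(nc = best_nc, rel_resid = sqrt(best_sse) / sqrt(sum(f^2)))
}

#' Run the full isotopologue analysis on clustered features
#'
#' For each cluster: assemble the observed envelope, estimate the carbon
#' count, correct for natural abundance, estimate fractional enrichment, and
#' classify the label call. The envelope (proportions over k, missing k
#' filled with 0) is the renormalized per-k median of the per-sample envelope
#' proportions across samples where the cluster is present -- the median
#' makes the envelope robust to sporadic missing cells, which would otherwise
#' distort an intensity-summed envelope whenever a high-abundance sample
#' loses one isotopologue.
#'
#' @param clusters Cluster table from [cluster_isotopologues()].
#' @param p_nat Natural 13C abundance.
#' @param min_incorporation Label-call threshold, see [classify_labeled()].
#' @return The cluster table with added columns `n_carbon_est`,
#'   `enrichment_at_pct`, `diagnostic_ratio`, `label_call`, and list-columns
#'   `f_obs` and `f_corr`.
#' @export
#' @examples
#' sp <- generate_species(5, seed = 1)
#' sim <- generate_feature_table(sp, seed = 1)
#' cl <- cluster_isotopologues(filter_features(sim$table))
#' analyze_clusters(cl)[, c("cluster_id", "n_members", "label_call")]
analyze_clusters <- function(clusters, p_nat = 0.0107, min_incorporation = 0.02) {
  sample_ints <- clusters$sample_intensities %||%
    lapply(clusters$members, function(m) matrix(m$intensity, ncol = 1))
  res <- purrr::map2(clusters$members, sample_ints, function(m, si) {
    max_k <- max(m$k)
    f_obs <- rep(0, max_k + 1)
    # complete samples: cluster present and no member lost to missingness
    # (missing = zero cell); their envelope proportions average cleanly,
    # whereas one zeroed cell in a high-abundance sample would distort an
    # intensity-summed envelope
    complete <- colSums(si > 0) == nrow(si)
    present <- colSums(si) > 0
    if (sum(complete) >= 2) {
      props <- sweep(si[, complete, drop = FALSE], 2,
                     colSums(si[, complete, drop = FALSE]), "/")
      f_obs[m$k + 1] <- rowMeans(props)
    } else if (sum(present) >= 2) {
      props <- sweep(si[, present, drop = FALSE], 2,
                     colSums(si[, present, drop = FALSE]), "/")
      f_obs[m$k + 1] <- apply(props, 1, median)
    } else {
      f_obs[m$k + 1] <- m$intensity
    }
    if (sum(f_obs) == 0) f_obs[m$k + 1] <- m$intensity
    f_obs <- f_obs / sum(f_obs)
    mass <- m$neutral_mass[m$k == 0][1]
    lo <- max(1L, floor(mass / 30)); hi <- max(lo, floor(mass / 12))
    if (nrow(m) >= 2) {
      # Natural hypothesis first: for an unlabeled envelope only the heavy
      # load nc * p_nat is identifiable (Poisson limit), so the corrected-
      # envelope grid residual cannot pin nc down. Fit the natural envelope
      # over the observed isotopologue support (restricted and renormalized,
      # which makes the fit robust to intensity-threshold truncation of the
      # tail): if the best-fitting natural carbon count is chemically
      # admissible -- with an allowance for fit noise near the cap, since
      # tracer levels the allowance could absorb sit below the 2% call
      # threshold anyway -- and the fit is good, the envelope is corrected
      # at that count; otherwise the heavy excess is beyond anything natural
      # and the carbon count comes from the labeled envelope shape.
      nat <- fit_natural_envelope(m$k, f_obs[m$k + 1], ceiling(1.2 * hi) + 2, p_nat)
      if (nat$nc <= ceiling(1.2 * hi) + 1 && nat$rel_resid <= 0.15) {
        # within the fit uncertainty, prefer the count that explains the
        # most envelope mass as natural (parsimony: least residual tracer)
        cand <- unique(pmax(max_k, max(1L, nat$nc) + (-4:4)))
        left <- vapply(cand, function(ncc) {
          fc <- natural_abundance_correct(pad_envelope(f_obs, ncc), ncc, p_nat)
          sum(fc[-1])
        }, numeric(1))
        nc_corr <- as.integer(cand[which.min(left)])
        nc <- as.integer(min(hi, max(lo, max_k, nc_corr)))
      } else {
        nc <- estimate_n_carbon(f_obs, mass, p_nat)
        nc_corr <- nc
      }
    } else {
      # no envelope to fit; chemically central guess, only used for reporting
      nc <- max(1L, as.integer(round(mass / 21)))
      nc_corr <- nc
    }
    f_corr <- natural_abundance_correct(pad_envelope(f_obs, nc_corr), nc_corr, p_nat)
    f_corr <- f_corr[seq_len(min(length(f_corr), nc + 1))]
    f_corr <- f_corr / sum(f_corr)
    cls <- classify_labeled(f_corr, nrow(m), min_incorporation)
    tibble::tibble(
      n_carbon_est = nc,
      enrichment_at_pct = estimate_enrichment(f_corr, nc),
      diagnostic_ratio = cls$diagnostic_ratio,
      label_call = cls$label_call,
      f_obs = list(f_obs),
      f_corr = list(f_corr)
    )
  })
  dplyr::bind_cols(clusters, dplyr::bind_rows(res))
}
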