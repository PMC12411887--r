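# Brute-force oracles, independent of the package's implementation paths.

# Convolution of independent per-atom heavy/light distributions.
bf_convolve_atoms <- function(n_atoms, p) {
  dist <- 1
  for (i in seq_len(n_atoms)) {
    one <- c(1 - p, p)
    new <- rep(0, length(dist) + 1)
    for (j in seq_along(dist)) {
      new[j] <- new[j] + dist[j] * one[1]
      new[j + 1] <- new[j + 1] + dist[j] * one[2]
    }
    dist <- new
  }
  dist
}

# Row-scan re-check of the feature filters.
bf_filter <- function(table, min_mass = 100, max_mass = 1200,
                      min_intensity = 2e6, min_snr = 3) {
  meta <- c("feature_id", "neutral_mass", "rt_min", "snr")
  keep <- logical(nrow(table))
  for (i in seq_len(nrow(table))) {
    inten <- as.numeric(table[i, setdiff(names(table), meta)])
    keep[i] <- table$neutral_mass[i] >= min_mass &&
      table$neutral_mass[i] <= max_mass &&
      max(inten) >= min_intensity &&
      table$snr[i] > min_snr
  }
  table[keep, ]
}

# Manhattan distances by explicit double loop (features x samples input).
bf_manhattan <- function(m) {
  n <- ncol(m)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      D[i, j] <- sum(abs(m[, i] - m[, j]))
    }
  }
  dimnames(D) <- list(colnames(m), colnames(m))
  D
}

# PERMANOVA pseudo-F from among/within sums of squared distances.
bf_pseudo_f <- function(D, groups) {
  D <- as.matrix(D)
  n <- nrow(D)
  groups <- factor(groups)
  a <- nlevels(groups)
  ss_total <- sum(D[lower.tri(D)]^2) / n
  ss_within <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    Dg <- D[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(Dg[lower.tri(Dg)]^2) / length(idx)
  }
  ss_among <- ss_total - ss_within
  (ss_among / (a - 1)) / (ss_within / (n - a))
}

# Exact permutation p-value by full enumeration of label assignments.
bf_enum_p <- function(D, groups) {
  f_obs <- bf_pseudo_f(D, groups)
  n <- length(groups)
  perms <- gtools_permutations(n)
  f_perm <- apply(perms, 1, function(idx) bf_pseudo_f(D, groups[idx]))
  mean(f_perm >= f_obs - 1e-12)
}

# All permutations of 1..n (n small), no external dependency.
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Average-linkage agglomeration oracle: returns sorted merge heights.
bf_upgma_heights <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(active)) {
      for (j in seq_len(i - 1)) {
        d <- D[active[i], active[j]]
        if (d < best_d) { best_d <- d; best <- c(active[i], active[j]) }
      }
    }
    heights <- c(heights, best_d)
    i <- best[1]; j <- best[2]
    # merged cluster stored in slot i; average linkage weights by size
    for (k in setdiff(active, c(i, j))) {
      D[i, k] <- D[k, i] <-
        (sizes[i] * D[i, k] + sizes[j] * D[j, k]) / (sizes[i] + sizes[j])
    }
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  sort(heights)
}

# Small default generator run shared by ground-truth recovery tests.
make_default_run <- function(n_species = 80, seed = 11,
                             noise = noise_config()) {
  sp <- generate_species(n_species, seed = seed)
  sim <- generate_feature_table(sp, sample_design(), noise = noise,
                                seed = seed + 1)
  list(species = sp, sim = sim, design = sample_design())
}

# Join analyzed clusters to ground-truth labeled flags (clusters whose
# members map to a real species).
join_cluster_truth <- function(analyzed, truth) {
  mem <- tidyr::unnest(analyzed[, c("cluster_id", "members", "label_call")],
                       "members")
  mem |>
    dplyr::left_join(truth$feature_map, by = "feature_id") |>
    dplyr::filter(!is.na(.data$species_id)) |>
    dplyr::left_join(truth$labeled_species, by = "species_id") |>
    dplyr::distinct(.data$cluster_id, .data$label_call, .data$labeled)
}
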