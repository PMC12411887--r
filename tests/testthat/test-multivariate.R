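toy_matrix <- function(vals, nr) {
  m <- matrix(vals, nr)
  rownames(m) <- paste0("f", seq_len(nr))
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  attr(m, "norm_state") <- "raw"
  m
}

test_that("median normalization equalizes per-sample nonzero medians", {
  a <- c(1, 2, 3, 4, 5)
  m <- toy_matrix(c(a, 2 * a), 5)
  out <- median_normalize(m)
  # a doubled sample becomes identical after normalization
  expect_equal(out[, 1], out[, 2])
  meds <- apply(out, 2, function(x) median(x[x > 0]))
  expect_equal(unname(meds[1]), unname(meds[2]))
  # identical samples unchanged up to a global constant
  m2 <- toy_matrix(c(a, a), 5)
  out2 <- median_normalize(m2)
  expect_equal(unname(out2[, 1] / m2[, 1]), rep(1, 5))
  # zeros stay zeros; all-zero sample errors
  m3 <- toy_matrix(c(0, 2, 4, 0, 0, 0), 3)
  expect_error(median_normalize(m3), "degenerate sample")
  expect_error(median_normalize(out), "raw matrix")
})

test_that("Pareto scaling divides centered rows by sqrt(sd)", {
  m <- toy_matrix(c(1, 5, 3, 5), 2)
  mn <- median_normalize(m)
  # hand case on the raw values (1,3): mean 2, sd sqrt(2)
  m2 <- toy_matrix(c(1, 10, 3, 10), 2)
  attr(m2, "norm_state") <- "median_normalized"
  out <- pareto_scale(m2)
  expect_equal(out[1, ], c(s1 = -1 / 2^0.25, s2 = 1 / 2^0.25))
  # constant features map to zero; every row mean is zero
  expect_equal(out[2, ], c(s1 = 0, s2 = 0))
  expect_equal(unname(rowMeans(pareto_scale(mn))), c(0, 0))
  expect_error(pareto_scale(m), "median-normalized")
})

test_that("Manhattan distances match the brute-force double loop", {
  m <- toy_matrix(c(0, 0, 1, 2), 2)
  d <- as.matrix(manhattan_distance(m))
  expect_equal(d["s1", "s2"], 3)
  expect_equal(unname(diag(d)), c(0, 0))
  set.seed(4)
  m2 <- toy_matrix(rnorm(24), 6)
  expect_equal(as.matrix(manhattan_distance(m2)), bf_manhattan(m2),
               tolerance = 1e-12)
})

test_that("PCoA reproduces Euclidean configurations and PCA scores", {
  set.seed(8)
  x <- matrix(rnorm(8 * 5), 8)
  rownames(x) <- paste0("s", 1:8)
  p <- pcoa(dist(x))
  # classical MDS equivalence: Procrustes error below 1e-8
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- ncol(p$coordinates)
  pro <- vegan::procrustes(p$coordinates, pc$x[, 1:k], symmetric = FALSE)
  expect_lt(pro$ss / sum(p$coordinates^2), 1e-8)
  # eigenvalue bookkeeping
  expect_true(all(diff(p$eigenvalues) <= 1e-8))
  expect_equal(sum(p$prop_var), 1)
  # two points: a single axis separated by the distance
  d2 <- stats::as.dist(matrix(c(0, 3, 3, 0), 2))
  p2 <- pcoa(d2)
  expect_equal(ncol(p2$coordinates), 1)
  expect_equal(abs(diff(p2$coordinates[, 1])), 3)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("eigenvalue total matches the centered-matrix trace", {
  set.seed(9)
  x <- matrix(rnorm(30), 6)
  D <- as.matrix(dist(x, method = "manhattan"))
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% D^2 %*% J
  p <- pcoa(stats::as.dist(D))
  expect_equal(sum(p$eigenvalues), sum(diag(G)), tolerance = 1e-8)
})

test_that("average-linkage clustering matches a brute-force agglomerator", {
  D <- stats::as.dist(matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3))
  hc <- hierarchical_cluster(D)
  expect_equal(hc$height[1], 1)
  expect_setequal(-hc$merge[1, ], c(1, 2))
  set.seed(10)
  for (i in 1:3) {
    x <- matrix(rnorm(24), 6)
    d <- dist(x)
    hc2 <- hierarchical_cluster(d)
    expect_equal(sort(hc2$height), bf_upgma_heights(d), tolerance = 1e-10)
    expect_true(all(diff(hc2$height) >= -1e-12))
  }
  expect_error(hierarchical_cluster(stats::as.dist(matrix(0, 1, 1))),
               "at least 2")
})

test_that("PERMANOVA pseudo-F equals the sums-of-squares formulation", {
  set.seed(11)
  x <- matrix(rnorm(12 * 6), 12)
  d <- dist(x, method = "manhattan")
  g <- rep(c("a", "b", "c"), each = 4)
  res <- permanova(d, g, n_permutations = 99, seed = 1)
  expect_equal(res$pseudo_f, bf_pseudo_f(d, g), tolerance = 1e-10)
  # reordering samples leaves the statistic unchanged
  idx <- sample(12)
  res2 <- permanova(stats::as.dist(as.matrix(d)[idx, idx]), g[idx],
                    n_permutations = 99, seed = 1)
  expect_equal(res2$pseudo_f, res$pseudo_f, tolerance = 1e-10)
  # seed reproducibility of the permutation p-value
  expect_equal(permanova(d, g, 199, seed = 5)$p_value,
               permanova(d, g, 199, seed = 5)$p_value)
  expect_error(permanova(d, rep("a", 12)), "2 groups")
})

test_that("permutation p converges to the exact enumeration on 4 samples", {
  # two tight pairs, far apart: only the observed split (and its mirror)
  # reaches the observed F, so the exact permutation p is 2/6
  x <- matrix(c(0, 0, 0.1, 0, 10, 0, 10.1, 0), 4, byrow = TRUE)
  d <- dist(x)
  g <- c("a", "a", "b", "b")
  expect_equal(bf_enum_p(d, g), 2 / 6, tolerance = 1e-12)
  p_hat <- permanova(d, g, n_permutations = 9999, seed = 3)$p_value
  expect_lt(abs(p_hat - 1 / 3), 0.03)
})

test_that("amended samples at the pulse peak separate in ordination", {
  # the transient microbial excursion at T1 drives both the omnibus
  # grouping and the specific PL-T1 contrast
  run <- make_default_run(n_species = 100, seed = 1001)
  cl <- cluster_isotopologues(filter_features(run$sim$table))
  m <- pareto_scale(median_normalize(cluster_abundance_matrix(cl)))
  dsg <- run$design
  keep <- dsg$sample_id[dsg$treatment != "LO"]
  ds2 <- dsg[match(keep, dsg$sample_id), ]
  d <- manhattan_distance(m[, keep])
  omni <- permanova(d, paste(ds2$treatment, ds2$timepoint, sep = "_"),
                    n_permutations = 999, seed = 1)
  expect_lte(omni$p_value, 0.05)
  grp <- ifelse(ds2$treatment == "PL" & ds2$timepoint == "T1", "PL_T1", "other")
  focal <- permanova(d, grp, n_permutations = 999, seed = 2)
  expect_lte(focal$p_value, 0.05)
})
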