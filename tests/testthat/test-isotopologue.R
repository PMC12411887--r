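make_toy_table <- function(mass, rt, snr, inten) {
  tibble::tibble(
    feature_id = make_feature_id(mass, rt),
    neutral_mass = mass, rt_min = rt, snr = snr,
    S1 = inten
  )
}

test_that("feature filters apply the documented boundary conventions", {
  tab <- make_toy_table(
    mass = c(99.9, 100.0, 1200.0, 1200.1, 500, 500, 500),
    rt = 1:7, snr = c(10, 10, 10, 10, 3, 3.01, 10),
    inten = c(1e7, 1e7, 1e7, 1e7, 1e7, 1e7, 1.9e6)
  )
  out <- filter_features(tab)
  # mass bounds inclusive; snr strictly greater than 3; intensity >= 2e6
  expect_setequal(out$rt_min, c(2, 3, 6))
  # identity when everything passes
  ok <- make_toy_table(c(150, 300), 1:2, c(10, 10), c(1e7, 1e7))
  expect_identical(filter_features(ok), ok)
  # empty in, empty out
  expect_equal(nrow(filter_features(ok[0, ])), 0)
  expect_error(filter_features(ok, min_mass = -1), "non-negative")
})

test_that("filtering equals a brute-force row scan and ignores row order", {
  run <- make_default_run(n_species = 40, seed = 71)
  tab <- run$sim$table
  expect_equal(filter_features(tab), bf_filter(tab))
  shuf <- tab[sample(nrow(tab)), ]
  a <- filter_features(shuf)
  b <- filter_features(tab)
  expect_setequal(a$feature_id, b$feature_id)
})

test_that("isotopologue clustering groups exact mass shifts at shared RT", {
  tab <- tibble::tibble(
    feature_id = c("a", "b", "c", "d"),
    neutral_mass = c(200, 200 + 1.0033548, 300, 300.5),
    rt_min = c(5, 5, 9, 9), snr = 10, S1 = c(1e7, 1e6, 1e7, 1e7)
  )
  cl <- cluster_isotopologues(tab)
  expect_equal(nrow(cl), 3)
  pair <- cl$members[[which(cl$base_feature_id == "a")]]
  expect_equal(pair$k, c(0L, 1L))
  # half-Dalton shift never joins
  expect_true(all(cl$n_members[cl$base_feature_id %in% c("c", "d")] == 1))
  expect_error(cluster_isotopologues(tab[0, ]), "empty feature set")
  expect_error(cluster_isotopologues(tab, rt_tol = 0), "rt_tol")
})

test_that("cluster membership matches ground truth and ignores column order", {
  run <- make_default_run(n_species = 80, seed = 31)
  filt <- filter_features(run$sim$table)
  cl <- cluster_isotopologues(filt)
  mem <- tidyr::unnest(cl[, c("cluster_id", "members")], "members")
  j <- dplyr::left_join(mem, run$sim$truth$feature_map, by = "feature_id")
  j <- j[!is.na(j$species_id), ]
  # within each cluster, all real members share one species
  agree <- tapply(j$species_id, j$cluster_id,
                  function(x) mean(x == names(sort(table(x), decreasing = TRUE))[1]))
  expect_gte(mean(unlist(agree)), 0.99)
  # sample-column order must not matter
  perm_cols <- c(1:4, sample(5:ncol(filt)))
  cl2 <- cluster_isotopologues(filt[, perm_cols])
  expect_equal(cl$n_members, cl2$n_members)
  expect_equal(cl$base_feature_id, cl2$base_feature_id)
})

test_that("natural-abundance correction inverts the forward convolution", {
  # pure natural two-carbon envelope flattens to the k = 0 vector
  f_obs <- bf_convolve_atoms(2, 0.0107)
  expect_equal(natural_abundance_correct(f_obs, 2), c(1, 0, 0),
               tolerance = 1e-8)
  # zero natural abundance: identity
  f <- c(0.2, 0.5, 0.3)
  expect_equal(natural_abundance_correct(f, 2, p_nat = 0), f)
  # round trip across a (nc, p) grid, against the convolution oracle
  for (nc in c(2, 5, 12, 25)) {
    for (p in c(0, 0.1, 0.3, 0.524, 0.9)) {
      f_corr <- binomial_envelope(nc, p)
      fwd <- as.vector(correction_matrix(nc) %*% f_corr)
      expect_equal(fwd, forward_convolve(f_corr, nc), tolerance = 1e-12)
      back <- natural_abundance_correct(fwd, nc)
      expect_lt(max(abs(back - f_corr)), 1e-6)
    }
  }
  expect_error(natural_abundance_correct(c(0.5, 0.5), 0), "n_carbon")
  expect_error(natural_abundance_correct(c(0.7, 0.7), 3), "sum to 1")
})

test_that("correction matrix is column-stochastic and lower triangular", {
  C <- correction_matrix(8)
  expect_equal(colSums(C), rep(1, 9))
  expect_true(all(C[upper.tri(C)] == 0))
})

test_that("carbon counts are recovered from labeled envelopes", {
  # glucose-like: mass 180.063, six carbons, noiseless tracer envelope
  f_obs <- forward_convolve(binomial_envelope(6, 0.524), 6)
  expect_equal(estimate_n_carbon(f_obs, 180.063), 6L)
  expect_error(estimate_n_carbon(c(1), 11), "non-organic")
  # noiseless sweep with the emission floor applied, nc up to 40
  set.seed(13)
  hits <- 0; n <- 0
  for (nc in 5:40) {
    mass <- runif(1, nc * 12.5, nc * 29)
    env <- forward_convolve(binomial_envelope(nc, 0.524), nc)
    env[env < 1e-4] <- 0
    est <- estimate_n_carbon(env / sum(env), mass)
    n <- n + 1; hits <- hits + (est == nc)
  }
  expect_gte(hits / n, 0.9)
})

test_that("enrichment estimation is exact on binomial envelopes", {
  expect_equal(estimate_enrichment(binomial_envelope(6, 0.5), 6), 50)
  expect_equal(estimate_enrichment(c(1, rep(0, 9)), 9), 0)
  for (nc in c(1, 3, 10, 25, 40)) {
    for (p in seq(0, 0.9, by = 0.1)) {
      expect_equal(estimate_enrichment(binomial_envelope(nc, p), nc), 100 * p,
                   tolerance = 1e-9)
    }
  }
  expect_error(estimate_enrichment(c(1), 0), "n_carbon")
})

test_that("label classification uses the corrected heavy fraction", {
  nat <- natural_abundance_correct(binomial_envelope(10, 0.0107), 10)
  r <- classify_labeled(nat, n_members = 2)
  expect_false(r$label_call)
  expect_lt(r$diagnostic_ratio, 1e-6)
  lab <- classify_labeled(binomial_envelope(10, 0.524), n_members = 5)
  expect_true(lab$label_call)
  expect_equal(lab$diagnostic_ratio, 1 - (1 - 0.524)^10, tolerance = 1e-12)
  # a lone feature is never called labeled
  expect_false(classify_labeled(binomial_envelope(10, 0.524), 1)$label_call)
})

test_that("label calls match ground truth exactly without noise", {
  run <- make_default_run(n_species = 80, seed = 41,
                          noise = noise_config(0, 0, 0, 0, 0))
  an <- analyze_clusters(cluster_isotopologues(filter_features(run$sim$table)))
  j <- join_cluster_truth(an, run$sim$truth)
  expect_identical(j$label_call, j$labeled)
})

test_that("label sensitivity and specificity reach 0.95 at default noise", {
  run <- make_default_run(n_species = 120, seed = 11)
  an <- analyze_clusters(cluster_isotopologues(filter_features(run$sim$table)))
  j <- join_cluster_truth(an, run$sim$truth)
  sens <- sum(j$label_call & j$labeled) / sum(j$labeled)
  spec <- sum(!j$label_call & !j$labeled) / sum(!j$labeled)
  expect_gte(sens, 0.95)
  expect_gte(spec, 0.95)
})

test_that("enrichment recovery is unbiased at the litter labeling level", {
  set.seed(2)
  q <- total_heavy_probability(0.524)
  ests <- replicate(100, {
    nc <- sample(5:40, 1)
    cnt <- simulate_envelope(nc, q, 1e4)
    f <- cnt / sum(cnt)
    mass <- runif(1, nc * 12.5, nc * 29)
    nch <- estimate_n_carbon(f, mass)
    estimate_enrichment(natural_abundance_correct(f, nch), nch)
  })
  expect_lt(abs(mean(ests) - 52.4), 0.5)
})

test_that("detection summaries round percentages half-up to 2 decimals", {
  expect_equal(round_half_up(32.1875, 2), 32.19)
  expect_equal(round_half_up(19.0625, 2), 19.06)
  s <- summarize_detection(n_features_total = 320, n_labeled = 164,
                           annotation_counts = c(annotated = 103))
  expect_equal(s$pct[s$category == "labeled"], 51.25)
  expect_equal(s$pct[s$category == "annotated"], 32.19)
  expect_error(summarize_detection(n_features_total = 0, n_labeled = 0),
               "positive count")
  expect_error(summarize_detection(n_features_total = 10, n_labeled = 11),
               "exceed")
})
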