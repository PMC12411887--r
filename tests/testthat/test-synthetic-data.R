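test_that("binomial envelope matches closed form and convolution oracle", {
  # six carbons at p = 0.5: proportions C(6,k)/64
  expect_equal(binomial_envelope(6, 0.5), choose(6, 0:6) / 64)
  # two carbons at natural abundance: brute-force convolution of two
  # one-carbon distributions, frozen to 8 decimals
  oracle <- bf_convolve_atoms(2, 0.0107)
  expect_equal(round(oracle, 8), c(0.97871449, 0.02117102, 0.00011449))
  expect_equal(binomial_envelope(2, 0.0107), oracle)
})

test_that("simulated envelopes are multinomial draws of the binomial law", {
  env <- simulate_envelope(6, 0.5, 1e4, seed = 3)
  expect_length(env, 7)
  expect_equal(sum(env), 1e4)
  # chi-square goodness of fit at large ion count
  gof <- suppressWarnings(
    stats::chisq.test(env, p = binomial_envelope(6, 0.5))
  )
  expect_gt(gof$p.value, 1e-4)
  # single ion: one-hot
  expect_equal(sum(simulate_envelope(5, 0.3, 1, seed = 1) == 1), 1)
  # determinism and seed sensitivity
  expect_identical(simulate_envelope(8, 0.4, 100, seed = 7),
                   simulate_envelope(8, 0.4, 100, seed = 7))
  expect_false(identical(simulate_envelope(8, 0.4, 1e4, seed = 7),
                         simulate_envelope(8, 0.4, 1e4, seed = 8)))
  expect_error(simulate_envelope(5, 0.3, 0), "ion_count")
})

test_that("species generation honors origin mix, enrichment and mass bounds", {
  sp <- generate_species(60, origin_mix = c(litter = 1), enrichment = 0.524,
                         seed = 2)
  expect_true(all(sp$origin == "litter"))
  expect_true(all(sp$enrichment == 0.524))
  expect_true(all(sp$neutral_mass >= 100 & sp$neutral_mass <= 1200))
  # carbon counts consistent with mass
  expect_true(all(sp$n_carbon >= pmax(1, floor(sp$neutral_mass / 30) - 1)))
  expect_true(all(sp$n_carbon <= ceiling(sp$neutral_mass / 12)))
  # zero tracer: observable envelope is pure natural abundance
  expect_equal(total_heavy_probability(0), 0.0107)
  expect_equal(total_heavy_probability(0.524), 0.5290932)
  # determinism
  expect_identical(generate_species(50, seed = 9), generate_species(50, seed = 9))
  expect_error(generate_species(0), "n_species")
  expect_error(generate_species(5, mass_range = c(200, 200)), "mass range")
  expect_error(generate_species(5, origin_mix = c(litter = 0.5)), "sum to 1")
})

test_that("sample design encodes the incubation layout", {
  d <- sample_design()
  expect_equal(nrow(d), 28)
  expect_true(all(d$timepoint[d$treatment == "LO"] == "T0"))
  expect_true(all(d$label_status[d$treatment == "PO"] == "unlabeled"))
  # 2 replicates per treatment x timepoint x label status
  counts <- dplyr::count(d, treatment, timepoint, label_status)
  expect_true(all(counts$n == 2))
  expect_equal(timepoint_to_day(c("T0", "T1", "T2", "T3")), c(0, 7, 18, 40))
  expect_error(timepoint_to_day("T9"), "unknown timepoint")
})

test_that("noiseless feature tables are proportional to the envelope", {
  sp <- generate_species(1, origin_mix = c(peat_native = 1), seed = 5)
  des <- sample_design()[5, ] # one PO sample
  sim <- generate_feature_table(sp, des, noise = noise_config(0, 0, 0, 0, 0),
                                seed = 6)
  env <- binomial_envelope(sp$n_carbon, 0.0107)
  ks <- which(env >= 1e-4) - 1
  expect_equal(nrow(sim$table), length(ks))
  inten <- sim$table[[5]]
  expect_equal(inten / sum(inten), env[ks + 1] / sum(env[ks + 1]),
               tolerance = 1e-12)
  # isotopologue masses shifted by k * 1.0033548
  expect_equal(sim$table$neutral_mass, sp$neutral_mass + ks * 1.0033548,
               tolerance = 1e-9)
})

test_that("dynamics: primed species decline in PL and stay flat in PO", {
  sp <- generate_species(10, origin_mix = c(peat_primed = 1), seed = 7)
  des <- sample_design()
  sim <- generate_feature_table(sp, des, noise = noise_config(0, 0, 0, 0, 0),
                                seed = 8)
  ab <- dplyr::left_join(sim$truth$abundance, des, by = "sample_id")
  pl <- ab |>
    dplyr::filter(treatment == "PL") |>
    dplyr::arrange(species_id, day)
  for (s in unique(pl$species_id)) {
    traj <- pl$true_abundance[pl$species_id == s]
    expect_true(all(diff(traj) <= 0))
  }
  po <- ab |> dplyr::filter(treatment == "PO")
  expect_true(all(tapply(po$true_abundance, po$species_id,
                         function(x) diff(range(x))) == 0))
})

test_that("feature table generation is byte-identical under a fixed seed", {
  sp <- generate_species(20, seed = 3)
  a <- generate_feature_table(sp, sample_design(), seed = 4)
  b <- generate_feature_table(sp, sample_design(), seed = 4)
  expect_identical(a$table, b$table)
  expect_identical(a$truth$feature_map, b$truth$feature_map)
  expect_error(generate_feature_table(sp, sample_design()[0, ], seed = 1))
  expect_error(noise_config(mass_ppm = -1), "non-negative")
})

test_that("NMR block carries the configured labeled fraction", {
  nmr <- generate_nmr_block(45, sample_design(), labeled_fraction = 0.4,
                            seed = 9)
  expect_equal(sum(nmr$labeled$labeled), 18)
  expect_true(all(nmr$concentrations$mass >= 32 &
                    nmr$concentrations$mass <= 355))
  none <- generate_nmr_block(45, sample_design(), labeled_fraction = 0,
                             seed = 9)
  expect_equal(sum(none$labeled$labeled), 0)
  expect_identical(generate_nmr_block(20, seed = 1),
                   generate_nmr_block(20, seed = 1))
  expect_error(generate_nmr_block(10, mass_range = c(10, 355)), "mass_range")
})

test_that("flux series ground truth closes exactly and mixes by hand arithmetic", {
  # day-7 litter flux forced to 4: L0 = 4 * exp(0.7) under k = 0.1
  cfg <- flux_config(baseline = 2, litter_l0 = 4 * exp(0.7), litter_k = 0.1,
                     priming_amp = 0, cv = 0, days = c(1, 7),
                     r_soil = 0.0108, r_litter = 0.524)
  sim <- simulate_flux_series(cfg, seed = 1)
  expect_equal(sim$truth$litter_flux + sim$truth$peat_flux,
               sim$truth$f_net_true)
  day7 <- sim$observations[sim$observations$treatment == "PL" &
                             sim$observations$day == 7, ]
  expect_equal(day7$r_net, rep((2 * 0.0108 + 4 * 0.524) / 6, nrow(day7)),
               tolerance = 1e-12)
  # no amendment: PL and PO identical without noise
  nil <- simulate_flux_series(flux_config(litter_l0 = 0, priming_amp = 0,
                                          cv = 0), seed = 2)
  po <- nil$observations[nil$observations$treatment == "PO", ]
  pl <- nil$observations[nil$observations$treatment == "PL", ]
  expect_equal(pl$f_net, po$f_net)
  # ill-posed end-members rejected
  expect_error(flux_config(r_soil = 0.5, r_litter = 0.5), "unidentifiable")
  # positive pulse raises the PL peat component above the PO baseline
  pulse <- simulate_flux_series(flux_config(cv = 0), seed = 3)
  peak <- pulse$truth[pulse$truth$treatment == "PL" & pulse$truth$day == 5, ]
  expect_true(all(peak$peat_flux > 2))
})
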