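#' Trajectory parameters for the synthetic incubation dynamics
#'
#' Controls how each origin pool evolves over incubation time in the
#' generator. Litter compounds decay exponentially in amended (PL) jars;
#' microbial products follow a pulse `A * (t/tau) * exp(1 - t/tau)` peaking at
#' `pulse_tau` days (the fast microbial response to fresh substrate);
#' peat-native compounds are constant; peat-primed compounds decline in PL
#' jars only (the priming signature: native compounds consumed after
#' amendment). Defaults are calibrated so the amended samples around the
#' day-7 harvest stand apart in a Manhattan-distance ordination: the
#' microbial pulse peaks shortly before that harvest and has largely decayed
#' by day 18, litter compounds decay with a ~14-day half-life (still
#' detectable at day 40), and primed species fall well below their T0 level
#' by day 40.
#'
#' @param litter_decay First-order decay rate of litter species in PL jars
#'   (per day).
#' @param pulse_amplitude Peak fold-increase (above baseline) of microbial
#'   products in PL jars.
#' @param pulse_tau Day of the microbial pulse peak.
#' @param primed_decay First-order decline rate of peat-primed species in PL
#'   jars (per day).
#' @return A list of class `"dynamics_config"`.
#' @export
dynamics_config <- function(litter_decay = 0.05,
                            pulse_amplitude = 10,
                            pulse_tau = 5,
                            primed_decay = 0.05) {
  stopifnot(litter_decay >= 0, pulse_tau > 0, primed_decay >= 0)
  structure(list(litter_decay = litter_decay, pulse_amplitude = pulse_amplitude,
                 pulse_tau = pulse_tau, primed_decay = primed_decay),
            class = "dynamics_config")
}

#' Noise parameters for the synthetic feature table
#'
#' @param mass_ppm SD of the relative mass error, in ppm.
#' @param rt_sd SD of retention-time jitter, in minutes.
#' @param intensity_cv Coefficient of variation of multiplicative log-normal
#'   intensity noise (mean-preserving).
#' @param noise_fraction Fraction of table rows that are unassigned noise
#'   features.
#' @param missing_rate Per-cell probability that an intensity is lost
#'   (recorded as 0, the sparse-table convention for below-detection).
#' @return A list of class `"noise_config"`.
#' @export
noise_config <- function(mass_ppm = 1,
                         rt_sd = 0.02,
                         intensity_cv = 0.2,
                         noise_fraction = 0.05,
                         missing_rate = 0.02) {
  vals <- c(mass_ppm, rt_sd, intensity_cv, noise_fraction, missing_rate)
  if (any(vals < 0)) stop("noise parameters must be non-negative")
  if (noise_fraction >= 1) stop("noise_fraction must be < 1")
  structure(list(mass_ppm = mass_ppm, rt_sd = rt_sd, intensity_cv = intensity_cv,
                 noise_fraction = noise_fraction, missing_rate = missing_rate),
            class = "noise_config")
}

# True (noiseless) abundance of one species in each sample of the design.
#' @noRd
true_abundance <- function(species_row, design, dynamics) {
  base <- species_row$base_abundance
  t <- design$day
  mult <- switch(
    species_row$origin,
    litter = ifelse(design$treatment == "LO", 1,
             ifelse(design$treatment == "PL", exp(-dynamics$litter_decay * t), 0)),
    peat_native = ifelse(design$treatment == "LO", 0, 1),
    microbial_product = ifelse(
      design$treatment == "LO", 0,
      ifelse(design$treatment == "PL",
             1 + dynamics$pulse_amplitude * (t / dynamics$pulse_tau) *
               exp(1 - t / dynamics$pulse_tau),
             1)),
    peat_primed = ifelse(design$treatment == "LO", 0,
                  ifelse(design$treatment == "PL", exp(-dynamics$primed_decay * t), 1)),
    stop("unknown origin: ", species_row$origin)
  )
  base * mult
}

# Mean-preserving multiplicative log-normal noise factors.
#' @noRd
lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic LC-MS feature table with ground truth
#'
#' Expands each molecular species into its isotopologue features (one row per
#' heavy-atom count k whose expected proportion exceeds `envelope_floor` under
#' either the labeled or the natural envelope -- an emission floor standing in
#' for detector dynamic range), places them at mass `neutral_mass + k *
#' 1.0033548` Da and the species retention time, fills per-sample intensities
#' from the incubation dynamics and the sample's effective labeling
#' probability (tracer enrichment in labeled jars, natural abundance
#' elsewhere), then applies mass/RT/intensity noise, sprinkles unassigned
#' noise rows, and zeroes a fraction of cells as missing.
#'
#' @param species Species table from [generate_species()].
#' @param design Sample design from [sample_design()].
#' @param dynamics A [dynamics_config()].
#' @param noise A [noise_config()].
#' @param p_nat Natural 13C abundance.
#' @param envelope_floor Minimum expected isotopologue proportion emitted as a
#'   feature row.
#' @param seed Optional integer seed; fixed seed reproduces the table exactly.
#'
#' @return A list with `table` (tibble: `feature_id`, `neutral_mass`,
#'   `rt_min`, `snr`, one intensity column per sample) and `truth` (species
#'   table, per-sample true abundances, feature-to-species map, per-species
#'   labeled flags, and the seed).
#' @export
#' @examples
#' sp <- generate_species(10, seed = 1)
#' sim <- generate_feature_table(sp, sample_design(), seed = 1)
#' dim(sim$table)
generate_feature_table <- function(species,
                                   design = sample_design(),
                                   dynamics = dynamics_config(),
                                   noise = noise_config(),
                                   p_nat = 0.0107,
                                   envelope_floor = 1e-4,
                                   seed = NULL) {
  check_design(design)
  stopifnot(nrow(species) > 0)

  with_seed_if(seed, {
    # per-sample observable heavy probability: tracer (labeled jars only, and
    # only for species actually enriched above natural) plus natural
    # abundance on the unlabeled positions; species at natural abundance
    # carry no tracer, so their envelope stays at p_nat everywhere
    p_eff <- function(sp_enr) {
      tracer <- ifelse(design$label_status == "labeled" & sp_enr > p_nat + 1e-9,
                       sp_enr, 0)
      total_heavy_probability(tracer, p_nat)
    }

    rows <- list(); maps <- list(); abunds <- list()
    for (i in seq_len(nrow(species))) {
      sp <- species[i, ]
      nc <- sp$n_carbon
      tracer_sp <- if (sp$enrichment > p_nat + 1e-9) sp$enrichment else 0
      env_lab <- binomial_envelope(nc, total_heavy_probability(tracer_sp, p_nat))
      env_nat <- binomial_envelope(nc, p_nat)
      ks <- which(pmax(env_lab, env_nat) >= envelope_floor) - 1L
      abund <- true_abundance(sp, design, dynamics)
      p_s <- p_eff(sp$enrichment)
      # intensity matrix: isotopologues x samples
      inten <- outer(ks, seq_len(nrow(design)),
                     function(k, s) abund[s] * dbinom(k, nc, p_s[s]))
      rows[[i]] <- tibble::tibble(
        species_id = sp$species_id,
        k = ks,
        mass = sp$neutral_mass + ks * C13_MASS_SHIFT,
        rt = sp$rt,
        snr = rlnorm(length(ks), meanlog = log(40), sdlog = 0.4),
        inten = lapply(seq_along(ks), function(j) inten[j, ])
      )
      abunds[[i]] <- tibble::tibble(
        species_id = sp$species_id,
        sample_id = design$sample_id,
        true_abundance = abund,
        p_effective = p_s
      )
    }
    real <- dplyr::bind_rows(rows)

    # measurement noise on mass, RT and intensities
    real$mass <- real$mass * (1 + rnorm(nrow(real), 0, noise$mass_ppm) * 1e-6)
    real$rt <- pmax(0, real$rt + rnorm(nrow(real), 0, noise$rt_sd))
    real$inten <- lapply(real$inten, function(v) {
      v <- v * lognormal_factor(length(v), noise$intensity_cv)
      if (noise$missing_rate > 0) {
        v[runif(length(v)) < noise$missing_rate] <- 0
      }
      v
    })

    # unassigned noise rows
    n_noise <- round(noise$noise_fraction / (1 - noise$noise_fraction) * nrow(real))
    if (n_noise > 0) {
      noise_rows <- tibble::tibble(
        species_id = NA_character_,
        k = NA_integer_,
        mass = runif(n_noise, min(species$neutral_mass), max(species$neutral_mass)),
        rt = runif(n_noise, min(species$rt), max(species$rt)),
        snr = rlnorm(n_noise, meanlog = log(4), sdlog = 0.7),
        inten = lapply(seq_len(n_noise), function(j) {
          v <- rlnorm(nrow(design), meanlog = log(4e6), sdlog = 1)
          v[runif(nrow(design)) < 0.7] <- 0
          v
        })
      )
      real <- dplyr::bind_rows(real, noise_rows)
    }

    real <- dplyr::arrange(real, .data$mass)
    ids <- make_feature_id(real$mass, real$rt)
    # guarantee unique ids (collisions only at print precision)
    while (anyDuplicated(ids) > 0) {
      dup <- duplicated(ids)
      real$rt[dup] <- real$rt[dup] + 1e-3
      ids <- make_feature_id(real$mass, real$rt)
    }

    inten_mat <- do.call(rbind, real$inten)
    colnames(inten_mat) <- design$sample_id
    table <- dplyr::bind_cols(
      tibble::tibble(feature_id = ids, neutral_mass = real$mass,
                     rt_min = real$rt, snr = real$snr),
      tibble::as_tibble(inten_mat)
    )

    truth <- list(
      species = species,
      abundance = dplyr::bind_rows(abunds),
      feature_map = tibble::tibble(feature_id = ids,
                                   species_id = real$species_id, k = real$k),
      labeled_species = tibble::tibble(
        species_id = species$species_id,
        labeled = species$enrichment > p_nat + 1e-6
      ),
      seed = seed
    )
    list(table = table, truth = truth)
  })
}

#' Generate a synthetic NMR-style metabolite concentration block
#'
#' Emulates a small-molecule (1H NMR) concentration table sharing the
#' incubation design: masses in the low-molecular-weight window, a
#' configurable fraction of metabolites flagged as isotopically labeled
#' (litter-derived), and concentrations that pulse in amended jars for the
#' labeled fraction.
#'
#' @param n_metabolites Number of metabolites (default 45).
#' @param design Sample design from [sample_design()].
#' @param labeled_fraction Fraction flagged labeled (default 0.4; flags =
#'   `round(labeled_fraction * n_metabolites)`).
#' @param mass_range Mass window in Da (default 32--355).
#' @param concentration_cv Multiplicative noise CV.
#' @param seed Optional integer seed.
#' @return A list with `concentrations` (tibble: `metabolite_id`, `mass`, one
#'   column per sample) and `labeled` (tibble: `metabolite_id`, `labeled`).
#' @export
generate_nmr_block <- function(n_metabolites = 45,
                               design = sample_design(),
                               labeled_fraction = 0.4,
                               mass_range = c(32, 355),
                               concentration_cv = 0.2,
                               seed = NULL) {
  check_design(design)
  stopifnot(n_metabolites >= 1, labeled_fraction >= 0, labeled_fraction <= 1)
  if (mass_range[1] < 32 || mass_range[2] > 355) {
    stop("mass_range must lie within [32, 355] Da")
  }
  with_seed_if(seed, {
    n_lab <- round(labeled_fraction * n_metabolites)
    labeled <- rep(FALSE, n_metabolites)
    if (n_lab > 0) labeled[sample.int(n_metabolites, n_lab)] <- TRUE
    base <- rlnorm(n_metabolites, meanlog = log(100), sdlog = 0.7)
    conc <- sapply(seq_len(nrow(design)), function(s) {
      t <- design$day[s]; trt <- design$treatment[s]
      mult <- ifelse(labeled,
                     # litter-derived: abundant in litter, pulsing in amended jars
                     switch(trt, LO = 3,
                            PL = 1 + 2 * (t / 7) * exp(1 - t / 7),
                            PO = 0.3),
                     switch(trt, LO = 0.2, 1))
      base * mult * lognormal_factor(n_metabolites, concentration_cv)
    })
    colnames(conc) <- design$sample_id
    ids <- sprintf("nmr%03d", seq_len(n_metabolites))
    list(
      concentrations = dplyr::bind_cols(
        tibble::tibble(metabolite_id = ids,
                       mass = runif(n_metabolites, mass_range[1], mass_range[2])),
        tibble::as_tibble(conc)
      ),
      labeled = tibble::tibble(metabolite_id = ids, labeled = labeled)
    )
  })
}
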