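#' Generate a synthetic pool of molecular species
#'
#' Draws a table of molecular species emulating the water-extractable
#' metabolite pool of a peat + litter incubation. Each species has a neutral
#' all-12C monoisotopic mass, a retention time, a carbon count consistent with
#' its mass (between mass/30 and mass/12 carbons, the plausible range for
#' CHO(N) organic matter), an origin pool, and a per-carbon 13C labeling
#' probability: litter-derived species carry the tracer enrichment, all other
#' pools sit at natural abundance.
#'
#' @param n_species Number of species to draw (>= 1).
#' @param origin_mix Named proportions over the origin pools `litter`,
#'   `peat_native`, `microbial_product`, `peat_primed`; must sum to 1.
#' @param mass_range Neutral-mass interval in Da, within \[100, 1200\].
#' @param enrichment Per-carbon 13C probability of litter species (default
#'   0.524, i.e. 52.4 atom percent).
#' @param enrichment_sd Between-species SD of litter enrichment (default 0:
#'   uniform labeling across compounds).
#' @param p_nat Natural 13C abundance as an atom fraction.
#' @param rt_range Retention-time interval in minutes.
#' @param seed Optional integer seed; fixed seed gives an identical table.
#'
#' @return A tibble with columns `species_id`, `origin`, `n_carbon`,
#'   `neutral_mass`, `rt`, `enrichment`, `base_abundance`.
#' @export
#' @examples
#' generate_species(5, seed = 1)
generate_species <- function(n_species,
                             origin_mix = c(litter = 0.35, peat_native = 0.3,
                                            microbial_product = 0.2, peat_primed = 0.15),
                             mass_range = c(100, 1200),
                             enrichment = 0.524,
                             enrichment_sd = 0,
                             p_nat = 0.0107,
                             rt_range = c(1, 70),
                             seed = NULL) {
  if (n_species < 1) stop("n_species must be >= 1")
  if (length(mass_range) != 2 || diff(mass_range) <= 0) stop("empty mass range")
  if (mass_range[1] < 100 || mass_range[2] > 1200) {
    stop("mass_range must lie within [100, 1200] Da")
  }
  if (abs(sum(origin_mix) - 1) > 1e-8) stop("origin_mix proportions must sum to 1")
  if (enrichment < 0 || enrichment > 1) stop("enrichment must be in [0, 1]")

  with_seed_if(seed, {
    mass <- runif(n_species, mass_range[1], mass_range[2])
    n_carbon <- pmax(1L, as.integer(round(runif(n_species, mass / 30, mass / 12))))
    origin <- sample(names(origin_mix), n_species, replace = TRUE, prob = origin_mix)
    enr <- ifelse(
      origin == "litter",
      pmin(1, pmax(0, rnorm(n_species, enrichment, enrichment_sd))),
      p_nat
    )
    tibble::tibble(
      species_id = sprintf("sp%04d", seq_len(n_species)),
      origin = origin,
      n_carbon = n_carbon,
      neutral_mass = mass,
      rt = runif(n_species, rt_range[1], rt_range[2]),
      enrichment = enr,
      # detected-feature abundances: the emulated pool is what survives the
      # 2e6 detection threshold, so bases sit well above it even after the
      # envelope spreads intensity over many isotopologues
      base_abundance = rlnorm(n_species, meanlog = log(2e8), sdlog = 0.8)
    )
  })
}

#' Per-carbon total heavy-isotope probability
#'
#' A carbon atom is heavy if it carries the tracer (probability `p_tracer`)
#' or, failing that, is naturally 13C: `q = p_tracer + (1 - p_tracer) *
#' p_nat`. This is the probability that generates the observable envelope;
#' natural-abundance correction later removes the `p_nat` contribution so
#' that enrichment estimates recover `p_tracer`. With `p_tracer = 0` the
#' envelope reduces to natural abundance.
#'
#' @param p_tracer Per-carbon tracer labeling probability.
#' @param p_nat Natural 13C abundance.
#' @return Total per-carbon heavy probability.
#' @export
#' @examples
#' total_heavy_probability(0.524) # 0.5290932
total_heavy_probability <- function(p_tracer, p_nat = 0.0107) {
  stopifnot(all(p_tracer >= 0 & p_tracer <= 1))
  p_tracer + (1 - p_tracer) * p_nat
}

#' Theoretical binomial isotopologue envelope
#'
#' Under uniform labeling every carbon is independently 13C with probability
#' `p`, so the proportion of molecules carrying k heavy atoms is
#' Binomial(n_carbon, p) evaluated at k.
#'
#' @param n_carbon Number of carbon atoms (>= 1).
#' @param p Per-carbon 13C probability.
#' @return Numeric vector of length `n_carbon + 1` summing to 1.
#' @export
#' @examples
#' binomial_envelope(6, 0.524)
binomial_envelope <- function(n_carbon, p) {
  stopifnot(n_carbon >= 1, p >= 0, p <= 1)
  dbinom(0:n_carbon, n_carbon, p)
}

#' Sample an isotopologue envelope by multinomial ion counting
#'
#' Simulates the measured isotopologue envelope of one species: `ion_count`
#' ions are drawn multinomially with the binomial envelope probabilities, so
#' counting noise shrinks as ion_count grows.
#'
#' @param n_carbon Number of carbon atoms.
#' @param p Per-carbon 13C probability.
#' @param ion_count Total ions to draw (>= 1).
#' @param seed Optional integer seed.
#' @return Integer vector of length `n_carbon + 1`; entries sum to `ion_count`.
#' @export
#' @examples
#' simulate_envelope(6, 0.5, 1e4, seed = 1)
simulate_envelope <- function(n_carbon, p, ion_count, seed = NULL) {
  if (ion_count < 1) stop("ion_count must be >= 1")
  probs <- binomial_envelope(n_carbon, p)
  with_seed_if(seed, as.vector(rmultinom(1, size = ion_count, prob = probs)))
}
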