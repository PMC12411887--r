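# Mass difference between 13C and 12C in Da. Fixed by physics, not a tuning knob.
C13_MASS_SHIFT <- 1.0033548

#' Isotope constants for 13C tracer calculations
#'
#' Bundles the physical constants used throughout the package: the 13C/12C
#' isotope ratio of the VPDB standard, the natural abundance of 13C expressed
#' as an atom fraction, and the delta-13C of the CO2 standard gas used to
#' flush incubation jars between gas samplings.
#'
#' @param r_standard_vpdb 13C/12C ratio of the Vienna Pee Dee Belemnite
#'   standard (dimensionless).
#' @param p_nat Natural abundance of 13C as an atom fraction (probability that
#'   any one carbon atom is 13C).
#' @param delta_standard_gas delta-13C of the flushing standard gas, in permil
#'   vs VPDB.
#'
#' @return A list of class `"isotope_constants"`.
#' @export
#'
#' @examples
#' isotope_constants()
isotope_constants <- function(r_standard_vpdb = 0.0111802,
                              p_nat = 0.0107,
                              delta_standard_gas = -33.8) {
  stopifnot(r_standard_vpdb > 0, p_nat > 0, p_nat < 1)
  structure(
    list(
      r_standard_vpdb = r_standard_vpdb,
      p_nat = p_nat,
      delta_standard_gas = delta_standard_gas
    ),
    class = "isotope_constants"
  )
}

# Run `expr` under `seed` when non-NULL, restoring RNG state afterwards.
#' @noRd
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}
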