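#' Natural-abundance correction matrix
#'
#' Entry `C[i+1, j+1]` is the probability that a molecule with j tracer-labeled
#' carbons is observed with i heavy atoms in total, i.e. the probability of
#' i - j additional naturally occurring 13C atoms among the remaining
#' `n_carbon - j` positions: `Binomial(n_carbon - j, p_nat)` at `i - j`. The
#' matrix is lower triangular and column-stochastic.
#'
#' @param n_carbon Number of carbon atoms.
#' @param p_nat Natural 13C abundance.
#' @return A `(n_carbon + 1) x (n_carbon + 1)` matrix.
#' @export
correction_matrix <- function(n_carbon, p_nat = 0.0107) {
  stopifnot(n_carbon >= 1, p_nat >= 0, p_nat < 1)
  k <- 0:n_carbon
  outer(k, k, function(i, j) dbinom(i - j, n_carbon - j, p_nat))
}

#' Forward-convolve a tracer envelope with natural abundance
#'
#' The adjoint of [natural_abundance_correct()]: given the distribution of
#' tracer-labeled carbon counts, returns the observable envelope once natural
#' 13C on the unlabeled positions is added.
#'
#' @param f_corr Proportions over tracer label counts (length at most
#'   `n_carbon + 1`; shorter vectors are zero-padded).
#' @param n_carbon Number of carbon atoms.
#' @param p_nat Natural 13C abundance.
#' @return Observable envelope proportions, length `n_carbon + 1`.
#' @export
forward_convolve <- function(f_corr, n_carbon, p_nat = 0.0107) {
  f <- pad_envelope(f_corr, n_carbon)
  as.vector(correction_matrix(n_carbon, p_nat) %*% f)
}

#' Remove natural-abundance 13C from an observed isotopologue envelope
#'
#' Solves `f_obs = C f_corr` for the tracer-only envelope by non-negative
#' least squares (so corrected proportions can never go negative, unlike a
#' plain matrix inversion), then renormalizes to sum to 1. With `p_nat = 0`
#' the correction is the identity.
#'
#' @param f_obs Observed envelope proportions over k = 0.. (length at most
#'   `n_carbon + 1`; missing high-k entries are treated as 0). Must sum to 1.
#' @param n_carbon Number of carbon atoms (>= 1; an envelope with more than
#'   one member needs at least one carbon).
#' @param p_nat Natural 13C abundance.
#' @return Corrected proportions `f_corr`, length `n_carbon + 1`, summing to 1.
#' @export
#' @examples
#' f_obs <- forward_convolve(c(1, 0, 0), 2)
#' natural_abundance_correct(f_obs, 2) # ~ (1, 0, 0)
natural_abundance_correct <- function(f_obs, n_carbon, p_nat = 0.0107) {
  if (n_carbon < 1) {
    if (length(f_obs[f_obs > 0]) > 1) {
      stop("inconsistent carbon count: multi-member envelope with n_carbon = 0")
    }
    stop("n_carbon must be >= 1")
  }
  if (abs(sum(f_obs) - 1) > 1e-6) stop("f_obs must sum to 1")
  if (p_nat == 0) return(pad_envelope(f_obs, n_carbon))
  C <- correction_matrix(n_carbon, p_nat)
  f <- pad_envelope(f_obs, n_carbon)
  sol <- pracma::lsqnonneg(C, f)
  x <- sol$x
  s <- sum(x)
  if (s <= 0) stop("natural-abundance correction produced an all-zero envelope")
  x / s
}

# Pad an envelope with zeros to length n_carbon + 1.
#' @noRd
pad_envelope <- function(f, n_carbon) {
  if (length(f) > n_carbon + 1) {
    if (any(f[-seq_len(n_carbon + 1)] > 0)) {
      stop("envelope has nonzero entries beyond k = n_carbon (length ",
           length(f), " > ", n_carbon + 1, ")")
    }
    f <- f[seq_len(n_carbon + 1)]
  }
  c(f, rep(0, n_carbon + 1 - length(f)))
}
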