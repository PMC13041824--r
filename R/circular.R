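# Circular statistics for spike phases.

#' Resultant vector length and preferred phase of a phase sample
#'
#' The resultant vector length (RVL) is the modulus of the mean unit phasor,
#' `|sum(exp(1i * theta))| / n`, ranging from 0 (uniform phases) to 1 (all
#' phases identical). The preferred phase is the argument of the sum (the
#' circular mean direction), reported in `[0, 2*pi)`.
#'
#' @param phases spike phases in radians.
#' @return list with `rvl`, `pref_phase`, `n`. With zero phases all fields
#'   are `NA` and `n = 0`.
#' @export
resultant_vector_length <- function(phases) {
  phases <- phases[is.finite(phases)]
  n <- length(phases)
  if (n == 0L) return(list(rvl = NA_real_, pref_phase = NA_real_, n = 0L))
  s <- sum(exp(1i * phases))
  list(rvl = Mod(s) / n, pref_phase = Arg(s) %% (2 * pi), n = n)
}

#' Expected RVL of a von Mises distribution
#'
#' Bessel-function ratio `I1(kappa) / I0(kappa)`, the population resultant
#' vector length of a von Mises phase distribution with concentration
#' `kappa`; used as the oracle when checking recovery of planted
#' phase-locked units.
#'
#' @param kappa concentration parameter (>= 0).
#' @return expected RVL in `[0, 1)`.
#' @export
von_mises_rvl <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' Wrap angles into `[0, 2*pi)`
#' @keywords internal
wrap_phase <- function(theta) theta %% (2 * pi)
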