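#' Reaction parameters of a selectable species
#'
#' A species in the selection pool is characterised by an amplitude `A`, the
#' maximum fraction of its copies that ever react (misfolded copies never do),
#' and a first-order rate constant `k` expressed relative to the reference
#' catalyst rate, so the best catalyst in a pool has `k = 1`. All reaction
#' times are passed as the scaled time `tau` (reaction time multiplied by the
#' reference rate and the substrate concentration), which makes the pair
#' `(A, k)` the complete kinetic description of a species.
#'
#' A background (non-catalytic) sequence is modelled with `A = 1` and a small
#' relative rate, typically `k = 1e-3`: the uncatalysed reaction does not
#' depend on folding, so no amplitude penalty applies.
#'
#' @param A Amplitude, a fraction in (0, 1].
#' @param k Rate relative to the reference catalyst, > 0. `k` may exceed 1
#'   when the species is faster than the nominal reference.
#' @param label Optional species label.
#'
#' @return An object of class `reaction_params`: a list with elements
#'   `label`, `A` and `k`.
#' @examples
#' best <- reaction_params(A = 0.55, k = 1, label = "seq1")
#' reaction_probability(best, tau = 5)
#' @export
reaction_params <- function(A, k, label = NULL) {
  if (!is.numeric(A) || length(A) != 1 || is.na(A) || A <= 0 || A > 1) {
    abort("`A` must be a single number in (0, 1].")
  }
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k <= 0) {
    abort("`k` must be a single positive number.")
  }
  structure(list(label = label, A = A, k = k), class = "reaction_params")
}

#' @export
print.reaction_params <- function(x, ...) {
  cat(sprintf("<reaction_params%s> A = %g, k = %g (relative to reference)\n",
              if (is.null(x$label)) "" else paste0(" ", x$label), x$A, x$k))
  invisible(x)
}

check_tau <- function(tau) {
  if (!is.numeric(tau) || anyNA(tau) || any(tau < 0)) {
    abort("`tau` must be nonnegative (scaled reaction time).")
  }
  tau
}

#' Probability that a species has reacted after scaled time tau
#'
#' For a first-order reaction the fraction of copies of a species that have
#' reacted after scaled time `tau` is `A * (1 - exp(-tau * k))`. The curve
#' rises from 0 and saturates at the amplitude `A`; `tau = Inf` is accepted
#' as a saturation sentinel and returns `A` exactly.
#'
#' The complement is evaluated with [expm1()] so that the small-`tau` limit
#' `A * k * tau` is computed without cancellation, which matters when taking
#' high-stringency (`tau << 1`) limits of enrichment factors.
#'
#' @param params A [reaction_params()] object.
#' @param tau Scaled reaction time(s), >= 0 (vectorised).
#' @return Reaction probability in `[0, A]`, same length as `tau`.
#' @examples
#' reaction_probability(reaction_params(0.55, 1), tau = 5)
#' @export
reaction_probability <- function(params, tau) {
  stopifnot(inherits(params, "reaction_params"))
  check_tau(tau)
  params$A * -expm1(-tau * params$k)
}

#' Combined reaction-and-recovery probability
#'
#' A reacted sequence is recovered from the reacted/unreacted mixture with
#' probability `Q`, so the probability that a copy both reacts and is
#' recovered in a round is `R(tau) = Q * A * (1 - exp(-tau * k))`.
#'
#' @inheritParams reaction_probability
#' @param Q Recovery probability of a reacted sequence, in `[0, 1]`.
#' @return Recovery probability, bounded above by `Q * A`.
#' @examples
#' bg <- reaction_params(A = 1, k = 0.001, label = "background")
#' recovery_probability(bg, Q = 0.2, tau = 5)
#' @export
recovery_probability <- function(params, Q, tau) {
  if (!is.numeric(Q) || length(Q) != 1 || is.na(Q) || Q < 0 || Q > 1) {
    abort("`Q` must be a single probability in [0, 1].")
  }
  Q * reaction_probability(params, tau)
}

#' Per-round enrichment factor of a species
#'
#' The frequency of species i changes across one round by the factor
#' `E_i = R_i / Rbar`, where `R_i` is its reaction-and-recovery probability
#' and `Rbar` the pool mean. `Rbar = 0` means no sequence at all was
#' recovered: the round is degenerate and an error is signalled.
#'
#' @param R_species Recovery probability of the species.
#' @param R_mean Mean recovery probability of the pool, > 0.
#' @return The ratio `R_species / R_mean`.
#' @export
enrichment_factor <- function(R_species, R_mean) {
  if (!is.numeric(R_mean) || anyNA(R_mean) || any(R_mean < 0)) {
    abort("`R_mean` must be a nonnegative number.")
  }
  if (any(R_mean == 0)) {
    abort("degenerate round: mean recovery probability is zero (no sequence recovered).")
  }
  R_species / R_mean
}

#' Maximum attainable enrichment factor
#'
#' In the early rounds, when catalysts are rare, the enrichment factor of a
#' catalyst against the background approaches `A * kcat / kback` as the
#' scaled reaction time tends to zero (highest stringency). This is the hard
#' ceiling on per-round enrichment for given kinetics.
#'
#' @param A Amplitude of the catalyst.
#' @param kcat Catalysed rate (any units).
#' @param kback Background rate in the same units, > 0.
#' @return The ratio `A * kcat / kback`.
#' @examples
#' max_enrichment(A = 0.5, kcat = 1, kback = 1e-3)     # 500
#' max_enrichment(A = 0.5, kcat = 0.02, kback = 1.4e-8) # ~7.1e5
#' @export
max_enrichment <- function(A, kcat, kback) {
  if (!is.numeric(kback) || length(kback) != 1 || is.na(kback) || kback <= 0) {
    abort("`kback` must be a single positive rate.")
  }
  if (!is.numeric(A) || any(A <= 0) || any(A > 1)) {
    abort("`A` must be in (0, 1].")
  }
  A * kcat / kback
}

#' Early-round enrichment factor of the best catalyst
#'
#' While catalysts and artefacts are still rare the pool mean recovery equals
#' the background recovery, so the enrichment factor of the reference
#' catalyst is `Ecat(tau) = A (1 - exp(-tau)) / (1 - exp(-tau kback/kcat))`.
#' It decreases with `tau` and approaches [max_enrichment()] as `tau -> 0`.
#'
#' @param A Catalyst amplitude.
#' @param rate_ratio `kback / kcat`, the background-to-catalyst rate ratio.
#' @param tau Scaled reaction time(s), >= 0.
#' @return Enrichment factor(s).
#' @examples
#' early_round_enrichment(A = 0.5, rate_ratio = 1e-3, tau = 5)
#' @export
early_round_enrichment <- function(A, rate_ratio, tau) {
  check_tau(tau)
  if (rate_ratio <= 0) abort("`rate_ratio` must be positive.")
  A * -expm1(-tau) / -expm1(-tau * rate_ratio)
}

#' Early-round enrichment factor of an artefact
#'
#' An artefact is recovered by the separation step without reacting, with a
#' tau-independent probability `Rart`. Against a rare-catalyst background its
#' enrichment factor is `Rart / (Q (1 - exp(-tau kback/kcat)))`, which grows
#' without bound as the reaction time is shortened: stringent schedules
#' favour artefacts.
#'
#' @param Rart Artefact recovery probability in `[0, 1]`.
#' @param Q Recovery probability of reacted sequences.
#' @param rate_ratio `kback / kcat`.
#' @param tau Scaled reaction time(s), > 0.
#' @return Enrichment factor(s).
#' @export
artefact_enrichment <- function(Rart, Q, rate_ratio, tau) {
  check_tau(tau)
  Rart / (Q * -expm1(-tau * rate_ratio))
}

#' Convert a physical reaction time to scaled time
#'
#' The models work in the dimensionless time `tau = kcat * Csub * t`, where
#' `kcat` is the reference catalyst rate and `Csub` the substrate
#' concentration (set `Csub = 1` for unimolecular reactions such as
#' self-cleavage).
#'
#' @param t Reaction time in physical units.
#' @param kcat Reference rate in inverse time (times concentration) units.
#' @param Csub Substrate concentration; default 1.
#' @return Scaled time `tau`.
#' @export
scaled_time <- function(t, kcat, Csub = 1) {
  if (any(t < 0) || kcat <= 0 || Csub <= 0) {
    abort("`t` must be >= 0 and `kcat`, `Csub` positive.")
  }
  kcat * Csub * t
}
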