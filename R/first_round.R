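#' Probability that a functional sequence survives the first round
#'
#' A functional sequence present at mean copy number `c` in the transcribed
#' pool is recovered at least once with probability `1 - exp(-QA * c)`, the
#' Poisson-limit of sampling `c` copies each surviving independently with
#' probability `QA` (recovery probability times amplitude). With `QA = 1`
#' this is the amplification-only case `1 - exp(-c)`.
#'
#' @param c Mean copy number entering the round, >= 0 (vectorised).
#' @param QA Combined recovery x amplitude probability in `[0, 1]`.
#' @return Survival probability in `[0, 1)`.
#' @examples
#' survival_probability(c = 3, QA = 1)    # ~0.95
#' survival_probability(c = 30, QA = 0.1) # same
#' @export
survival_probability <- function(c, QA = 1) {
  if (any(c < 0)) abort("`c` must be nonnegative.")
  if (any(QA < 0) || any(QA > 1)) abort("`QA` must be in [0, 1].")
  -expm1(-QA * c)
}

#' Smallest mean copy number giving a target survival probability
#'
#' Finds the smallest integer mean copy number `c` for which
#' [survival_probability()] reaches `confidence`. The search is over
#' integers directly rather than taking the ceiling of the real-valued
#' solution, which avoids an off-by-one when `-log(1 - confidence) / QA`
#' lands exactly on an integer.
#'
#' @param confidence Target survival probability, in (0, 1).
#' @param QA Combined recovery x amplitude probability in (0, 1].
#' @return Integer copy number.
#' @examples
#' min_copies_for_confidence(0.95, QA = 0.1) # 30
#' min_copies_for_confidence(0.95, QA = 1)   # 3
#' @export
min_copies_for_confidence <- function(confidence, QA = 1) {
  if (!is.numeric(confidence) || length(confidence) != 1 ||
      is.na(confidence) || confidence <= 0 || confidence >= 1) {
    abort("`confidence` must be a single probability strictly between 0 and 1.")
  }
  if (QA <= 0 || QA > 1) abort("`QA` must be in (0, 1].")
  guess <- max(0L, as.integer(floor(-log1p(-confidence) / QA)) - 2L)
  c_try <- guess
  while (survival_probability(c_try, QA) < confidence) c_try <- c_try + 1L
  as.integer(c_try)
}

#' Mean copy number of a library sequence after amplification
#'
#' If the DNA library holds `n_dna` distinct sequences and `n_rna` RNA
#' molecules enter the first round after PCR and transcription, each library
#' sequence is represented on average `c = n_rna / n_dna` times.
#'
#' @param n_rna Number of RNA molecules entering the first round.
#' @param n_dna Number of distinct DNA sequences in the library, > 0.
#' @return The ratio `n_rna / n_dna`.
#' @examples
#' mean_copy_number(5.3e15, 1.6e14) # ~33
#' @export
mean_copy_number <- function(n_rna, n_dna) {
  if (any(n_dna <= 0)) abort("`n_dna` must be positive.")
  if (any(n_rna < 0)) abort("`n_rna` must be nonnegative.")
  n_rna / n_dna
}

check_NR <- function(N, R) {
  if (!is.numeric(N) || length(N) != 1 || is.na(N) || N < 0 || N != floor(N)) {
    abort("`N` must be a single nonnegative integer.")
  }
  if (!is.numeric(R) || length(R) != 1 || is.na(R) || R < 0 || R > 1) {
    abort("`R` must be a single probability in [0, 1].")
  }
}

#' Distribution of the number of copies recovered in one round
#'
#' When `N` copies of a sequence enter a round and each reacts and is
#' recovered independently with probability `R`, the number recovered is
#' binomial(N, R). Returned as a tibble so it pipes straight into dplyr and
#' ggplot2.
#'
#' @param N Number of copies entering the round.
#' @param R Per-copy reaction-and-recovery probability.
#' @return A tibble with columns `n_recovered` (0..N) and `probability`.
#' @examples
#' recovery_count_pmf(N = 30, R = 0.1)
#' @export
recovery_count_pmf <- function(N, R) {
  check_NR(N, R)
  tibble(n_recovered = 0:N, probability = dbinom(0:N, N, R))
}

#' Most likely number of recovered copies
#'
#' The mode of the binomial(N, R) recovery distribution. When the mode drops
#' to zero the most likely single-round outcome is to lose the sequence
#' entirely even though the mean `N * R` may still be well above zero — the
#' key first-round hazard of over-stringent (small-tau) schedules.
#'
#' Ties between two adjacent equally likely counts (which occur when
#' `(N + 1) * R` is an integer) are broken toward the smaller count, the
#' conservative choice when the mode is used to flag loss risk.
#'
#' @inheritParams recovery_count_pmf
#' @return Integer mode of the distribution.
#' @examples
#' recovery_count_mode(30, 0.1)   # 3
#' recovery_count_mode(30, 0.001) # 0
#' @export
recovery_count_mode <- function(N, R) {
  check_NR(N, R)
  p <- dbinom(0:N, N, R)
  top <- max(p)
  as.integer(which(p >= top * (1 - 1e-12))[1] - 1L)
}

#' Draw the number of recovered copies
#'
#' A reproducible binomial draw of the number of copies recovered from `N`
#' entering a round. When `seed` is given the draw runs in an isolated RNG
#' state (via [withr::with_seed()]) so it neither perturbs nor is perturbed
#' by other random draws in the session.
#'
#' @inheritParams recovery_count_pmf
#' @param n Number of draws.
#' @param seed Optional integer seed for an isolated, reproducible stream.
#' @return Integer vector of length `n`.
#' @export
sample_recovery_count <- function(N, R, n = 1, seed = NULL) {
  check_NR(N, R)
  draw <- function() rbinom(n, N, R)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Realised enrichment factor from a stochastic recovery count
#'
#' When only `n_recovered` of the `N` entering copies come through, the
#' realised enrichment factor is `n_recovered / (N * R_back)` (almost all
#' other sequences are background early on). Setting `n_recovered` to its
#' mean `N * R_cat` recovers the deterministic ratio `R_cat / R_back`; a
#' draw of zero means the sequence is lost and the factor is 0.
#'
#' @param n_recovered Number of copies recovered, 0..N.
#' @param N Number of copies entering, > 0.
#' @param R_back Background recovery probability, > 0.
#' @return Realised enrichment factor.
#' @export
stochastic_enrichment <- function(n_recovered, N, R_back) {
  if (any(N <= 0)) abort("`N` must be positive.")
  if (any(R_back <= 0)) abort("`R_back` must be positive.")
  if (any(n_recovered < 0) || any(n_recovered > N)) {
    abort("`n_recovered` must lie in 0..N.")
  }
  n_recovered / (N * R_back)
}

#' First-round enrichment summary across reaction times
#'
#' Tabulates, for each scaled time `tau`, the mean-based, mode-based and
#' (optionally) sampled enrichment factor of a catalyst entering with `N`
#' copies against a background, together with the survival probability.
#' This is the working view of the first-round trade-off: stringent
#' schedules maximise the mean enrichment but collapse the mode to zero.
#'
#' @param tau Vector of scaled reaction times.
#' @param N Copies of the catalyst entering the round.
#' @param A Catalyst amplitude.
#' @param Q Recovery probability.
#' @param kback Background rate relative to the catalyst.
#' @param seed Optional seed; when given, a sampled `n_recovered` column is
#'   added with one binomial draw per `tau`.
#' @return A tibble with one row per `tau`: `tau`, `R_cat`, `R_back`,
#'   `survival`, `E_mean`, `E_mode`, and with a seed also `n_recovered`,
#'   `E_sampled`.
#' @export
first_round_summary <- function(tau, N, A, Q, kback = 0.001, seed = NULL) {
  cat_p <- reaction_params(A = A, k = 1)
  back_p <- reaction_params(A = 1, k = kback)
  res <- purrr::map_dfr(tau, function(tt) {
    Rcat <- recovery_probability(cat_p, Q, tt)
    Rback <- recovery_probability(back_p, Q, tt)
    tibble(
      tau = tt, R_cat = Rcat, R_back = Rback,
      survival = survival_probability(N, QA = Rcat),
      E_mean = if (Rback > 0) Rcat / Rback else NA_real_,
      E_mode = if (Rback > 0) {
        stochastic_enrichment(recovery_count_mode(N, Rcat), N, Rback)
      } else NA_real_
    )
  })
  if (!is.null(seed)) {
    draws <- withr::with_seed(seed, vapply(res$R_cat, function(r) {
      rbinom(1, N, r)
    }, integer(1)))
    res$n_recovered <- draws
    res$E_sampled <- ifelse(res$R_back > 0,
                            draws / (N * res$R_back), NA_real_)
  }
  res
}
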