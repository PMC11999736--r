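#' Assemble a pool of cofactor-dependent species
#'
#' For selections targeting a cofactor-dependent ribozyme, each species is
#' classed by how it behaves without the cofactor:
#' \describe{
#'   \item{constitutive}{active regardless of the cofactor — same `(A, k)`
#'     in both steps; the undesired outcome.}
#'   \item{strict}{the desired species — fully dependent, behaving as a
#'     background sequence without the cofactor.}
#'   \item{leaky}{dependent but with residual activity: rate multiplied by
#'     `leak` (default 1/2) without the cofactor, same amplitude.}
#' }
#' `A` and `k` are the with-cofactor parameters; rates are relative to the
#' fastest species with cofactor.
#'
#' @param species Data frame with columns `label`, `class` (one of
#'   `"constitutive"`, `"strict"`, `"leaky"`), `A`, `k`, `p0`, and
#'   optionally `leak` (per-species residual-rate factor).
#' @inheritParams species_pool
#' @param leak Default residual-rate factor for leaky species.
#' @return An object of class `cofactor_pool`.
#' @examples
#' pool <- cofactor_pool(tibble::tibble(
#'   label = c("seq1", "seq2", "seq3"),
#'   class = c("constitutive", "strict", "leaky"),
#'   A = 0.5, k = c(1, 0.8, 0.8), p0 = 1e-14
#' ))
#' @export
cofactor_pool <- function(species, Q = 0.2, kback = 0.001, leak = 0.5) {
  species <- as_tibble(species)
  needed <- c("label", "class", "A", "k", "p0")
  if (!all(needed %in% names(species))) {
    abort(paste0("`species` must have columns ", paste(needed, collapse = ", "), "."))
  }
  ok <- c("constitutive", "strict", "leaky")
  if (!all(species$class %in% ok)) {
    abort(paste0("`class` must be one of: ", paste(ok, collapse = ", "), "."))
  }
  if (!"leak" %in% names(species)) species$leak <- leak
  species$leak[is.na(species$leak)] <- leak
  if (any(species$leak < 0) || any(species$leak > 1)) {
    abort("`leak` factors must lie in [0, 1].")
  }
  base <- species_pool(species[c("label", "A", "k", "p0")], Q = Q, kback = kback)
  base$species <- species
  class(base) <- c("cofactor_pool", class(base))
  base
}

without_cofactor_recovery <- function(class, A, k, leak, Q, kback, tau) {
  switch(class,
    constitutive = Q * A * -expm1(-tau * k),
    strict       = Q * -expm1(-tau * kback),
    leaky        = Q * A * -expm1(-tau * k * leak),
    abort(sprintf("unknown cofactor class '%s'.", class))
  )
}

#' Probability of passing a counter-selection round
#'
#' A counter-selected round has two steps: a reaction without the cofactor
#' whose *recovered* sequences are discarded, then a positive reaction with
#' the cofactor whose recovered sequences advance. The per-round pass
#' probability is therefore
#' `(1 - R_without(tau_counter)) * R_with(tau_positive)`, and the two steps
#' may use different reaction times. Because `Q` and `A` are below 1, a
#' constitutively active sequence still slips past the counter step with
#' probability `1 - Q A (1 - exp(-tau k))`, which is why counter-selection
#' is intrinsically weak.
#'
#' @param class One of `"constitutive"`, `"strict"`, `"leaky"`, or
#'   `"background"`.
#' @param A,k With-cofactor amplitude and relative rate (ignored for
#'   `"background"`).
#' @param Q Recovery probability of a reacted sequence.
#' @param tau_counter Scaled time of the counter (no-cofactor) step.
#' @param tau_positive Scaled time of the positive (with-cofactor) step.
#' @param kback Background relative rate.
#' @param leak Residual-rate factor without cofactor for `"leaky"`.
#' @return Pass probability in `[0, 1]`.
#' @examples
#' counter_selection_pass_probability("strict", A = 0.5, k = 0.8, Q = 0.2,
#'                                    tau_counter = 5, tau_positive = 5)
#' @export
counter_selection_pass_probability <- function(class, A = NULL, k = NULL,
                                               Q = 0.2, tau_counter = 5,
                                               tau_positive = 5,
                                               kback = 0.001, leak = 0.5) {
  check_tau(tau_counter); check_tau(tau_positive)
  if (class == "background") {
    r_wo <- Q * -expm1(-tau_counter * kback)
    r_wi <- Q * -expm1(-tau_positive * kback)
  } else {
    if (is.null(A) || is.null(k)) abort("`A` and `k` required for catalyst classes.")
    r_wo <- without_cofactor_recovery(class, A, k, leak, Q, kback, tau_counter)
    r_wi <- Q * A * -expm1(-tau_positive * k)
  }
  (1 - r_wo) * r_wi
}

#' Run a multi-round counter-selection
#'
#' Iterates [round_update()] with the per-round recovery probabilities
#' replaced by counter-selection pass probabilities
#' ([counter_selection_pass_probability()]). The counter and positive steps
#' take their reaction times from separate schedules, so stringency can be
#' raised in one step but not the other.
#'
#' @param pool A [cofactor_pool()].
#' @param schedule_counter,schedule_positive [tau_schedule()]s (or numeric
#'   vectors) for the two steps.
#' @param n_rounds Number of rounds; defaults to the shorter schedule.
#' @return A `selex_trajectory` (kind `"counter-selection"`).
#' @export
run_counter_selection <- function(pool, schedule_counter, schedule_positive,
                                  n_rounds = min(length(schedule_counter),
                                                 length(schedule_positive))) {
  stopifnot(inherits(pool, "cofactor_pool"))
  tc <- as.numeric(schedule_counter)[seq_len(n_rounds)]
  tp <- as.numeric(schedule_positive)[seq_len(n_rounds)]
  if (anyNA(tc) || anyNA(tp)) abort("schedules shorter than `n_rounds`.")
  sp <- pool$species
  p <- pool_init_freqs(pool)
  rows <- vector("list", n_rounds + 1)
  rows[[1]] <- tibble(round = 0L, tau = NA_real_, species = names(p),
                      frequency = unname(p), enrichment = NA_real_)
  for (n in seq_len(n_rounds)) {
    R_cat <- purrr::pmap_dbl(
      sp[c("class", "A", "k", "leak")],
      function(class, A, k, leak) {
        counter_selection_pass_probability(class, A, k, Q = pool$Q,
                                           tau_counter = tc[n],
                                           tau_positive = tp[n],
                                           kback = pool$kback, leak = leak)
      }
    )
    R <- c(R_cat, counter_selection_pass_probability(
      "background", Q = pool$Q, tau_counter = tc[n], tau_positive = tp[n],
      kback = pool$kback))
    p_new <- round_update(p, R)
    E <- ifelse(p > 0, unname(p_new) / unname(p), NA_real_)
    p <- setNames(as.numeric(p_new), names(p))
    rows[[n + 1]] <- tibble(round = n, tau = tp[n], species = names(p),
                            frequency = unname(p), enrichment = unname(E))
  }
  new_trajectory(dplyr::bind_rows(rows), pool, tp, kind = "counter-selection")
}
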