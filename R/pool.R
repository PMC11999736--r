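#' Assemble a selection pool from a species table
#'
#' Builds the pool object driving multi-round selection. The species table
#' lists the catalysts with their amplitudes, relative rates and initial
#' frequencies; a background species (amplitude 1, rate `kback`) absorbs the
#' remaining frequency, and an optional artefact — a sequence recovered by
#' the separation step without reacting — is carried with a tau-independent
#' recovery probability `Rart`.
#'
#' @param species A data frame with columns `label`, `A`, `k` and `p0`
#'   (initial frequency). Rates are relative to the reference catalyst.
#' @param Q Recovery probability of a reacted sequence (default 0.2, a
#'   typical net efficiency of the processing and purification steps).
#' @param kback Background rate relative to the reference catalyst
#'   (default 1e-3).
#' @param artefact Optional list or named vector with `Rart` and `p0`.
#' @return An object of class `species_pool`.
#' @examples
#' pool <- species_pool(tibble::tibble(
#'   label = c("seq1", "seq2", "seq3", "seq4"),
#'   A = c(0.55, 0.5, 0.7, 0.5),
#'   k = c(1.0, 0.8, 0.6, 0.5),
#'   p0 = 1e-14
#' ))
#' pool
#' @export
species_pool <- function(species, Q = 0.2, kback = 0.001, artefact = NULL) {
  species <- as_tibble(species)
  needed <- c("label", "A", "k", "p0")
  if (!all(needed %in% names(species))) {
    abort(paste0("`species` must have columns ", paste(needed, collapse = ", "), "."))
  }
  if (anyDuplicated(species$label)) abort("species labels must be unique.")
  if (any(species$A <= 0) || any(species$A > 1)) abort("amplitudes must lie in (0, 1].")
  if (any(species$k <= 0)) abort("rates must be positive.")
  if (any(species$p0 < 0)) abort("initial frequencies must be nonnegative.")
  if (Q <= 0 || Q > 1) abort("`Q` must be in (0, 1].")
  if (kback <= 0) abort("`kback` must be positive.")
  if (!is.null(artefact)) {
    artefact <- as.list(artefact)
    if (is.null(artefact$Rart) || is.null(artefact$p0)) {
      abort("`artefact` needs elements `Rart` and `p0`.")
    }
    if (artefact$Rart < 0 || artefact$Rart > 1) abort("`Rart` must be in [0, 1].")
  }
  p_named <- sum(species$p0) + if (is.null(artefact)) 0 else artefact$p0
  if (p_named > 1) abort("initial frequencies exceed 1; nothing left for background.")
  structure(
    list(species = species, Q = Q, kback = kback, artefact = artefact,
         p_back0 = 1 - p_named),
    class = "species_pool"
  )
}

#' @export
print.species_pool <- function(x, ...) {
  cat(sprintf("<species_pool> %d catalyst(s), Q = %g, kback = %g\n",
              nrow(x$species), x$Q, x$kback))
  print(x$species)
  if (!is.null(x$artefact)) {
    cat(sprintf("artefact: Rart = %g, p0 = %g\n", x$artefact$Rart, x$artefact$p0))
  }
  cat(sprintf("background p0 = %g\n", x$p_back0))
  invisible(x)
}

pool_labels <- function(pool) {
  c(pool$species$label,
    if (!is.null(pool$artefact)) "artefact",
    "background")
}

pool_init_freqs <- function(pool) {
  setNames(
    c(pool$species$p0,
      if (!is.null(pool$artefact)) pool$artefact$p0,
      pool$p_back0),
    pool_labels(pool)
  )
}

#' Stringency schedule of scaled reaction times
#'
#' Either an explicit per-round vector of `tau` values, or the standard
#' stepped schedule: `tau0` held for the rounds before `from_round`, then
#' divided by `decay` each subsequent round. The shorthand is expanded once
#' into an explicit per-round vector.
#'
#' @param taus Explicit vector of per-round scaled times (overrides the
#'   shorthand when given).
#' @param tau0 Initial scaled time (default 5, long enough that reaction
#'   curves approach saturation).
#' @param decay Factor by which `tau` shrinks per round once decay starts
#'   (default 5); `decay = 1` gives a constant schedule.
#' @param from_round First round at which `tau` is divided by `decay`
#'   (default 6).
#' @param n_rounds Number of rounds to expand the shorthand to.
#' @return Numeric vector of class `tau_schedule`, one `tau` per round.
#' @examples
#' tau_schedule(n_rounds = 10)                # 5 5 5 5 5 1 0.2 ...
#' tau_schedule(n_rounds = 10, decay = 1)     # constant 5
#' tau_schedule(taus = c(5, 5, 1, 0.5))
#' @export
tau_schedule <- function(taus = NULL, tau0 = 5, decay = 5, from_round = 6,
                         n_rounds = NULL) {
  if (is.null(taus)) {
    if (is.null(n_rounds)) abort("give `n_rounds` to expand the schedule.")
    if (tau0 < 0 || decay <= 0 || from_round < 1) {
      abort("need tau0 >= 0, decay > 0, from_round >= 1.")
    }
    rounds <- seq_len(n_rounds)
    taus <- tau0 / decay^pmax(0, rounds - (from_round - 1))
  } else {
    if (any(taus < 0)) abort("all `tau` values must be nonnegative.")
    if (!is.null(n_rounds) && length(taus) < n_rounds) {
      abort("explicit schedule shorter than `n_rounds`.")
    }
  }
  structure(as.numeric(taus), class = c("tau_schedule", "numeric"))
}

#' @export
print.tau_schedule <- function(x, ...) {
  cat("<tau_schedule> ", paste(signif(unclass(x), 4), collapse = " "), "\n")
  invisible(x)
}
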