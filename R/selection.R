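#' Per-species reaction-and-recovery probabilities at one reaction time
#'
#' Evaluates `R_i(tau) = Q A_i (1 - exp(-tau k_i))` for every catalyst in the
#' pool, `R_back(tau) = Q (1 - exp(-tau kback))` for the background, and the
#' tau-independent `Rart` for the artefact if present.
#'
#' @param pool A [species_pool()].
#' @param tau Scaled reaction time, >= 0.
#' @param Q Recovery probability; defaults to the pool's.
#' @return Named numeric vector over the pool's species (catalysts, then
#'   artefact if any, then background).
#' @export
species_recovery_probabilities <- function(pool, tau, Q = pool$Q) {
  stopifnot(inherits(pool, "species_pool"))
  check_tau(tau)
  R <- Q * pool$species$A * -expm1(-tau * pool$species$k)
  out <- c(R,
           if (!is.null(pool$artefact)) pool$artefact$Rart,
           Q * -expm1(-tau * pool$kback))
  setNames(out, pool_labels(pool))
}

#' Advance the pool frequencies by one selection round
#'
#' One round multiplies each frequency by its recovery probability and
#' renormalises: `p_i(n) = p_i(n-1) R_i / Rbar` with
#' `Rbar = sum_i p_i(n-1) R_i`. If `Rbar` is zero nothing was recovered
#' and the round is degenerate.
#'
#' @param freqs Frequency vector summing to 1.
#' @param R Recovery-probability vector, same length.
#' @return Updated frequency vector (sums to 1), with attribute `R_mean`.
#' @examples
#' round_update(c(0.5, 0.5), c(0.2, 0.1)) # 2/3, 1/3
#' @export
round_update <- function(freqs, R) {
  if (length(freqs) != length(R)) abort("`freqs` and `R` lengths differ.")
  if (any(freqs < 0) || any(R < 0)) abort("frequencies and probabilities must be >= 0.")
  if (abs(sum(freqs) - 1) > 1e-9) abort("`freqs` must sum to 1.")
  R_mean <- sum(freqs * R)
  if (R_mean == 0) {
    abort("degenerate round: mean recovery probability is zero (no sequence recovered).")
  }
  out <- freqs * R / R_mean
  attr(out, "R_mean") <- R_mean
  out
}

new_trajectory <- function(tbl, pool, taus, kind = "selection") {
  structure(
    list(frequencies = tbl, pool = pool,
         schedule = as.numeric(taus), kind = kind),
    class = "selex_trajectory"
  )
}

#' Run a deterministic multi-round selection
#'
#' Iterates [round_update()] for `n_rounds` rounds with the per-round scaled
#' reaction time taken from the schedule. Frequencies evolve
#' deterministically — appropriate from the second round on, once every
#' surviving sequence is present in many copies.
#'
#' @param pool A [species_pool()].
#' @param schedule A [tau_schedule()] (or plain numeric vector of per-round
#'   tau values).
#' @param n_rounds Number of rounds; defaults to the schedule length.
#' @return A `selex_trajectory` object. Its `frequencies` element (also
#'   available via [tidy()]) is a tibble with one row per round x species:
#'   columns `round` (0 = initial pool), `tau`, `species`, `frequency`,
#'   `enrichment`.
#' @examples
#' pool <- species_pool(tibble::tibble(
#'   label = paste0("seq", 1:4),
#'   A = c(0.55, 0.5, 0.7, 0.5), k = c(1, 0.8, 0.6, 0.5), p0 = 1e-14
#' ))
#' traj <- run_selection(pool, tau_schedule(n_rounds = 20, decay = 1))
#' detect_dominant(traj)
#' @export
run_selection <- function(pool, schedule, n_rounds = length(schedule)) {
  stopifnot(inherits(pool, "species_pool"))
  taus <- as.numeric(schedule)
  if (length(taus) < n_rounds) abort("schedule shorter than `n_rounds`.")
  taus <- taus[seq_len(n_rounds)]
  p <- pool_init_freqs(pool)
  rows <- vector("list", n_rounds + 1)
  rows[[1]] <- tibble(round = 0L, tau = NA_real_, species = names(p),
                      frequency = unname(p), enrichment = NA_real_)
  for (n in seq_len(n_rounds)) {
    R <- species_recovery_probabilities(pool, taus[n])
    p_new <- round_update(p, R)
    E <- ifelse(p > 0, unname(p_new) / unname(p), NA_real_)
    p <- setNames(as.numeric(p_new), names(p))
    rows[[n + 1]] <- tibble(round = n, tau = taus[n], species = names(p),
                            frequency = unname(p), enrichment = unname(E))
  }
  new_trajectory(dplyr::bind_rows(rows), pool, taus)
}

#' @export
print.selex_trajectory <- function(x, ...) {
  n_rounds <- max(x$frequencies$round)
  cat(sprintf("<selex_trajectory> %s, %d rounds, %d species\n",
              x$kind, n_rounds, length(unique(x$frequencies$species))))
  fin <- dplyr::filter(x$frequencies, .data$round == n_rounds)
  fin <- dplyr::arrange(fin, dplyr::desc(.data$frequency))
  cat("final frequencies:\n")
  print(dplyr::select(fin, "species", "frequency"))
  invisible(x)
}

#' @describeIn run_selection Tidy the per-round frequencies into a tibble.
#' @param x A `selex_trajectory`.
#' @param ... Unused.
#' @export
tidy.selex_trajectory <- function(x, ...) x$frequencies

#' @describeIn run_selection One-row summary: rounds run, dominant species
#'   and its final frequency, number of order crossings among catalysts.
#' @export
glance.selex_trajectory <- function(x, ...) {
  n_rounds <- max(x$frequencies$round)
  fin <- dplyr::filter(x$frequencies, .data$round == n_rounds)
  top <- fin[which.max(fin$frequency), ]
  tibble(
    n_rounds = n_rounds,
    n_species = nrow(fin),
    dominant = top$species,
    dominant_frequency = top$frequency,
    n_crossings = nrow(detect_crossings(x))
  )
}

#' @describeIn run_selection Log-frequency trajectories, one line per
#'   species.
#' @param object A `selex_trajectory`.
#' @export
autoplot.selex_trajectory <- function(object, ...) {
  dat <- dplyr::filter(object$frequencies, .data$frequency > 0)
  ggplot2::ggplot(dat, ggplot2::aes(.data$round, .data$frequency,
                                    colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "selection round", y = "frequency",
                  title = sprintf("%s trajectory", object$kind)) +
    ggplot2::theme_minimal()
}

#' Species with the highest frequency at a given round
#'
#' @param trajectory A `selex_trajectory`.
#' @param round Round to inspect; defaults to the last.
#' @param tol Relative tolerance below which the top two frequencies are
#'   declared tied (an error, since "dominant" is then meaningless).
#' @return The species label (character scalar).
#' @export
detect_dominant <- function(trajectory, round = NULL, tol = 1e-9) {
  stopifnot(inherits(trajectory, "selex_trajectory"))
  if (is.null(round)) round <- max(trajectory$frequencies$round)
  if (!round %in% trajectory$frequencies$round) abort("`round` outside trajectory.")
  fin <- dplyr::filter(trajectory$frequencies, .data$round == !!round)
  ord <- order(fin$frequency, decreasing = TRUE)
  top <- fin$frequency[ord[1]]
  second <- if (nrow(fin) > 1) fin$frequency[ord[2]] else -Inf
  if (is.finite(second) && top > 0 && (top - second) <= tol * top) {
    abort("no dominant species: top frequencies are tied.")
  }
  fin$species[ord[1]]
}

#' Rounds at which catalyst frequency curves cross
#'
#' With a constant reaction time and equal starting frequencies, pairwise
#' frequency ratios are geometric in the round number and the curves never
#' cross; a decreasing-tau schedule can reorder the catalysts. Crossings of
#' observed cluster frequencies are therefore a signature of changing
#' stringency (or, in the mutation models, of changing cluster fitness).
#'
#' @param trajectory A `selex_trajectory`.
#' @param species Labels to consider; defaults to the catalysts (background
#'   and artefact excluded).
#' @return A tibble with columns `round` (the round after which the order of
#'   the pair differs from the round before), `species_a`, `species_b`.
#'   Zero rows when no crossing occurs.
#' @export
detect_crossings <- function(trajectory, species = NULL) {
  stopifnot(inherits(trajectory, "selex_trajectory"))
  tbl <- trajectory$frequencies
  if (is.null(species)) {
    species <- setdiff(unique(tbl$species), c("background", "artefact"))
  }
  if (length(species) < 2) {
    return(tibble(round = integer(), species_a = character(),
                  species_b = character()))
  }
  wide <- tidyr::pivot_wider(tbl[tbl$species %in% species, c("round", "species", "frequency")],
                             names_from = "species", values_from = "frequency")
  wide <- dplyr::arrange(wide, .data$round)
  out <- list()
  pairs <- utils::combn(species, 2, simplify = FALSE)
  for (pr in pairs) {
    d <- wide[[pr[1]]] - wide[[pr[2]]]
    sgn <- sign(d)
    flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    if (length(flips)) {
      out[[length(out) + 1]] <- tibble(round = wide$round[flips + 1],
                                       species_a = pr[1], species_b = pr[2])
    }
  }
  if (length(out)) dplyr::bind_rows(out) else {
    tibble(round = integer(), species_a = character(), species_b = character())
  }
}
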