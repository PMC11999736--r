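#' Mutation model for cluster evolution
#'
#' During the PCR amplification between rounds, each recovered sequence is
#' copied `C = lambda^ncyc` times with a per-base error rate `u`. A copy of
#' a sequence carrying `m1` mismatched conserved sites acquires a beneficial
#' mutation (one of the mismatches corrected, no new error elsewhere) with
#' probability roughly `m1 * u / 3`. Whether beneficial mutants actually
#' arise in a cluster depends on its abundance: the expected number of
#' beneficial copies is `p * Ntot * C * pben`, so mutation flow switches on
#' once the cluster frequency exceeds `pmin = 1 / (Ntot * C * pben)`.
#'
#' Either supply `pmin` directly (the worked default is `1e-10` with
#' `pben = 1e-4`), or supply `Ntot` and let `pmin` be derived.
#'
#' @param pben Per-copy beneficial mutation probability (default 1e-4).
#' @param pmin Cluster-frequency threshold gating mutation flow (default
#'   1e-10). Overridden by the derived value when `Ntot` is given.
#' @param u Per-base error rate per copying (default 1e-5, typical of Taq).
#' @param lambda Per-cycle amplification factor (default 1.6; 2 is perfect
#'   doubling).
#' @param ncyc PCR cycles per round (default 15, giving C ~ 1153 with the
#'   default lambda — a realistic per-round multiplication of ~1000).
#' @param Ntot Total sequences recovered per round; when given,
#'   `pmin = mutation_threshold(Ntot, lambda^ncyc, pben)`.
#' @return An object of class `mutation_model`.
#' @examples
#' mutation_model()
#' mutation_model(Ntot = 1e10)
#' @export
mutation_model <- function(pben = 1e-4, pmin = 1e-10, u = 1e-5, lambda = 1.6,
                           ncyc = 15, Ntot = NULL) {
  if (pben < 0 || pben > 1) abort("`pben` must be a probability.")
  if (u <= 0 || u >= 1) abort("`u` must lie strictly between 0 and 1.")
  if (lambda <= 1) abort("`lambda` must exceed 1.")
  if (ncyc < 0) abort("`ncyc` must be nonnegative.")
  if (!is.null(Ntot)) {
    pmin <- mutation_threshold(Ntot, amplification_factor(lambda, ncyc), pben)
  }
  if (pmin <= 0) abort("`pmin` must be positive.")
  structure(list(pben = pben, pmin = pmin, u = u, lambda = lambda,
                 ncyc = ncyc, Ntot = Ntot),
            class = "mutation_model")
}

#' @export
print.mutation_model <- function(x, ...) {
  cat(sprintf("<mutation_model> pben = %g, pmin = %g, u = %g, C = %g\n",
              x$pben, x$pmin, x$u, amplification_factor(x$lambda, x$ncyc)))
  invisible(x)
}

#' Probability that a copy acquires a beneficial mutation
#'
#' For a sequence with `m1` of its `s` conserved sites mismatched, a copy is
#' improved when exactly one of the `m1` bad sites mutates to the required
#' base (probability `u/3` each) and no other site mutates:
#' `pben = m1 (u/3) (1 - u/3)^(m1-1) (1 - u)^(s-m1)`, which is `m1 u / 3`
#' to first order in `u`.
#'
#' @param m1 Number of mismatched conserved sites (vectorised).
#' @param u Per-base error rate.
#' @param s Total number of conserved sites.
#' @return Probability.
#' @examples
#' beneficial_mutation_probability(1, u = 1e-5, s = 13)
#' @export
beneficial_mutation_probability <- function(m1, u, s) {
  if (any(m1 < 0) || any(m1 > s)) abort("need 0 <= m1 <= s.")
  if (u <= 0 || u >= 1) abort("`u` must lie strictly between 0 and 1.")
  m1 * (u / 3) * (1 - u / 3)^(pmax(m1 - 1, 0)) * (1 - u)^(s - m1)
}

#' Net amplification factor of one PCR stage
#'
#' @param lambda Per-cycle amplification factor.
#' @param ncyc Number of cycles.
#' @return `lambda^ncyc` (e.g. 2^10 = 1024, 1.6^15 ~ 1153).
#' @export
amplification_factor <- function(lambda, ncyc) {
  if (lambda <= 0) abort("`lambda` must be positive.")
  if (ncyc < 0) abort("`ncyc` must be nonnegative.")
  lambda^ncyc
}

#' Cluster-frequency threshold for mutation onset
#'
#' @param Ntot Total sequences recovered per round.
#' @param C Net amplification factor per round.
#' @param pben Per-copy beneficial mutation probability.
#' @return `1 / (Ntot * C * pben)`; infinite when `pben = 0` (mutation
#'   never triggers).
#' @export
mutation_threshold <- function(Ntot, C, pben) {
  if (Ntot <= 0 || C <= 0 || pben < 0) {
    abort("`Ntot` and `C` must be positive and `pben` nonnegative.")
  }
  if (pben == 0) return(Inf)
  1 / (Ntot * C * pben)
}

#' Draw per-cluster kinetic parameters
#'
#' Each of `n_clusters` founder lineages holds three representative
#' sequences at mutational distance m = 0, 1, 2 from its optimum. The
#' optimal rate `k0` is uniform on `k0_range` and the optimal amplitude
#' `A0` uniform on `A0_range`; each extra mutation divides the rate by a
#' uniform factor on `z_range` and subtracts a uniform amount on `a_range`
#' from the amplitude (floored just above zero so amplitudes stay valid).
#'
#' @param n_clusters Number of clusters.
#' @param seed Optional seed for a reproducible, isolated draw.
#' @param k0_range,A0_range Ranges for the optimal rate and amplitude.
#' @param z_range Range of the per-mutation rate-division factor.
#' @param a_range Range of the per-mutation amplitude decrement.
#' @return An object of class `cluster_params`: a tibble with one row per
#'   cluster and columns `cluster`, `k0`, `k1`, `k2`, `A0`, `A1`, `A2`.
#' @examples
#' generate_clusters(50, seed = 1)
#' @export
generate_clusters <- function(n_clusters, seed = NULL,
                              k0_range = c(0.5, 1.0), A0_range = c(0.8, 1.0),
                              z_range = c(2, 4), a_range = c(0, 0.2)) {
  if (n_clusters < 1) abort("`n_clusters` must be at least 1.")
  draw <- function() {
    runif2 <- function(rg) stats::runif(n_clusters, rg[1], rg[2])
    k0 <- runif2(k0_range)
    k1 <- k0 / runif2(z_range)
    k2 <- k1 / runif2(z_range)
    A0 <- runif2(A0_range)
    A1 <- pmax(A0 - runif2(a_range), 1e-6)
    A2 <- pmax(A1 - runif2(a_range), 1e-6)
    tibble(cluster = seq_len(n_clusters),
           k0 = k0, k1 = k1, k2 = k2, A0 = A0, A1 = A1, A2 = A2)
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(out, class = c("cluster_params", class(out)))
}

cluster_matrices <- function(params) {
  k <- unname(as.matrix(params[c("k0", "k1", "k2")]))
  A <- unname(as.matrix(params[c("A0", "A1", "A2")]))
  list(k = k, A = A)
}

#' One round of cluster selection with gated beneficial mutations
#'
#' The round has two stages. Selection: every level of every cluster (and
#' the background) is reweighted by its recovery probability,
#' `p'_im = p_im R_im / Rbar`. Mutation: within each cluster, a fraction
#' `pben` of the level-2 mass moves to level 1 and of the level-1 mass to
#' level 0 — but only for levels whose post-selection frequency exceeds
#' `pmin`, since below that abundance no beneficial mutant is expected among
#' the copies made. Gating applies to the post-selection (primed)
#' frequencies. Total frequency is conserved exactly: the mutation stage is
#' a within-cluster stochastic reshuffle.
#'
#' @param p Matrix of cluster frequencies, `n_clusters` x 3 (levels m = 0,
#'   1, 2).
#' @param p_back Background frequency.
#' @param params A [generate_clusters()] result.
#' @param tau Scaled reaction time of the round.
#' @param Q Recovery probability.
#' @param kback Background relative rate.
#' @param model A [mutation_model()].
#' @return List with the updated `p` matrix, `p_back`, and the round's
#'   `R_mean`.
#' @export
cluster_round_update <- function(p, p_back, params, tau, Q = 0.2,
                                 kback = 0.001, model = mutation_model()) {
  stopifnot(inherits(params, "cluster_params"), inherits(model, "mutation_model"))
  check_tau(tau)
  km <- cluster_matrices(params)
  R <- Q * km$A * -expm1(-tau * km$k)
  R_back <- Q * -expm1(-tau * kback)
  R_mean <- sum(p * R) + p_back * R_back
  if (R_mean == 0) {
    abort("degenerate round: mean recovery probability is zero (no sequence recovered).")
  }
  pp <- p * R / R_mean
  p_back2 <- p_back * R_back / R_mean
  eps1 <- model$pben * (pp[, 2] > model$pmin)
  eps2 <- model$pben * (pp[, 3] > model$pmin)
  out <- pp
  out[, 1] <- pp[, 1] + eps1 * pp[, 2]
  out[, 2] <- (1 - eps1) * pp[, 2] + eps2 * pp[, 3]
  out[, 3] <- (1 - eps2) * pp[, 3]
  list(p = out, p_back = p_back2, R_mean = R_mean)
}

#' Run a multi-round cluster-evolution simulation
#'
#' Simulates competition among founder clusters, each represented by
#' sequences at mutational distance 0, 1 and 2 from its optimum, under a
#' stringency schedule, with beneficial mutations flowing 2 -> 1 -> 0 once
#' a level's frequency clears the mutation threshold. The default initial
#' condition founds every cluster with its suboptimal level-2 sequence at
#' frequency 1e-14 (`init = "suboptimal"`); `init = "optimal"` founds at
#' level 0 instead (used with `pben = 0` to model clusters whose fitness
#' never changes).
#'
#' @param params A [generate_clusters()] result.
#' @param schedule A [tau_schedule()] or numeric vector of per-round taus.
#' @param model A [mutation_model()].
#' @param n_rounds Number of rounds; defaults to the schedule length.
#' @param init `"suboptimal"` (founders at level 2) or `"optimal"`
#'   (founders at level 0).
#' @param p0 Founder frequency per cluster (default 1e-14).
#' @param Q,kback Recovery probability and background relative rate.
#' @return An object of class `cluster_simulation` with elements `levels`
#'   (tibble: round, tau, cluster, level, frequency), `clusters` (tibble:
#'   round, tau, cluster, frequency, fitness, enrichment), `background`
#'   (tibble: round, frequency), plus the inputs.
#' @examples
#' params <- generate_clusters(50, seed = 1)
#' sim <- run_cluster_simulation(params, tau_schedule(n_rounds = 20))
#' glance(sim)
#' @export
run_cluster_simulation <- function(params, schedule, model = mutation_model(),
                                   n_rounds = length(schedule),
                                   init = c("suboptimal", "optimal"),
                                   p0 = 1e-14, Q = 0.2, kback = 0.001) {
  stopifnot(inherits(params, "cluster_params"))
  init <- match.arg(init)
  taus <- as.numeric(schedule)
  if (length(taus) < n_rounds) abort("schedule shorter than `n_rounds`.")
  taus <- taus[seq_len(n_rounds)]
  nc <- nrow(params)
  km <- cluster_matrices(params)
  fit <- km$A * km$k

  p <- matrix(0, nc, 3)
  p[, if (init == "suboptimal") 3 else 1] <- p0
  p_back <- 1 - sum(p)
  if (p_back < 0) abort("founder frequencies exceed 1.")

  lev <- vector("list", n_rounds + 1)
  cl <- vector("list", n_rounds + 1)
  bg <- numeric(n_rounds + 1)
  snapshot <- function(n, tau, p, p_back, E) {
    ptot <- rowSums(p)
    fbar <- ifelse(ptot > 0, rowSums(p * fit) / ptot, NA_real_)
    lev[[n + 1]] <<- tibble(round = n, tau = tau,
                            cluster = rep(params$cluster, 3),
                            level = rep(0:2, each = nc),
                            frequency = as.vector(p))
    cl[[n + 1]] <<- tibble(round = n, tau = tau, cluster = params$cluster,
                           frequency = ptot, fitness = fbar, enrichment = E)
    bg[n + 1] <<- p_back
  }
  snapshot(0L, NA_real_, p, p_back, NA_real_)
  for (n in seq_len(n_rounds)) {
    prev_tot <- rowSums(p)
    up <- cluster_round_update(p, p_back, params, taus[n], Q = Q,
                               kback = kback, model = model)
    p <- up$p; p_back <- up$p_back
    E <- ifelse(prev_tot > 0, rowSums(p) / prev_tot, NA_real_)
    snapshot(n, taus[n], p, p_back, E)
  }
  structure(
    list(levels = dplyr::bind_rows(lev), clusters = dplyr::bind_rows(cl),
         background = tibble(round = 0:n_rounds, frequency = bg),
         params = params, model = model, schedule = taus,
         init = init, Q = Q, kback = kback),
    class = "cluster_simulation"
  )
}

#' @export
print.cluster_simulation <- function(x, ...) {
  cat(sprintf("<cluster_simulation> %d clusters, %d rounds, %s founders, pben = %g\n",
              nrow(x$params), max(x$clusters$round), x$init, x$model$pben))
  invisible(x)
}

#' @describeIn run_cluster_simulation Per-round per-cluster tibble
#'   (frequency, mean fitness, enrichment factor).
#' @param x A `cluster_simulation`.
#' @param ... Unused.
#' @export
tidy.cluster_simulation <- function(x, ...) x$clusters

#' @describeIn run_cluster_simulation One-row summary with the dominant
#'   cluster and the number of frequency crossings.
#' @export
glance.cluster_simulation <- function(x, ...) {
  n_rounds <- max(x$clusters$round)
  fin <- dplyr::filter(x$clusters, .data$round == n_rounds)
  tibble(
    n_clusters = nrow(x$params),
    n_rounds = n_rounds,
    dominant_cluster = fin$cluster[which.max(fin$frequency)],
    dominant_frequency = max(fin$frequency),
    n_crossings = nrow(cluster_crossings(x)),
    background_final = x$background$frequency[n_rounds + 1]
  )
}

#' @describeIn run_cluster_simulation Log-frequency cluster trajectories.
#' @param object A `cluster_simulation`.
#' @export
autoplot.cluster_simulation <- function(object, ...) {
  dat <- dplyr::filter(object$clusters, .data$frequency > 0)
  ggplot2::ggplot(dat, ggplot2::aes(.data$round, .data$frequency,
                                    group = .data$cluster,
                                    colour = factor(.data$cluster))) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "selection round", y = "cluster frequency") +
    ggplot2::theme_minimal()
}

#' Rounds at which cluster frequency curves cross
#'
#' @param sim A `cluster_simulation`.
#' @return Tibble with columns `round`, `cluster_a`, `cluster_b`, one row
#'   per pairwise order flip between consecutive rounds.
#' @export
cluster_crossings <- function(sim) {
  stopifnot(inherits(sim, "cluster_simulation"))
  wide <- tidyr::pivot_wider(sim$clusters[c("round", "cluster", "frequency")],
                             names_from = "cluster", values_from = "frequency")
  wide <- dplyr::arrange(wide, .data$round)
  mat <- as.matrix(wide[-1])
  ids <- as.integer(colnames(mat))
  out <- list()
  nc <- ncol(mat)
  for (a in seq_len(nc - 1)) {
    d <- mat[, a] - mat[, (a + 1):nc, drop = FALSE]
    sgn <- sign(d)
    flips <- which(sgn[-1, , drop = FALSE] * sgn[-nrow(sgn), , drop = FALSE] < 0,
                   arr.ind = TRUE)
    if (nrow(flips)) {
      out[[length(out) + 1]] <- tibble(
        round = wide$round[flips[, 1] + 1],
        cluster_a = ids[a],
        cluster_b = ids[a + flips[, 2]]
      )
    }
  }
  if (length(out)) dplyr::bind_rows(out) else {
    tibble(round = integer(), cluster_a = integer(), cluster_b = integer())
  }
}

#' Mean fitness of a cluster at a round
#'
#' The fitness of a sequence is the product `A * k` (its enrichment is
#' proportional to it in the high-stringency limit); the fitness of a
#' cluster is the frequency-weighted mean over its three levels.
#'
#' @param sim A `cluster_simulation`.
#' @param cluster Cluster id.
#' @param round Round number; defaults to the last.
#' @return Mean fitness (A.k units).
#' @export
cluster_mean_fitness <- function(sim, cluster, round = NULL) {
  stopifnot(inherits(sim, "cluster_simulation"))
  if (is.null(round)) round <- max(sim$clusters$round)
  row <- dplyr::filter(sim$clusters, .data$cluster == !!cluster,
                       .data$round == !!round)
  if (nrow(row) != 1) abort("cluster/round not found in simulation.")
  if (is.na(row$fitness)) abort("cluster has zero frequency at this round.")
  row$fitness
}

#' Per-round enrichment factors of one cluster
#'
#' `E_i(n) = p_i(n) / p_i(n-1)` for every round of the simulation.
#'
#' @param sim A `cluster_simulation`.
#' @param cluster Cluster id.
#' @return Tibble with columns `round`, `enrichment`.
#' @export
enrichment_series <- function(sim, cluster) {
  stopifnot(inherits(sim, "cluster_simulation"))
  rows <- dplyr::filter(sim$clusters, .data$cluster == !!cluster,
                        .data$round > 0)
  rows[c("round", "enrichment")]
}

#' Correlation of cluster fitness with frequency and enrichment
#'
#' At a chosen round, correlates the clusters' mean fitnesses with (i) their
#' log10 frequencies, (ii) their enrichment factor over the round just
#' completed, `E(n)`, and (iii) over the following round, `E(n+1)`. Both
#' Pearson and Spearman coefficients are reported: frequencies span many
#' decades (hence the log), and the rank coefficient is scale-free.
#'
#' In a run with beneficial mutations, fitness is essentially uncorrelated
#' with frequency — frequency integrates fitness over the whole history,
#' not the present mixture — but strongly correlated with `E(n+1)`, which
#' the present mixture determines. Without mutations and with optimal
#' founders, all three correlations are strong.
#'
#' @param sim A `cluster_simulation`.
#' @param round Round at which fitness and frequency are taken; needs
#'   `round + 1 <= n_rounds` for the `E(n+1)` column.
#' @return Tibble with columns `measure` (`log10_frequency`,
#'   `enrichment_n`, `enrichment_n1`), `pearson`, `spearman`, `n_clusters`.
#'   Degenerate (zero-variance) inputs yield `NA` coefficients with a
#'   warning rather than a silent 0.
#' @export
fitness_correlation_report <- function(sim, round = 12) {
  stopifnot(inherits(sim, "cluster_simulation"))
  n_max <- max(sim$clusters$round)
  if (round < 2 || round > n_max) abort("`round` must lie in 2..n_rounds.")
  at <- dplyr::filter(sim$clusters, .data$round == !!round)
  nxt <- dplyr::filter(sim$clusters, .data$round == !!round + 1)
  fitness <- at$fitness
  vars <- list(
    log10_frequency = log10(at$frequency),
    enrichment_n = at$enrichment,
    enrichment_n1 = if (nrow(nxt)) nxt$enrichment[match(at$cluster, nxt$cluster)]
                    else rep(NA_real_, nrow(at))
  )
  degenerate <- FALSE
  safe_cor <- function(x, y, method) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      degenerate <<- TRUE
      return(NA_real_)
    }
    cor(x[ok], y[ok], method = method)
  }
  out <- purrr::imap_dfr(vars, function(v, nm) {
    tibble(measure = nm,
           pearson = safe_cor(fitness, v, "pearson"),
           spearman = safe_cor(fitness, v, "spearman"),
           n_clusters = sum(is.finite(fitness) & is.finite(v)))
  })
  if (degenerate) {
    warn("correlation undefined (fewer than 3 clusters or zero variance); NA reported.")
  }
  out
}
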