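test_that("cluster parameter draws respect the documented ranges", {
  params <- generate_clusters(50, seed = 1)
  expect_true(all(params$k0 >= 0.5 & params$k0 <= 1))
  expect_true(all(params$A0 >= 0.8 & params$A0 <= 1))
  expect_true(all(params$k1 >= params$k0 / 4 & params$k1 <= params$k0 / 2))
  expect_true(all(params$k2 >= params$k1 / 4 & params$k2 <= params$k1 / 2))
  expect_true(all(params$A1 <= params$A0 & params$A0 - params$A1 <= 0.2))
  expect_true(all(params$A2 <= params$A1 & params$A1 - params$A2 <= 0.2))
  expect_identical(params, generate_clusters(50, seed = 1))
  fixed <- generate_clusters(3, seed = 2, k0_range = c(0.8, 0.8),
                             A0_range = c(0.9, 0.9), z_range = c(2, 2),
                             a_range = c(0.1, 0.1))
  expect_equal(fixed$k1, rep(0.4, 3))
  expect_equal(fixed$A2, rep(0.7, 3))
})

test_that("beneficial mutation probability matches its exact form and approximation", {
  expect_equal(beneficial_mutation_probability(0, 1e-5, 13), 0)
  expect_equal(beneficial_mutation_probability(1, 1e-5, 13), 3.333e-6,
               tolerance = 1e-3)
  u <- 1e-5; s <- 13
  for (m1 in 0:s) {
    exact <- beneficial_mutation_probability(m1, u, s)
    approx <- m1 * u / 3
    if (m1 > 0) expect_lt(abs(exact - approx) / approx, 2 * s * u)
  }
})

test_that("amplification factor and mutation threshold follow the definitions", {
  expect_equal(amplification_factor(2, 10), 1024)
  expect_equal(round(amplification_factor(1.6, 15)), 1153)
  expect_equal(amplification_factor(3.7, 0), 1)
  expect_equal(mutation_threshold(1e10, 1e3, 1e-4), 1e-9)
  expect_identical(mutation_threshold(1e10, 1e3, 0), Inf)
  m <- mutation_model(Ntot = 1e10, lambda = 2, ncyc = 10, pben = 1e-4)
  expect_equal(m$pmin, 1 / (1e10 * 1024 * 1e-4))
})

test_that("cluster round update gates mutation flow on the primed frequencies", {
  params <- generate_clusters(1, seed = 3)
  model <- mutation_model(pben = 1e-4, pmin = 1e-10)
  # all mass at level 2, above threshold after selection: level 1 gains
  # exactly pben * p2'
  p <- matrix(c(0, 0, 1e-6), 1, 3)
  up <- cluster_round_update(p, 1 - 1e-6, params, tau = 5, model = model)
  km <- selexdyn:::cluster_matrices(params)
  R2 <- 0.2 * km$A[1, 3] * (1 - exp(-5 * km$k[1, 3]))
  p2_primed <- 1e-6 * R2 / up$R_mean
  expect_equal(up$p[1, 2], model$pben * p2_primed, tolerance = 1e-12)
  expect_equal(up$p[1, 3], (1 - model$pben) * p2_primed, tolerance = 1e-12)
  # below threshold: no flow
  p_small <- matrix(c(0, 0, 1e-14), 1, 3)
  up2 <- cluster_round_update(p_small, 1 - 1e-14, params, tau = 5, model = model)
  expect_equal(up2$p[1, 2], 0)
  # pben = 0 reduces to the plain selection update per level
  model0 <- mutation_model(pben = 0)
  p3 <- matrix(c(2e-7, 3e-7, 5e-7), 1, 3)
  up3 <- cluster_round_update(p3, 1 - 1e-6, params, tau = 5, model = model0)
  R <- 0.2 * km$A[1, ] * (1 - exp(-5 * km$k[1, ]))
  Rback <- 0.2 * (1 - exp(-5 * 0.001))
  Rbar <- sum(p3 * R) + (1 - 1e-6) * Rback
  expect_equal(as.numeric(up3$p), as.numeric(p3 * R / Rbar), tolerance = 1e-12)
  expect_equal(up3$R_mean, Rbar, tolerance = 1e-12)
  # conservation through selection + mutation
  expect_equal(sum(up$p) + up$p_back, 1, tolerance = 1e-12)
})

test_that("level-0 frequency never decreases through the mutation stage", {
  withr::local_seed(8)
  params <- generate_clusters(5, seed = 8)
  model <- mutation_model(pben = 1e-3, pmin = 1e-12)
  p <- matrix(stats::runif(15, 1e-8, 1e-6), 5, 3)
  p_back <- 1 - sum(p)
  up <- cluster_round_update(p, p_back, params, tau = 2, model = model)
  km <- selexdyn:::cluster_matrices(params)
  R <- 0.2 * km$A * (1 - exp(-2 * km$k))
  primed0 <- p[, 1] * R[, 1] / up$R_mean
  expect_true(all(up$p[, 1] >= primed0 - 1e-18))
})

test_that("cluster simulations conserve total frequency to 1e-12", {
  params <- generate_clusters(50, seed = 1)
  sim <- run_cluster_simulation(params, tau_schedule(n_rounds = 20))
  tot <- tapply(sim$clusters$frequency, sim$clusters$round, sum)
  expect_true(all(abs(tot + sim$background$frequency - 1) < 1e-12))
  lev <- tapply(sim$levels$frequency, sim$levels$round, sum)
  expect_equal(as.numeric(lev), as.numeric(tot), tolerance = 1e-14)
})

test_that("a single cluster sweeps to fixation", {
  params <- generate_clusters(1, seed = 4)
  sim <- run_cluster_simulation(params, tau_schedule(n_rounds = 20))
  fin <- dplyr::filter(sim$clusters, round == 20)
  expect_gt(fin$frequency, 0.999)
})

test_that("with pben = 0 the cluster model reduces to the species recursion", {
  params <- generate_clusters(50, seed = 6)
  sim <- run_cluster_simulation(params, tau_schedule(n_rounds = 12, decay = 1),
                                model = mutation_model(pben = 0))
  # same system as 150 independent species (only level 2 is populated)
  species <- tibble::tibble(
    label = paste0("c", rep(params$cluster, each = 3), "_m", rep(0:2, 50)),
    A = as.vector(t(as.matrix(params[c("A0", "A1", "A2")]))),
    k = as.vector(t(as.matrix(params[c("k0", "k1", "k2")]))),
    p0 = rep(c(0, 0, 1e-14), 50)
  )
  pool <- species_pool(species, Q = 0.2, kback = 0.001)
  traj <- run_selection(pool, tau_schedule(n_rounds = 12, decay = 1))
  fin <- dplyr::filter(tidy(traj), round == 12, grepl("_m2$", species))
  sim_fin <- dplyr::filter(sim$levels, round == 12, level == 2)
  expect_equal(sim_fin$frequency, fin$frequency, tolerance = 1e-10)
})

test_that("mean cluster fitness is the frequency-weighted A*k", {
  params <- generate_clusters(2, seed = 5)
  sim <- run_cluster_simulation(params, tau_schedule(n_rounds = 6, decay = 1),
                                model = mutation_model(pben = 0),
                                init = "optimal")
  f <- cluster_mean_fitness(sim, cluster = 1, round = 3)
  expect_equal(f, params$A0[1] * params$k0[1], tolerance = 1e-12)
  fits <- dplyr::filter(sim$clusters, !is.na(fitness))
  lo <- pmin(params$A0 * params$k0, params$A1 * params$k1,
             params$A2 * params$k2)[fits$cluster]
  hi <- pmax(params$A0 * params$k0, params$A1 * params$k1,
             params$A2 * params$k2)[fits$cluster]
  expect_true(all(fits$fitness >= lo - 1e-12 & fits$fitness <= hi + 1e-12))
})

test_that("enrichment series equals the frequency ratio between rounds", {
  params <- generate_clusters(3, seed = 9)
  sim <- run_cluster_simulation(params, tau_schedule(n_rounds = 8))
  es <- enrichment_series(sim, cluster = 2)
  freq <- dplyr::filter(sim$clusters, cluster == 2)$frequency
  expect_equal(es$enrichment, freq[-1] / freq[-length(freq)], tolerance = 1e-12)
})

test_that("realised enrichment approaches A*k*tau*Q/Rbar at high stringency", {
  params <- generate_clusters(10, seed = 10)
  sim <- run_cluster_simulation(params, tau_schedule(taus = rep(1e-3, 1)),
                                model = mutation_model(pben = 0),
                                init = "optimal", n_rounds = 1)
  p0 <- 1e-14; tau <- 1e-3; Q <- 0.2
  Rback <- Q * (1 - exp(-tau * 0.001))
  Rbar <- sum(p0 * Q * params$A0 * (1 - exp(-tau * params$k0))) +
    (1 - 10 * p0) * Rback
  E_obs <- dplyr::filter(sim$clusters, round == 1)$enrichment
  E_pred <- params$A0 * params$k0 * tau * Q / Rbar
  expect_equal(E_obs, E_pred, tolerance = 0.01)
})

test_that("beneficial mutations decouple fitness from frequency but not from enrichment", {
  gaps <- vapply(1:20, function(sd) {
    params <- generate_clusters(50, seed = sd)
    sim <- run_cluster_simulation(params, tau_schedule(n_rounds = 20))
    rep <- fitness_correlation_report(sim, round = 12)
    expect_gt(nrow(cluster_crossings(sim)), 0)
    rep$pearson[rep$measure == "enrichment_n1"] -
      rep$pearson[rep$measure == "log10_frequency"]
  }, numeric(1))
  expect_true(all(gaps >= 0.5))
})

test_that("without mutations and with optimal founders fitness predicts frequency too", {
  params <- generate_clusters(50, seed = 1)
  sim <- run_cluster_simulation(params, tau_schedule(n_rounds = 20),
                                model = mutation_model(pben = 0),
                                init = "optimal")
  rep <- fitness_correlation_report(sim, round = 12)
  expect_gt(rep$pearson[rep$measure == "log10_frequency"], 0.5)
  expect_gt(rep$pearson[rep$measure == "enrichment_n1"], 0.5)
  # constant tau, no mutations: no crossings
  sim_const <- run_cluster_simulation(params, tau_schedule(n_rounds = 20, decay = 1),
                                      model = mutation_model(pben = 0),
                                      init = "optimal")
  expect_identical(nrow(cluster_crossings(sim_const)), 0L)
})

test_that("degenerate cluster sets flag undefined correlations", {
  params <- generate_clusters(5, seed = 2, k0_range = c(0.8, 0.8),
                              A0_range = c(0.9, 0.9), z_range = c(3, 3),
                              a_range = c(0.05, 0.05))
  sim <- run_cluster_simulation(params, tau_schedule(n_rounds = 14))
  expect_warning(rep <- fitness_correlation_report(sim, round = 12),
                 "undefined")
  expect_true(anyNA(rep$pearson))
})

test_that("cluster simulation accessors work", {
  params <- generate_clusters(4, seed = 12)
  sim <- run_cluster_simulation(params, tau_schedule(n_rounds = 10))
  expect_s3_class(tidy(sim), "tbl_df")
  g <- glance(sim)
  expect_identical(g$n_clusters, 4L)
  expect_s3_class(autoplot(sim), "ggplot")
})
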