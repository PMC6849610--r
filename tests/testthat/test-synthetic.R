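# rook-adjacency contiguity check on decoded (row, col) indices
is_contiguous <- function(cells) {
  rc <- cell_rowcol(cells)
  n <- nrow(rc)
  if (n == 1L) return(TRUE)
  seen <- logical(n)
  seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (i in frontier) {
      adj <- which(!seen &
                     abs(rc[, 1] - rc[i, 1]) + abs(rc[, 2] - rc[i, 2]) == 1)
      seen[adj] <- TRUE
      nxt <- c(nxt, adj)
    }
    frontier <- nxt
  }
  all(seen)
}

test_that("the landscape generator is deterministic and balanced", {
  cfg <- simulation_config()
  l1 <- generate_landscape(cfg, 5)
  l2 <- generate_landscape(cfg, 5)
  expect_identical(l1, l2)
  expect_false(identical(l1, generate_landscape(cfg, 6)))
  # realm split: exactly half the cells in each realm by construction
  expect_equal(mean(l1$realm), 0.5)
  # conversion classes both well represented
  expect_gt(mean(l1$C), 0.1); expect_lt(mean(l1$C), 0.9)
  expect_true(all(l1$converted_fraction >= 0 & l1$converted_fraction <= 1))
  expect_identical(l1$C, classify_conversion(l1$converted_fraction))
})

test_that("ranges honour requested sizes and are contiguous", {
  cfg <- simulation_config(n_species = 3, n_single_cell = 0)
  l <- generate_landscape(cfg, 5)
  r <- generate_ranges(cfg, l, 9, sizes = c(1L, 9L, 100L))
  expect_identical(unname(lengths(r)), c(1L, 9L, 100L))
  expect_true(all(unlist(r) %in% l$cell_id))
  expect_true(all(vapply(r, is_contiguous, TRUE)))
  # default configuration includes a deliberate single-cell range
  r2 <- generate_ranges(simulation_config(), l, 10)
  expect_identical(min(lengths(r2)), 1L)
})

test_that("occupancy truth follows the transition model at the extremes", {
  cfg <- simulation_config(n_species = 4, grid_nrow = 8, grid_ncol = 8,
                           range_size_min = 4, range_size_max = 16)
  l <- generate_landscape(cfg, 3)
  r <- generate_ranges(cfg, l, 4)
  # psi = 1 and phi -> 1 everywhere: occupancy is total in both periods
  p_full <- model_params(S = 4, fixed = c(alpha0 = 30, alpha1 = 30),
                         species = cbind(0, 0, 0, 30, 0, 0, 0)[rep(1, 4), ])
  tr <- simulate_truth(r, l, p_full, cfg$grid, 11)
  expect_true(all(tr$pairs$z1 == 1L & tr$pairs$z2 == 1L))
  # psi = 0 and gamma = 0: nothing is ever occupied
  p_empty <- model_params(S = 4,
                          species = cbind(0, 0, -30, -30, 0, 0, 0)[rep(1, 4), ])
  tr0 <- simulate_truth(r, l, p_empty, cfg$grid, 11)
  expect_true(all(tr0$pairs$z1 == 0L & tr0$pairs$z2 == 0L))
})

test_that("edge-prone truth raises extinction frequency at the edge", {
  # strong negative slope in the Palearctic-like realm: realized
  # extinctions among occupied edge cells (D' > 0.8) must exceed those
  # among core cells (D' < 0.4)
  cfg <- simulation_config(n_species = 40, grid_nrow = 16, grid_ncol = 16,
                           range_size_min = 40, range_size_max = 120,
                           true_params = model_params(
                             S = 40, fixed = c(alpha0 = 1.5, alpha1 = 1.5,
                                               beta0 = -6, beta1 = -6),
                             hyper = c(sigma_u = 0.2, sigma_v = 0.2,
                                       mu_gamma = -4, sigma_gamma = 0.2,
                                       mu_psi = 2.5, sigma_psi = 0.2,
                                       mu_delta1 = -1.5,
                                       sigma_delta1 = 0.2,
                                       mu_delta2 = 1, sigma_delta2 = 0.2,
                                       mu_delta3 = 2, sigma_delta3 = 0.2)))
  l <- generate_landscape(cfg, 31)
  set.seed(32)
  params <- draw_species_params(cfg$true_params, 40)
  r <- generate_ranges(cfg, l, 33)
  tr <- simulate_truth(r, l, params, cfg$grid, 34)
  occ <- tr$pairs[tr$pairs$z1 == 1L, ]
  expect_gt(nrow(occ), 1000)
  # compact gridded ranges rarely score D' below ~0.5 (the geometric-mean
  # metric treats small-range cores as near-edge), so "core" here is the
  # low half of the realized D' distribution
  edge <- occ$Dprime > 0.8
  core <- occ$Dprime < 0.55
  expect_gt(sum(edge), 100); expect_gt(sum(core), 100)
  ext_edge <- mean(1 - occ$z2[edge])
  ext_core <- mean(1 - occ$z2[core])
  expect_gt(ext_edge, ext_core)
})

test_that("perfect detection records every present species", {
  cfg <- simulation_config(n_species = 5, grid_nrow = 6, grid_ncol = 6,
                           range_size_min = 4, range_size_max = 12,
                           true_params = model_params(
                             S = 5, fixed = c(alpha0 = 2, alpha1 = 2),
                             hyper = c(sigma_u = 0.2, sigma_v = 0.2,
                                       mu_gamma = -3, sigma_gamma = 0.2,
                                       mu_psi = 2, sigma_psi = 0.2,
                                       mu_delta1 = 15,
                                       sigma_delta1 = 1e-3,
                                       mu_delta2 = 0, sigma_delta2 = 1e-3,
                                       mu_delta3 = 0,
                                       sigma_delta3 = 1e-3)))
  sim <- simulate_dataset(cfg, seed = 12)
  expect_true(all(sim$survey_log$n_detected == sim$survey_log$n_present))
  expect_identical(nrow(sim$records), sum(sim$survey_log$n_detected))
})

test_that("no occupancy means no records at all", {
  cfg <- simulation_config(n_species = 4, grid_nrow = 6, grid_ncol = 6,
                           range_size_min = 4, range_size_max = 10,
                           true_params = model_params(
                             S = 4,
                             hyper = c(mu_psi = -30, sigma_psi = 1e-3,
                                       mu_gamma = -30, sigma_gamma = 1e-3,
                                       sigma_u = 0.2, sigma_v = 0.2,
                                       mu_delta1 = 0, sigma_delta1 = 0.2,
                                       mu_delta2 = 0, sigma_delta2 = 0.2,
                                       mu_delta3 = 0, sigma_delta3 = 0.2)))
  sim <- simulate_dataset(cfg, seed = 13)
  expect_null(sim$records)
  expect_true(all(sim$survey_log$n_detected == 0L))
})

test_that("records never contradict the latent truth", {
  sim <- simulate_dataset(simulation_config(n_species = 12,
                                            grid_nrow = 12, grid_ncol = 12,
                                            range_size_min = 6,
                                            range_size_max = 50), seed = 14)
  key_rec <- unique(paste(sim$records$species_id, sim$records$cell_id,
                          assign_period(sim$records$year)))
  tp <- sim$truth$pairs
  key_true <- c(paste(tp$species_id, tp$cell_id, 1L)[tp$z1 == 1L],
                paste(tp$species_id, tp$cell_id, 2L)[tp$z2 == 1L])
  expect_true(all(key_rec %in% key_true))
})

test_that("detection frequency matches the closed form by list category", {
  # homogeneous detection effects so the closed form is exact per stratum
  cfg <- simulation_config(n_species = 15, grid_nrow = 12, grid_ncol = 12,
                           range_size_min = 40, range_size_max = 100,
                           effort_mean = 8, pool_mean = 7,
                           true_params = model_params(
                             S = 15, fixed = c(alpha0 = 2, alpha1 = 2,
                                               delta_t = 0.3),
                             hyper = c(sigma_u = 0.2, sigma_v = 0.2,
                                       mu_gamma = -3, sigma_gamma = 0.2,
                                       mu_psi = 2.5, sigma_psi = 0.2,
                                       mu_delta1 = -1.5,
                                       sigma_delta1 = 1e-4,
                                       mu_delta2 = 1, sigma_delta2 = 1e-4,
                                       mu_delta3 = 2.2,
                                       sigma_delta3 = 1e-4)))
  sim <- simulate_dataset(cfg, seed = 15, keep_detections = TRUE)
  det <- sim$detections
  for (t in 1:2) {
    sub <- det[det$effort_category == "long" & det$period == t, ]
    expect_gt(nrow(sub), 5000)
    p_expect <- plogis(-1.5 + 2.2 + 0.3 * (t == 2))
    tol <- 4 * sqrt(p_expect * (1 - p_expect) / nrow(sub))
    expect_equal(mean(sub$detected), p_expect, tolerance = tol / p_expect)
  }
})

test_that("assembled surveys round-trip the generator's bookkeeping", {
  sim <- simulate_dataset(simulation_config(n_species = 10,
                                            grid_nrow = 10, grid_ncol = 10,
                                            range_size_min = 5,
                                            range_size_max = 40), seed = 16)
  sv <- build_surveys(sim$records)
  log <- sim$survey_log[sim$survey_log$realized, ]
  expect_identical(nrow(sv), nrow(log))
  key_sv <- paste(sv$cell_id, sv$year)
  key_log <- paste(log$cell_id, log$year)
  expect_setequal(key_sv, key_log)
  m <- match(key_sv, key_log)
  expect_identical(sv$list_length, log$n_detected[m])
  expect_identical(sv$period, log$period[m])
})

test_that("the sign of the edge slope is identifiable from generated data", {
  # strong shared slope, tight species scatter and generous effort, so the
  # edge effect is attributed to beta0 rather than the species slopes
  base_hyper <- c(sigma_u = 0.2, sigma_v = 0.15, mu_gamma = -3,
                  sigma_gamma = 0.2, mu_psi = 2.5, sigma_psi = 0.2,
                  mu_delta1 = -0.5, sigma_delta1 = 0.2, mu_delta2 = 1,
                  sigma_delta2 = 0.2, mu_delta3 = 2.2, sigma_delta3 = 0.2)
  fit_beta0 <- function(b0) {
    cfg <- simulation_config(n_species = 20, grid_nrow = 14, grid_ncol = 14,
                             range_size_min = 30, range_size_max = 90,
                             n_single_cell = 0, effort_mean = 8,
                             pool_mean = 6,
                             true_params = model_params(
                               S = 20,
                               fixed = c(alpha0 = 1.5, alpha1 = 1.5,
                                         beta0 = b0, beta1 = b0,
                                         delta_t = 0.1),
                               hyper = base_hyper))
    sim <- simulate_dataset(cfg, seed = 17)     # matched seeds
    ds <- build_model_dataset(build_surveys(sim$records), sim$ranges,
                              sim$landscape, cfg$grid)
    dr <- run_mcmc(ds, settings = mcmc_settings(chains = 1, iter = 2500,
                                                burn_in = 2500, thin = 5,
                                                seed = 18))
    s <- posterior_summary(dr, pars = c("beta0", "beta1"),
                           species_means = FALSE)
    s$mean
  }
  expect_true(all(fit_beta0(-6) < 0))
  expect_true(all(fit_beta0(6) > 0))
})
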