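# fabricate an occu_draws object from explicit parameter vectors
fake_draws <- function(param_rows, S, species = sprintf("sp%02d", seq_len(S)),
                       nchain = 1L) {
  m <- do.call(rbind, param_rows)
  colnames(m) <- occuedge:::param_names(S)
  structure(list(chains = rep(list(m), nchain),
                 param_names = colnames(m),
                 monitor = colnames(m)[1:21], S = S, species = species,
                 settings = mcmc_settings(), backend = "marginal"),
            class = "occu_draws")
}

test_that("extinction curves transform draws before summarizing", {
  S <- 1L
  p <- model_params(S = S, fixed = c(alpha0 = 9.067, beta0 = -7.719))
  row <- occuedge:::params_to_vector(p)
  dr <- fake_draws(list(row), S)
  cv <- extinction_curve(dr, realm = 0, conv = 0, dgrid = c(0.5, 1))
  # closed form at D' = 0.5 with the single draw
  expect_equal(cv$median[1], 1 - plogis(9.067), tolerance = 1e-10)
  expect_equal(cv$median[1], 1.15e-4, tolerance = 1e-2)
  # degenerate draws give a zero-width band
  expect_equal(cv$q_lo, cv$q_hi)
  # negative slope: extinction increases toward the edge
  grid <- seq(0.2, 1, 0.05)
  cv2 <- extinction_curve(dr, 0, 0, dgrid = grid)
  expect_true(all(diff(cv2$median) > 0))
  # stratum selection: (1, 1) uses alpha1 + alpha3
  p2 <- model_params(S = S, fixed = c(alpha1 = 1.821, alpha3 = 0.882))
  cv3 <- extinction_curve(fake_draws(list(occuedge:::params_to_vector(p2)),
                                     S), 1, 1, dgrid = 0.5)
  expect_equal(cv3$median, 1 - plogis(2.703), tolerance = 1e-10)
  expect_error(extinction_curve(dr, 2, 0), "realm")
})

test_that("richness change recovers data-pinned occupancy", {
  # two species, one cell; near-perfect detection pins z: species 1 seen
  # in both periods, species 2 only before 1980
  cell <- cell_id_from_rowcol(10L, 10L)
  det1 <- rbind(c(0, 0, 3), c(0, 0, 3))
  det2 <- rbind(c(0, 0, 3), c(0, 0, 0))
  tot <- rbind(c(0, 0, 3), c(0, 0, 3))
  ds <- make_pair_dataset(det1, det2, tot, tot, Dprime = c(1, 1),
                          R = c(0L, 0L), C = c(0L, 0L), sp = 1:2, S = 2L)
  ds$pairs$cell_id <- c(cell, cell); ds$cells <- cell
  p <- model_params(S = 2, fixed = c(alpha0 = 0),
                    species = cbind(u = c(0, 0), v = c(0, 0),
                                    lgamma = qlogis(c(0.5, 0.5)),
                                    lpsi = c(0, 0),
                                    delta1 = c(0, 0), delta2 = c(0, 0),
                                    delta3 = c(8, 8)))  # p -> 1 on long lists
  dr <- fake_draws(rep(list(occuedge:::params_to_vector(p)), 50), 2L)
  rc <- richness_change(dr, ds, seed = 2)
  expect_equal(rc$mean_before, 2)
  expect_equal(rc$mean_after, 1)
  expect_equal(rc$mean_change, -1)
  expect_equal(rc$confidence, 0)
  expect_equal(rc$n_inrange, 2)
})

test_that("richness-change ties follow the documented conventions", {
  cell <- cell_id_from_rowcol(10L, 10L)
  det <- rbind(c(0, 0, 3))
  ds <- make_pair_dataset(det, det, det, det, Dprime = 1, R = 0L, C = 0L,
                          sp = 1L)
  ds$pairs$cell_id <- cell; ds$cells <- cell
  p <- model_params(S = 1, species = matrix(c(0, 0, 0, 0, 0, 0, 8), 1, 7))
  dr <- fake_draws(rep(list(occuedge:::params_to_vector(p)), 40), 1L)
  strict <- richness_change(dr, ds, ties = "strict", seed = 3)
  half <- richness_change(dr, ds, ties = "half", seed = 3)
  expect_equal(strict$mean_change, 0)
  expect_equal(strict$confidence, 0)
  expect_equal(half$confidence, 0.5)
})

test_that("imputed richness is conserved across cells", {
  w <- shared_small_fit()
  m <- as.matrix(w$draws)
  p <- occuedge:::vector_to_params(m[nrow(m), ], w$draws$S)
  set.seed(10)
  z <- occuedge:::.sample_z(w$dataset, p)
  cell_index <- match(w$dataset$pairs$cell_id, w$dataset$cells)
  J <- length(w$dataset$cells)
  r1 <- occuedge:::.cell_totals(z$z1, cell_index, J)
  expect_equal(sum(r1), sum(z$z1))
  expect_true(all(r1 <= occuedge:::.cell_totals(rep(1, length(z$z1)),
                                                cell_index, J)))
})

test_that("richness confidence is stable under thinning the draws", {
  w <- shared_small_fit()
  rc1 <- richness_change(w$draws, w$dataset, n_draws = 800, seed = 6)
  thinned <- w$draws
  thinned$chains <- lapply(w$draws$chains, function(m)
    m[seq(1, nrow(m), by = 2), , drop = FALSE])
  rc2 <- richness_change(thinned, w$dataset, n_draws = 800, seed = 7)
  expect_lt(max(abs(rc1$confidence - rc2$confidence)), 0.05)
})

test_that("species effects table reports 1-u, v and range size", {
  S <- 3L
  ranges <- list(sp01 = 1:4, sp02 = 1:9, sp03 = 7L)
  p <- model_params(S = S)
  dr <- fake_draws(rep(list(occuedge:::params_to_vector(p)), 10), S)
  tb <- species_effects_table(dr, ranges)
  expect_identical(nrow(tb), S)
  expect_equal(tb$ext_rate, rep(1, S))          # u = 0 -> 1 - u = 1
  expect_equal(tb$edge_proneness, rep(0, S))
  expect_identical(tb$range_cells, c(4L, 9L, 1L))
})

test_that("a species with edge-concentrated extinctions gets the lowest v", {
  cfg <- simulation_config(
    n_species = 10, grid_nrow = 14, grid_ncol = 14,
    range_size_min = 30, range_size_max = 80, n_single_cell = 0,
    effort_mean = 8,
    true_params = model_params(
      S = 10, fixed = c(alpha0 = 1.5, alpha1 = 1.5, delta_t = 0.1),
      hyper = c(sigma_u = 0.3, sigma_v = 0.3, mu_gamma = -3,
                sigma_gamma = 0.3, mu_psi = 2, sigma_psi = 0.3,
                mu_delta1 = 0, sigma_delta1 = 0.3, mu_delta2 = 1,
                sigma_delta2 = 0.3, mu_delta3 = 2, sigma_delta3 = 0.3)))
  set.seed(55)
  landscape <- generate_landscape(cfg, 56)
  params <- draw_species_params(cfg$true_params, 10)
  params$species[, "u"] <- 0
  params$species[, "v"] <- 0
  params$species[1, "v"] <- -6     # extinctions forced toward the edge
  rownames(params$species) <- sprintf("sp%02d", 1:10)
  ranges <- generate_ranges(cfg, landscape, 57)
  truth <- simulate_truth(ranges, landscape, params, cfg$grid, 58)
  sv <- simulate_surveys(truth, cfg, 59)
  ds <- build_model_dataset(build_surveys(sv$records), ranges, landscape,
                            cfg$grid)
  dr <- run_mcmc(ds, settings = mcmc_settings(chains = 1, iter = 3000,
                                              burn_in = 2000, thin = 4,
                                              seed = 60))
  eff <- species_effects_table(dr, ranges)
  expect_identical(eff$species_id[which.min(eff$edge_proneness)], "sp01")
})
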