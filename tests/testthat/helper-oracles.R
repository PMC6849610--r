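# Independent oracles and fixture builders used across the test files.

# brute-force enumeration over the latent states (z1, z2): the likelihood
# of one pair's detection history, written as an explicit 4-branch loop
# over survey-level Bernoulli products (independent of the package's
# analytic factorization)
oracle_pair_lik <- function(y1, p1, y2, p2, psi, phi, gamma) {
  lik <- 0
  for (z1 in 0:1) for (z2 in 0:1) {
    pr_state <- (if (z1 == 1) psi else 1 - psi) *
      (if (z1 == 1) (if (z2 == 1) phi else 1 - phi)
       else (if (z2 == 1) gamma else 1 - gamma))
    pr_obs <- 1
    for (k in seq_along(y1)) {
      pk <- z1 * p1[k]
      pr_obs <- pr_obs * (if (y1[k] == 1) pk else 1 - pk)
    }
    for (k in seq_along(y2)) {
      pk <- z2 * p2[k]
      pr_obs <- pr_obs * (if (y2[k] == 1) pk else 1 - pk)
    }
    lik <- lik + pr_state * pr_obs
  }
  lik
}

# geometric-mean distance oracle: explicit double loop over cell pairs
oracle_D0 <- function(cells, grid = grid_spec()) {
  cc <- cell_centroid(cells, grid)
  n <- length(cells)
  out <- numeric(n)
  for (j in seq_len(n)) {
    s <- 0
    for (jp in seq_len(n)) {
      if (jp == j) next
      s <- s + log(gc_distance_km(cc[j, "lon"], cc[j, "lat"],
                                  cc[jp, "lon"], cc[jp, "lat"]))
    }
    out[j] <- exp(s / (n - 1))
  }
  stats::setNames(out, cells)
}

# hand-build a minimal occu_data object for likelihood-level tests: one
# pair per row of the supplied survey design.  `surv1`/`surv2` give the
# per-category survey counts at the pair's cell, `det1`/`det2` the
# detections, per period.
make_pair_dataset <- function(det1, det2, tot1, tot2, Dprime, R, C, sp,
                              S = max(sp)) {
  n <- nrow(det1)
  ord <- order(sp)
  pairs <- data.frame(species_id = sprintf("sp%02d", sp[ord]),
                      cell_id = seq_len(n),
                      Dprime = Dprime[ord], R = R[ord], C = C[ord],
                      sp = sp[ord])
  structure(list(species = sprintf("sp%02d", seq_len(S)),
                 cells = seq_len(n), pairs = pairs,
                 det1 = det1[ord, , drop = FALSE],
                 det2 = det2[ord, , drop = FALSE],
                 tot1 = tot1[ord, , drop = FALSE],
                 tot2 = tot2[ord, , drop = FALSE],
                 surveys = NULL,
                 counts = list(n_pairs = n)),
            class = "occu_data")
}

# random pair history with <= max_surveys surveys per period, plus random
# parameters; returns everything needed for both the oracle and the package
random_pair_case <- function(max_surveys = 4L) {
  n1 <- sample(0:max_surveys, 1L)
  n2 <- sample(0:max_surveys, 1L)
  cat1 <- sample(c("single", "short", "long"), n1, replace = TRUE)
  cat2 <- sample(c("single", "short", "long"), n2, replace = TRUE)
  psi <- runif(1, 0.05, 0.95)
  phi <- runif(1, 0.05, 0.95)
  gamma <- runif(1, 0.05, 0.95)
  d1 <- rnorm(1); d2 <- rnorm(1); d3 <- rnorm(1); dt <- rnorm(1, 0, 0.5)
  p1 <- plogis(d1 + d2 * (cat1 == "short") + d3 * (cat1 == "long"))
  p2 <- plogis(dt + d1 + d2 * (cat2 == "short") + d3 * (cat2 == "long"))
  # detections only possible when the occupied branch allows them; draw
  # unconditionally and let impossible all-zero branches carry the mass
  y1 <- rbinom(n1, 1L, p1 * rbinom(1, 1, psi))
  y2 <- rbinom(n2, 1L, p2 * 0.7)
  list(n1 = n1, n2 = n2, cat1 = cat1, cat2 = cat2,
       psi = psi, phi = phi, gamma = gamma,
       d1 = d1, d2 = d2, d3 = d3, dt = dt,
       p1 = p1, p2 = p2, y1 = y1, y2 = y2)
}

# package a random_pair_case() as a 1-species, 1-cell occu_data + params
pair_case_to_dataset <- function(case) {
  cat_lev <- c("single", "short", "long")
  count3 <- function(cats, y, want) {
    vapply(cat_lev, function(cc) sum(cats == cc & y == want), 0)
  }
  det1 <- matrix(vapply(cat_lev, function(cc) sum(case$cat1 == cc &
                                                    case$y1 == 1), 0), 1L)
  det2 <- matrix(vapply(cat_lev, function(cc) sum(case$cat2 == cc &
                                                    case$y2 == 1), 0), 1L)
  tot1 <- matrix(vapply(cat_lev, function(cc) sum(case$cat1 == cc), 0), 1L)
  tot2 <- matrix(vapply(cat_lev, function(cc) sum(case$cat2 == cc), 0), 1L)
  ds <- make_pair_dataset(det1, det2, tot1, tot2,
                          Dprime = 0.5, R = 0L, C = 0L, sp = 1L)
  params <- model_params(
    S = 1L,
    fixed = c(alpha0 = qlogis(case$phi), delta_t = case$dt),
    species = matrix(c(0, 0, qlogis(case$gamma), qlogis(case$psi),
                       case$d1, case$d2, case$d3), 1L, 7L))
  list(dataset = ds, params = params)
}

# small shared synthetic world + fit, built once per test run and reused by
# the posterior-product tests (kept deliberately small for speed)
.shared_env <- new.env()
shared_small_fit <- function() {
  if (!is.null(.shared_env$fit)) return(.shared_env$fit)
  cfg <- simulation_config(n_species = 10L, grid_nrow = 12L,
                           grid_ncol = 12L, range_size_min = 6L,
                           range_size_max = 50L)
  sim <- simulate_dataset(cfg, seed = 99L)
  sv <- build_surveys(sim$records)
  ds <- build_model_dataset(sv, sim$ranges, sim$landscape, cfg$grid)
  dr <- run_mcmc(ds, prior_spec(),
                 mcmc_settings(chains = 2L, iter = 1600L, burn_in = 1200L,
                               thin = 2L, seed = 5L))
  .shared_env$fit <- list(sim = sim, surveys = sv, dataset = ds, draws = dr)
  .shared_env$fit
}
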