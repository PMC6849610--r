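## Posterior products: extinction-rate curves along the core-to-edge
## gradient, per-cell richness change with confidence, and species-level
## effect tables.

#' Extinction rate as a function of range position
#'
#' For one realm x conversion stratum, transforms every posterior draw of
#' the stratum's fixed effects into an extinction-rate curve
#' `1 - invlogit(alpha_s + beta_s (D' - 0.5))` for the average species
#' (random effects at zero), then summarizes per D' value by the posterior
#' median and a credible band.  Transform-then-summarize order is
#' deliberate: summarizing parameters first and transforming afterwards
#' would not give posterior quantiles of the curve.
#'
#' @param draws an `occu_draws` object (or a matrix of draws with the fixed
#'   effect columns).
#' @param realm,conv stratum indicators (0/1 scalars).
#' @param dgrid D' values at which to evaluate (default 0.2..1).
#' @param probs three quantile levels: lower band, centre, upper band
#'   (default 80% credible interval around the median).
#' @param random_effects if `TRUE`, integrate species random-effect
#'   uncertainty by adding `u, v ~ N(0, sigma)` noise per draw; default
#'   `FALSE` (the average species).
#' @return data frame: `R, C, Dprime, q_lo, median, q_hi` (extinction
#'   rates, i.e. `1 - phi`).
#' @export
extinction_curve <- function(draws, realm, conv,
                             dgrid = seq(0.2, 1, by = 0.02),
                             probs = c(0.1, 0.5, 0.9),
                             random_effects = FALSE) {
  stopifnot(realm %in% 0:1, conv %in% 0:1, length(probs) == 3L)
  m <- if (inherits(draws, "occu_draws")) as.matrix(draws) else as.matrix(draws)
  a <- m[, "alpha0"] * (1 - realm) + m[, "alpha1"] * realm +
    m[, "alpha2"] * (1 - realm) * conv + m[, "alpha3"] * realm * conv
  b <- m[, "beta0"] * (1 - realm) + m[, "beta1"] * realm +
    m[, "beta2"] * (1 - realm) * conv + m[, "beta3"] * realm * conv
  if (random_effects) {
    a <- a + rnorm(length(a), 0, m[, "sigma_u"])
    b <- b + rnorm(length(b), 0, m[, "sigma_v"])
  }
  qs <- vapply(dgrid, function(d) {
    ext <- 1 - plogis(a + b * (d - 0.5))
    quantile(ext, probs = probs, names = FALSE)
  }, numeric(3L))
  data.frame(R = realm, C = conv, Dprime = dgrid,
             q_lo = qs[1L, ], median = qs[2L, ], q_hi = qs[3L, ])
}

#' Extinction curves for all four strata
#'
#' @inheritParams extinction_curve
#' @return row-bound data frame over the strata (R, C) in (0,0), (0,1),
#'   (1,0), (1,1).
#' @export
extinction_curves_all <- function(draws, dgrid = seq(0.2, 1, by = 0.02),
                                  probs = c(0.1, 0.5, 0.9)) {
  do.call(rbind, lapply(list(c(0, 0), c(0, 1), c(1, 0), c(1, 1)),
                        function(s) extinction_curve(draws, s[1], s[2],
                                                     dgrid, probs)))
}

# per-cell totals of a per-pair vector (cells with no pairs get 0)
.cell_totals <- function(x, cell_index, J) {
  out <- numeric(J)
  t <- rowsum(x, cell_index)
  out[as.integer(rownames(t))] <- t[, 1L]
  out
}

#' Per-cell species-richness change with confidence
#'
#' For each posterior draw, imputes the latent occupancy states of every
#' in-range pair from their exact conditional distribution given the pair's
#' detection history and that draw's parameters (posterior-predictive
#' imputation; works for both sampler backends), accumulates cell richness
#' `sum_i z(i, j, t)`, and reports the posterior mean richness per period,
#' the mean change, and the proportion of draws in which richness is
#' strictly higher after the period boundary (the confidence of a gain).
#' Ties count 0 under the default strict rule, or 1/2 with
#' `ties = "half"`.
#'
#' @param draws an `occu_draws` object.
#' @param dataset the `occu_data` the model was fitted to.
#' @param n_draws maximum number of posterior draws to use (evenly
#'   subsampled; default 1000).
#' @param ties `"strict"` (default) or `"half"`.
#' @param seed seed for the imputation randomness.
#' @return data frame: `cell_id, n_inrange, mean_before, mean_after,
#'   mean_change, confidence`.
#' @export
richness_change <- function(draws, dataset, n_draws = 1000L,
                            ties = c("strict", "half"), seed = 1L) {
  ties <- match.arg(ties)
  stopifnot(inherits(draws, "occu_draws"), inherits(dataset, "occu_data"))
  set.seed(seed)
  m <- as.matrix(draws)
  idx <- if (nrow(m) > n_draws)
    unique(round(seq(1L, nrow(m), length.out = n_draws))) else seq_len(nrow(m))
  S <- draws$S
  J <- length(dataset$cells)
  cell_index <- match(dataset$pairs$cell_id, dataset$cells)
  sum1 <- sum2 <- conf <- numeric(J)
  for (r in idx) {
    p <- vector_to_params(m[r, ], S)
    z <- .sample_z(dataset, p)
    r1 <- .cell_totals(z$z1, cell_index, J)
    r2 <- .cell_totals(z$z2, cell_index, J)
    sum1 <- sum1 + r1
    sum2 <- sum2 + r2
    conf <- conf + (r2 > r1) + if (ties == "half") 0.5 * (r2 == r1) else 0
  }
  n <- length(idx)
  data.frame(cell_id = dataset$cells,
             n_inrange = .cell_totals(rep(1L, nrow(dataset$pairs)),
                                      cell_index, J),
             mean_before = sum1 / n, mean_after = sum2 / n,
             mean_change = (sum2 - sum1) / n, confidence = conf / n)
}

#' Species-level extinction rate, edge proneness and range size
#'
#' Posterior means of the species-level transforms: relative extinction
#' rate `1 - u_i` (departure of the species' persistence intercept from the
#' average species), edge proneness `v_i` (negative values: extinctions
#' concentrated toward the range edge; positive: toward the core), and
#' geographic range size as the occupied-cell count.  No formal test of the
#' interrelationship is computed; the table supports qualitative
#' comparison.
#'
#' @param draws an `occu_draws` object.
#' @param ranges named list of per-species range cell vectors (names must
#'   cover the fitted species).
#' @return data frame: `species_id, ext_rate, edge_proneness, range_cells`.
#' @export
species_effects_table <- function(draws, ranges) {
  stopifnot(inherits(draws, "occu_draws"))
  m <- as.matrix(draws)
  S <- draws$S
  u <- colMeans(m[, paste0("u[", seq_len(S), "]"), drop = FALSE])
  v <- colMeans(m[, paste0("v[", seq_len(S), "]"), drop = FALSE])
  sz <- vapply(draws$species, function(s) length(ranges[[s]]), 1L)
  data.frame(species_id = draws$species,
             ext_rate = as.numeric(1 - u),
             edge_proneness = as.numeric(v),
             range_cells = as.integer(sz), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Plot extinction-rate curves by stratum
#'
#' Base-graphics rendering of [extinction_curves_all()] output: one panel
#' per realm x conversion stratum, posterior median line with a shaded
#' credible band.
#'
#' @param curves output of [extinction_curves_all()].
#' @param ... passed to [plot()].
#' @return invisibly, `curves`.
#' @export
plot_extinction_curves <- function(curves, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  labs <- c("0.0" = "Palearctic, unconverted",
            "0.1" = "Palearctic, human-dominated",
            "1.0" = "Indo-Malaya, unconverted",
            "1.1" = "Indo-Malaya, human-dominated")
  for (key in names(labs)) {
    rc <- as.numeric(strsplit(key, ".", fixed = TRUE)[[1L]])
    s <- curves[curves$R == rc[1] & curves$C == rc[2], ]
    if (nrow(s) == 0L) next
    plot(s$Dprime, s$median, type = "n", ylim = range(s$q_lo, s$q_hi),
         xlab = "D' (1 = range edge)", ylab = "extinction rate (1 - phi)",
         main = labs[[key]], ...)
    graphics::polygon(c(s$Dprime, rev(s$Dprime)), c(s$q_lo, rev(s$q_hi)),
                      col = "grey85", border = NA)
    graphics::lines(s$Dprime, s$median, lwd = 2)
  }
  invisible(curves)
}
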