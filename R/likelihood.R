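## Model likelihood: persistence and detection linear predictors, the
## per-pair marginal likelihood (latent occupancy summed out), and the log
## posterior.

#' Persistence linear predictor (logit phi)
#'
#' `logit phi = alpha + beta * (D' - 0.5)` where the intercept and slope
#' are stratum composites:
#' `alpha = alpha0 (1-R) + alpha1 R + alpha2 (1-R) C + alpha3 R C + u_i`
#' and analogously `beta` with `beta0..beta3` and `v_i`.  Subtracting 0.5
#' from D' decorrelates intercept and slope.  Positive `beta` means higher
#' persistence at the range edge (extinctions concentrated in the core).
#'
#' @param Dprime edge scores in (0, 1] (vectorized).
#' @param R,C realm and conversion indicators (0/1, vectorized).
#' @param params an [model_params()] object (its `fixed` slot is used).
#' @param u,v species random effects (default 0 = the average species).
#' @return logit-scale persistence (same length as the inputs).
#' @export
persistence_logit <- function(Dprime, R, C, params, u = 0, v = 0) {
  f <- params$fixed
  a <- f["alpha0"] * (1 - R) + f["alpha1"] * R +
    f["alpha2"] * (1 - R) * C + f["alpha3"] * R * C + u
  b <- f["beta0"] * (1 - R) + f["beta1"] * R +
    f["beta2"] * (1 - R) * C + f["beta3"] * R * C + v
  unname(a + b * (Dprime - 0.5))
}

#' Expected second-period occupancy
#'
#' `E[z2] = z1 * phi + (1 - z1) * gamma`: occupied cells persist with
#' probability `phi` (local extinction rate `1 - phi`); empty cells are
#' colonized with probability `gamma`.
#'
#' @param z1 first-period occupancy (0/1).
#' @param phi persistence probability.
#' @param gamma colonization probability.
#' @return probability that the cell is occupied in period 2.
#' @export
transition_expectation <- function(z1, phi, gamma) {
  z1 * phi + (1 - z1) * gamma
}

#' Detection linear predictor (logit p)
#'
#' `logit p = delta_t * [t = 2] + delta1_i + delta2_i * short_k +
#' delta3_i * long_k`.  Period 1 is the baseline; single-species lists get
#' neither list-length effect.
#'
#' @param category survey list-length category: "single", "short" or
#'   "long" (vectorized).
#' @param period survey period (1 or 2).
#' @param delta_t period-2 offset in detectability.
#' @param delta1,delta2,delta3 species detection effects.
#' @return logit-scale detection probability.
#' @export
detection_logit <- function(category, period, delta_t,
                            delta1, delta2, delta3) {
  delta_t * (period == 2) + delta1 +
    delta2 * (category == "short") + delta3 * (category == "long")
}

#' Marginal log-likelihood of one pair's detection history
#'
#' Sums the latent occupancy states (z1, z2) out of the likelihood of one
#' species:cell pair.  Detections are impossible in an unoccupied cell, so
#' branches with z = 0 contribute only when the corresponding period has no
#' detections:
#' `L = psi A1(1) [phi A2(1) + (1-phi) A2(0)] +
#'     (1-psi) A1(0) [gamma A2(1) + (1-gamma) A2(0)]`
#' with `A_t(1) = prod_k p_k^y (1-p_k)^(1-y)` over the period's surveys and
#' `A_t(0) = 1` iff the period has no detections.  A pair with no surveys
#' has likelihood 1.
#'
#' @param y1,y2 binary detection vectors for the pair's surveys in periods
#'   1 and 2 (may be empty).
#' @param p1,p2 per-survey detection probabilities matching `y1`, `y2`.
#' @param psi initial occupancy probability.
#' @param phi persistence probability.
#' @param gamma colonization probability.
#' @return the log-likelihood (a scalar).
#' @export
pair_marginal_loglik <- function(y1, p1, y2, p2, psi, phi, gamma) {
  stopifnot(length(y1) == length(p1), length(y2) == length(p2))
  A1_occ <- prod(ifelse(y1 == 1, p1, 1 - p1))
  A2_occ <- prod(ifelse(y2 == 1, p2, 1 - p2))
  A1_emp <- as.numeric(!any(y1 == 1))
  A2_emp <- as.numeric(!any(y2 == 1))
  lik <- psi * A1_occ * (phi * A2_occ + (1 - phi) * A2_emp) +
    (1 - psi) * A1_emp * (gamma * A2_occ + (1 - gamma) * A2_emp)
  log(lik)
}

# per-pair marginal log-likelihoods for a whole dataset (C++ fast path)
dataset_logliks <- function(dataset, params) {
  pair_logliks_cpp(unname(params$fixed), params$species,
                   dataset$pairs$sp, dataset$pairs$Dprime,
                   as.integer(dataset$pairs$R), as.integer(dataset$pairs$C),
                   dataset$det1, dataset$det2, dataset$tot1, dataset$tot2)
}

# log prior + random-effect log-densities, as one scalar
.log_prior <- function(params, priors) {
  f <- params$fixed; h <- params$hyper; sp <- params$species
  sig <- h[grep("^sigma", names(h))]
  if (any(sig <= 0)) return(-Inf)
  lp <- sum(dnorm(f, 0, priors$fixed_sd, log = TRUE)) +
    sum(dnorm(h[grep("^mu", names(h))], 0, priors$fixed_sd, log = TRUE)) +
    sum(dnorm(sig, 0, priors$sigma_scale, log = TRUE) + log(2))
  lp + sum(dnorm(sp[, "u"], 0, h["sigma_u"], log = TRUE)) +
    sum(dnorm(sp[, "v"], 0, h["sigma_v"], log = TRUE)) +
    sum(dnorm(sp[, "lgamma"], h["mu_gamma"], h["sigma_gamma"], log = TRUE)) +
    sum(dnorm(sp[, "lpsi"], h["mu_psi"], h["sigma_psi"], log = TRUE)) +
    sum(dnorm(sp[, "delta1"], h["mu_delta1"], h["sigma_delta1"], log = TRUE)) +
    sum(dnorm(sp[, "delta2"], h["mu_delta2"], h["sigma_delta2"], log = TRUE)) +
    sum(dnorm(sp[, "delta3"], h["mu_delta3"], h["sigma_delta3"], log = TRUE))
}

#' Log posterior density (up to a constant)
#'
#' Sum of the per-pair marginal log-likelihoods, the random-effect
#' log-densities and the log-priors.  With `by_term = TRUE` the additive
#' decomposition is returned for testing.
#'
#' @param params an [model_params()] object.
#' @param dataset an `occu_data` object from [build_model_dataset()], or
#'   `NULL` for the prior alone.
#' @param priors a [prior_spec()].
#' @param by_term return `list(pair_loglik, log_prior, total)` instead of
#'   the scalar.
#' @return scalar log posterior (or the decomposition).
#' @export
log_posterior <- function(params, dataset = NULL, priors = prior_spec(),
                          by_term = FALSE) {
  pll <- if (is.null(dataset)) numeric(0) else dataset_logliks(dataset, params)
  lp <- .log_prior(params, priors)
  if (!all(is.finite(pll)))
    warning("non-finite pair log-likelihood at pair(s) ",
            paste(utils::head(which(!is.finite(pll)), 5L), collapse = ", "))
  if (by_term) list(pair_loglik = pll, log_prior = lp, total = sum(pll) + lp)
  else sum(pll) + lp
}
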