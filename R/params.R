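## Parameter container for the multispecies dynamic occupancy model.

.FIXED_NAMES <- c("alpha0", "alpha1", "alpha2", "alpha3",
                  "beta0", "beta1", "beta2", "beta3", "delta_t")
.HYPER_NAMES <- c("sigma_u", "sigma_v",
                  "mu_gamma", "sigma_gamma", "mu_psi", "sigma_psi",
                  "mu_delta1", "sigma_delta1", "mu_delta2", "sigma_delta2",
                  "mu_delta3", "sigma_delta3")
.SPECIES_COLS <- c("u", "v", "lgamma", "lpsi", "delta1", "delta2", "delta3")

#' Model parameter set
#'
#' Bundles all parameters of the occupancy-detection model: the eight
#' persistence fixed effects (intercepts `alpha0..alpha3`, slopes
#' `beta0..beta3` for the realm x conversion strata), the period-2
#' detection offset `delta_t`, the random-effect hyperparameters, and a
#' species matrix with columns `u` (persistence intercept deviation), `v`
#' (edge-proneness slope deviation), `lgamma` (logit colonization), `lpsi`
#' (logit initial occupancy) and `delta1..delta3` (detection effects).
#'
#' @param S number of species (ignored if `species` is supplied).
#' @param fixed named numeric vector (defaults 0) over
#'   `alpha0..alpha3, beta0..beta3, delta_t`; partial names allowed.
#' @param hyper named numeric vector of hyperparameters; SDs default 1,
#'   means 0.
#' @param species numeric S x 7 matrix (columns
#'   `u, v, lgamma, lpsi, delta1, delta2, delta3`); defaults to zeros.
#' @return object of class `occu_params`.
#' @export
model_params <- function(S = NULL, fixed = NULL, hyper = NULL,
                         species = NULL) {
  fx <- stats::setNames(numeric(9L), .FIXED_NAMES)
  if (!is.null(fixed)) {
    stopifnot(all(names(fixed) %in% .FIXED_NAMES))
    fx[names(fixed)] <- fixed
  }
  hy <- stats::setNames(rep(c(1, 0), c(2L, 10L)), .HYPER_NAMES)
  hy[grep("^sigma", .HYPER_NAMES)] <- 1
  hy[grep("^mu", .HYPER_NAMES)] <- 0
  if (!is.null(hyper)) {
    stopifnot(all(names(hyper) %in% .HYPER_NAMES))
    hy[names(hyper)] <- hyper
  }
  if (is.null(species)) {
    stopifnot(!is.null(S))
    species <- matrix(0, S, 7L, dimnames = list(NULL, .SPECIES_COLS))
  } else {
    species <- as.matrix(species)
    stopifnot(ncol(species) == 7L)
    colnames(species) <- .SPECIES_COLS
  }
  if (any(hy[grep("^sigma", names(hy))] <= 0))
    stop("random-effect SDs must be positive")
  structure(list(fixed = fx, hyper = hy, species = species),
            class = "occu_params")
}

#' Draw species-level parameters from their hyperdistributions
#'
#' @param params an `occu_params` whose hyperparameters are populated.
#' @param S number of species.
#' @return `params` with a freshly drawn species matrix.
#' @export
draw_species_params <- function(params, S) {
  h <- params$hyper
  params$species <- cbind(
    u = rnorm(S, 0, h["sigma_u"]),
    v = rnorm(S, 0, h["sigma_v"]),
    lgamma = rnorm(S, h["mu_gamma"], h["sigma_gamma"]),
    lpsi = rnorm(S, h["mu_psi"], h["sigma_psi"]),
    delta1 = rnorm(S, h["mu_delta1"], h["sigma_delta1"]),
    delta2 = rnorm(S, h["mu_delta2"], h["sigma_delta2"]),
    delta3 = rnorm(S, h["mu_delta3"], h["sigma_delta3"]))
  params
}

# flat named vector of all parameters, in storage order
params_to_vector <- function(p) {
  S <- nrow(p$species)
  sp <- as.numeric(p$species)
  names(sp) <- paste0(rep(.SPECIES_COLS, each = S), "[", seq_len(S), "]")
  c(p$fixed, p$hyper, sp)
}

param_names <- function(S) {
  c(.FIXED_NAMES, .HYPER_NAMES,
    paste0(rep(.SPECIES_COLS, each = S), "[", seq_len(S), "]"))
}

vector_to_params <- function(v, S) {
  model_params(S = S, fixed = v[.FIXED_NAMES], hyper = v[.HYPER_NAMES],
               species = matrix(v[-(1:21)], S, 7L,
                                dimnames = list(NULL, .SPECIES_COLS)))
}

#' Prior specification
#'
#' Minimally informative priors: Normal(0, `fixed_sd`^2) on every top-level
#' logit-scale fixed effect and hypermean, and half-Normal(0,
#' `sigma_scale`^2) on every random-effect SD.
#'
#' @param fixed_sd prior SD for fixed effects and hypermeans.
#' @param sigma_scale scale of the half-Normal prior on random-effect SDs.
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(fixed_sd = 10, sigma_scale = 5) {
  stopifnot(fixed_sd > 0, sigma_scale > 0)
  structure(list(fixed_sd = fixed_sd, sigma_scale = sigma_scale),
            class = "prior_spec")
}
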