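## MCMC for the multispecies dynamic occupancy model: adaptive
## Metropolis-within-Gibbs on the marginalized likelihood (default) and a
## data-augmentation sampler (explicit latent occupancy) as a cross-check.

#' MCMC sampler settings
#'
#' Desk-scale defaults: 3 chains, 4,000 burn-in iterations, then 8,000
#' sampling iterations thinned by 2 (4,000 retained draws per chain).
#' Heavier settings (e.g. 250,000 burn-in, 25,000 iterations, thin 10) can
#' be requested for production runs.
#'
#' @param chains number of chains (>= 2 for convergence diagnostics).
#' @param iter post-burn-in iterations per chain (`iter / thin` draws are
#'   retained).
#' @param burn_in adaptation/burn-in iterations (discarded).
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param seed integer seed; each chain derives its own stream.
#' @return a list of settings.
#' @export
mcmc_settings <- function(chains = 3L, iter = 8000L, burn_in = 4000L,
                          thin = 2L, seed = 1L) {
  stopifnot(chains >= 1L, iter >= 1L, burn_in >= 0L, thin >= 1L)
  list(chains = as.integer(chains), iter = as.integer(iter),
       burn_in = as.integer(burn_in), thin = as.integer(thin),
       seed = as.integer(seed))
}

# segment sums of a per-pair vector by species (pairs sorted by species)
.group_sum <- function(x, tab, ends) {
  cs <- cumsum(c(0, x))
  cs[ends + 1L] - cs[ends - tab + 1L]
}

# detection/state building blocks per pair, on the log scale (R reference
# path; used by the data-augmentation backend and by z imputation)
.pair_parts_fs <- function(dataset, fixed, spm) {
  sp <- dataset$pairs$sp
  eta1 <- cbind(spm[, "delta1"],
                spm[, "delta1"] + spm[, "delta2"],
                spm[, "delta1"] + spm[, "delta3"])
  eta2 <- eta1 + fixed[[9L]]
  lp1 <- plogis(eta1, log.p = TRUE);  lq1 <- plogis(-eta1, log.p = TRUE)
  lp2 <- plogis(eta2, log.p = TRUE);  lq2 <- plogis(-eta2, log.p = TRUE)
  logA1 <- rowSums(dataset$det1 * lp1[sp, , drop = FALSE] +
                   (dataset$tot1 - dataset$det1) * lq1[sp, , drop = FALSE])
  logA2 <- rowSums(dataset$det2 * lp2[sp, , drop = FALSE] +
                   (dataset$tot2 - dataset$det2) * lq2[sp, , drop = FALSE])
  R <- dataset$pairs$R; C <- dataset$pairs$C
  a <- fixed[[1L]] * (1 - R) + fixed[[2L]] * R + fixed[[3L]] * (1 - R) * C +
    fixed[[4L]] * R * C + spm[sp, "u"]
  b <- fixed[[5L]] * (1 - R) + fixed[[6L]] * R + fixed[[7L]] * (1 - R) * C +
    fixed[[8L]] * R * C + spm[sp, "v"]
  list(logA1 = logA1, logA2 = logA2,
       any1 = rowSums(dataset$det1) > 0, any2 = rowSums(dataset$det2) > 0,
       lphi = a + b * (dataset$pairs$Dprime - 0.5),
       lpsi = spm[sp, "lpsi"], lgam = spm[sp, "lgamma"])
}

.pair_parts <- function(dataset, params) {
  .pair_parts_fs(dataset, unname(params$fixed), params$species)
}

# four-branch log-weights over (z1, z2) given the detection history
.branch_logw <- function(parts) {
  w <- cbind(t11 = plogis(parts$lpsi, log.p = TRUE) + parts$logA1 +
               plogis(parts$lphi, log.p = TRUE) + parts$logA2,
             t10 = plogis(parts$lpsi, log.p = TRUE) + parts$logA1 +
               plogis(-parts$lphi, log.p = TRUE),
             t01 = plogis(-parts$lpsi, log.p = TRUE) +
               plogis(parts$lgam, log.p = TRUE) + parts$logA2,
             t00 = plogis(-parts$lpsi, log.p = TRUE) +
               plogis(-parts$lgam, log.p = TRUE))
  w[parts$any2, "t10"] <- -Inf
  w[parts$any1, "t01"] <- -Inf
  w[parts$any1 | parts$any2, "t00"] <- -Inf
  w
}

# draw (z1, z2) per pair from the exact conditional given history + params
.sample_z <- function(dataset, params, parts = NULL) {
  if (is.null(parts)) parts <- .pair_parts(dataset, params)
  w <- .branch_logw(parts)
  m <- pmax(w[, 1L], w[, 2L], w[, 3L], w[, 4L])
  pw <- exp(w - m)
  pw <- pw / rowSums(pw)
  u <- runif(nrow(pw))
  br <- 1L + (u > pw[, 1L]) + (u > pw[, 1L] + pw[, 2L]) +
    (u > pw[, 1L] + pw[, 2L] + pw[, 3L])
  list(z1 = as.integer(br <= 2L), z2 = as.integer(br %in% c(1L, 3L)))
}

# complete-data per-pair log-likelihood given imputed z
.pair_logliks_da_fs <- function(dataset, fixed, spm, z1, z2) {
  parts <- .pair_parts_fs(dataset, fixed, spm)
  state <- ifelse(z1 == 1L, plogis(parts$lpsi, log.p = TRUE),
                  plogis(-parts$lpsi, log.p = TRUE)) +
    ifelse(z1 == 1L,
           ifelse(z2 == 1L, plogis(parts$lphi, log.p = TRUE),
                  plogis(-parts$lphi, log.p = TRUE)),
           ifelse(z2 == 1L, plogis(parts$lgam, log.p = TRUE),
                  plogis(-parts$lgam, log.p = TRUE)))
  state + z1 * parts$logA1 + z2 * parts$logA2
}

#' One-dimensional random-walk Metropolis sampler
#'
#' Small generic utility (also used internally for random-effect SD
#' updates): symmetric Gaussian proposals on an unconstrained scalar.
#'
#' @param logtarget function of a scalar returning the log target density.
#' @param init starting value.
#' @param n number of iterations.
#' @param scale proposal SD.
#' @return list with `draws` (length n) and acceptance rate `acc`.
#' @export
rw_metropolis <- function(logtarget, init, n, scale) {
  draws <- numeric(n)
  cur <- init
  lcur <- logtarget(cur)
  acc <- 0L
  for (i in seq_len(n)) {
    prop <- cur + rnorm(1L, 0, scale)
    lprop <- logtarget(prop)
    if (is.finite(lprop) && log(runif(1L)) < lprop - lcur) {
      cur <- prop; lcur <- lprop; acc <- acc + 1L
    }
    draws[i] <- cur
  }
  list(draws = draws, acc = acc / n)
}

.fam_hyper <- function(h, fam) {
  switch(fam,
         u = c(0, h[["sigma_u"]]),
         v = c(0, h[["sigma_v"]]),
         lgamma = c(h[["mu_gamma"]], h[["sigma_gamma"]]),
         lpsi = c(h[["mu_psi"]], h[["sigma_psi"]]),
         delta1 = c(h[["mu_delta1"]], h[["sigma_delta1"]]),
         delta2 = c(h[["mu_delta2"]], h[["sigma_delta2"]]),
         delta3 = c(h[["mu_delta3"]], h[["sigma_delta3"]]))
}

# default overdispersed initial values, drawn under the caller's RNG state
.init_params <- function(S) {
  fx <- stats::setNames(rnorm(9L, 0, 1), .FIXED_NAMES)
  hy <- stats::setNames(numeric(12L), .HYPER_NAMES)
  hy[grep("^mu", .HYPER_NAMES)] <- rnorm(5L, 0, 1)
  hy[grep("^sigma", .HYPER_NAMES)] <- runif(7L, 0.3, 1)
  draw_species_params(model_params(S = S, fixed = fx, hyper = hy), S)
}

# one MCMC chain; returns a draws matrix (stored iterations x parameters).
# Update scheme per iteration (marginalized backend; the DA backend adds a
# latent-state refresh first and evaluates the complete-data likelihood):
#   1. three fixed-effect blocks (alphas; betas; delta_t), random walk
#   2. three species blocks (u+v; lgamma+lpsi; delta1..3), proposed for all
#      species at once with per-species accept/reject (valid because pair
#      likelihoods partition by species given the fixed effects)
#   3. rescaling moves (u, sigma_u) -> (c u, c sigma_u) and likewise for v:
#      an ancillarity-sufficiency interweaving step that breaks the funnel
#      coupling between random effects and their SD
#   4. conjugate Gibbs for the five hypermeans
#   5. log-scale random walks for the seven random-effect SDs
# Proposal scales adapt (Robbins-Monro) during burn-in only.
.mcmc_chain <- function(dataset, priors, settings, chain_seed, backend,
                        init = NULL) {
  set.seed(chain_seed)
  S <- length(dataset$species)
  sp <- as.integer(dataset$pairs$sp)
  Dp <- as.numeric(dataset$pairs$Dprime)
  Rj <- as.integer(dataset$pairs$R)
  Cj <- as.integer(dataset$pairs$C)
  det1 <- dataset$det1; det2 <- dataset$det2
  tot1 <- dataset$tot1; tot2 <- dataset$tot2
  tab <- tabulate(sp, S)
  ends <- cumsum(tab)
  da <- identical(backend, "da")
  z <- NULL

  pll <- function(fx, spm) {
    if (da) .pair_logliks_da_fs(dataset, fx, spm, z$z1, z$z2)
    else pair_logliks_cpp(fx, spm, sp, Dp, Rj, Cj, det1, det2, tot1, tot2)
  }

  cur <- if (is.null(init)) .init_params(S) else init
  fx <- unname(cur$fixed)
  hy <- cur$hyper
  spm <- cur$species
  if (da) z <- .sample_z(dataset, cur)
  cur_pll <- pll(fx, spm)
  cur_sum <- sum(cur_pll)
  tau0 <- priors$fixed_sd

  fixed_blocks <- list(1:4, 5:8, 9L)   # intercepts, slopes, delta_t:
  sc_fb <- c(0.2, 0.6, 0.1)            # slopes need far larger steps
  targ_fb <- c(0.25, 0.25, 0.44)
  sp_blocks <- list(c("u", "v"), c("lgamma", "lpsi"),
                    c("delta1", "delta2", "delta3"))
  sc_sb <- list(c(0.4, 0.6), c(0.6, 0.4), c(0.25, 0.3, 0.3))
  targ_sb <- c(0.35, 0.35, 0.3)
  resc_fams <- c("u", "v", "lgamma", "lpsi", "delta2", "delta3")
  resc_sigs <- c("sigma_u", "sigma_v", "sigma_gamma", "sigma_psi",
                 "sigma_delta2", "sigma_delta3")
  resc_every <- c(1L, 1L, 1L, 1L, 2L, 2L)   # delta rescales alternate
  sc_resc <- rep(0.4, length(resc_fams))
  trans_fams <- c("lgamma", "lpsi")
  sc_trans <- c(0.6, 0.3)
  sc_sig <- rep(0.3, 7L)
  sig_names <- c("sigma_u", "sigma_v", "sigma_gamma", "sigma_psi",
                 "sigma_delta1", "sigma_delta2", "sigma_delta3")
  sig_fam <- c("u", "v", "lgamma", "lpsi", "delta1", "delta2", "delta3")
  mu_names <- c(lgamma = "mu_gamma", lpsi = "mu_psi", delta1 = "mu_delta1",
                delta2 = "mu_delta2", delta3 = "mu_delta3")

  n_total <- settings$burn_in + settings$iter
  n_keep <- settings$iter %/% settings$thin
  draws <- matrix(NA_real_, n_keep, 21L + 7L * S,
                  dimnames = list(NULL, param_names(S)))
  kept <- 0L

  for (it in seq_len(n_total)) {
    adapting <- it <= settings$burn_in
    gam <- min(0.25, 2 / sqrt(it))

    if (da) {             # refresh latent occupancy, then recompute
      z <- .sample_z(dataset, vector_to_params(c(
        stats::setNames(fx, .FIXED_NAMES), hy, as.numeric(spm)), S))
      cur_pll <- pll(fx, spm)
      cur_sum <- sum(cur_pll)
    }

    ## 1. fixed-effect blocks
    for (b in seq_along(fixed_blocks)) {
      idx <- fixed_blocks[[b]]
      pfx <- fx
      pfx[idx] <- fx[idx] + rnorm(length(idx), 0, sc_fb[b])
      ppll <- pll(pfx, spm)
      logr <- sum(ppll) - cur_sum +
        sum(dnorm(pfx[idx], 0, tau0, log = TRUE) -
            dnorm(fx[idx], 0, tau0, log = TRUE))
      acc <- is.finite(logr) && log(runif(1L)) < logr
      if (acc) { fx <- pfx; cur_pll <- ppll; cur_sum <- sum(ppll) }
      if (adapting) sc_fb[b] <- sc_fb[b] * exp(gam * (acc - targ_fb[b]))
    }

    ## 2. species blocks (all species proposed, per-species acceptance)
    for (b in seq_along(sp_blocks)) {
      cols <- sp_blocks[[b]]
      pspm <- spm
      dlp <- numeric(S)
      for (ci in seq_along(cols)) {
        cn <- cols[ci]
        pspm[, cn] <- spm[, cn] + rnorm(S, 0, sc_sb[[b]][ci])
        hp <- .fam_hyper(hy, cn)
        dlp <- dlp + dnorm(pspm[, cn], hp[1], hp[2], log = TRUE) -
          dnorm(spm[, cn], hp[1], hp[2], log = TRUE)
      }
      ppll <- pll(fx, pspm)
      dls <- .group_sum(ppll - cur_pll, tab, ends)
      acc_s <- is.finite(dls) & (log(runif(S)) < dls + dlp)
      if (any(acc_s)) {
        spm[acc_s, cols] <- pspm[acc_s, cols]
        take <- acc_s[sp]
        cur_pll[take] <- ppll[take]
        cur_sum <- sum(cur_pll)
      }
      if (adapting)
        sc_sb[[b]] <- sc_sb[[b]] * exp(gam * (mean(acc_s) - targ_sb[b]))
    }

    ## 3. interweaving moves that break the random-effect funnels:
    ##    (a) rescale deviations and SD jointly; (b) translate a family
    ##    and its hypermean jointly (mean families only)
    for (b in seq_along(resc_fams)) {
      if (it %% resc_every[b] != 0L) next
      cn <- resc_fams[b]
      sn <- resc_sigs[b]
      mu0 <- .fam_hyper(hy, cn)[1]
      lc <- rnorm(1L, 0, sc_resc[b])
      cc <- exp(lc)
      pspm <- spm
      pspm[, cn] <- mu0 + (spm[, cn] - mu0) * cc
      ppll <- pll(fx, pspm)
      news <- hy[[sn]] * cc
      logr <- sum(ppll) - cur_sum + lc +
        dnorm(news, 0, priors$sigma_scale, log = TRUE) -
        dnorm(hy[[sn]], 0, priors$sigma_scale, log = TRUE)
      acc <- is.finite(logr) && log(runif(1L)) < logr
      if (acc) {
        spm <- pspm; hy[sn] <- news
        cur_pll <- ppll; cur_sum <- sum(ppll)
      }
      if (adapting) sc_resc[b] <- sc_resc[b] * exp(gam * (acc - 0.44))
    }
    for (b in seq_along(trans_fams)) {
      cn <- trans_fams[b]
      mn <- mu_names[[cn]]
      dd <- rnorm(1L, 0, sc_trans[b])
      pspm <- spm
      pspm[, cn] <- spm[, cn] + dd
      ppll <- pll(fx, pspm)
      pmu <- hy[[mn]] + dd
      logr <- sum(ppll) - cur_sum +
        dnorm(pmu, 0, tau0, log = TRUE) - dnorm(hy[[mn]], 0, tau0, log = TRUE)
      acc <- is.finite(logr) && log(runif(1L)) < logr
      if (acc) {
        spm <- pspm; hy[mn] <- pmu
        cur_pll <- ppll; cur_sum <- sum(ppll)
      }
      if (adapting) sc_trans[b] <- sc_trans[b] * exp(gam * (acc - 0.44))
    }

    ## 3c. free Gibbs moves along the likelihood-invariant directions
    ##     u_i + d with alpha0 - d, alpha1 - d (and v with beta0, beta1):
    ##     the likelihood depends on u only through alpha_ij, so shifting
    ##     all species and both realm intercepts in opposition leaves it
    ##     unchanged and the conditional of d is Normal
    for (b in 1:2) {
      cn <- c("u", "v")[b]
      sn <- c("sigma_u", "sigma_v")[b]
      idx <- if (b == 1L) 1:2 else 5:6
      prec <- S / hy[[sn]]^2 + 2 / tau0^2
      dmean <- (-sum(spm[, cn]) / hy[[sn]]^2 + sum(fx[idx]) / tau0^2) / prec
      dd <- rnorm(1L, dmean, sqrt(1 / prec))
      spm[, cn] <- spm[, cn] + dd
      fx[idx] <- fx[idx] - dd
    }

    ## 4. hypermeans: conjugate Gibbs given the species effects
    for (fam in names(mu_names)) {
      sig <- .fam_hyper(hy, fam)[2]
      x <- spm[, fam]
      prec <- S / sig^2 + 1 / tau0^2
      hy[mu_names[[fam]]] <- rnorm(1L, (sum(x) / sig^2) / prec,
                                   sqrt(1 / prec))
    }

    ## 5. random-effect SDs: random walk on log sigma (half-Normal prior)
    for (k in seq_len(7L)) {
      nm <- sig_names[k]
      xc <- spm[, sig_fam[k]] - .fam_hyper(hy, sig_fam[k])[1]
      lt <- function(ls) {
        s <- exp(ls)
        sum(dnorm(xc, 0, s, log = TRUE)) +
          dnorm(s, 0, priors$sigma_scale, log = TRUE) + log(2) + ls
      }
      step <- rw_metropolis(lt, log(hy[[nm]]), 1L, sc_sig[k])
      hy[nm] <- exp(step$draws[1L])
      if (adapting) sc_sig[k] <- sc_sig[k] * exp(gam * (step$acc - 0.44))
    }

    if (!adapting) {
      post <- it - settings$burn_in
      if (post %% settings$thin == 0L) {
        kept <- kept + 1L
        draws[kept, ] <- c(fx, hy, spm)
      }
    }
  }
  draws[seq_len(kept), , drop = FALSE]
}

#' Fit the occupancy model by MCMC
#'
#' Samples the posterior of the multispecies dynamic occupancy-detection
#' model.  The default backend works on the marginalized likelihood (latent
#' occupancy states summed out analytically; fast C++ kernel) with adaptive
#' Metropolis-within-Gibbs updates: blocked random walks on the fixed
#' effects, parallel per-species random walks on the random-effect
#' families, interweaving rescaling moves that decorrelate each zero-mean
#' random-effect family from its SD, conjugate Gibbs draws for the
#' hypermeans and log-scale random walks for the random-effect SDs.
#' Adaptation runs only during burn-in.  The `"da"` backend instead imputes
#' the latent states every iteration (data augmentation) and updates
#' parameters against the complete-data likelihood; it is slower and
#' retained as an independent cross-check of the marginalized sampler.
#'
#' @param dataset an `occu_data` object from [build_model_dataset()].
#' @param priors a [prior_spec()].
#' @param settings an [mcmc_settings()] list; `settings$seed` drives all
#'   randomness (chain c uses `seed + 7919 * c`).
#' @param backend `"marginal"` (default) or `"da"`.
#' @param inits optional list of [model_params()] (one per chain).
#' @return an object of class `occu_draws`: per-chain draw matrices plus
#'   settings and metadata.
#' @export
run_mcmc <- function(dataset, priors = prior_spec(),
                     settings = mcmc_settings(),
                     backend = c("marginal", "da"), inits = NULL) {
  backend <- match.arg(backend)
  if (nrow(dataset$pairs) == 0L) stop("empty dataset")
  t0 <- proc.time()[["elapsed"]]
  chains <- lapply(seq_len(settings$chains), function(ch) {
    .mcmc_chain(dataset, priors, settings,
                chain_seed = settings$seed + 7919L * ch, backend = backend,
                init = if (is.null(inits)) NULL else inits[[ch]])
  })
  structure(list(chains = chains,
                 param_names = colnames(chains[[1L]]),
                 monitor = c(.FIXED_NAMES, .HYPER_NAMES),
                 S = length(dataset$species),
                 species = dataset$species,
                 settings = settings, backend = backend,
                 elapsed_s = proc.time()[["elapsed"]] - t0),
            class = "occu_draws")
}

#' @export
print.occu_draws <- function(x, ...) {
  cat(sprintf("occu_draws: %d chain(s) x %d stored draws x %d parameters (%s backend)\n",
              length(x$chains), nrow(x$chains[[1L]]),
              length(x$param_names), x$backend))
  invisible(x)
}

#' @export
as.matrix.occu_draws <- function(x, ...) do.call(rbind, x$chains)

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) Rhat from between- and within-chain variances.
#' Parameters with zero variance everywhere return 1 by convention.
#'
#' @param x an `occu_draws` object or a list of draw matrices (one per
#'   chain, equal dimensions, named columns).
#' @param pars parameters to evaluate (default: monitored top-level
#'   parameters for `occu_draws`, all columns for a list).
#' @return named numeric vector of Rhat values.
#' @export
gelman_rubin <- function(x, pars = NULL) {
  chains <- if (inherits(x, "occu_draws")) x$chains else x
  if (length(chains) < 2L) stop("need at least 2 chains for Rhat")
  if (is.null(pars))
    pars <- if (inherits(x, "occu_draws")) x$monitor else colnames(chains[[1L]])
  n <- nrow(chains[[1L]])
  if (n < 10L) stop("need at least 10 draws per chain")
  vapply(pars, function(p) {
    d <- vapply(chains, function(m) m[, p], numeric(n))
    W <- mean(apply(d, 2L, var))
    B_over_n <- var(colMeans(d))
    if (W == 0) return(1)
    sqrt((n - 1) / n + B_over_n / W)
  }, numeric(1L))
}

#' Sign-consistency statistic f
#'
#' Confidence that a parameter is positive or negative: the proportion of
#' posterior draws lying on the dominant side of zero.  The default
#' (`side = "confidence"`) reports the larger of the two sign-side
#' proportions and therefore always lies in \[0.5, 1\];
#' `side = "mean"` reports the literal proportion of draws sharing the sign
#' of the posterior mean, which coincides with the default whenever the
#' mean's sign-side holds the majority (virtually always for real
#' posteriors) but is not bounded below by 0.5 for pathological samples.
#' Draws exactly at 0 count toward the mean's sign side in both modes.
#'
#' @param x numeric vector of posterior draws.
#' @param side `"confidence"` (default) or `"mean"`; see Details.
#' @return scalar f.
#' @export
f_statistic <- function(x, side = c("confidence", "mean")) {
  side <- match.arg(side)
  stopifnot(length(x) > 0L)
  s <- if (mean(x) >= 0) 1 else -1
  f_mean <- mean(x * s >= 0)
  if (side == "mean") f_mean else max(f_mean, 1 - f_mean)
}

#' Posterior summary table
#'
#' Per-parameter posterior mean, SD, 2.5% and 97.5% quantiles, Rhat and the
#' sign-consistency statistic f.  Species-level colonization and detection
#' parameters are additionally summarized as per-draw means across species
#' (rows `Gamma` -- mean colonization probability -- and
#' `delta_1..delta_3`, on the logit scale), mirroring the usual reporting
#' layout.
#'
#' @param draws an `occu_draws` object.
#' @param pars parameters to summarize; default: all stored parameters plus
#'   the across-species means.
#' @param species_means include the across-species derived rows.
#' @return a data frame with columns `param, mean, sd, q2.5, q97.5, Rhat,
#'   f`.
#' @export
posterior_summary <- function(draws, pars = NULL, species_means = TRUE) {
  stopifnot(inherits(draws, "occu_draws"))
  chains <- draws$chains
  S <- draws$S
  if (species_means) {
    chains <- lapply(chains, function(m) {
      lg <- m[, paste0("lgamma[", seq_len(S), "]"), drop = FALSE]
      add <- cbind(Gamma = rowMeans(plogis(lg)),
                   delta_1 = rowMeans(m[, paste0("delta1[", seq_len(S), "]"),
                                        drop = FALSE]),
                   delta_2 = rowMeans(m[, paste0("delta2[", seq_len(S), "]"),
                                        drop = FALSE]),
                   delta_3 = rowMeans(m[, paste0("delta3[", seq_len(S), "]"),
                                        drop = FALSE]))
      cbind(m, add)
    })
  }
  if (is.null(pars)) pars <- colnames(chains[[1L]])
  all_draws <- do.call(rbind, chains)[, pars, drop = FALSE]
  rh <- if (length(chains) >= 2L && nrow(chains[[1L]]) >= 10L)
    gelman_rubin(chains, pars = pars) else rep(NA_real_, length(pars))
  q <- t(apply(all_draws, 2L, quantile, probs = c(0.025, 0.975),
               names = FALSE))
  data.frame(param = pars,
             mean = colMeans(all_draws),
             sd = apply(all_draws, 2L, sd),
             q2.5 = q[, 1L], q97.5 = q[, 2L],
             Rhat = as.numeric(rh),
             f = apply(all_draws, 2L, f_statistic),
             row.names = NULL, stringsAsFactors = FALSE)
}
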