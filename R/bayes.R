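# Bayesian three-source, two-isotope mixing model.
#
# Model: source fractions p ~ Dirichlet(alpha); for isotope j and
# observation i,
#   obs_ij ~ Normal( sum_k p_k mu_jk , sqrt( sum_k p_k^2 sigma_jk^2 + sigma_j^2 ) )
# with per-isotope residual SDs sigma_j under half-normal priors. This is
# the classical fully-hierarchical-free mixing likelihood (the simmr/
# MixSIAR form without discrimination factors or concentration
# dependence). The sampler is a component-blocked adaptive random-walk
# Metropolis on stick-breaking log-ratio coordinates (logit fossil
# fraction, logit C3 share of non-fossil carbon) and log residual SDs, so
# every draw lies on the simplex by construction and the artifact stays dependency-light and fully seeded.

#' Dirichlet prior on the source fractions
#'
#' @param alpha Positive length-3 concentration parameters, order fossil,
#'   C3, C4. The prior mean is `alpha / sum(alpha)`.
#' @return An object of class `mixing_prior`.
#' @export
mixing_prior <- function(alpha) {
  alpha <- as.numeric(alpha)
  if (length(alpha) != 3L || anyNA(alpha) || any(alpha <= 0)) {
    stop_fmt("alpha must be three positive numbers (fossil, C3, C4)")
  }
  structure(list(alpha = stats::setNames(alpha, c("fossil", "C3", "C4")),
                 mean = alpha / sum(alpha)),
            class = "mixing_prior")
}

#' Uniform prior on the simplex
#' @return `mixing_prior(c(1, 1, 1))`.
#' @export
uniform_prior <- function() mixing_prior(c(1, 1, 1))

#' Build a Dirichlet prior from an enumeration summary
#'
#' Moment matching: `alpha_k = m_k * nu` with `m_k` the feasible-set means
#' and the concentration `nu` chosen so that the average Dirichlet-implied
#' variance `m_k (1 - m_k) / (nu + 1)` matches the average feasible-set
#' variance. Each `alpha_k` is floored at 0.5 so no source is ruled out a
#' priori.
#'
#' @param x A `feasible_set` (needs `n_feasible >= 2` so the spread is
#'   defined), or a numeric length-3 vector of means.
#' @param vars Length-3 feasible-set variances (only when `x` is a numeric
#'   vector of means).
#' @param nu Optional concentration override; skips moment matching.
#' @param alpha_floor Lower bound applied to each `alpha_k` (default 0.5).
#' @param ... Passed between methods.
#' @return A [mixing_prior()].
#' @examples
#' build_prior(c(0.4, 0.4, 0.2), nu = 10)   # alpha (4, 4, 2)
#' @export
build_prior <- function(x, ...) UseMethod("build_prior")

#' @rdname build_prior
#' @export
build_prior.feasible_set <- function(x, ...) {
  if (x$n_feasible < 2) {
    stop_fmt("feasible-set spread undefined (n_feasible < 2); use a uniform prior fallback")
  }
  s <- x$summary
  build_prior(stats::setNames(s$mean, s$source), vars = s$sd^2, ...)
}

#' @rdname build_prior
#' @export
build_prior.default <- function(x, vars = NULL, nu = NULL, alpha_floor = 0.5,
                                ...) {
  m <- as.numeric(x)
  if (length(m) != 3L || anyNA(m) || !all(is.finite(m))) {
    stop_fmt("means must be three finite numbers")
  }
  if (is.null(nu)) {
    if (is.null(vars) || anyNA(vars) || !all(is.finite(vars))) {
      stop_fmt("non-finite feasible-set moments")
    }
    vbar <- mean(vars)
    if (vbar <= 0) {
      stop_fmt("zero feasible-set variance; supply nu or use a uniform prior")
    }
    nu <- mean(m * (1 - m)) / vbar - 1
    if (!is.finite(nu) || nu <= 0) {
      stop_fmt("moment matching failed (implied concentration <= 0)")
    }
    nu <- min(nu, 1e5)
  }
  mixing_prior(pmax(m * nu, alpha_floor))
}

#' MCMC sampler settings
#'
#' @param n_iter Total iterations per chain (including burn-in).
#' @param n_burn Burn-in iterations discarded per chain; proposal-scale
#'   adaptation runs only during burn-in and is frozen afterwards.
#' @param n_chains Number of chains (>= 2 so split R-hat is defined).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed; identical config and inputs give bit-identical
#'   draws.
#' @param proposal_scale Initial random-walk SD for both blocks; adapted
#'   towards a 20-40% acceptance rate during burn-in.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 10000L, n_burn = 5000L, n_chains = 4L,
                        thin = 1L, seed = 42L, proposal_scale = 0.5) {
  n_iter <- as.integer(n_iter); n_burn <- as.integer(n_burn)
  n_chains <- as.integer(n_chains); thin <- as.integer(thin)
  if (n_iter <= n_burn) stop_fmt("n_iter must exceed n_burn")
  if (n_chains < 2L) stop_fmt("n_chains must be >= 2 for diagnostics")
  if (thin < 1L) stop_fmt("thin must be >= 1")
  if (proposal_scale <= 0) stop_fmt("proposal_scale must be > 0")
  structure(list(n_iter = n_iter, n_burn = n_burn, n_chains = n_chains,
                 thin = thin, seed = as.integer(seed),
                 proposal_scale = proposal_scale),
            class = "mcmc_config")
}

#' Fit the Bayesian mixing model by MCMC
#'
#' @param obs Observations sharing one fraction triple: a data frame with
#'   columns `d13c_permil` and `D14c_permil` (aliases `d13c`, `D14c`), or
#'   a numeric matrix with those two columns.
#' @param ems An [endmember_set()].
#' @param prior A [mixing_prior()]; default uniform.
#' @param cfg An [mcmc_config()].
#' @param resid_scales Half-normal prior scales for the residual SDs,
#'   `c(d13c, D14c)` in permil; defaults 1 and 100 (weakly informative at
#'   each isotope's natural scale).
#' @param likelihood Set `FALSE` to sample the prior only (used by
#'   prior-recovery checks).
#' @return An object of class `mixfit`: `draws` (matrix of post-burn-in,
#'   thinned draws from all chains: `f_fossil`, `f_C3`, `f_C4`,
#'   `sigma_d13c`, `sigma_D14c`), `chain` (chain index per draw),
#'   `summary` (posterior mean, SD, 2.5/97.5% quantiles, split R-hat and
#'   ESS per parameter), `converged` flag (`FALSE`, with a warning, when
#'   any R-hat exceeds 1.05), `n_obs`, and the prior/config echo.
#' @examples
#' \donttest{
#' fit <- fit_mixture(list(d13c = -25.7, D14c = -380.7),
#'                    cfg = mcmc_config(n_iter = 3000, n_burn = 1000,
#'                                      n_chains = 2, seed = 1))
#' fit$summary
#' }
#' @export
fit_mixture <- function(obs, ems = default_endmembers(),
                        prior = uniform_prior(), cfg = mcmc_config(),
                        resid_scales = c(1, 100), likelihood = TRUE) {
  if (is.list(obs) && !is.data.frame(obs)) obs <- as.data.frame(obs)
  if (is.matrix(obs)) obs <- as.data.frame(obs)
  x1 <- obs[["d13c_permil"]] %||% obs[["d13c"]]
  x2 <- obs[["D14c_permil"]] %||% obs[["D14c"]]
  if (is.null(x1) || is.null(x2) || length(x1) == 0) {
    stop_fmt("obs must provide at least one (d13c, D14c) pair")
  }
  if (anyNA(x1) || anyNA(x2)) stop_fmt("obs contain missing isotope values")
  stopifnot(inherits(prior, "mixing_prior"), inherits(cfg, "mcmc_config"))
  if (length(resid_scales) != 2L || any(resid_scales <= 0)) {
    stop_fmt("resid_scales must be two positive values (d13c, D14c)")
  }

  mu1 <- ems$d13c_mean; s1sq <- ems$d13c_sd^2
  mu2 <- ems$D14c_mean; s2sq <- ems$D14c_sd^2
  alpha <- prior$alpha
  hs2 <- resid_scales^2
  use_lik <- isTRUE(likelihood)

  # Stick-breaking log-ratio coordinates aligned with the two isotopic
  # constraints: th[1] = logit(f_fossil) is the direction the radiocarbon
  # balance pins, th[2] = logit(f_C3 / (f_C3 + f_C4)) the direction the
  # d13c balance pins. The Jacobian determinant is p1*p2*p3, identical to
  # the additive log-ratio transform, so the Dirichlet prior contributes
  # sum(alpha * log p).
  p_of <- function(th) {
    p1 <- stats::plogis(th[1L])
    s <- stats::plogis(th[2L])
    c(p1, (1 - p1) * s, (1 - p1) * (1 - s))
  }
  log_post <- function(th) {
    p <- p_of(th)
    logp <- log(p)
    u <- th[3:4]
    sig2 <- exp(2 * u)
    lp <- sum(alpha * logp) - sum(sig2 / (2 * hs2)) + sum(u)
    if (use_lik) {
      m1 <- p[1L] * mu1[1L] + p[2L] * mu1[2L] + p[3L] * mu1[3L]
      v1 <- p[1L]^2 * s1sq[1L] + p[2L]^2 * s1sq[2L] + p[3L]^2 * s1sq[3L] + sig2[1L]
      m2 <- p[1L] * mu2[1L] + p[2L] * mu2[2L] + p[3L] * mu2[3L]
      v2 <- p[1L]^2 * s2sq[1L] + p[2L]^2 * s2sq[2L] + p[3L]^2 * s2sq[3L] + sig2[2L]
      lp <- lp + sum(stats::dnorm(x1, m1, sqrt(v1), log = TRUE)) +
        sum(stats::dnorm(x2, m2, sqrt(v2), log = TRUE))
    }
    lp
  }

  n_keep <- (cfg$n_iter - cfg$n_burn) %/% cfg$thin
  # component-wise blocks: the posterior can be an order of magnitude
  # tighter along the fossil log-ratio than along the C3/C4 one (the
  # radiocarbon constraint), so every coordinate gets its own adapted scale
  n_par <- 4L
  prior_mean <- pmax(prior$mean, 1e-4)
  z_center <- c(stats::qlogis(prior_mean[1]),
                stats::qlogis(prior_mean[2] / (prior_mean[2] + prior_mean[3])))
  u_center <- log(resid_scales / 2)

  set.seed(cfg$seed)
  chain_draws <- vector("list", cfg$n_chains)
  for (ch in seq_len(cfg$n_chains)) {
    th <- c(z_center + stats::rnorm(2, 0, 0.5),
            u_center + stats::rnorm(2, 0, 0.25))
    lp_cur <- log_post(th)
    log_scale <- rep(log(cfg$proposal_scale), n_par)
    acc <- integer(n_par)
    batch <- 0L
    draws <- matrix(NA_real_, n_keep, 5L)
    k <- 0L
    for (it in seq_len(cfg$n_iter)) {
      adapting <- it <= cfg$n_burn
      for (b in seq_len(n_par)) {
        prop <- th
        prop[b] <- prop[b] + exp(log_scale[b]) * stats::rnorm(1)
        lp_prop <- log_post(prop)
        if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur) {
          th <- prop
          lp_cur <- lp_prop
          acc[b] <- acc[b] + 1L
        }
      }
      if (adapting && it %% 50L == 0L) {
        batch <- batch + 1L
        rate <- acc / 50
        log_scale <- log_scale + (rate - 0.35) / sqrt(batch)
        acc[] <- 0L
      }
      if (!adapting && (it - cfg$n_burn) %% cfg$thin == 0L) {
        k <- k + 1L
        draws[k, 1:3] <- p_of(th)
        draws[k, 4:5] <- exp(th[3:4])
      }
    }
    chain_draws[[ch]] <- draws[seq_len(k), , drop = FALSE]
  }

  par_names <- c("f_fossil", "f_C3", "f_C4", "sigma_d13c", "sigma_D14c")
  all_draws <- do.call(rbind, chain_draws)
  colnames(all_draws) <- par_names
  chain_id <- rep(seq_len(cfg$n_chains),
                  vapply(chain_draws, nrow, integer(1)))

  summ <- data.frame(
    param = par_names,
    mean = colMeans(all_draws),
    sd = apply(all_draws, 2, stats::sd),
    q2.5 = apply(all_draws, 2, stats::quantile, probs = 0.025),
    q97.5 = apply(all_draws, 2, stats::quantile, probs = 0.975),
    rhat = vapply(seq_along(par_names), function(j) {
      split_rhat(lapply(chain_draws, function(m) m[, j]))
    }, numeric(1)),
    ess = vapply(seq_along(par_names), function(j) {
      ess_mean(lapply(chain_draws, function(m) m[, j]))
    }, numeric(1)),
    row.names = NULL
  )
  converged <- all(summ$rhat <= 1.05, na.rm = TRUE)
  if (!converged) {
    warning(sprintf("mixing-model MCMC may not have converged: max split R-hat = %.3f",
                    max(summ$rhat, na.rm = TRUE)), call. = FALSE)
  }
  structure(list(draws = all_draws, chain = chain_id, summary = summ,
                 converged = converged, n_obs = length(x1),
                 prior = prior, config = cfg,
                 resid_scales = resid_scales),
            class = "mixfit")
}

#' @export
print.mixfit <- function(x, ...) {
  cat(sprintf("Bayesian mixing fit: %d observation(s), %d chains x %d kept draws%s\n",
              x$n_obs, x$config$n_chains,
              nrow(x$draws) / x$config$n_chains,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  s <- x$summary
  s[, -1] <- round(s[, -1], 4)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Pooled source apportionment over sample groups
#'
#' Two-stage apportionment for each group of samples: every sample is
#' enumerated ([enumerate_mixtures()]), the per-sample feasible-set means
#' and variances are averaged within the group and moment-matched to a
#' Dirichlet prior ([build_prior()]), and the group's observation pairs
#' are fitted jointly with [fit_mixture()]. Seasonal contributions pool
#' all samples of a site-season cell; annual contributions pool all
#' samples of a site.
#'
#' @param samples A sample data frame (see [load_samples()]).
#' @param ems An [endmember_set()].
#' @param grouping `"site_annual"`, `"site_season"`, or `"per_sample"`.
#' @param enum_cfg An [enum_config()] used for the prior stage. Samples
#'   whose radiocarbon fossil fraction falls outside `[0, 1]` have the
#'   band centre clipped into `[0, 1]`; samples whose enumeration is
#'   empty are dropped from the prior stage (with a warning), and a
#'   uniform prior is used if no sample in the group could be enumerated.
#' @param cfg An [mcmc_config()]; group `g` (in stable first-appearance
#'   order) is fitted with seed `cfg$seed + g - 1`, so a single-group
#'   call reproduces `fit_mixture` at `cfg$seed` exactly.
#' @param respect_exclusion Drop rows flagged `excluded` first (default
#'   `TRUE`).
#' @return An object of class `pooled_fits`: `summary` (a tidy data frame
#'   with columns `group`, `source`, `mean`, `sd`, `q2.5`, `q97.5`,
#'   `rhat`, `ess`, `n_obs`) and `fits` (named list of `mixfit` objects).
#'   Empty groups are skipped with a warning and listed in
#'   `attr(, "skipped")`.
#' @export
pool_and_fit <- function(samples, ems = default_endmembers(),
                         grouping = c("site_annual", "site_season", "per_sample"),
                         enum_cfg = enum_config(), cfg = mcmc_config(),
                         respect_exclusion = TRUE) {
  grouping <- match.arg(grouping)
  if (respect_exclusion) samples <- samples[!samples$excluded, , drop = FALSE]
  if (nrow(samples) == 0) stop_fmt("no samples left after exclusion filtering")
  key <- switch(grouping,
                site_annual = samples$site,
                site_season = paste(samples$site, samples$season, sep = ":"),
                per_sample = samples$sample_id)
  groups <- unique(key)
  fits <- list()
  rows <- list()
  skipped <- character(0)
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    sub <- samples[key == g, , drop = FALSE]
    if (nrow(sub) == 0) {
      warning(sprintf("group '%s' is empty; skipped", g), call. = FALSE)
      skipped <- c(skipped, g)
      next
    }
    means <- matrix(NA_real_, nrow(sub), 3)
    vars <- matrix(NA_real_, nrow(sub), 3)
    for (i in seq_len(nrow(sub))) {
      center <- fossil_fraction_14c(sub$D14c_permil[i], ems)$fraction
      center <- min(max(center, 0), 1)
      fs <- tryCatch(
        enumerate_mixtures(sub[i, ], ems, enum_cfg, fossil_center = center),
        error = function(e) NULL)
      if (!is.null(fs)) {
        means[i, ] <- fs$summary$mean
        vars[i, ] <- fs$summary$sd^2
      }
    }
    ok <- stats::complete.cases(means)
    if (!all(ok)) {
      warning(sprintf("group '%s': %d sample(s) had empty enumerations and were dropped from the prior stage",
                      g, sum(!ok)), call. = FALSE)
    }
    prior <- if (any(ok)) {
      tryCatch(
        build_prior(colMeans(means[ok, , drop = FALSE]),
                    vars = colMeans(vars[ok, , drop = FALSE])),
        error = function(e) uniform_prior())
    } else {
      warning(sprintf("group '%s': enumeration failed for every sample; using a uniform prior", g),
              call. = FALSE)
      uniform_prior()
    }
    cfg_g <- cfg
    cfg_g$seed <- cfg$seed + gi - 1L
    fit <- fit_mixture(sub[, c("d13c_permil", "D14c_permil")], ems,
                       prior = prior, cfg = cfg_g)
    fits[[g]] <- fit
    s <- fit$summary[1:3, ]
    rows[[g]] <- data.frame(group = g,
                            source = c("fossil", "C3", "C4"),
                            mean = s$mean, sd = s$sd,
                            q2.5 = s$q2.5, q97.5 = s$q97.5,
                            rhat = s$rhat, ess = s$ess,
                            n_obs = fit$n_obs,
                            row.names = NULL)
  }
  summary <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- structure(list(summary = summary, fits = fits, grouping = grouping),
                   class = "pooled_fits")
  attr(out, "skipped") <- skipped
  out
}

#' @export
print.pooled_fits <- function(x, ...) {
  cat(sprintf("Pooled mixing fits (%s): %d group(s)\n", x$grouping,
              length(x$fits)))
  s <- x$summary
  s[, 3:8] <- round(s[, 3:8], 3)
  print(s, row.names = FALSE)
  invisible(x)
}
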