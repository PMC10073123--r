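small_cfg <- function(seed = 1, chains = 2) {
  mcmc_config(n_iter = 4000, n_burn = 2000, n_chains = chains, seed = seed)
}

test_that("moment matching builds the documented Dirichlet", {
  # uniform case: means 1/3, variances 1/18 imply nu = (2/9)/(1/18) - 1 = 3
  pr <- build_prior(rep(1 / 3, 3), vars = rep(1 / 18, 3))
  expect_equal(unname(pr$alpha), rep(1, 3), tolerance = 1e-9)
  # explicit concentration: alpha = m * nu
  pr2 <- build_prior(c(0.4, 0.4, 0.2), nu = 10)
  expect_equal(unname(pr2$alpha), c(4, 4, 2))
  expect_equal(unname(pr2$mean), c(0.4, 0.4, 0.2))
  # floor keeps every source representable
  pr3 <- build_prior(c(0.01, 0.49, 0.5), nu = 10)
  expect_equal(unname(pr3$alpha[1]), 0.5)
  expect_error(build_prior(c(0.4, NA, 0.2), vars = rep(0.01, 3)), "finite")
  expect_error(build_prior(c(0.4, 0.4, 0.2), vars = rep(0, 3)), "variance")
})

test_that("a feasible set feeds the prior its own moments", {
  fs <- enumerate_mixtures(list(d13c = -25.7, D14c = -380.7))
  pr <- build_prior(fs)
  expect_equal(unname(pr$mean), fs$summary$mean, tolerance = 1e-9)
  single <- fs
  single$points <- fs$points[1, ]
  single$n_feasible <- 1L
  single$summary <- summarize_feasible(single)
  expect_error(build_prior(single), "n_feasible")
})

test_that("mcmc_config rejects inconsistent settings", {
  expect_error(mcmc_config(n_iter = 100, n_burn = 100), "n_iter")
  expect_error(mcmc_config(n_chains = 1), "n_chains")
  expect_error(mcmc_config(thin = 0), "thin")
  expect_error(mixing_prior(c(1, -1, 1)), "positive")
})

test_that("posterior collapses onto the pure source in the delta limit", {
  ems <- endmember_set(c(-29, -26.7, -16.4), rep(1e-6, 3),
                       c(-1000, 30, 30), rep(1e-6, 3))
  fit <- fit_mixture(list(d13c = -26.7, D14c = 30), ems = ems,
                     cfg = small_cfg(seed = 7),
                     resid_scales = c(0.05, 5))
  m <- fit$summary$mean[1:3]
  expect_lt(max(abs(m - c(0, 1, 0))), 0.01)
})

test_that("tight endmembers recover the exact-solver solution", {
  ems <- endmember_set(c(-29, -26.7, -16.4), rep(0.1, 3),
                       c(-1000, 30, 30), rep(1, 3))
  fit <- fit_mixture(list(d13c = -25.7, D14c = -380.7), ems = ems,
                     cfg = small_cfg(seed = 8),
                     resid_scales = c(0.2, 20))
  expect_equal(fit$summary$mean[1:3], c(0.3987, 0.4151, 0.1861),
               tolerance = 0.05)
})

test_that("draws are seeded, simplex-closed, and summarized with diagnostics", {
  obs <- list(d13c = -25.7, D14c = -380.7)
  f1 <- fit_mixture(obs, cfg = small_cfg(seed = 42))
  f2 <- fit_mixture(obs, cfg = small_cfg(seed = 42))
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_mixture(obs, cfg = small_cfg(seed = 43))
  expect_false(identical(f1$draws, f3$draws))
  expect_equal(rowSums(f1$draws[, 1:3]), rep(1, nrow(f1$draws)),
               tolerance = 1e-12)
  expect_true(all(f1$draws[, 1:3] >= 0))
  expect_true(all(f1$draws[, 4:5] > 0))
  expect_true(all(is.finite(f1$summary$rhat)))
  expect_true(all(f1$summary$ess > 50))
})

test_that("with the likelihood disabled the posterior is the prior", {
  pr <- mixing_prior(c(2, 3, 4))
  fit <- fit_mixture(list(d13c = -25, D14c = -400), prior = pr,
                     cfg = mcmc_config(n_iter = 12000, n_burn = 2000,
                                       n_chains = 2, seed = 5),
                     likelihood = FALSE)
  expect_equal(fit$summary$mean[1:3], c(2, 3, 4) / 9, tolerance = 0.02)
  # Dirichlet variance m(1-m)/(nu+1), nu = 9
  expect_equal(fit$summary$sd[1:3]^2,
               (c(2, 3, 4) / 9) * (1 - c(2, 3, 4) / 9) / 10,
               tolerance = 0.15)
})

test_that("posterior means recover a known mixture from its own noise", {
  p_true <- c(0.5, 0.3, 0.2)
  set.seed(901)
  obs <- gen_obs_at_truth(50, p_true)
  fit <- fit_mixture(obs, cfg = small_cfg(seed = 902))
  s <- fit$summary
  for (k in 1:3) {
    expect_lt(abs(s$mean[k] - p_true[k]), 2 * s$sd[k] + 0.01)
  }
})

test_that("lower Delta14C never decreases the fossil posterior mean", {
  fits <- lapply(c(-250, -450, -650), function(D) {
    fit_mixture(list(d13c = -25.5, D14c = D), cfg = small_cfg(seed = 10))
  })
  fossil <- vapply(fits, function(f) f$summary$mean[1], numeric(1))
  expect_true(all(diff(fossil) > 0))
})

test_that("pool_and_fit groups, excludes, and seeds as documented", {
  s <- load_table1()
  pf <- pool_and_fit(s, grouping = "site_annual",
                     cfg = mcmc_config(n_iter = 2000, n_burn = 1000,
                                       n_chains = 2, seed = 3))
  expect_equal(sort(unique(pf$summary$group)), sort(c("TRF", "SNU", "HUF", "CRI")))
  expect_equal(nrow(pf$summary), 12L)  # 4 groups x 3 sources
  expect_equal(unique(pf$summary$n_obs[pf$summary$group == "SNU"]), 18L)
  expect_equal(unique(pf$summary$n_obs[pf$summary$group == "TRF"]), 21L)

  # a single-sample call reduces exactly to fit_mixture at the same seed
  one <- s[s$sample_id == "TRF_2020-02-07", ]
  pf1 <- pool_and_fit(one, grouping = "per_sample",
                      cfg = mcmc_config(n_iter = 2000, n_burn = 1000,
                                        n_chains = 2, seed = 17))
  center <- fossil_fraction_14c(one$D14c_permil)$fraction
  fs <- enumerate_mixtures(one, cfg = enum_config(), fossil_center = center)
  manual <- fit_mixture(one[, c("d13c_permil", "D14c_permil")],
                        prior = build_prior(fs),
                        cfg = mcmc_config(n_iter = 2000, n_burn = 1000,
                                          n_chains = 2, seed = 17))
  expect_identical(pf1$fits[[1]]$draws, manual$draws)
})

test_that("site-season pooling covers the observed cells", {
  s <- load_table1()
  sub <- s[s$site %in% c("HUF", "CRI"), ]
  pf <- pool_and_fit(sub, grouping = "site_season",
                     cfg = mcmc_config(n_iter = 1500, n_burn = 500,
                                       n_chains = 2, seed = 9))
  # HUF: winter + fall; CRI: winter + fall
  expect_equal(length(pf$fits), 4L)
  expect_true(all(grepl(":(winter|fall)$", names(pf$fits))))
})
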