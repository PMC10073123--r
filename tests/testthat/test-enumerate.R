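test_that("enum_config validates its ranges", {
  expect_error(enum_config(increment = 0), "increment")
  expect_error(enum_config(increment = 0.1), "increment")
  expect_error(enum_config(tol_d13c = 0), "tol_d13c")
  expect_error(enum_config(fossil_band_halfwidth = 1.5), "fossil_band")
})

test_that("pinned enumeration reproduces the closed-form feasible band", {
  # fossil pinned at the radiocarbon value 0.39874; the delta13C tolerance
  # maps to f_C3 in (central +/- 0.1/10.3) = [0.40543, 0.42485]
  fs <- enumerate_mixtures(list(d13c = -25.7, D14c = -380.7),
                           cfg = enum_config(increment = 0.001,
                                             pin_fossil = TRUE))
  s <- fs$summary
  expect_equal(s$mean[s$source == "C3"], 0.4151, tolerance = 0.0015)
  expect_gte(min(fs$points$f_C3), 0.40543)
  expect_lte(max(fs$points$f_C3), 0.42485)
  expect_equal(unique(fs$points$f_fossil), 410.7 / 1030, tolerance = 1e-12)
  # every point closes exactly
  expect_equal(rowSums(fs$points), rep(1, fs$n_feasible), tolerance = 1e-12)
})

test_that("every returned point passes an independent constraint re-check", {
  obs <- list(d13c = -25.1, D14c = -422.0)
  cfg <- enum_config(increment = 0.01)
  fs <- enumerate_mixtures(obs, cfg = cfg)
  mix <- as.matrix(fs$points) %*% ems_default$d13c_mean
  expect_true(all(abs(mix - obs$d13c) <= cfg$tol_d13c + 1e-9))
  expect_true(all(abs(fs$points$f_fossil - fs$fossil_center) <=
                    cfg$fossil_band_halfwidth + 1e-9))
  # and none are missed: compare against a brute-force simplex scan
  bf <- brute_force_feasible(obs$d13c, fs$fossil_center,
                             inc = 0.01, tol = cfg$tol_d13c,
                             band = cfg$fossil_band_halfwidth)
  pts <- as.matrix(fs$points)
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  expect_equal(nrow(pts), nrow(bf))
  expect_equal(unname(pts), unname(bf), tolerance = 1e-12)
})

test_that("a vacuous tolerance retains the whole simplex lattice", {
  fs <- enumerate_mixtures(list(d13c = -25, D14c = -400),
                           cfg = enum_config(increment = 0.05, tol_d13c = 10,
                                             fossil_band_halfwidth = 1))
  N <- 20  # 1 / 0.05
  expect_equal(fs$n_feasible, (N + 1) * (N + 2) / 2)  # 231 lattice triples
  bf <- brute_force_feasible(-25, fs$fossil_center, inc = 0.05, tol = 10, band = 1)
  expect_equal(fs$n_feasible, nrow(bf))
})

test_that("an observation at an endmember concentrates the feasible set", {
  fs <- enumerate_mixtures(list(d13c = -16.4, D14c = 30),
                           cfg = enum_config(increment = 0.001))
  expect_equal(fs$fossil_center, 0)
  expect_gt(fs$summary$mean[fs$summary$source == "C4"], 0.98)
  # the vertex itself is feasible
  expect_true(any(fs$points$f_C4 == 1))
  # pinning the band at the vertex tightens the set onto it
  pinned <- enumerate_mixtures(list(d13c = -16.4, D14c = 30),
                               cfg = enum_config(increment = 0.001,
                                                 pin_fossil = TRUE))
  expect_gt(pinned$summary$mean[3], fs$summary$mean[3])
})

test_that("feasible-set means converge to the exact solution", {
  # pinned fossil band, shrinking increment: mean approaches solve_exact
  # within the lattice bound 2*increment + tol/|d13c_C3 - d13c_C4|
  obs <- list(d13c = -26.0, D14c = -450)
  exact <- solve_exact(obs$d13c, obs$D14c)
  for (inc in c(0.005, 0.001)) {
    fs <- enumerate_mixtures(obs, cfg = enum_config(increment = inc,
                                                    pin_fossil = TRUE))
    bound <- 2 * inc + 0.1 / abs(ems_default$d13c_mean[2] - ems_default$d13c_mean[3])
    expect_equal(fs$summary$mean, unlist(exact[1, 1:3], use.names = FALSE),
                 tolerance = bound)
  }
})

test_that("empty feasible sets error with guidance instead of silence", {
  expect_error(
    enumerate_mixtures(list(d13c = -16.4, D14c = -1000),
                       cfg = enum_config(increment = 0.05, tol_d13c = 0.1,
                                         fossil_band_halfwidth = 0)),
    "no feasible mixtures")
  expect_error(
    enumerate_mixtures(list(d13c = -23.7, D14c = 589.7)),
    "outside \\[0, 1\\]")
  # but an explicit clipped centre overrides
  fs <- enumerate_mixtures(list(d13c = -23.7, D14c = 589.7),
                           fossil_center = 0)
  expect_gt(fs$n_feasible, 0)
})

test_that("enumeration is deterministic", {
  a <- enumerate_mixtures(list(d13c = -25.7, D14c = -380.7))
  b <- enumerate_mixtures(list(d13c = -25.7, D14c = -380.7))
  expect_identical(a$points, b$points)
})

test_that("summarize_feasible computes equal-weight moments", {
  two <- data.frame(f_fossil = c(0.4, 0.4), f_C3 = c(0.5, 0.3),
                    f_C4 = c(0.1, 0.3))
  s <- summarize_feasible(two)
  expect_equal(s$mean, c(0.4, 0.4, 0.2))
  expect_equal(s$sd, c(0, sd(c(0.5, 0.3)), sd(c(0.1, 0.3))))
  one <- summarize_feasible(two[1, ])
  expect_equal(one$mean, c(0.4, 0.5, 0.1))
  expect_equal(one$sd, c(0, 0, 0))
  expect_error(summarize_feasible(two[0, ]), "empty")
})

test_that("the fossil band propagates a Delta14C measurement SD linearly", {
  # 2 * 25.75 / 1030 = 0.05, the default band half-width
  expect_equal(fossil_band_from_sd(25.75), 0.05, tolerance = 1e-12)
  expect_equal(fossil_band_from_sd(10, k = 1), 10 / 1030, tolerance = 1e-12)
})
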