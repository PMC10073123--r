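# Shared fixtures for the test suite. Everything is built in code.

ems_default <- default_endmembers()

# Write a small sample CSV and return its path.
write_sample_csv <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "samples.csv")
  writeLines(lines, path, useBytes = TRUE)
  path
}

csv_header <- "site,date,duration_h,tc_ugC_m3,d13c_permil,D14c_permil,levoglucosan_ng_m3,excluded"

# Generate n observations that share one true fraction triple, using the
# mixing model's own generative process (realized endmembers plus
# measurement noise). Used for parameter-recovery and coverage checks.
gen_obs_at_truth <- function(n, p, ems = ems_default,
                             sd_d13c = 0.2, sd_D14c = 10) {
  e13 <- matrix(rnorm(n * 3, rep(ems$d13c_mean, each = n),
                      rep(ems$d13c_sd, each = n)), n, 3)
  e14 <- matrix(rnorm(n * 3, rep(ems$D14c_mean, each = n),
                      rep(ems$D14c_sd, each = n)), n, 3)
  pm <- matrix(p, n, 3, byrow = TRUE)
  data.frame(d13c_permil = rowSums(pm * e13) + rnorm(n, 0, sd_d13c),
             D14c_permil = rowSums(pm * e14) + rnorm(n, 0, sd_D14c))
}

# Independent brute-force enumeration oracle: scans the full simplex
# lattice and applies both constraints directly.
brute_force_feasible <- function(d13c_obs, center, inc, tol, band,
                                 ems = ems_default) {
  N <- round(1 / inc)
  g <- expand.grid(i = 0:N, j = 0:N)
  g <- g[g$i + g$j <= N, ]
  f <- cbind(g$i, g$j, N - g$i - g$j) * inc
  mix <- as.vector(f %*% ems$d13c_mean)
  keep <- abs(f[, 1] - center) <= band + 1e-9 & abs(mix - d13c_obs) <= tol + 1e-9
  m <- f[keep, , drop = FALSE]
  colnames(m) <- c("f_fossil", "f_C3", "f_C4")
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}
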