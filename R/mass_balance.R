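# Closed-form two-isotope, three-source mass balance.
#
# With sources fossil, C3, C4 and observed (d13c, D14c), the system is
#   sum_k f_k * d13c_k = d13c_obs
#   sum_k f_k * D14c_k = D14c_obs
#   sum_k f_k          = 1
# which is exactly determined for three sources. Closure is enforced
# structurally (f_C4 = 1 - f_fossil - f_C3), so returned triples sum to 1
# exactly. Solutions outside the simplex are returned unclipped with
# `feasible = FALSE`: the out-of-range value is itself the diagnostic
# (e.g. a modern-carbon-enriched sample with Delta14C above the plant
# endmember yields a negative fossil fraction).

FEAS_TOL <- 1e-9

#' Fossil fraction of total carbon from radiocarbon alone
#'
#' Two-source radiocarbon balance between radiocarbon-dead fossil carbon
#' and contemporary biogenic carbon:
#' `f_fossil = (D14c_bio - D14c_obs) / (D14c_bio - D14c_fossil)`.
#' Requires the C3 and C4 Delta14C means to coincide (the shared biogenic
#' value); otherwise use [solve_exact()].
#'
#' @param D14c_obs Observed Delta14C (permil); vectorized.
#' @param ems An [endmember_set()].
#' @return A data frame with columns `fraction` and `feasible`. Values
#'   outside `[0, 1]` are returned unclipped with `feasible = FALSE`.
#' @examples
#' fossil_fraction_14c(-380.7)        # ~0.399
#' fossil_fraction_14c(589.7)         # negative, feasible = FALSE
#' @export
fossil_fraction_14c <- function(D14c_obs, ems = default_endmembers()) {
  D <- ems$D14c_mean
  if (abs(D[2] - D[3]) > FEAS_TOL) {
    stop_fmt("C3 and C4 Delta14C means differ; the two-source radiocarbon balance does not apply (use solve_exact)")
  }
  d_bio <- D[2]
  d_fossil <- D[1]
  if (abs(d_bio - d_fossil) < FEAS_TOL) {
    stop_fmt("degenerate endmembers: fossil and biogenic Delta14C means are equal")
  }
  f <- (d_bio - D14c_obs) / (d_bio - d_fossil)
  data.frame(fraction = f, feasible = f >= -FEAS_TOL & f <= 1 + FEAS_TOL)
}

#' Exact algebraic solution of the dual-isotope mixing system
#'
#' Solves the two isotope balances plus closure for the unique source
#' fraction triple. The solve uses the reduced 2x2 system obtained by
#' eliminating `f_C4` through closure, so the components sum to 1 exactly.
#'
#' @param d13c_obs,D14c_obs Observed isotope values (permil); vectorized
#'   and recycled to a common length.
#' @param ems An [endmember_set()].
#' @return A data frame of class `fraction_triple` with columns
#'   `f_fossil`, `f_C3`, `f_C4`, `feasible`. `feasible` is `FALSE` when
#'   any component falls outside `[0, 1]` (to 1e-9); components are never
#'   clipped.
#' @examples
#' solve_exact(-25.7, -380.7)   # (0.3987, 0.4151, 0.1861)
#' @export
solve_exact <- function(d13c_obs, D14c_obs, ems = default_endmembers()) {
  n <- max(length(d13c_obs), length(D14c_obs))
  d13c_obs <- rep_len(d13c_obs, n)
  D14c_obs <- rep_len(D14c_obs, n)
  mu <- ems$d13c_mean
  D <- ems$D14c_mean
  # columns: fossil, C3; C4 eliminated by closure
  a11 <- mu[1] - mu[3]; a12 <- mu[2] - mu[3]
  a21 <- D[1] - D[3];   a22 <- D[2] - D[3]
  det <- a11 * a22 - a12 * a21
  scale <- max(abs(c(a11, a12, a21, a22)), 1)
  if (abs(det) < 1e-9 * scale) {
    stop_fmt(paste0("singular mixing system: endmembers are collinear in ",
                    "(d13c, D14c) space, the three sources cannot be separated"))
  }
  b1 <- d13c_obs - mu[3]
  b2 <- D14c_obs - D[3]
  f_fossil <- (a22 * b1 - a12 * b2) / det
  f_C3 <- (a11 * b2 - a21 * b1) / det
  f_C4 <- 1 - f_fossil - f_C3
  feasible <- f_fossil >= -FEAS_TOL & f_fossil <= 1 + FEAS_TOL &
    f_C3 >= -FEAS_TOL & f_C3 <= 1 + FEAS_TOL &
    f_C4 >= -FEAS_TOL & f_C4 <= 1 + FEAS_TOL
  out <- data.frame(f_fossil = f_fossil, f_C3 = f_C3, f_C4 = f_C4,
                    feasible = feasible)
  class(out) <- c("fraction_triple", "data.frame")
  out
}
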