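# Convert source fractions to carbon concentrations and PM2.5 shares.

#' Per-source carbon concentrations for one sample
#'
#' Multiplies the sample's total carbon concentration by each source
#' fraction; the three components sum to TC exactly.
#'
#' @param sample A one-row sample data frame (needs `tc_ugC_m3`), or a
#'   single TC concentration in ug C m-3.
#' @param f A one-row `fraction_triple` (from [solve_exact()]) or a
#'   numeric length-3 vector `(fossil, C3, C4)` on the simplex.
#' @param force Allow an infeasible (out-of-simplex) triple; default
#'   `FALSE`, which errors so flagged samples are not silently attributed.
#' @return Named numeric vector `c(fossil, C3, C4)` in ug C m-3.
#' @examples
#' source_concentrations(5.0, c(0.46, 0.35, 0.19))
#' @export
source_concentrations <- function(sample, f, force = FALSE) {
  tc <- if (is.numeric(sample) && length(sample) == 1L) sample else sample[["tc_ugC_m3"]]
  if (is.null(tc) || is.na(tc)) stop_fmt("sample has no tc_ugC_m3 value")
  if (tc < 0) stop_fmt("tc_ugC_m3 must be >= 0")
  if (inherits(f, "fraction_triple") || is.data.frame(f)) {
    if (!force && !is.null(f$feasible) && !all(f$feasible)) {
      stop_fmt("fraction triple is flagged infeasible; pass force = TRUE to attribute anyway")
    }
    f <- c(f$f_fossil[1], f$f_C3[1], f$f_C4[1])
  }
  f <- as.numeric(f)
  if (length(f) != 3L || abs(sum(f) - 1) > 1e-6) {
    stop_fmt("fractions must be three values summing to 1")
  }
  if (!force && (any(f < -1e-9) || any(f > 1 + 1e-9))) {
    stop_fmt("fractions lie outside [0, 1]; pass force = TRUE to attribute anyway")
  }
  stats::setNames(tc * f, c("fossil", "C3", "C4"))
}

#' Per-group source concentrations and contributions
#'
#' Reconstructs the seasonal/annual attribution table: per-sample
#' concentrations are computed first (TC times fraction) and then
#' averaged within each group (mean of products, not product of means);
#' percentages are group-mean fractions x 100 (the mean relative
#' contribution convention).
#'
#' @param samples A sample data frame.
#' @param fractions A data frame keyed by `sample_id` with columns
#'   `f_fossil`, `f_C3`, `f_C4` (e.g. from [solve_exact()] on each sample,
#'   or posterior means of per-sample fits).
#' @param grouping `"site_season"` (default) or `"site_annual"`.
#' @param respect_exclusion Drop rows flagged `excluded` (default `TRUE`).
#' @return A data frame with one row per group x source: `site`,
#'   (`season`,) `source`, `conc_mean`, `conc_sd`, `pct_mean`, `n`.
#'   Groups with no matching fractions are omitted with a warning.
#' @export
table2_report <- function(samples, fractions,
                          grouping = c("site_season", "site_annual"),
                          respect_exclusion = TRUE) {
  grouping <- match.arg(grouping)
  if (respect_exclusion) samples <- samples[!samples$excluded, , drop = FALSE]
  need <- c("sample_id", "f_fossil", "f_C3", "f_C4")
  if (!all(need %in% names(fractions))) {
    stop_fmt("fractions must have columns %s", paste(need, collapse = ", "))
  }
  m <- merge(samples, fractions[, need], by = "sample_id", sort = FALSE)
  missing_frac <- setdiff(samples$sample_id, fractions$sample_id)
  if (length(missing_frac) > 0) {
    warning(sprintf("%d sample(s) without fractions were omitted from the report",
                    length(missing_frac)), call. = FALSE)
  }
  if (nrow(m) == 0) stop_fmt("no samples with fractions in scope")
  key <- if (grouping == "site_season") paste(m$site, m$season, sep = ":") else m$site
  rows <- list()
  for (g in unique(key)) {
    sub <- m[key == g, , drop = FALSE]
    for (src in c("fossil", "C3", "C4")) {
      fcol <- c(fossil = "f_fossil", C3 = "f_C3", C4 = "f_C4")[[src]]
      conc <- sub$tc_ugC_m3 * sub[[fcol]]
      rows[[length(rows) + 1L]] <- data.frame(
        site = sub$site[1],
        season = if (grouping == "site_season") sub$season[1] else "annual",
        source = src,
        conc_mean = mean(conc),
        conc_sd = sd0(conc),
        pct_mean = 100 * mean(sub[[fcol]]),
        n = nrow(sub),
        row.names = NULL
      )
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Share of total PM2.5 attributable to one carbon source
#'
#' The product of the carbonaceous share of PM2.5 mass and the source's
#' share of that carbon: e.g. if ~30% of PM2.5 is carbon and ~50% of the
#' carbon is fossil, ~15% of PM2.5 is fossil carbon (0.3 x 0.5 = 0.15).
#'
#' @param tc_share_of_pm25 Fraction of PM2.5 mass that is total carbon,
#'   in `[0, 1]` (typically from a co-located mass monitor).
#' @param source_fraction_of_tc Fraction of TC from the source, in
#'   `[0, 1]`.
#' @return The source's fraction of total PM2.5 mass.
#' @examples
#' share_of_pm25(0.3, 0.5)   # 0.15
#' share_of_pm25(0.3, 0.2)   # 0.06
#' @export
share_of_pm25 <- function(tc_share_of_pm25, source_fraction_of_tc) {
  for (v in list(tc_share_of_pm25, source_fraction_of_tc)) {
    if (any(v < 0 | v > 1, na.rm = TRUE)) stop_fmt("inputs must lie in [0, 1]")
  }
  tc_share_of_pm25 * source_fraction_of_tc
}
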