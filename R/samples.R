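# Core data model: PM2.5 filter samples, CSV I/O, seasons, group summaries.

SITE_CODES <- c("TRF", "SNU", "HUF", "CRI")
SEASONS <- c("spring", "summer", "fall", "winter")

# Canonical exchange schema shared by real and synthetic data.
SAMPLE_COLUMNS <- c("site", "date", "duration_h", "tc_ugC_m3",
                    "d13c_permil", "D14c_permil", "levoglucosan_ng_m3",
                    "excluded")
NUMERIC_COLUMNS <- c("duration_h", "tc_ugC_m3", "d13c_permil",
                     "D14c_permil", "levoglucosan_ng_m3")

#' Assign a climatological season to a date
#'
#' Month-based mapping: Mar-May spring, Jun-Aug summer, Sep-Nov fall,
#' Dec-Feb winter (December belongs to the following winter).
#'
#' @param date A `Date` vector, or anything `as.Date()` accepts.
#' @return A character vector over `"spring"`, `"summer"`, `"fall"`,
#'   `"winter"`.
#' @examples
#' assign_season(as.Date(c("2020-04-10", "2020-12-11")))
#' @export
assign_season <- function(date) {
  date <- tryCatch(as.Date(date), error = function(e) NA)
  if (anyNA(date)) stop_fmt("assign_season: invalid date")
  m <- as.integer(format(date, "%m"))
  c("winter", "winter", "spring", "spring", "spring",
    "summer", "summer", "summer",
    "fall", "fall", "fall", "winter")[m]
}

#' Load PM2.5 filter samples from CSV
#'
#' Reads the canonical sample schema: columns `site`, `date` (ISO-8601),
#' `duration_h`, `tc_ugC_m3`, `d13c_permil`, `D14c_permil`,
#' `levoglucosan_ng_m3`, `excluded`. Extra columns (e.g. `tc_pct_pm25`,
#' the TC share of the co-located PM2.5 monitor) are carried through
#' unchanged. Missing levoglucosan may be written as an empty cell or
#' `NA`; it is parsed as missing, never as zero. Numeric cells may use
#' either the ASCII hyphen-minus or the Unicode minus sign.
#'
#' @param path Path to a CSV file (UTF-8, comma-separated, header
#'   mandatory).
#' @return A data frame with one row per sample, the schema columns plus
#'   derived `season` and `sample_id` (`site_date`).
#' @seealso [load_table1()] for the packaged field dataset,
#'   [write_samples()] for the inverse.
#' @export
load_samples <- function(path) {
  if (!file.exists(path)) stop_fmt("sample file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         fileEncoding = "UTF-8", check.names = FALSE)
  missing_cols <- setdiff(SAMPLE_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop_fmt("sample CSV is missing required column(s): %s",
             paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  out <- raw
  for (col in intersect(c(NUMERIC_COLUMNS, "tc_pct_pm25"), names(raw))) {
    v <- parse_table_number(raw[[col]])
    if (any(is.nan(v))) {
      row <- which(is.nan(v))[1]
      stop_fmt("malformed row %d, field '%s': cannot parse '%s'",
               row, col, raw[[col]][row])
    }
    out[[col]] <- v
  }
  required <- setdiff(NUMERIC_COLUMNS, "levoglucosan_ng_m3")
  for (col in required) {
    if (anyNA(out[[col]])) {
      stop_fmt("malformed row %d, field '%s': value required",
               which(is.na(out[[col]]))[1], col)
    }
  }
  bad_site <- !(out$site %in% SITE_CODES)
  if (any(bad_site)) {
    stop_fmt("unknown site code '%s' in row %d (expected %s)",
             out$site[bad_site][1], which(bad_site)[1],
             paste(SITE_CODES, collapse = "/"))
  }
  date <- as.Date(out$date, format = "%Y-%m-%d")
  if (anyNA(date)) {
    stop_fmt("malformed row %d, field 'date': expected ISO-8601 (yyyy-mm-dd)",
             which(is.na(date))[1])
  }
  out$date <- date
  excl <- toupper(trimws(raw$excluded))
  if (!all(excl %in% c("TRUE", "FALSE", "T", "F", ""))) {
    stop_fmt("malformed row %d, field 'excluded': expected TRUE/FALSE",
             which(!(excl %in% c("TRUE", "FALSE", "T", "F", "")))[1])
  }
  out$excluded <- excl %in% c("TRUE", "T")
  if (any(out$duration_h <= 0)) {
    stop_fmt("malformed row %d, field 'duration_h': must be > 0",
             which(out$duration_h <= 0)[1])
  }
  if (any(out$tc_ugC_m3 < 0)) {
    stop_fmt("malformed row %d, field 'tc_ugC_m3': must be >= 0",
             which(out$tc_ugC_m3 < 0)[1])
  }
  lev <- out$levoglucosan_ng_m3
  if (any(lev < 0, na.rm = TRUE)) {
    stop_fmt("malformed row %d, field 'levoglucosan_ng_m3': must be >= 0 or missing",
             which(lev < 0)[1])
  }
  out$season <- assign_season(out$date)
  out$sample_id <- make.unique(paste(out$site, format(out$date), sep = "_"))
  rownames(out) <- NULL
  out
}

#' Write samples to CSV in the canonical schema
#'
#' Inverse of [load_samples()]: numeric fields round-trip at full stored
#' precision, missing levoglucosan is written as `NA`.
#'
#' @param samples A sample data frame as returned by [load_samples()] or
#'   [simulate_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  cols <- c(SAMPLE_COLUMNS, intersect("tc_pct_pm25", names(samples)))
  out <- samples[, cols, drop = FALSE]
  out$date <- format(as.Date(out$date))
  for (col in intersect(c(NUMERIC_COLUMNS, "tc_pct_pm25"), names(out))) {
    out[[col]] <- vapply(out[[col]], function(v) {
      if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE)
    }, character(1))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' The packaged forest/urban PM2.5 field dataset
#'
#' 48 PM2.5 filter samples collected 2019-2020 at a rural pine forest
#' (TRF, n = 21), an urban campus rooftop (SNU, n = 19), an urban pine
#' forest (HUF, n = 2), and an urban traffic island with pines (CRI,
#' n = 6) in South Korea, with total carbon concentration, delta13C,
#' Delta14C, and (where assayed) levoglucosan. One SNU winter sample
#' carries an anomalous, physically infeasible Delta14C of +589.7 permil
#' and is flagged `excluded = TRUE`; all summaries and model fits drop it
#' by default.
#'
#' @return A sample data frame; see [load_samples()].
#' @examples
#' samples <- load_table1()
#' table(samples$site)
#' @export
load_table1 <- function() {
  load_samples(system.file("extdata", "table1.csv", package = "dualcarbon",
                           mustWork = TRUE))
}

#' Summarize one measured field over a group of samples
#'
#' @param samples A sample data frame.
#' @param field One of `"tc_ugC_m3"`, `"d13c_permil"`, `"D14c_permil"`,
#'   `"levoglucosan_ng_m3"` (short aliases `"tc"`, `"d13c"`, `"D14c"`,
#'   `"levoglucosan"` accepted).
#' @param respect_exclusion Drop rows flagged `excluded` before computing
#'   (default `TRUE`).
#' @return A list with `mean`, `sd`, and `n` (the number of values
#'   actually used, after dropping missing and excluded rows). A single
#'   value reports `sd = 0` by convention.
#' @examples
#' samples <- load_table1()
#' summarize_group(samples[samples$site == "TRF", ], "D14c")
#' @export
summarize_group <- function(samples, field, respect_exclusion = TRUE) {
  aliases <- c(tc = "tc_ugC_m3", d13c = "d13c_permil", D14c = "D14c_permil",
               levoglucosan = "levoglucosan_ng_m3")
  if (field %in% names(aliases)) field <- aliases[[field]]
  if (!field %in% names(samples)) stop_fmt("unknown field '%s'", field)
  x <- samples[[field]]
  if (respect_exclusion) x <- x[!samples$excluded]
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    stop_fmt("empty group: no non-missing values of '%s' after filtering", field)
  }
  list(mean = mean(x), sd = sd0(x), n = length(x))
}
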