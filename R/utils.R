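# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Parse a character vector of numbers as printed in environmental data
# tables: accepts ASCII hyphen-minus and the Unicode minus sign, interior
# spaces after the sign ("- 25.7"), and "NA"/empty cells as missing.
# Returns a numeric vector; genuinely malformed entries come back NaN so
# callers can distinguish them from missing values.
parse_table_number <- function(x) {
  x <- gsub("−", "-", as.character(x))
  x <- gsub("[  ]", "", x)
  missing <- is.na(x) | x == "" | toupper(x) == "NA"
  out <- suppressWarnings(as.numeric(x))
  bad <- !missing & is.na(out)
  out[missing] <- NA_real_
  out[bad] <- NaN
  out
}

# sd with the n = 1 convention used throughout the package: a single value
# has spread 0 (documented), never NA.
sd0 <- function(x) {
  if (length(x) <= 1L) return(0)
  stats::sd(x)
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
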