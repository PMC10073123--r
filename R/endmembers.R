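#' Isotopic endmembers for the three-source mixing model
#'
#' An endmember set holds the assumed isotopic signature (mean and SD for
#' each of the two isotopes) of the three carbon sources considered by the
#' mixing model: fossil fuel, C3 plants, and C4 plants. The delta13C means
#' must be pairwise distinct, otherwise the dual-isotope system is not
#' solvable.
#'
#' @param d13c_mean,d13c_sd Numeric length-3 vectors, delta13C mean and SD
#'   (permil vs VPDB) in the order fossil, C3, C4.
#' @param D14c_mean,D14c_sd Numeric length-3 vectors, Delta14C mean and SD
#'   (permil), same order.
#' @return A data frame of class `endmember_set` with one row per source
#'   (`fossil`, `C3`, `C4`) and columns `source`, `d13c_mean`, `d13c_sd`,
#'   `D14c_mean`, `D14c_sd`.
#' @examples
#' endmember_set(c(-29, -26.7, -16.4), c(1.3, 1.8, 1.4),
#'               c(-1000, 30, 30), c(5, 5, 5))
#' @export
endmember_set <- function(d13c_mean, d13c_sd, D14c_mean, D14c_sd) {
  for (arg in list(d13c_mean, d13c_sd, D14c_mean, D14c_sd)) {
    if (length(arg) != 3L || !is.numeric(arg) || anyNA(arg)) {
      stop_fmt("each endmember field must be a numeric vector of length 3 (fossil, C3, C4)")
    }
  }
  if (any(d13c_sd < 0) || any(D14c_sd < 0)) {
    stop_fmt("endmember SDs must be >= 0")
  }
  if (min(dist(d13c_mean)) < 1e-9) {
    stop_fmt("endmember d13c means must be pairwise distinct (mixing model solvability)")
  }
  out <- data.frame(
    source = c("fossil", "C3", "C4"),
    d13c_mean = as.numeric(d13c_mean),
    d13c_sd = as.numeric(d13c_sd),
    D14c_mean = as.numeric(D14c_mean),
    D14c_sd = as.numeric(D14c_sd),
    stringsAsFactors = FALSE
  )
  class(out) <- c("endmember_set", "data.frame")
  out
}

#' Default endmember values
#'
#' delta13C: -29.0 +/- 1.3 permil (fossil fuel), -26.7 +/- 1.8 permil
#' (C3 plants), -16.4 +/- 1.4 permil (C4 plants). Delta14C: -1000 permil for
#' radiocarbon-dead fossil carbon and +30 permil for both plant sources,
#' matching contemporary tropospheric CO2. The Delta14C reference values
#' carry no stated uncertainty; they are treated as near-point values with
#' a small default SD.
#'
#' @param D14c_sd Delta14C SD (permil) applied to all three sources;
#'   default 5.
#' @return An [endmember_set()].
#' @export
default_endmembers <- function(D14c_sd = 5) {
  endmember_set(
    d13c_mean = c(-29.0, -26.7, -16.4),
    d13c_sd = c(1.3, 1.8, 1.4),
    D14c_mean = c(-1000, 30, 30),
    D14c_sd = rep(D14c_sd, 3)
  )
}

#' Read an endmember set from a YAML file
#'
#' Expects a top-level `sources` mapping with entries `fossil`, `C3`, `C4`,
#' each holding `d13c_mean`, `d13c_sd`, `D14c_mean`, `D14c_sd`. The packaged
#' default lives at `system.file("extdata", "endmembers.yaml",
#' package = "dualcarbon")`.
#'
#' @param path Path to a YAML file.
#' @return An [endmember_set()].
#' @export
read_endmembers <- function(path) {
  if (!file.exists(path)) stop_fmt("endmember file not found: %s", path)
  y <- yaml::read_yaml(path)
  src <- y$sources
  if (is.null(src) || !all(c("fossil", "C3", "C4") %in% names(src))) {
    stop_fmt("endmember YAML must define sources: fossil, C3, C4")
  }
  get <- function(field) vapply(c("fossil", "C3", "C4"),
                                function(s) as.numeric(src[[s]][[field]]), numeric(1))
  endmember_set(get("d13c_mean"), get("d13c_sd"), get("D14c_mean"), get("D14c_sd"))
}

#' @export
print.endmember_set <- function(x, ...) {
  cat("Endmember set (permil):\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
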