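# Supporting statistics: seasonal tracer summaries, one-way ANOVA with
# Tukey's HSD, and simple OLS regression. The model fits go through base
# R (lm/anova, ptukey); this module adds the domain-facing surface,
# Tukey-Kramer pairwise tables, and compact letter displays.

#' Seasonal levoglucosan means at one site
#'
#' @param samples A sample data frame.
#' @param site One of `"TRF"`, `"SNU"`, `"HUF"`, `"CRI"`.
#' @param respect_exclusion Drop rows flagged `excluded` (default `TRUE`).
#' @return A data frame with one row per season (`spring`, `summer`,
#'   `fall`, `winter`): `season`, `mean` (ng m-3, `NA` when the season has
#'   no assayed values — never zero), `n`.
#' @examples
#' seasonal_levoglucosan(load_table1(), "TRF")
#' @export
seasonal_levoglucosan <- function(samples, site, respect_exclusion = TRUE) {
  if (!site %in% samples$site) stop_fmt("site '%s' not present in data", site)
  sub <- samples[samples$site == site, , drop = FALSE]
  if (respect_exclusion) sub <- sub[!sub$excluded, , drop = FALSE]
  out <- data.frame(season = SEASONS, mean = NA_real_, n = 0L)
  for (i in seq_along(SEASONS)) {
    x <- sub$levoglucosan_ng_m3[sub$season == SEASONS[i]]
    x <- x[!is.na(x)]
    out$n[i] <- length(x)
    if (length(x) > 0) out$mean[i] <- mean(x)
  }
  out
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition via `lm`/`anova`. The degenerate
#' edge of zero within-group variance with unequal means reports
#' `F = Inf`, `p = 0`.
#'
#' @param groups A list (optionally named) of two or more numeric vectors.
#' @return A list with `F`, `p`, and `df = c(between, within)`.
#' @examples
#' oneway_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))  # F = 3
#' @export
oneway_anova <- function(groups) {
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  k <- length(groups)
  n_i <- lengths(groups)
  if (k < 2L) stop_fmt("need at least two groups")
  if (any(n_i < 1L)) stop_fmt("each group needs at least one value")
  y <- unlist(groups, use.names = FALSE)
  if (length(y) <= k) stop_fmt("total n must exceed the number of groups")
  if (stats::var(y) == 0) {
    stop_fmt("all values identical: the F statistic is undefined")
  }
  g <- factor(rep(seq_len(k), n_i))
  a <- suppressWarnings(stats::anova(stats::lm(y ~ g)))  # perfect-fit warning
  ssb <- a$`Sum Sq`[1]; ssw <- a$`Sum Sq`[2]
  if (ssw <= 1e-10 * (ssb + ssw)) {
    return(list(F = Inf, p = 0, df = a$Df))
  }
  list(F = a$`F value`[1], p = a$`Pr(>F)`[1], df = a$Df)
}

#' Tukey's honest significant difference test
#'
#' Tukey-Kramer studentized-range pairwise comparisons at family level
#' `alpha`, with a compact letter display (groups sharing a letter are
#' not significantly different — the familiar a/ab/b superscripts of
#' summary tables).
#'
#' @param groups A list of two or more numeric vectors; names are used as
#'   group labels.
#' @param alpha Family-wise significance level in (0, 1); default 0.05.
#' @return A list with `table` (one row per pair: `group1`, `group2`,
#'   `diff` = mean1 - mean2, `q` statistic, `p_adj` from the studentized
#'   range distribution, `significant`), `letters` (named character
#'   vector), and `alpha`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop_fmt("alpha must be in (0, 1)")
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  k <- length(groups)
  if (k < 2L) stop_fmt("need at least two groups")
  labels <- names(groups) %||% as.character(seq_len(k))
  if (is.null(names(groups)) || any(names(groups) == "")) {
    labels <- ifelse(is.na(labels) | labels == "", as.character(seq_len(k)), labels)
  }
  n_i <- lengths(groups)
  if (any(n_i < 2L)) stop_fmt("each group needs at least two values for Tukey's HSD")
  means <- vapply(groups, mean, numeric(1))
  dfw <- sum(n_i) - k
  msw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) / dfw
  pairs <- utils::combn(k, 2)
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    d <- means[i] - means[j]
    se <- sqrt(msw / 2 * (1 / n_i[i] + 1 / n_i[j]))
    q <- if (se > 0) abs(d) / se else if (abs(d) > 0) Inf else 0
    p <- if (is.infinite(q)) 0 else stats::ptukey(q, k, dfw, lower.tail = FALSE)
    data.frame(group1 = labels[i], group2 = labels[j], diff = d, q = q,
               p_adj = p, significant = p < alpha, row.names = NULL)
  })
  table <- do.call(rbind, rows)
  differs <- matrix(FALSE, k, k, dimnames = list(labels, labels))
  for (c_ in seq_len(ncol(pairs))) {
    i <- pairs[1, c_]; j <- pairs[2, c_]
    differs[i, j] <- differs[j, i] <- table$significant[c_]
  }
  list(table = table, letters = tukey_letters(differs, order(-means)),
       alpha = alpha)
}

# Compact letter display by insert-and-absorb: maintain maximal sets of
# mutually non-different groups, then letter them in the given group
# order (conventionally descending mean, so 'a' marks the largest).
tukey_letters <- function(differs, preference = seq_len(nrow(differs))) {
  k <- nrow(differs)
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!differs[i, j]) next
      new_sets <- list()
      for (s in sets) {
        if (i %in% s && j %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      # absorb subsets
      keep <- rep(TRUE, length(new_sets))
      for (a in seq_along(new_sets)) {
        for (b in seq_along(new_sets)) {
          if (a != b && keep[a] && all(new_sets[[a]] %in% new_sets[[b]]) &&
              length(new_sets[[a]]) < length(new_sets[[b]])) {
            keep[a] <- FALSE
          }
        }
      }
      sets <- unique(new_sets[keep])
    }
  }
  # order sets by the preferred (e.g. descending-mean) rank of their groups
  first_rank <- vapply(sets, function(s) min(match(s, preference)), numeric(1))
  sets <- sets[order(first_rank)]
  out <- stats::setNames(rep("", k), rownames(differs))
  for (s in seq_along(sets)) {
    out[sets[[s]]] <- paste0(out[sets[[s]]], letters[s])
  }
  out
}

#' Ordinary least-squares regression of y on x
#'
#' @param x,y Numeric vectors; pairs with missing values are dropped.
#' @return A list with `slope`, `intercept`, `r_squared`
#'   (`1 - SSE/SST`, defined as 0 when y is constant), `p` (two-sided
#'   slope t-test; 1 when the slope variance is degenerate), and `n`.
#' @examples
#' ols_regression(c(0, 1, 2), c(1, 3, 5))  # slope 2, intercept 1, R2 = 1
#' @export
ols_regression <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop_fmt("need at least 3 complete (x, y) pairs")
  if (stats::sd(x) == 0) stop_fmt("x is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  co <- suppressWarnings(summary(fit))$coefficients  # "perfect fit" warning
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 0
  p <- if (nrow(co) < 2 || !is.finite(co[2, 4])) 1 else co[2, 4]
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, p = p, n = length(x))
}
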