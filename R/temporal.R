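# Temporal analyses of component abundances at the time-series sites:
# per-sample diversity, Escoufier equivalent-vector indicator selection,
# rhythmicity classification and seasonal summaries.

#' Diversity indices of one sample
#'
#' Species richness `S` (number of positive entries), Shannon diversity
#' `H = -sum(p log p)` (natural log) and Pielou evenness `J = H / log(S)`
#' (0 when a single taxon is present). Set `one_minus_pielou = TRUE` to
#' report `1 - J` instead of `J`.
#'
#' @param x Non-negative abundance vector with positive sum.
#' @param one_minus_pielou Report the complement of the evenness?
#' @return List with `richness_S`, `shannon_H`, `pielou_J`.
#' @export
diversity_summary <- function(x, one_minus_pielou = FALSE) {
  if (any(x < 0)) stop("abundances must be non-negative")
  tot <- sum(x)
  if (tot == 0) stop("all-zero sample")
  p <- x[x > 0] / tot
  S <- length(p)
  H <- -sum(p * log(p))
  J <- if (S >= 2L) H / log(S) else 0
  if (one_minus_pielou) J <- 1 - J
  list(richness_S = S, shannon_H = H, pielou_J = J)
}

#' Escoufier's RV coefficient between two sets of variables
#'
#' `RV = tr(XX' YY') / sqrt(tr((XX')^2) tr((YY')^2))`, a matrix
#' correlation in \[0, 1\] that generalizes the squared correlation;
#' invariant to rescaling of either matrix.
#'
#' @param X,Y Numeric matrices with the same number of rows (columns are
#'   centred internally).
#' @return The RV coefficient.
#' @export
rv_coefficient <- function(X, Y) {
  X <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  Y <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same rows")
  if (nrow(X) < 2L) stop("need at least 2 rows")
  Sxx <- crossprod(X); Syy <- crossprod(Y); Sxy <- crossprod(X, Y)
  den <- sqrt(sum(Sxx^2) * sum(Syy^2))
  if (den == 0) stop("zero-variance matrix")
  sum(Sxy^2) / den
}

#' Escoufier equivalent-vector selection of indicator components
#'
#' Greedy forward selection of the component columns whose sub-matrix best
#' reproduces the structure of the full community matrix in the RV sense:
#' at each step the candidate maximizing `RV(selected + candidate, full)`
#' enters (ties broken by larger total abundance, then smaller id). The
#' selected indicators are the shortest prefix whose cumulative RV reaches
#' `level`; level 1 returns every column. Components observed on fewer
#' than `min_occurrence` dates are excluded before selection.
#'
#' @param m Abundance matrix, dates x components (columns named by
#'   component id).
#' @param level Cumulative RV level to reach, in (0, 1\].
#' @param min_occurrence Minimum number of dates with positive abundance.
#' @return List of class `"rv_trace"`: `order` (ids in selection order),
#'   `cumulative_rv` (non-decreasing), `selected` (prefix reaching
#'   `level`), `excluded` (ids dropped by the occurrence screen).
#' @export
escoufier_select <- function(m, level = 0.75, min_occurrence = 5) {
  stopifnot(is.matrix(m))
  if (!(level > 0 && level <= 1)) stop("level must lie in (0, 1]")
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  occ <- colSums(m > 0)
  excluded <- colnames(m)[occ < min_occurrence]
  m <- m[, occ >= min_occurrence, drop = FALSE]
  if (ncol(m) == 0L) stop("no component passes the occurrence screen")
  tot <- colSums(m)
  Yc <- scale(m, center = TRUE, scale = FALSE)
  Syy <- crossprod(Yc)
  den_y <- sqrt(sum(Syy^2))
  sel <- character(0)
  trace <- numeric(0)
  remaining <- colnames(m)
  while (length(remaining)) {
    vals <- vapply(remaining, function(j) {
      cols <- c(sel, j)
      Xc <- Yc[, cols, drop = FALSE]
      Sxx <- crossprod(Xc)
      Sxy <- crossprod(Xc, Yc)
      sum(Sxy^2) / (sqrt(sum(Sxx^2)) * den_y)
    }, 0)
    best <- max(vals)
    ties <- remaining[vals >= best - 1e-12]
    if (length(ties) > 1L) {
      ties <- ties[order(-tot[ties], ties)]
    }
    pick <- ties[1L]
    sel <- c(sel, pick)
    trace <- c(trace, vals[[pick]])
    remaining <- setdiff(remaining, pick)
  }
  k <- which(trace >= level)[1L]
  if (is.na(k)) k <- length(sel)
  structure(list(order = sel, cumulative_rv = trace,
                 selected = sel[seq_len(k)], excluded = excluded),
            class = "rv_trace")
}

#' @export
print.rv_trace <- function(x, ...) {
  cat("Escoufier selection:", length(x$selected), "indicator(s) of",
      length(x$order), "component(s)\n")
  cat("  cumulative RV at cut:",
      sprintf("%.4f", x$cumulative_rv[length(x$selected)]), "\n")
  invisible(x)
}

#' Rhythmic components by peak normalized power
#'
#' Components whose periodogram peak exceeds the threshold (strictly;
#' the conventional cut `PNmax > 10` corresponds to p < 0.01).
#'
#' @param results data.frame with columns `cc_id` and `pn_max` (e.g. one
#'   row per [lomb_scargle()] result).
#' @param pn_threshold Strict threshold on `pn_max`.
#' @return Character vector of rhythmic component ids.
#' @export
rhythmic_set <- function(results, pn_threshold = 10) {
  if (nrow(results) == 0L) return(character(0))
  results$cc_id[results$pn_max > pn_threshold]
}

#' Rhythmic indicator components
#'
#' Components that are both community indicators (Escoufier-selected) and
#' rhythmic (periodogram peak above threshold).
#'
#' @param escoufier An `"rv_trace"` from [escoufier_select()].
#' @param rhythmic Character vector of rhythmic ids.
#' @return Character vector (intersection, in selection order).
#' @export
rhythmic_indicators <- function(escoufier, rhythmic) {
  intersect(escoufier$selected, rhythmic)
}

#' Seasonal prevalence of a component in one year
#'
#' Number of distinct meteorological seasons (DJF/MAM/JJA/SON) of the
#' given year with at least one positive observation. Note that December
#' belongs to the winter labelled by the calendar year it falls in.
#'
#' @param times Date vector of observations.
#' @param values Abundance values, same length.
#' @param year Calendar year (integer).
#' @return Integer count in 0..4.
#' @export
seasonal_prevalence <- function(times, values, year) {
  times <- as.Date(times)
  stopifnot(length(times) == length(values))
  in_year <- as.integer(format(times, "%Y")) == year
  pos <- in_year & values > 0
  length(unique(season_of(times[pos])))
}

#' Annual mean monthly abundance of a component
#'
#' For one year, the abundance values are first averaged within each
#' observed month, then the monthly means are averaged; months without
#' samples are excluded rather than imputed.
#'
#' @param times Date vector of observations.
#' @param values Abundance values, same length.
#' @param year Calendar year (integer).
#' @return Mean of monthly means, or `NA` when the year has no samples.
#' @export
annual_mean_monthly_abundance <- function(times, values, year) {
  times <- as.Date(times)
  stopifnot(length(times) == length(values))
  in_year <- as.integer(format(times, "%Y")) == year
  if (!any(in_year)) return(NA_real_)
  month <- format(times[in_year], "%m")
  mean(tapply(values[in_year], month, mean))
}
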