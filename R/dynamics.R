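#' Feature time series for one plant
#'
#' @param plant_id identifier.
#' @param timepoints strictly increasing integer ordinals (days or stage
#'   ranks).
#' @param gpar,tbr,par,tcr numeric vectors, one value per timepoint
#'   (`NA` = missing).
#' @return A data frame of class `feature_series`.
#' @export
feature_series <- function(plant_id, timepoints, gpar = NA, tbr = NA,
                           par = NA, tcr = NA) {
  n <- length(timepoints)
  stopifnot(n >= 1L, !is.unsorted(timepoints, strictly = TRUE))
  df <- data.frame(
    plant_id = plant_id, timepoint = as.integer(timepoints),
    gpar = rep_len(gpar, n), tbr = rep_len(tbr, n),
    par = rep_len(par, n), tcr = rep_len(tcr, n)
  )
  class(df) <- c("feature_series", "data.frame")
  df
}

#' Change in a feature between two timepoints
#'
#' Defined as the feature value after stress minus the value before stress,
#' componentwise over the four features. A missing side yields a missing
#' delta.
#'
#' @param before,after `drought_features` objects (or named lists/vectors
#'   with fields `gpar`, `tbr`, `par`, `tcr`).
#' @return Named numeric vector of deltas `c(gpar=, tbr=, par=, tcr=)`.
#' @export
feature_change <- function(before, after) {
  fields <- c("gpar", "tbr", "par", "tcr")
  get1 <- function(x, fn) {
    v <- if (is.null(x[[fn]])) NA_real_ else as.numeric(x[[fn]])
    if (length(v) != 1L) NA_real_ else v
  }
  vapply(fields, function(fn) get1(after, fn) - get1(before, fn), numeric(1))
}

#' First derivative of a feature series
#'
#' The discrete first derivative `d_i = X_i - X_{i-1}`, indexed by the
#' later timepoint. A derivative is defined only between consecutive
#' ordinals (gap of exactly 1) with both values present; gaps yield missing
#' entries and are never interpolated.
#'
#' @param series a [feature_series()] or a plain numeric vector (implicit
#'   timepoints `1..n`).
#' @param feature_name for a `feature_series`, one of `"gpar"`, `"tbr"`,
#'   `"par"`, `"tcr"`.
#' @return For a numeric vector, the numeric vector of differences
#'   (length `n - 1`, empty when `n < 2`). For a `feature_series`, a data
#'   frame with columns `timepoint` (the later one) and `delta`.
#' @export
first_derivative <- function(series, feature_name = NULL) {
  UseMethod("first_derivative")
}

#' @export
first_derivative.numeric <- function(series, feature_name = NULL) {
  if (length(series) < 2L) return(numeric(0))
  diff(series)
}

#' @export
first_derivative.feature_series <- function(series, feature_name) {
  stopifnot(feature_name %in% c("gpar", "tbr", "par", "tcr"))
  x <- series[[feature_name]]
  t <- series$timepoint
  if (length(x) < 2L)
    return(data.frame(timepoint = integer(0), delta = numeric(0)))
  d <- x[-1] - x[-length(x)]
  gap <- diff(t) != 1L
  d[gap] <- NA_real_
  data.frame(timepoint = t[-1], delta = d)
}

#' Detect the onset of leaf-rolling in a feature series
#'
#' Rolling narrows the silhouette, so its visible onset shows as an
#' extremum of the first derivative of the shape descriptors: a peak for
#' PAR and a valley for TBR and TCR. Each descriptor votes for the
#' timepoint of its extremum; the onset is the majority candidate, with
#' ties broken in favour of the PAR candidate (PAR being the most robust
#' and sensitive rolling descriptor). GPAR tracks senescence, not rolling,
#' and is excluded from the vote. A descriptor whose derivative is flat
#' (all zero) or undefined abstains; if every descriptor abstains the
#' result is a no-onset report.
#'
#' @param series a [feature_series()] with at least 3 timepoints.
#' @return List of class `onset_report` with `onset_index` (a timepoint, or
#'   `NA` for no onset), `per_descriptor_votes` (named vector over
#'   par/tbr/tcr, `NA` = abstained) and `magnitude` (the derivative
#'   extremum of the winning descriptor).
#' @export
detect_rolling_onset <- function(series) {
  stopifnot(inherits(series, "feature_series"), nrow(series) >= 3L)
  cand <- c(par = NA_integer_, tbr = NA_integer_, tcr = NA_integer_)
  mag <- c(par = NA_real_, tbr = NA_real_, tcr = NA_real_)
  for (fn in names(cand)) {
    d <- first_derivative(series, fn)
    ok <- !is.na(d$delta)
    if (!any(ok) || all(d$delta[ok] == 0)) next # abstain
    pick <- if (fn == "par") which.max(d$delta) else which.min(d$delta)
    cand[fn] <- d$timepoint[pick]
    mag[fn] <- d$delta[pick]
  }
  votes <- cand[!is.na(cand)]
  if (!length(votes)) {
    return(structure(list(onset_index = NA_integer_,
                          per_descriptor_votes = cand,
                          magnitude = NA_real_),
                     class = "onset_report"))
  }
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  onset <- if (length(winners) == 1L) {
    winners
  } else if (!is.na(cand["par"]) && cand["par"] %in% winners) {
    cand[["par"]]
  } else {
    min(winners)
  }
  lead <- if (!is.na(cand["par"]) && cand[["par"]] == onset) "par"
          else names(cand)[!is.na(cand) & cand == onset][1]
  structure(
    list(onset_index = onset, per_descriptor_votes = cand,
         magnitude = mag[[lead]]),
    class = "onset_report"
  )
}

#' @export
print.onset_report <- function(x, ...) {
  if (is.na(x$onset_index)) {
    cat("<onset_report: no onset detected (flat series)>\n")
  } else {
    cat(sprintf("<onset_report: onset at timepoint %d (derivative %.4g)>\n",
                x$onset_index, x$magnitude))
  }
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: `F = MS_between / MS_within` on
#' `(k - 1, N - k)` degrees of freedom, with the p-value from the upper
#' tail of the F distribution. Used to ask whether a feature separates
#' groups (e.g. drought-resistant vs drought-sensitive accessions).
#'
#' Zero within-group variance with non-zero between-group variance yields
#' an infinite F with p = 0 and `degenerate = TRUE`; fully constant input
#' is rejected.
#'
#' @param groups named or unnamed list of numeric vectors, at least 2
#'   groups with at least 2 values each.
#' @return List of class `group_comparison` with `group_labels`,
#'   `F`, `df_between`, `df_within`, `p`, `degenerate`.
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs at least 2 values")
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("group", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(labels, vapply(groups, length, integer(1))),
              levels = labels)
  k <- length(groups)
  N <- length(y)
  means <- tapply(y, g, mean)
  ssb <- sum(tabulate(g) * (means - mean(y))^2)
  ssw <- sum((y - means[g])^2)
  dfb <- k - 1L
  dfw <- N - k
  if (ssw <= .Machine$double.eps * max(ssb, 1)) {
    if (ssb <= .Machine$double.eps)
      stop("degenerate input: zero variance within and between groups")
    return(structure(
      list(group_labels = labels, F = Inf, df_between = dfb,
           df_within = dfw, p = 0, degenerate = TRUE),
      class = "group_comparison"
    ))
  }
  Fstat <- (ssb / dfb) / (ssw / dfw)
  structure(
    list(group_labels = labels, F = Fstat, df_between = dfb,
         df_within = dfw,
         p = stats::pf(Fstat, dfb, dfw, lower.tail = FALSE),
         degenerate = FALSE),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<one-way ANOVA: F(%d, %d) = %.4g, p = %.4g>\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Pearson correlation coefficient
#'
#' Sample Pearson correlation between two equal-length vectors, used to
#' relate feature changes measured under controlled conditions to those
#' measured in the field. Pairs with a missing value on either side are
#' dropped pairwise; at least 3 complete pairs and non-zero variance on
#' both sides are required.
#'
#' @param x,y numeric vectors of equal length.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(x, y)
}
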