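#' @include AllClasses.R
NULL

#' Derive open/closed thresholds from bound and apo distance series
#'
#' The closed-state ceiling is the mean of the ligand-bound series over its
#' trailing window; the open-state floor is the mean of the apo series over
#' its trailing window (the bound aptamer defines the closed conformation,
#' the free aptamer the open one).
#'
#' @param boundSeries,apoSeries numeric distance series (A).
#' @param windowFraction trailing fraction of each series to average over
#'   (in (0, 1]).
#' @return a [StateSeries]-compatible threshold list of class
#'   `StateThresholds`: `closedMax`, `openMin`, `source = "derived"`
#' @export
deriveThresholds <- function(boundSeries, apoSeries, windowFraction = 0.5) {
  stopifnot(length(boundSeries) >= 1L, length(apoSeries) >= 1L,
            windowFraction > 0, windowFraction <= 1)
  tailMean <- function(x) {
    k <- max(1L, ceiling(length(x) * windowFraction))
    mean(utils::tail(x, k))
  }
  closedMax <- tailMean(boundSeries)
  openMin <- tailMean(apoSeries)
  if (closedMax >= openMin)
    stop(sprintf(paste0("threshold-order error: closedMax (%.3f) must be ",
                        "< openMin (%.3f)"), closedMax, openMin),
         call. = FALSE)
  structure(list(closedMax = closedMax, openMin = openMin,
                 source = "derived"), class = "StateThresholds")
}

#' Explicit state thresholds
#' @param closedMax,openMin thresholds in A, `closedMax < openMin`.
#' @return `StateThresholds` list
#' @export
stateThresholds <- function(closedMax, openMin) {
  if (closedMax >= openMin)
    stop("closedMax must be < openMin", call. = FALSE)
  structure(list(closedMax = closedMax, openMin = openMin,
                 source = "configured"), class = "StateThresholds")
}

#' Classify frames into open/middle/closed states
#'
#' A frame with distance strictly greater than `openMin` is open, strictly
#' less than `closedMax` is closed, anything else (boundaries included) is
#' middle.
#'
#' @param series numeric distance series (A).
#' @param thresholds a `StateThresholds` (from [stateThresholds()] or
#'   [deriveThresholds()]).
#' @return a [StateSeries]
#' @export
classifyStates <- function(series, thresholds) {
  lab <- ifelse(series > thresholds$openMin, "open",
                ifelse(series < thresholds$closedMax, "closed", "middle"))
  new("StateSeries",
      labels = factor(lab, levels = c("closed", "middle", "open")),
      closedMax = thresholds$closedMax, openMin = thresholds$openMin,
      source = thresholds$source)
}

#' State percentages from labels
#'
#' @param labels a [StateSeries] or a character/factor vector of labels.
#' @return named numeric: `pct_open`, `pct_middle`, `pct_closed` (exact
#'   fractions x 100; sum to 100)
#' @export
statePercentages <- function(labels) {
  if (is(labels, "StateSeries")) return(statePercent(labels))
  labels <- as.character(labels)
  if (!length(labels)) stop("no state labels", call. = FALSE)
  n <- length(labels)
  c(pct_open = 100 * sum(labels == "open") / n,
    pct_middle = 100 * sum(labels == "middle") / n,
    pct_closed = 100 * sum(labels == "closed") / n)
}

#' Sample Pearson correlation
#'
#' @param x,y numeric vectors of equal length `>= 3` with nonzero variance.
#' @return correlation coefficient
#' @export
pearsonR <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  stats::cor(x, y)
}

#' Coefficient of determination r^2
#'
#' The square of the sample Pearson correlation between predicted and
#' experimental values.
#'
#' @param pred,exp numeric vectors of equal length `>= 3`.
#' @return r^2
#' @export
coefficientOfDetermination <- function(pred, exp) {
  pearsonR(pred, exp)^2
}

#' Binding free energy from a dissociation constant
#'
#' `dG = R T ln(Kd)` with `R = 0.0019872` kcal/(mol K) and `Kd` in molar
#' (reference state 1 M): sub-molar dissociation constants give negative
#' binding free energies.
#'
#' @param Kd dissociation constant, M, `> 0`.
#' @param T temperature, K.
#' @return free energy in kcal/mol
#' @export
kdToDg <- function(Kd, T = 298.15) {
  if (any(Kd <= 0)) stop("Kd must be > 0", call. = FALSE)
  stopifnot(T > 0)
  .R_GAS * T * log(Kd)
}
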