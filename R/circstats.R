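# Circular (angular) arithmetic for tilt variables.  Signed tilt lives on a
# 360-degree circle, unsigned tilt and orientation cues on a 180-degree one.

DEG <- pi / 180

.checkPeriod <- function(period) {
  if (!period %in% c(180, 360))
    stop("period must be 180 or 360 (degrees)")
  period
}

#' Signed circular difference between two angles
#'
#' The difference `a - b` wrapped to `(-period/2, period/2]`.  Antipodal
#' pairs (difference exactly half a period) map to `+period/2`, a
#' deterministic, sign-stable tie-break.
#'
#' @param a,b angles in degrees (vectorized, recycled).
#' @param period 360 for signed tilt, 180 for unsigned tilt/orientations.
#' @return degrees in `(-period/2, period/2]`.
#' @examples
#' circDiff(10, 350)        # +20
#' circDiff(0, 180)         # +180 (antipodal tie)
#' circDiff(0, 90, 180)     # +90
#' @export
circDiff <- function(a, b, period = 360) {
  .checkPeriod(period)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("circDiff: inputs must be finite")
  d <- (a - b) %% period
  ifelse(d > period / 2, d - period, d)
}

#' Absolute circular distance between two angles
#'
#' `|arg(exp(j(a-b)))|` on the circle of the given period: the magnitude of
#' [circDiff()], in `[0, period/2]`.
#'
#' @inheritParams circDiff
#' @return degrees in `[0, period/2]`.
#' @examples
#' circAbsDiff(350, 10)     # 20
#' @export
circAbsDiff <- function(a, b, period = 360) {
  abs(circDiff(a, b, period))
}

#' Weighted circular mean and resultant
#'
#' Angles are mapped onto the full circle (multiplied by `360/period`),
#' summed as weighted unit phasors, and the argument of the resultant is
#' mapped back, so the 180-degree case uses the standard angle-doubling
#' estimator.  The resultant length (vector strength) is returned alongside
#' the mean.
#'
#' @param angles degrees.
#' @param weights nonnegative weights, recycled; default equal.
#' @param period 360 or 180.
#' @param tol resultant lengths below `tol` (fraction of total weight) have
#'   an undefined mean and raise an error.
#' @return list with `mean` (degrees in `[0, period)`), `resultant` (in
#'   `[0, 1]`), `n`, and `weightTotal`.
#' @examples
#' circMean(c(350, 10))$mean            # 0
#' circMean(c(10, 20, 30))$mean         # 20
#' @export
circMean <- function(angles, weights = NULL, period = 360, tol = 1e-9) {
  .checkPeriod(period)
  if (length(angles) < 1L) stop("circMean: need at least one angle")
  if (any(!is.finite(angles))) stop("circMean: angles must be finite")
  if (is.null(weights)) weights <- rep(1, length(angles))
  if (length(weights) != length(angles))
    weights <- rep_len(weights, length(angles))
  if (any(weights < 0)) stop("circMean: weights must be nonnegative")
  wtot <- sum(weights)
  if (wtot <= 0) stop("circMean: weights must not be all zero")
  k <- 360 / period
  th <- angles * k * DEG
  C <- sum(weights * cos(th)); S <- sum(weights * sin(th))
  R <- sqrt(C^2 + S^2) / wtot
  if (R < tol)
    stop("circMean: degenerate resultant (length ", format(R),
         "); mean undefined")
  mu <- (atan2(S, C) / DEG / k) %% period
  if (period - mu < 1e-9) mu <- 0  # guard against float wrap at the period
  list(mean = mu, resultant = R, n = length(angles), weightTotal = wtot)
}

#' Circular variance
#'
#' One minus the resultant length: 0 for identical angles, approaching 1 for
#' angles uniform on the circle.
#'
#' @inheritParams circMean
#' @return unitless in `[0, 1]`.
#' @export
circVariance <- function(angles, weights = NULL, period = 360) {
  .checkPeriod(period)
  if (length(angles) < 1L) stop("circVariance: need at least one angle")
  if (is.null(weights)) weights <- rep(1, length(angles))
  weights <- rep_len(weights, length(angles))
  wtot <- sum(weights)
  k <- 360 / period
  th <- angles * k * DEG
  R <- sqrt(sum(weights * cos(th))^2 + sum(weights * sin(th))^2) / wtot
  1 - R
}

#' Mean absolute circular tilt difference across pairs
#'
#' Aggregates the per-pair absolute circular distances `|tau_i - tau_0|`
#' into one summary.  The default, `method = "phasor"`, takes the argument
#' of the summed unit phasors of the absolute differences,
#' `arg(sum_k exp(j |tau_i^k - tau_0^k|))`, reduced to `[0, 360)`; the
#' conventional arithmetic mean of the absolute differences is available as
#' `method = "arithmetic"`.  The two agree when the differences are tightly
#' clustered and diverge when they are dispersed; both are exposed so the
#' aggregation rule is an explicit analysis choice.
#'
#' @param a,b paired angle vectors in degrees, or `a` a 2-column matrix of
#'   pairs with `b` missing.
#' @param period circle period of the underlying tilts (default 360).
#' @param method "phasor" or "arithmetic".
#' @return degrees.
#' @examples
#' meanAbsDiff(c(10, 50), c(350, 10))   # diffs 20 and 40 -> 30
#' @export
meanAbsDiff <- function(a, b = NULL, period = 360,
                        method = c("phasor", "arithmetic")) {
  method <- match.arg(method)
  if (is.null(b)) {
    if (is.matrix(a) && ncol(a) == 2L) { b <- a[, 2]; a <- a[, 1] }
    else stop("meanAbsDiff: supply paired vectors or a 2-column matrix")
  }
  if (length(a) < 1L) stop("meanAbsDiff: need at least one pair")
  d <- circAbsDiff(a, b, period)
  if (method == "arithmetic") return(mean(d))
  # phasor aggregation: arg of summed unit phasors at the absolute
  # differences, reduced to [0, 360)
  C <- sum(cos(d * DEG)); S <- sum(sin(d * DEG))
  R <- sqrt(C^2 + S^2) / length(d)
  if (R < 1e-9)
    stop("meanAbsDiff: degenerate resultant; mean undefined")
  (atan2(S, C) / DEG) %% 360
}

# Phasor-accumulator helper used by the lookup tables and the difference
# maps: circular mean from accumulated cos/sin sums.  `half = TRUE` reduces
# the result mod 180 (the "printed" unsigned-mean convention: phasors taken
# at the raw angle, mean folded onto [0, 180)).
.meanFromSums <- function(C, S, n, half = FALSE, tol = 1e-9) {
  R <- sqrt(C^2 + S^2) / pmax(n, 1)
  mu <- (atan2(S, C) / DEG) %% 360
  mu[360 - mu < 1e-9] <- 0
  mu[n <= 0 | R < tol] <- NA_real_
  if (half) mu <- mu %% 180
  mu
}
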