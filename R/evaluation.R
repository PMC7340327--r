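# Evaluation machinery: estimation/prediction error, error-vs-pooling-
# diameter sweeps, bootstrap confidence intervals, per-tilt best diameters,
# reliability diagnostics, and the consensus baseline.

#' Mean tilt error between estimates and references
#'
#' Per-row absolute circular distance (period 360) — the estimation error
#' when references are groundtruth tilts, the prediction error when they
#' are observer estimates — aggregated with [meanAbsDiff()]'s phasor rule
#' by default or the arithmetic mean.
#'
#' @param estimates,references degrees, matched rows; NA rows are dropped.
#' @param method "phasor" or "arithmetic".
#' @return degrees.
#' @export
meanTiltError <- function(estimates, references,
                          method = c("phasor", "arithmetic")) {
  method <- match.arg(method)
  ok <- !is.na(estimates) & !is.na(references)
  if (!any(ok)) stop("meanTiltError: no matched rows")
  meanAbsDiff(estimates[ok], references[ok], period = 360, method = method)
}

#' Error as a function of pooling diameter
#'
#' For each diameter, pools the local estimate maps at the given targets
#' ([estimateGlobal()]) and computes the mean error against the reference
#' tilts.  The diameter-0 entry equals the local model's error exactly
#' (the single-pixel region returns the local estimate unchanged).
#'
#' @param localMaps list of local-estimate matrices, one per scene.
#' @param geometry a [ViewingGeometry-class].
#' @param targets data.frame with `scene`, `row`, `col`, and `reference`
#'   (degrees: groundtruth tilt for estimation error, observer estimates
#'   for prediction error).
#' @param diameters increasing vector of pooling diameters (fixed) or
#'   average equivalent diameters (adaptive), arcmin.
#' @param mode,spec,keyMode,taper passed to [estimateGlobal()].
#' @param keyMaps list of groundtruth tilt matrices (for `keyMode =
#'   "groundtruth"`).
#' @param errorMethod aggregation for [meanTiltError()].
#' @return data.frame (class `ErrorCurve`) with `diameter`, `meanError`,
#'   `n`; per-target errors for each diameter in `attr(, "perTarget")`.
#' @export
sweepDiameters <- function(localMaps, geometry, targets, diameters,
                           mode = "fixed", spec = NULL,
                           keyMode = "groundtruth", keyMaps = NULL,
                           taper = "uniform", errorMethod = "phasor") {
  stopifnot(length(diameters) >= 1, !is.unsorted(diameters),
            all(c("scene", "row", "col", "reference") %in% names(targets)))
  perTarget <- matrix(NA_real_, nrow(targets), length(diameters))
  for (di in seq_along(diameters)) {
    est <- rep(NA_real_, nrow(targets))
    for (si in unique(targets$scene)) {
      rows <- which(targets$scene == si)
      est[rows] <- estimateGlobal(
        localMaps[[si]], geometry,
        targets = cbind(targets$row[rows], targets$col[rows]),
        mode = mode, diameter = diameters[di], spec = spec,
        keyMode = keyMode,
        keyMap = if (is.null(keyMaps)) NULL else keyMaps[[si]],
        taper = taper)
    }
    perTarget[, di] <- circAbsDiff(est, targets$reference, period = 360)
  }
  curve <- data.frame(
    diameter = diameters,
    meanError = vapply(seq_along(diameters), function(di) {
      e <- perTarget[, di]
      if (errorMethod == "arithmetic") mean(e, na.rm = TRUE)
      else {
        e <- e[!is.na(e)]
        (atan2(sum(sin(e * DEG)), sum(cos(e * DEG))) / DEG) %% 360
      }
    }, numeric(1)),
    n = colSums(!is.na(perTarget)))
  attr(curve, "perTarget") <- perTarget
  class(curve) <- c("ErrorCurve", class(curve))
  curve
}

#' Bootstrap confidence interval for a mean-error statistic
#'
#' Resamples stimuli with replacement `nSets` times and returns the
#' 2.5/97.5 percentiles of the resampled mean error.
#'
#' @param errors per-stimulus absolute errors, degrees.
#' @param nSets bootstrap sets (default 1000).
#' @param seed integer seed.
#' @param method aggregation ("phasor" or "arithmetic").
#' @return list with `point`, `lower`, `upper`, `nSets`.
#' @export
bootstrapCI <- function(errors, nSets = 1000L, seed = 1L,
                        method = "arithmetic") {
  errors <- errors[!is.na(errors)]
  stopifnot(length(errors) >= 2)
  agg <- function(e) {
    if (method == "arithmetic") mean(e)
    else (atan2(sum(sin(e * DEG)), sum(cos(e * DEG))) / DEG) %% 360
  }
  set.seed(as.integer(seed))
  n <- length(errors)
  stat <- vapply(seq_len(nSets),
                 function(i) agg(errors[sample.int(n, n, replace = TRUE)]),
                 numeric(1))
  q <- stats::quantile(stat, c(0.025, 0.975), names = FALSE, type = 7)
  list(point = agg(errors), lower = q[1], upper = q[2], nSets = nSets)
}

#' Best pooling diameter per target-tilt bin
#'
#' From a sweep's per-target errors, the diameter minimizing the mean error
#' within each target-tilt bin (ties broken toward the smallest diameter),
#' plus the Pearson correlation between the per-bin best diameters and a
#' reference diameter vector (e.g. the per-bin equivalent diameters of a
#' [PoolingSpec-class]) with a permutation p-value.
#'
#' @param curve an `ErrorCurve` from [sweepDiameters()] (with its
#'   `perTarget` attribute).
#' @param targetBins integer tilt bin per target row.
#' @param referenceDiameters optional per-bin reference, arcmin (one per
#'   bin present).
#' @param nPerm permutations for the p-value (default 10000).
#' @param seed integer seed.
#' @param errorMethod aggregation within bins.
#' @return list with `table` (bin, bestDiameter, minError, n),
#'   `correlation`, `pValue` (NA, flagged, when either vector has zero
#'   variance).
#' @export
bestDiameterPerTilt <- function(curve, targetBins,
                                referenceDiameters = NULL, nPerm = 10000L,
                                seed = 1L, errorMethod = "arithmetic") {
  perTarget <- attr(curve, "perTarget")
  stopifnot(!is.null(perTarget), length(targetBins) == nrow(perTarget))
  bins <- sort(unique(targetBins))
  agg <- function(e) {
    e <- e[!is.na(e)]
    if (!length(e)) return(NA_real_)
    if (errorMethod == "arithmetic") mean(e)
    else (atan2(sum(sin(e * DEG)), sum(cos(e * DEG))) / DEG) %% 360
  }
  tab <- do.call(rbind, lapply(bins, function(b) {
    rows <- targetBins == b
    if (!any(rows)) stop("bestDiameterPerTilt: empty bin ", b)
    errs <- apply(perTarget[rows, , drop = FALSE], 2, agg)
    best <- which(errs == min(errs, na.rm = TRUE))[1]  # ties: smallest
    data.frame(bin = b, bestDiameter = curve$diameter[best],
               minError = errs[best], n = sum(rows))
  }))
  corr <- NA_real_; pval <- NA_real_; flagged <- FALSE
  if (!is.null(referenceDiameters)) {
    stopifnot(length(referenceDiameters) == nrow(tab))
    x <- tab$bestDiameter; y <- referenceDiameters
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      flagged <- TRUE
    } else {
      corr <- stats::cor(x, y)
      set.seed(as.integer(seed))
      perm <- vapply(seq_len(nPerm),
                     function(i) stats::cor(x, sample(y)), numeric(1))
      pval <- (1 + sum(abs(perm) >= abs(corr))) / (nPerm + 1)
    }
  }
  list(table = tab, correlation = corr, pValue = pval,
       degenerate = flagged)
}

#' Reliability diagnostic: groundtruth given the local estimate
#'
#' Conditional distributions of groundtruth tilt given the value of the
#' local estimate, one per estimate bin (12 bins of 30 degrees by
#' default), each normalized to sum 1, plus a shift-invariance score: the
#' mean pairwise total-variation distance between the conditionals after
#' recentring each on its estimate-bin centre.  Approximate
#' shift-invariance means every local estimate is an equally reliable
#' predictor of groundtruth regardless of its value; the score is
#' reported, not asserted.
#'
#' @param estimates,groundtruth degrees, matched rows.
#' @param nEstBins estimate bins (default 12).
#' @param nGtBins groundtruth histogram bins (default 24).
#' @return list with `conditionals` (nEstBins x nGtBins matrix, rows sum
#'   to 1; NA rows where an estimate bin is empty), `estBinCenters`,
#'   `gtBinCenters`, `shiftInvariance` (mean pairwise TV distance, 0 =
#'   perfectly shift-invariant).
#' @export
reliabilityDiagnostic <- function(estimates, groundtruth, nEstBins = 12L,
                                  nGtBins = 24L) {
  ok <- !is.na(estimates) & !is.na(groundtruth)
  eb <- tiltBin(estimates[ok], nEstBins)
  gb <- tiltBin(groundtruth[ok], nGtBins)
  cond <- matrix(NA_real_, nEstBins, nGtBins)
  for (b in 0:(nEstBins - 1L)) {
    rows <- eb == b
    if (!any(rows)) next
    h <- tabulate(gb[rows] + 1L, nGtBins)
    cond[b + 1L, ] <- h / sum(h)
  }
  # recentre each conditional on its estimate-bin centre (gt bins per
  # estimate bin step) and score pairwise total-variation distance
  stepBins <- nGtBins / nEstBins
  recentred <- cond
  for (b in 0:(nEstBins - 1L)) {
    if (anyNA(cond[b + 1L, ])) next
    sh <- round(b * stepBins)
    recentred[b + 1L, ] <- cond[b + 1L, 1L + ((seq_len(nGtBins) - 1L + sh) %%
                                                nGtBins)]
  }
  full <- which(!apply(recentred, 1, anyNA))
  si <- NA_real_
  if (length(full) >= 2) {
    prs <- utils::combn(full, 2)
    si <- mean(apply(prs, 2, function(p)
      0.5 * sum(abs(recentred[p[1], ] - recentred[p[2], ]))))
  }
  list(conditionals = cond,
       estBinCenters = tiltBinCenter(0:(nEstBins - 1L), nEstBins),
       gtBinCenters = tiltBinCenter(0:(nGtBins - 1L), nGtBins),
       shiftInvariance = si)
}

#' Consensus baseline: circular mean of observer estimates
#'
#' Per stimulus, the circular mean of the responses of all observers — a
#' post-hoc upper-bound reference for prediction-error comparisons (it
#' sees the responses, not the images).  Stimuli with fewer than two
#' observers are an error; degenerate resultants are flagged with NA.
#'
#' @param responses data.frame with `stimulus`, `observer`, `response`
#'   (degrees).
#' @return data.frame with `stimulus`, `consensus` (deg; NA flagged),
#'   `nObservers`.
#' @export
consensusBaseline <- function(responses) {
  stopifnot(all(c("stimulus", "observer", "response") %in% names(responses)))
  sp <- split(responses$response, responses$stimulus)
  if (any(vapply(sp, length, integer(1)) < 2))
    stop("consensusBaseline: every stimulus needs at least 2 observers")
  cons <- vapply(sp, function(v) {
    tryCatch(circMean(v, period = 360)$mean, error = function(e) NA_real_)
  }, numeric(1))
  data.frame(stimulus = names(sp), consensus = cons,
             nObservers = vapply(sp, length, integer(1)),
             row.names = NULL)
}
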