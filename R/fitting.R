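#' @include AllClasses.R trace-features.R hh-simulate.R
NULL

#' Feature normalizers of the fitting error function
#'
#' The error function sums squared feature differences across features with
#' heterogeneous units; each difference is first divided by a fixed
#' species-scale constant so the sum is unit-free.  The constants are part of
#' the method definition and are versioned here: 10 mV for amplitude-like
#' features (plateau, spike amplitude, resting potential), 5 ms for timing
#' and duration, 1 for counts (spike number, rebound spikes), 0.1 for the
#' sag ratio.  \code{unmatchedPenalty} is the squared cost of a spike present
#' on one side only, (pulse duration / timing scale)^2 = (200/5)^2; the same
#' penalty is charged when a feature is computable on one side only.
#'
#' @return Named list of scale constants.
#' @export
featureNormalizers <- function() {
  list(amplitude_mv = 10, timing_ms = 5, count = 1, sag = 0.1,
       unmatchedPenalty = (200 / 5)^2)
}

# one squared, normalized term; both-missing -> 0, one-sided -> penalty
.errTerm <- function(a, b, scale, penalty) {
  if (is.na(a) && is.na(b)) return(0)
  if (is.na(a) || is.na(b)) return(penalty)
  ((a - b) / scale)^2
}

#' Fitting error between two feature vectors
#'
#' Mean-squares error over the eight features used for fitting: plateau
#' amplitude, spike amplitude, spike duration, number of spikes, the timing
#' of each individual spike, resting membrane potential, sag ratio and
#' rebound firing.  Each difference is normalized by the species-scale
#' constants of \code{\link{featureNormalizers}} before squaring, so the sum
#' is unit-free.  Spike times are matched in order up to the smaller count;
#' each unmatched spike adds the fixed penalty (during grid search such
#' candidates are disregarded instead; see \code{\link{gridSearch}}).
#'
#' The function is symmetric in its arguments, non-negative, and zero iff
#' all compared features agree.
#'
#' @param modelFv,bioFv IntrinsicFeatures of the model and biological traces
#'   (both from the canonical +100 / -140 pA protocol pair).
#' @param normalizers as \code{\link{featureNormalizers}}.
#' @return Unitless error, >= 0.
#' @export
fitError <- function(modelFv, bioFv, normalizers = featureNormalizers()) {
  stopifnot(is(modelFv, "IntrinsicFeatures"), is(bioFv, "IntrinsicFeatures"))
  ns <- normalizers
  pen <- ns$unmatchedPenalty
  e <- 0
  e <- e + .errTerm(modelFv@plateauAmplitudeMv, bioFv@plateauAmplitudeMv,
                    ns$amplitude_mv, pen)
  e <- e + .errTerm(modelFv@spikeAmplitudeMv, bioFv@spikeAmplitudeMv,
                    ns$amplitude_mv, pen)
  e <- e + .errTerm(modelFv@spikeDurationMs, bioFv@spikeDurationMs,
                    ns$timing_ms, pen)
  e <- e + ((modelFv@nSpikes - bioFv@nSpikes) / ns$count)^2
  k <- min(modelFv@nSpikes, bioFv@nSpikes)
  if (k > 0)
    e <- e + sum(((modelFv@spikeTimesMs[seq_len(k)] -
                   bioFv@spikeTimesMs[seq_len(k)]) / ns$timing_ms)^2)
  e <- e + abs(modelFv@nSpikes - bioFv@nSpikes) * pen *
    (modelFv@nSpikes != bioFv@nSpikes)
  e <- e + .errTerm(modelFv@restingPotentialMv, bioFv@restingPotentialMv,
                    ns$amplitude_mv, pen)
  e <- e + .errTerm(modelFv@sagRatio, bioFv@sagRatio, ns$sag, pen)
  rb_m <- as.numeric(modelFv@reboundSpikes)
  rb_b <- as.numeric(bioFv@reboundSpikes)
  e <- e + .errTerm(rb_m, rb_b, ns$count, pen)
  e
}

#' Published full-resolution search grid
#'
#' The exhaustive-search grid over the five conductances: gNa 200-2500 nS
#' (step 20), gK 50-750 (step 10), gSK 0-15 (step 0.2), gh 0-15 (step 0.2),
#' gCaT 0-10 (step 0.2) -- about 2.43e9 candidates, cluster-scale.
#'
#' @return A \linkS4class{ConductanceGrid}.
#' @export
speciesGrid <- function() {
  new("ConductanceGrid",
      min = c(gNa = 200, gK = 50, gSK = 0, gh = 0, gCaT = 0),
      max = c(gNa = 2500, gK = 750, gSK = 15, gh = 15, gCaT = 10),
      step = c(gNa = 20, gK = 10, gSK = 0.2, gh = 0.2, gCaT = 0.2))
}

#' Desk-scale search grid
#'
#' A coarse grid spanning given ranges with a fixed number of points per
#' axis, for single-workstation searches (the full-resolution grid of
#' \code{\link{speciesGrid}} requires a cluster).
#'
#' @param pointsPerAxis grid points per conductance axis (default 5).
#' @param min,max named per-axis bounds, nS; default a stable sub-range of
#'   the published ranges.
#' @return A \linkS4class{ConductanceGrid}.
#' @export
deskGrid <- function(pointsPerAxis = 5,
                     min = c(gNa = 400, gK = 100, gSK = 1, gh = 1, gCaT = 1),
                     max = c(gNa = 1600, gK = 500, gSK = 9, gh = 9, gCaT = 7)) {
  nm <- conductanceNames()
  step <- (max[nm] - min[nm]) / (pointsPerAxis - 1)
  new("ConductanceGrid", min = min[nm], max = max[nm], step = step)
}

.axisPoints <- function(grid) {
  nm <- conductanceNames()
  pts <- floor((grid@max[nm] - grid@min[nm]) / grid@step[nm] + 1e-9) + 1
  stats::setNames(as.integer(pts), nm)
}

#' Number of candidates in a search grid
#'
#' Product over axes of floor((max - min)/step) + 1.
#'
#' @param grid a ConductanceGrid.
#' @return Candidate count (double, since full grids exceed integer range).
#' @examples
#' gridSize(speciesGrid())  # 2,426,127,936
#' @export
gridSize <- function(grid) {
  stopifnot(is(grid, "ConductanceGrid"))
  prod(as.numeric(.axisPoints(grid)))
}

#' Axis values of a search grid
#'
#' @param grid a ConductanceGrid.
#' @return Named list of per-axis value vectors.
#' @export
gridAxes <- function(grid) {
  pts <- .axisPoints(grid)
  nm <- conductanceNames()
  stats::setNames(lapply(nm, function(a)
    grid@min[[a]] + grid@step[[a]] * (seq_len(pts[[a]]) - 1)), nm)
}

# all candidates, ordered so that row order is lexicographic in
# (gNa, gK, gSK, gh, gCaT); ties in error then resolve to the first row
.gridCandidates <- function(grid) {
  ax <- gridAxes(grid)
  g <- expand.grid(gCaT = ax$gCaT, gh = ax$gh, gSK = ax$gSK, gK = ax$gK,
                   gNa = ax$gNa, KEEP.OUT.ATTRS = FALSE)
  as.matrix(g[, conductanceNames()])
}

# Reconstruct the step protocol of a recorded/simulated trace
.traceProtocol <- function(trace) {
  pr <- trace@metadata$protocol
  if (is.null(pr)) stop("trace metadata lacks its stimulus protocol")
  pr
}

#' Exhaustive grid search of the five conductances
#'
#' Evaluates every candidate of the grid: simulates the canonical
#' depolarizing and hyperpolarizing pulses with the candidate conductances,
#' applies the spike-count disregard rule (any candidate whose simulated
#' spike train has a different number of spikes than the biological trace --
#' on the depolarizing pulse, or a different rebound count on the
#' hyperpolarizing pulse -- is disregarded before the error is computed),
#' computes the fitting error for the admissible candidates, and returns the
#' global minimum.  Ties are broken deterministically toward the
#' lexicographically smaller (gNa, gK, gSK, gh, gCaT) tuple.
#'
#' @param depolTrace,hyperpolTrace the target responses (canonical +100 and
#'   -140 pA pulses).
#' @param grid a ConductanceGrid; desk-scale by default.  The published
#'   full-resolution grid (~2.4e9 candidates) is cluster-scale.
#' @param params base HHParameters; everything except the five fitted
#'   conductances is held at these values.
#' @param keepTable store the full per-candidate error table (for error
#'   landscapes); off by default to save memory.
#' @param neuronId label for the fit.
#' @return A \linkS4class{GridFit}.  Fails with "no admissible candidate"
#'   when every candidate is disregarded.
#' @export
gridSearch <- function(depolTrace, hyperpolTrace, grid = deskGrid(),
                       params = referenceParameters(), keepTable = FALSE,
                       neuronId = NULL) {
  stopifnot(is(grid, "ConductanceGrid"))
  if (is.null(neuronId))
    neuronId <- depolTrace@metadata$neuron_id %||% "target"
  bioFv <- extractFeatures(depolTrace, hyperpolTrace)
  dpr <- .traceProtocol(depolTrace)
  hpr <- .traceProtocol(hyperpolTrace)
  dt <- dpr@dtMs
  # target spike counts for the disregard rule (same detector as features)
  n_dep <- bioFv@nSpikes
  n_reb <- bioFv@reboundSpikes

  cands <- .gridCandidates(grid)
  n_cand <- nrow(cands)
  errs <- rep(NA_real_, n_cand)
  disregarded <- 0L
  P0 <- params
  pulse_dep <- c(dpr@preMs, dpr@preMs + dpr@stimMs)
  off_h <- hpr@preMs + hpr@stimMs

  for (i in seq_len(n_cand)) {
    pc <- P0
    pc@conductances[conductanceNames()] <- cands[i, ]
    tr_d <- tryCatch(simulateNeuron(pc, dpr), error = function(e) NULL)
    if (is.null(tr_d)) { disregarded <- disregarded + 1L; next }
    cnt <- length(.hh_spike_onsets(tr_d@voltageMv, dt, 10, 2, 15, 5,
                                   round(pulse_dep[1] / dt) + 1L,
                                   round(pulse_dep[2] / dt)))
    if (cnt != n_dep) { disregarded <- disregarded + 1L; next }
    tr_h <- tryCatch(simulateNeuron(pc, hpr), error = function(e) NULL)
    if (is.null(tr_h)) { disregarded <- disregarded + 1L; next }
    if (!is.na(n_reb)) {
      reb <- length(.hh_spike_onsets(tr_h@voltageMv, hpr@dtMs, 10, 2, 15, 5,
                                     round(off_h / hpr@dtMs) + 1L,
                                     round(min(off_h + 200,
                                               max(tr_h@timeMs)) / hpr@dtMs)))
      if (reb != n_reb) { disregarded <- disregarded + 1L; next }
    }
    fv <- extractFeatures(tr_d, tr_h)
    errs[i] <- fitError(fv, bioFv)
  }

  ok <- which(!is.na(errs))
  if (!length(ok))
    stop("no admissible candidate: every grid point was disregarded by the spike-count rule")
  best <- ok[which.min(errs[ok])]   # first minimum = lexicographic tie-break
  tab <- if (keepTable)
    data.frame(cands, error = errs, check.names = FALSE) else data.frame()
  new("GridFit",
      conductances = stats::setNames(as.numeric(cands[best, ]),
                                     conductanceNames()),
      error = errs[best], neuronId = as.character(neuronId),
      disregarded = disregarded, evaluated = as.integer(n_cand),
      errorTable = tab)
}

#' Two-conductance error-landscape slice
#'
#' From a grid search run with \code{keepTable = TRUE}: the minimum error
#' over the remaining axes for every value pair of two chosen conductances
#' (disregarded candidates excluded).
#'
#' @param fit a GridFit with an error table.
#' @param axes character(2), e.g. c("gNa", "gSK").
#' @return data.frame with the two axis columns and min_error.
#' @export
landscapeSlice <- function(fit, axes = c("gNa", "gSK")) {
  stopifnot(is(fit, "GridFit"), length(axes) == 2,
            all(axes %in% conductanceNames()))
  tab <- fit@errorTable
  if (!nrow(tab)) stop("fit has no error table; rerun gridSearch(keepTable = TRUE)")
  tab <- tab[!is.na(tab$error), ]
  agg <- aggregate(tab$error, by = tab[axes], FUN = min)
  names(agg) <- c(axes, "min_error")
  agg[order(agg[[1]], agg[[2]]), , drop = FALSE]
}

#' Prediction error ratios for held-out current injections
#'
#' Simulates the fitted model at current amplitudes not used in fitting,
#' computes the fitting error of each prediction against the corresponding
#' held-out biological trace, and reports the ratio to the 100 pA fit error.
#' Spike-count mismatches are penalized (the disregard rule does not apply
#' to prediction).  A zero fit error is replaced by a floor epsilon with a
#' warning.
#'
#' @param fit a GridFit (or a named conductance vector).
#' @param fitError100 the fit error at 100 pA (taken from \code{fit} when a
#'   GridFit is supplied).
#' @param heldOutTraces named list of depolarizing VoltageTrace objects, one
#'   per held-out amplitude (e.g. "75", "150", "175").
#' @param hyperpolTrace the -140 pA response used for the sag/rebound
#'   features of each comparison.
#' @param params base HHParameters.
#' @param epsilon floor for the denominator.
#' @return Named numeric vector of error ratios, one per held-out amplitude.
#' @export
predictionScores <- function(fit, heldOutTraces, hyperpolTrace,
                             params = referenceParameters(),
                             fitError100 = NULL, epsilon = 1e-6) {
  if (is(fit, "GridFit")) {
    g <- conductances(fit)
    if (is.null(fitError100)) fitError100 <- fit@error
  } else {
    g <- fit[conductanceNames()]
    if (is.null(fitError100))
      stop("fitError100 must be given when fit is a plain conductance vector")
  }
  if (fitError100 < epsilon) {
    warning("fit error is (near) zero; ratios reported against floor epsilon")
    fitError100 <- epsilon
  }
  pc <- withConductances(params, g)
  hpr <- .traceProtocol(hyperpolTrace)
  tr_hm <- simulateNeuron(pc, hpr)
  out <- vapply(names(heldOutTraces), function(nmv) {
    bio <- heldOutTraces[[nmv]]
    pr <- .traceProtocol(bio)
    tr_m <- simulateNeuron(pc, pr)
    fitError(extractFeatures(tr_m, tr_hm), extractFeatures(bio, hyperpolTrace)) /
      fitError100
  }, numeric(1))
  stats::setNames(out, names(heldOutTraces))
}

#' Cross-validation of model predictions across birds
#'
#' For the best-fit neuron of each bird, compares the model's prediction for
#' a held-out amplitude (150 pA) against the actual response of every
#' neuron, normalizing each comparison by that model's own 100 pA fit error.
#' The diagonal holds each neuron's own prediction ratio; good models give
#' off-diagonal (cross-bird) ratios well above the diagonal.
#'
#' @param fits data.frame with columns neuron_id, bird_id, the five
#'   conductances, and error (the 100 pA fit error; zero replaced by
#'   epsilon).
#' @param traces named list (by neuron_id) with elements "+100", "-140" and
#'   the held-out amplitude label (default "+150") of VoltageTrace objects.
#' @param amplitudeLabel label of the held-out traces.
#' @param params base HHParameters.
#' @param epsilon denominator floor.
#' @return List: \code{matrix} (rows = predicting neuron, cols = target
#'   neuron, normalized errors), \code{summary} = mean off-diagonal / mean
#'   diagonal, \code{neurons} = the per-bird best-fit neuron ids.
#' @export
crossValidate <- function(fits, traces, amplitudeLabel = "+150",
                          params = referenceParameters(), epsilon = 1e-6) {
  stopifnot(all(c("neuron_id", "bird_id", "error", conductanceNames())
                %in% names(fits)))
  birds <- unique(fits$bird_id)
  if (length(birds) < 3)
    stop("cross-validation needs at least 3 birds")
  # one best-fit neuron per bird
  sel <- do.call(rbind, lapply(birds, function(b) {
    sub <- fits[fits$bird_id == b, ]
    sub[which.min(sub$error), , drop = FALSE]
  }))
  nb <- nrow(sel)
  # features of every selected neuron's actual held-out response
  bioFv <- lapply(seq_len(nb), function(j) {
    trs <- traces[[sel$neuron_id[j]]]
    extractFeatures(trs[[amplitudeLabel]], trs[["-140"]])
  })
  M <- matrix(NA_real_, nb, nb,
              dimnames = list(sel$neuron_id, sel$neuron_id))
  for (i in seq_len(nb)) {
    pc <- withConductances(params,
                           stats::setNames(as.numeric(sel[i, conductanceNames()]),
                                           conductanceNames()))
    pr <- .traceProtocol(traces[[sel$neuron_id[i]]][[amplitudeLabel]])
    hpr <- .traceProtocol(traces[[sel$neuron_id[i]]][["-140"]])
    fv_m <- extractFeatures(simulateNeuron(pc, pr), simulateNeuron(pc, hpr))
    denom <- max(sel$error[i], epsilon)
    for (j in seq_len(nb))
      M[i, j] <- fitError(fv_m, bioFv[[j]]) / denom
  }
  list(matrix = M,
       summary = mean(M[row(M) != col(M)]) / mean(diag(M)),
       neurons = sel$neuron_id)
}
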