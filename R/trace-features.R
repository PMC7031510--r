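#' @include AllClasses.R
NULL

# Pulse sample window (1-based index range) from a trace's protocol metadata.
.pulseWindow <- function(trace) {
  pr <- trace@metadata$protocol
  if (is.null(pr)) stop("trace has no protocol metadata; cannot locate pulse")
  dt <- trace@dtMs
  i0 <- round(pr@preMs / dt) + 1L
  i1 <- round((pr@preMs + pr@stimMs) / dt)
  if (i1 < i0) stop("no pulse found in protocol (zero stimulus duration)")
  list(from = i0, to = i1, preMs = pr@preMs, stimMs = pr@stimMs,
       postMs = pr@postMs, amplitude = pr@amplitude)
}

#' Detect action potentials in a voltage trace
#'
#' Spikes are detected as upward crossings of a dV/dt threshold (default
#' 10 mV/ms, measured on a ~0.2 ms smoothed derivative), merged within a
#' refractory window and validated by requiring a genuine upstroke (>= 15 mV
#' rise within 5 ms).  For each spike the peak, threshold (voltage at the
#' dV/dt crossing preceding the peak), amplitude (peak minus threshold) and
#' duration (full width at half amplitude above threshold) are measured, and
#' a fixed waveform snippet around the peak is extracted.
#'
#' @param trace a VoltageTrace (dt must be <= 0.5 ms).
#' @param dvdtThreshold slope criterion, mV/ms.
#' @param refractoryMs merge window for threshold crossings, ms.
#' @param window optional c(fromMs, toMs) restricting detection.
#' @param snippetMs c(before, after) extent of the waveform snippet, ms.
#' @return data.frame with one row per spike: peak_time_ms, peak_mv,
#'   threshold_time_ms, threshold_mv, amplitude_mv, duration_ms, and the
#'   snippet matrix in attribute "snippets" (rows = spikes).
#' @export
detectSpikes <- function(trace, dvdtThreshold = 10, refractoryMs = 2,
                         window = NULL, snippetMs = c(2, 5)) {
  stopifnot(is(trace, "VoltageTrace"))
  dt <- trace@dtMs
  if (dt > 0.5)
    stop("sample interval too coarse for spike detection (dt > 0.5 ms)")
  v <- trace@voltageMv
  n <- length(v)
  if (is.null(window)) {
    i_from <- 1L; i_to <- n
  } else {
    i_from <- max(1L, round(window[1] / dt) + 1L)
    i_to <- min(n, round(window[2] / dt) + 1L)
  }
  onsets <- .hh_spike_onsets(v, dt, dvdtThreshold, refractoryMs, 15, 5,
                             i_from, i_to)
  k <- length(onsets)
  empty <- data.frame(peak_time_ms = numeric(0), peak_mv = numeric(0),
                      threshold_time_ms = numeric(0), threshold_mv = numeric(0),
                      amplitude_mv = numeric(0), duration_ms = numeric(0))
  if (k == 0L) {
    attr(empty, "snippets") <- matrix(numeric(0), 0, 0)
    return(empty)
  }
  peak_idx <- integer(k)
  for (j in seq_len(k)) {
    hi <- if (j < k) onsets[j + 1] - 1L else min(n, onsets[j] + round(8 / dt))
    hi <- min(hi, onsets[j] + round(8 / dt))
    seg <- onsets[j]:hi
    peak_idx[j] <- seg[which.max(v[seg])]
  }
  thr_v <- v[onsets]
  amp <- v[peak_idx] - thr_v
  dur <- numeric(k)
  for (j in seq_len(k)) {
    half <- thr_v[j] + amp[j] / 2
    # walk out from the peak to the half-amplitude crossings
    i_left <- peak_idx[j]
    while (i_left > 1L && v[i_left - 1L] > half) i_left <- i_left - 1L
    i_right <- peak_idx[j]
    while (i_right < n && v[i_right + 1L] > half) i_right <- i_right + 1L
    dur[j] <- (i_right - i_left) * dt
  }
  before <- round(snippetMs[1] / dt)
  after <- round(snippetMs[2] / dt)
  snips <- matrix(NA_real_, k, before + after + 1L)
  for (j in seq_len(k)) {
    idx <- (peak_idx[j] - before):(peak_idx[j] + after)
    ok <- idx >= 1L & idx <= n
    snips[j, ok] <- v[idx[ok]]
  }
  out <- data.frame(
    peak_time_ms = trace@timeMs[peak_idx],
    peak_mv = v[peak_idx],
    threshold_time_ms = trace@timeMs[onsets],
    threshold_mv = thr_v,
    amplitude_mv = amp,
    duration_ms = dur
  )
  attr(out, "snippets") <- snips
  out
}

#' Extract the intrinsic-property feature vector of one neuron
#'
#' Combines a depolarizing-step response (spike train, waveform and plateau
#' features) with a hyperpolarizing-step response (sag, rebound) into the
#' feature vector used by the fitting error function and the population
#' statistics.  Fields that cannot be computed are NA.
#'
#' Definitions: spike times are peak times relative to pulse onset; spike
#' rate is count over the pulse duration; plateau amplitude is the mean of
#' the inter-spike voltage minima during the pulse minus rest (with fewer
#' than two spikes, the mean pulse voltage excluding 10 ms around spikes,
#' minus rest); resting potential is the mean pre-pulse voltage; the sag
#' ratio is (V_ss - V_min)/(V_base - V_min) with V_min the most negative
#' pulse voltage, V_ss the mean over the final 20 ms of the pulse and V_base
#' the mean over the 50 ms before it; rebound firing is the spike count in
#' the 200 ms after pulse offset.
#'
#' @param depolTrace response to a depolarizing step (amplitude > 0).
#' @param hyperpolTrace response to a hyperpolarizing step (amplitude < 0),
#'   or NULL to skip sag/rebound features.
#' @param ... passed to \code{\link{detectSpikes}}.
#' @return An \linkS4class{IntrinsicFeatures} object.
#' @export
extractFeatures <- function(depolTrace, hyperpolTrace = NULL, ...) {
  stopifnot(is(depolTrace, "VoltageTrace"))
  w <- .pulseWindow(depolTrace)
  if (w$amplitude <= 0)
    stop("depolTrace must come from a positive current step")
  dt <- depolTrace@dtMs
  v <- depolTrace@voltageMv
  tms <- depolTrace@timeMs
  pulse_t <- c(w$preMs, w$preMs + w$stimMs)
  sp <- detectSpikes(depolTrace, window = pulse_t, ...)
  nsp <- nrow(sp)
  rest <- mean(v[tms < w$preMs])
  spike_times <- sp$peak_time_ms - w$preMs
  isis <- if (nsp >= 2) diff(spike_times) else numeric(0)

  # plateau: inter-spike minima during the pulse, else spike-free pulse mean
  plateau <- NA_real_
  in_pulse <- tms >= pulse_t[1] & tms < pulse_t[2]
  if (nsp >= 2) {
    mins <- numeric(nsp - 1)
    for (j in seq_len(nsp - 1)) {
      seg <- tms > sp$peak_time_ms[j] & tms < sp$peak_time_ms[j + 1]
      mins[j] <- min(v[seg])
    }
    plateau <- mean(mins) - rest
  } else {
    keep <- in_pulse
    if (nsp == 1)
      keep <- keep & abs(tms - sp$peak_time_ms[1]) > 10
    if (any(keep)) plateau <- mean(v[keep]) - rest
  }

  feat <- new("IntrinsicFeatures",
    nSpikes = as.integer(nsp),
    spikeTimesMs = as.numeric(spike_times),
    isisMs = as.numeric(isis),
    spikeRateHz = nsp / (w$stimMs / 1000),
    spikeAmplitudeMv = if (nsp) sp$amplitude_mv[1] else NA_real_,
    spikeThresholdMv = if (nsp) sp$threshold_mv[1] else NA_real_,
    spikeDurationMs = if (nsp) sp$duration_ms[1] else NA_real_,
    plateauAmplitudeMv = plateau,
    restingPotentialMv = rest,
    firstSpikeWaveform = if (nsp) as.numeric(attr(sp, "snippets")[1, ])
                         else numeric(0)
  )

  if (!is.null(hyperpolTrace)) {
    stopifnot(is(hyperpolTrace, "VoltageTrace"))
    hw <- .pulseWindow(hyperpolTrace)
    if (hw$amplitude >= 0)
      stop("hyperpolTrace must come from a negative current step")
    hv <- hyperpolTrace@voltageMv
    ht <- hyperpolTrace@timeMs
    p0 <- hw$preMs; p1 <- hw$preMs + hw$stimMs
    in_p <- ht >= p0 & ht < p1
    v_min <- min(hv[in_p])
    v_ss <- mean(hv[ht >= p1 - 20 & ht < p1])
    v_base <- mean(hv[ht >= p0 - 50 & ht < p0])
    denom <- v_base - v_min
    sag <- if (denom > 0.5) (v_ss - v_min) / denom else 0
    sag <- min(max(sag, 0), 1)
    reb <- detectSpikes(hyperpolTrace,
                        window = c(p1, min(p1 + 200, max(ht))), ...)
    post <- ht >= p1 & ht < p1 + 200
    feat@sagRatio <- sag
    feat@reboundSpikes <- as.integer(nrow(reb))
    feat@reboundDepolarizationMv <- max(hv[post]) - v_base
  }
  validObject(feat)
  feat
}

#' Sag amplitude of a hyperpolarizing response
#'
#' Depolarizing relaxation during the pulse: mean voltage over the final
#' 20 ms of the pulse minus the most negative pulse voltage, mV.
#'
#' @param trace response to a hyperpolarizing step.
#' @return Sag amplitude, mV (>= 0).
#' @export
sagAmplitude <- function(trace) {
  w <- .pulseWindow(trace)
  v <- trace@voltageMv; tms <- trace@timeMs
  p0 <- w$preMs; p1 <- w$preMs + w$stimMs
  in_p <- tms >= p0 & tms < p1
  mean(v[tms >= p1 - 20 & tms < p1]) - min(v[in_p])
}

#' Input resistance from small hyperpolarizing steps
#'
#' R = dV_ss / dI averaged over the provided steps, where dV_ss is the
#' steady-state voltage deflection (mean over the final 20 ms of the pulse
#' minus the pre-pulse baseline).  Steps must have magnitudes in the 5-25 pA
#' range used experimentally.
#'
#' @param traces list of VoltageTrace objects from small negative steps.
#' @return Input resistance, MOhm.
#' @examples
#' leaky <- withConductances(referenceParameters(),
#'   c(gNa = 0, gK = 0, gSK = 0, gh = 0, gCaT = 0, gCaL = 0, gA = 0, gL = 5))
#' tr <- simulateNeuron(leaky, stepProtocol(-10))
#' inputResistance(list(tr))  # ~200 MOhm
#' @export
inputResistance <- function(traces) {
  if (is(traces, "VoltageTrace")) traces <- list(traces)
  stopifnot(length(traces) >= 1)
  rs <- vapply(traces, function(tr) {
    w <- .pulseWindow(tr)
    amp <- w$amplitude
    if (amp >= 0 || abs(amp) < 5 || abs(amp) > 25)
      stop(sprintf(
        "input-resistance steps must be hyperpolarizing, 5-25 pA (got %g pA)",
        amp))
    v <- tr@voltageMv; tms <- tr@timeMs
    p0 <- w$preMs; p1 <- p0 + w$stimMs
    dv <- mean(v[tms >= p1 - 20 & tms < p1]) - mean(v[tms < p0])
    1000 * dv / amp     # mV/pA = GOhm; report MOhm
  }, numeric(1))
  mean(rs)
}

#' Tabulate features for a set of neurons
#'
#' @param featureList named list (by neuron id) of IntrinsicFeatures.
#' @param birdIds character vector parallel to featureList.
#' @return data.frame, one row per neuron, with the scalar feature fields
#'   plus first three ISIs (isi1, isi2, isi3).
#' @export
featuresTable <- function(featureList, birdIds = NA_character_) {
  birdIds <- rep_len(birdIds, length(featureList))
  rows <- lapply(seq_along(featureList), function(i) {
    f <- featureList[[i]]
    isi <- c(f@isisMs, rep(NA_real_, 3))[1:3]
    data.frame(
      neuron_id = names(featureList)[i] %||% as.character(i),
      bird_id = birdIds[i],
      n_spikes = f@nSpikes,
      spike_rate_hz = f@spikeRateHz,
      isi1_ms = isi[1], isi2_ms = isi[2], isi3_ms = isi[3],
      spike_amplitude_mv = f@spikeAmplitudeMv,
      spike_threshold_mv = f@spikeThresholdMv,
      spike_duration_ms = f@spikeDurationMs,
      plateau_amplitude_mv = f@plateauAmplitudeMv,
      resting_potential_mv = f@restingPotentialMv,
      sag_ratio = f@sagRatio,
      rebound_spikes = f@reboundSpikes,
      input_resistance_mohm = f@inputResistanceMohm,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
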