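#' @import methods
NULL

#' Names of the five fitted maximal conductances
#'
#' The five principal currents whose maximal conductances are varied during
#' fitting: fast sodium, delayed-rectifier potassium, SK
#' (calcium-activated potassium), h-current and T-type calcium.
#'
#' @return Character vector of length five.
#' @export
conductanceNames <- function() c("gNa", "gK", "gSK", "gh", "gCaT")

.fixedConductanceNames <- c("gCaL", "gA", "gL")

#' HHParameters: full parameter set of the single-compartment model
#'
#' Holds membrane capacitance, the eight maximal conductances (five varied,
#' three fixed), reversal potentials, the gating-kinetics constants and the
#' calcium-pool constants.  Units: pF, nS, mV, ms, uM.
#'
#' @slot capacitance membrane capacitance, pF.
#' @slot conductances named numeric: gNa, gK, gSK, gh, gCaT, gCaL, gA, gL (nS).
#' @slot reversals named numeric: ENa, EK, Eh, ECa, EL (mV).
#' @slot kinetics named numeric vector of sigmoid midpoints/slopes and
#'   time-constant parameters for every gating variable.
#' @slot calcium named numeric: ks (uM), kca (uM/(pA ms)), tauCa (ms), ca0 (uM).
#'
#' @export
setClass("HHParameters",
  representation(
    capacitance = "numeric",
    conductances = "numeric",
    reversals = "numeric",
    kinetics = "numeric",
    calcium = "numeric"
  )
)

setValidity("HHParameters", function(object) {
  msg <- character()
  g <- object@conductances
  if (!all(c(conductanceNames(), .fixedConductanceNames) %in% names(g)))
    msg <- c(msg, "conductances must be named gNa, gK, gSK, gh, gCaT, gCaL, gA, gL")
  if (any(g < 0)) msg <- c(msg, "all conductances must be >= 0")
  if (length(object@capacitance) != 1L || object@capacitance <= 0)
    msg <- c(msg, "capacitance must be a single positive number")
  E <- object@reversals
  if (!all(c("ENa", "EK", "Eh", "ECa", "EL") %in% names(E)))
    msg <- c(msg, "reversals must be named ENa, EK, Eh, ECa, EL")
  else if (!(E[["ENa"]] > 0 && E[["EK"]] < 0))
    msg <- c(msg, "require ENa > 0 > EK")
  ca <- object@calcium
  if (!all(c("ks", "kca", "tauCa", "ca0") %in% names(ca)))
    msg <- c(msg, "calcium must be named ks, kca, tauCa, ca0")
  else if (ca[["tauCa"]] <= 0)
    msg <- c(msg, "calcium removal time constant must be > 0")
  tau_base <- grep("^tau.*base$", names(object@kinetics), value = TRUE)
  if (length(tau_base) && any(object@kinetics[tau_base] <= 0))
    msg <- c(msg, "gating time-constant bases must be > 0")
  if (length(msg)) msg else TRUE
})

#' StimulusProtocol: description of one current-clamp stimulus
#'
#' The canonical protocol is a 200 ms current step preceded and followed by
#' 200 ms of quiescence, delivered from a -70 mV holding potential.
#'
#' @slot kind "step", "chaotic" or "custom".
#' @slot amplitude step amplitude, pA (peak scale for chaotic stimuli).
#' @slot preMs,stimMs,postMs durations of the quiescent/stimulus epochs, ms.
#' @slot dtMs sample interval, ms.
#' @slot holdingMv target holding potential, mV.
#' @slot seed integer seed for generated (chaotic) waveforms, NA otherwise.
#' @slot waveform stimulus-epoch current samples for non-step kinds (pA,
#'   relative to the holding bias); length 0 for steps.
#'
#' @export
setClass("StimulusProtocol",
  representation(
    kind = "character",
    amplitude = "numeric",
    preMs = "numeric",
    stimMs = "numeric",
    postMs = "numeric",
    dtMs = "numeric",
    holdingMv = "numeric",
    seed = "integer",
    waveform = "numeric"
  ),
  prototype(kind = "step", amplitude = 0, preMs = 200, stimMs = 200,
            postMs = 200, dtMs = 0.02, holdingMv = -70, seed = NA_integer_,
            waveform = numeric(0))
)

setValidity("StimulusProtocol", function(object) {
  msg <- character()
  if (!object@kind %in% c("step", "chaotic", "custom"))
    msg <- c(msg, "kind must be step, chaotic or custom")
  if (any(c(object@preMs, object@stimMs, object@postMs) < 0))
    msg <- c(msg, "durations must be >= 0")
  if (object@dtMs <= 0) msg <- c(msg, "dt must be > 0")
  if (length(msg)) msg else TRUE
})

#' VoltageTrace: one voltage time series with its stimulus
#'
#' @slot timeMs uniform time grid starting at 0, ms.
#' @slot voltageMv membrane potential samples, mV.
#' @slot currentPa injected current samples, pA.
#' @slot dtMs sample interval, ms.
#' @slot metadata list: neuron_id, bird_id, protocol (StimulusProtocol),
#'   provenance ("simulated", "synthetic-cohort" or "external"), and any
#'   extra annotations.
#'
#' @export
setClass("VoltageTrace",
  representation(
    timeMs = "numeric",
    voltageMv = "numeric",
    currentPa = "numeric",
    dtMs = "numeric",
    metadata = "list"
  )
)

setValidity("VoltageTrace", function(object) {
  msg <- character()
  n <- length(object@timeMs)
  if (length(object@voltageMv) != n || length(object@currentPa) != n)
    msg <- c(msg, "voltage and current must have the same length as the time grid")
  if (n >= 2) {
    dts <- diff(object@timeMs)
    if (max(abs(dts - object@dtMs)) > 1e-8)
      msg <- c(msg, "time grid must be uniform with spacing dtMs")
  }
  if (length(msg)) msg else TRUE
})

#' IntrinsicFeatures: waveform and spike-train features of one neuron
#'
#' The feature set entering the fitting error function and the population
#' statistics.  Fields that cannot be computed (e.g. ISIs with fewer than two
#' spikes) are NA, never silently zero.
#'
#' @slot nSpikes spike count during the depolarizing pulse.
#' @slot spikeTimesMs spike peak times relative to pulse onset, ms.
#' @slot isisMs successive inter-spike intervals, ms.
#' @slot spikeRateHz nSpikes / pulse duration, Hz.
#' @slot spikeAmplitudeMv first-spike amplitude (peak minus threshold), mV.
#' @slot spikeThresholdMv first-spike threshold voltage, mV.
#' @slot spikeDurationMs first-spike width at half amplitude, ms.
#' @slot plateauAmplitudeMv depolarized plateau above rest, mV.
#' @slot restingPotentialMv mean pre-pulse voltage, mV.
#' @slot sagRatio (V_ss - V_min)/(V_base - V_min) on the hyperpolarizing
#'   pulse, in [0, 1]; 0 means no sag.
#' @slot reboundSpikes spike count in the 200 ms after hyperpolarizing offset.
#' @slot reboundDepolarizationMv peak post-offset voltage minus baseline, mV.
#' @slot inputResistanceMohm input resistance when small steps available, MOhm.
#' @slot firstSpikeWaveform voltage snippet around the first spike peak, mV.
#'
#' @export
setClass("IntrinsicFeatures",
  representation(
    nSpikes = "integer",
    spikeTimesMs = "numeric",
    isisMs = "numeric",
    spikeRateHz = "numeric",
    spikeAmplitudeMv = "numeric",
    spikeThresholdMv = "numeric",
    spikeDurationMs = "numeric",
    plateauAmplitudeMv = "numeric",
    restingPotentialMv = "numeric",
    sagRatio = "numeric",
    reboundSpikes = "integer",
    reboundDepolarizationMv = "numeric",
    inputResistanceMohm = "numeric",
    firstSpikeWaveform = "numeric"
  ),
  prototype(nSpikes = 0L, spikeTimesMs = numeric(0), isisMs = numeric(0),
            spikeRateHz = NA_real_, spikeAmplitudeMv = NA_real_,
            spikeThresholdMv = NA_real_, spikeDurationMs = NA_real_,
            plateauAmplitudeMv = NA_real_, restingPotentialMv = NA_real_,
            sagRatio = NA_real_, reboundSpikes = NA_integer_,
            reboundDepolarizationMv = NA_real_,
            inputResistanceMohm = NA_real_, firstSpikeWaveform = numeric(0))
)

setValidity("IntrinsicFeatures", function(object) {
  msg <- character()
  if (object@nSpikes != length(object@spikeTimesMs))
    msg <- c(msg, "nSpikes must equal length(spikeTimesMs)")
  if (object@nSpikes >= 2 &&
      max(abs(object@isisMs - diff(object@spikeTimesMs))) > 1e-8)
    msg <- c(msg, "isisMs must be the successive differences of spikeTimesMs")
  if (!is.na(object@sagRatio) &&
      (object@sagRatio < -1e-8 || object@sagRatio > 1 + 1e-8))
    msg <- c(msg, "sagRatio must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ConductanceGrid: exhaustive-search grid over the five conductances
#'
#' Per-axis (min, max, step) in nS.  The published full-resolution grid is
#' available via \code{\link{speciesGrid}}; desk-scale sub-grids via
#' \code{\link{deskGrid}}.
#'
#' @slot min,max,step named numeric vectors over gNa, gK, gSK, gh, gCaT.
#'
#' @export
setClass("ConductanceGrid",
  representation(min = "numeric", max = "numeric", step = "numeric")
)

setValidity("ConductanceGrid", function(object) {
  msg <- character()
  nm <- conductanceNames()
  for (s in c("min", "max", "step")) {
    v <- slot(object, s)
    if (length(v) != 5L || !all(nm %in% names(v))) {
      msg <- c(msg, sprintf("%s must be a named numeric over %s",
                            s, paste(nm, collapse = ", ")))
      return(msg)
    }
  }
  if (any(object@min[nm] > object@max[nm])) msg <- c(msg, "min must be <= max")
  if (any(object@step[nm] <= 0)) msg <- c(msg, "step must be > 0")
  if (length(msg)) msg else TRUE
})

#' GridFit: result of an exhaustive conductance search
#'
#' @slot conductances best-fitting named conductance vector (nS).
#' @slot error best (minimum) error over admissible candidates, unitless.
#' @slot neuronId identifier of the target neuron.
#' @slot disregarded number of candidates discarded by the spike-count rule.
#' @slot evaluated number of candidates evaluated in total.
#' @slot errorTable optional per-candidate table (conductances + error,
#'   NA where disregarded) for error-landscape slices.
#'
#' @export
setClass("GridFit",
  representation(
    conductances = "numeric",
    error = "numeric",
    neuronId = "character",
    disregarded = "integer",
    evaluated = "integer",
    errorTable = "data.frame"
  ),
  prototype(errorTable = data.frame())
)

setValidity("GridFit", function(object) {
  msg <- character()
  if (!all(conductanceNames() %in% names(object@conductances)))
    msg <- c(msg, "conductances must be named over the five fitted axes")
  if (length(object@error) != 1L || object@error < 0)
    msg <- c(msg, "error must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' BirdCohort: neurons grouped by bird
#'
#' The central population container: a per-neuron conductance table (true
#' values for synthetic cohorts, fitted values otherwise), per-bird centroids,
#' optional simulated traces, an optional song-similarity matrix, and the
#' generating configuration for provenance.
#'
#' @slot conductances data.frame with columns neuron_id, bird_id and the five
#'   conductances (nS).
#' @slot centroids data.frame with bird_id and per-bird centroid conductances.
#' @slot traces named list (by neuron_id) of named lists (by amplitude label)
#'   of VoltageTrace objects; empty when traces were not simulated.
#' @slot similarity square bird-by-bird song-similarity matrix (percent-like,
#'   (0, 100]); 0 x 0 when absent.
#' @slot config list snapshot of the generating configuration.
#'
#' @export
setClass("BirdCohort",
  representation(
    conductances = "data.frame",
    centroids = "data.frame",
    traces = "list",
    similarity = "matrix",
    config = "list"
  ),
  prototype(traces = list(), similarity = matrix(numeric(0), 0, 0),
            config = list())
)

setValidity("BirdCohort", function(object) {
  msg <- character()
  need <- c("neuron_id", "bird_id", conductanceNames())
  if (!all(need %in% names(object@conductances)))
    msg <- c(msg, sprintf("conductances table must have columns %s",
                          paste(need, collapse = ", ")))
  if (nrow(object@similarity) != ncol(object@similarity))
    msg <- c(msg, "similarity matrix must be square")
  if (length(msg)) msg else TRUE
})
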