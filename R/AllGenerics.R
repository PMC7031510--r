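#' @include AllClasses.R
NULL

#' Extract the five fitted conductances
#'
#' @param object an HHParameters, GridFit or BirdCohort object.
#' @param ... unused.
#' @return For HHParameters and GridFit, a named numeric vector over
#'   gNa, gK, gSK, gh, gCaT (nS); for BirdCohort, the per-neuron table.
#' @export
setGeneric("conductances", function(object, ...) standardGeneric("conductances"))

#' Replace conductances
#'
#' @param object an HHParameters object.
#' @param value named numeric; any subset of gNa, gK, gSK, gh, gCaT, gCaL,
#'   gA, gL.
#' @return The modified object.
#' @export
setGeneric("conductances<-", function(object, value) standardGeneric("conductances<-"))

#' @rdname conductances
#' @export
setMethod("conductances", "HHParameters", function(object, ...)
  object@conductances[conductanceNames()])

#' @rdname conductances-set
#' @name conductances<-
#' @aliases conductances<-,HHParameters-method
#' @export
setMethod("conductances<-", "HHParameters", function(object, value) {
  stopifnot(is.numeric(value), !is.null(names(value)))
  bad <- setdiff(names(value), names(object@conductances))
  if (length(bad))
    stop("unknown conductance name(s): ", paste(bad, collapse = ", "))
  object@conductances[names(value)] <- value
  validObject(object)
  object
})

#' @rdname conductances
#' @export
setMethod("conductances", "GridFit", function(object, ...)
  object@conductances[conductanceNames()])

#' @rdname conductances
#' @export
setMethod("conductances", "BirdCohort", function(object, ...)
  object@conductances)

#' Bird identifiers of a cohort
#'
#' @param object a BirdCohort.
#' @return Character vector of bird ids, in centroid-table order.
#' @export
setGeneric("birdIds", function(object) standardGeneric("birdIds"))

#' @rdname birdIds
#' @export
setMethod("birdIds", "BirdCohort", function(object)
  as.character(object@centroids$bird_id))

#' Per-bird centroid conductances
#'
#' @param object a BirdCohort.
#' @return data.frame with bird_id and the five centroid conductances.
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))

#' @rdname centroids
#' @export
setMethod("centroids", "BirdCohort", function(object) object@centroids)

#' Simulated traces of a cohort
#'
#' @param object a BirdCohort.
#' @param neuronId optional neuron id; if given, that neuron's traces.
#' @return Named list of per-neuron trace lists (or one neuron's list).
#' @export
setGeneric("cohortTraces", function(object, neuronId = NULL)
  standardGeneric("cohortTraces"))

#' @rdname cohortTraces
#' @export
setMethod("cohortTraces", "BirdCohort", function(object, neuronId = NULL) {
  if (is.null(neuronId)) return(object@traces)
  object@traces[[neuronId]]
})

#' Song-similarity matrix of a cohort
#'
#' @param object a BirdCohort.
#' @return Square bird-by-bird similarity matrix, or NULL when absent.
#' @export
setGeneric("songSimilarity", function(object) standardGeneric("songSimilarity"))

#' @rdname songSimilarity
#' @export
setMethod("songSimilarity", "BirdCohort", function(object) {
  if (nrow(object@similarity) == 0L) NULL else object@similarity
})

setMethod("show", "HHParameters", function(object) {
  g <- object@conductances
  cat("HHParameters (single-compartment HVC_X model)\n")
  cat(sprintf("  Cm: %g pF\n", object@capacitance))
  cat("  varied g (nS): ",
      paste(sprintf("%s=%g", conductanceNames(), g[conductanceNames()]),
            collapse = ", "), "\n", sep = "")
  cat("  fixed g (nS):  ",
      paste(sprintf("%s=%g", .fixedConductanceNames, g[.fixedConductanceNames]),
            collapse = ", "), "\n", sep = "")
})

setMethod("show", "StimulusProtocol", function(object) {
  cat(sprintf("StimulusProtocol: %s, %g pA, %g/%g/%g ms (pre/stim/post), dt %g ms, holding %g mV\n",
              object@kind, object@amplitude, object@preMs, object@stimMs,
              object@postMs, object@dtMs, object@holdingMv))
})

setMethod("show", "VoltageTrace", function(object) {
  md <- object@metadata
  cat(sprintf("VoltageTrace: %d samples, dt %g ms (%.0f ms)\n",
              length(object@timeMs), object@dtMs,
              if (length(object@timeMs)) max(object@timeMs) else 0))
  if (!is.null(md$neuron_id))
    cat(sprintf("  neuron %s (bird %s), provenance %s\n",
                md$neuron_id, md$bird_id %||% "?", md$provenance %||% "?"))
})

setMethod("show", "IntrinsicFeatures", function(object) {
  cat("IntrinsicFeatures\n")
  cat(sprintf("  spikes: %d (rate %.1f Hz), first ISI %s ms\n",
              object@nSpikes,
              ifelse(is.na(object@spikeRateHz), NA, object@spikeRateHz),
              if (length(object@isisMs)) sprintf("%.2f", object@isisMs[1]) else "NA"))
  cat(sprintf("  first spike: amplitude %.1f mV, threshold %.1f mV, duration %.2f ms\n",
              object@spikeAmplitudeMv, object@spikeThresholdMv,
              object@spikeDurationMs))
  cat(sprintf("  plateau %.1f mV, rest %.1f mV, sag %.3f, rebound %d\n",
              object@plateauAmplitudeMv, object@restingPotentialMv,
              object@sagRatio, object@reboundSpikes))
})

setMethod("show", "ConductanceGrid", function(object) {
  cat("ConductanceGrid (nS)\n")
  for (nm in conductanceNames())
    cat(sprintf("  %-5s [%g, %g] step %g (%d points)\n", nm,
                object@min[[nm]], object@max[[nm]], object@step[[nm]],
                .axisPoints(object)[[nm]]))
  cat(sprintf("  candidates: %s\n", format(gridSize(object), big.mark = ",")))
})

setMethod("show", "GridFit", function(object) {
  cat(sprintf("GridFit for neuron %s\n", object@neuronId))
  cat("  best: ",
      paste(sprintf("%s=%g", conductanceNames(),
                    object@conductances[conductanceNames()]), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  error %.4g; %d/%d candidates disregarded\n",
              object@error, object@disregarded, object@evaluated))
})

setMethod("show", "BirdCohort", function(object) {
  cat(sprintf("BirdCohort: %d neurons in %d birds (preset %s)\n",
              nrow(object@conductances), nrow(object@centroids),
              object@config$preset %||% "custom"))
  cat(sprintf("  traces: %s; song similarity: %s\n",
              if (length(object@traces)) "yes" else "no",
              if (nrow(object@similarity)) "yes" else "no"))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
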