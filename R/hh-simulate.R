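#' @include AllClasses.R hh-parameters.R
NULL

#' Step-current stimulus protocol
#'
#' @param amplitude step amplitude, pA (positive depolarizing).
#' @param preMs,stimMs,postMs epoch durations, ms (canonical 200/200/200).
#' @param dtMs sample interval, ms.
#' @param holdingMv holding potential, mV.
#' @return A \linkS4class{StimulusProtocol}.
#' @export
stepProtocol <- function(amplitude, preMs = 200, stimMs = 200, postMs = 200,
                         dtMs = 0.02, holdingMv = -70) {
  new("StimulusProtocol", kind = "step", amplitude = amplitude,
      preMs = preMs, stimMs = stimMs, postMs = postMs, dtMs = dtMs,
      holdingMv = holdingMv)
}

#' Canonical stimulation protocols
#'
#' The standard protocol family: 40 pA steps, depolarizing up to +200 pA and
#' hyperpolarizing down to -200 pA, plus the canonical +100 pA and -140 pA
#' fitting pulses.  Every member is a 200 ms step flanked by 200 ms of
#' quiescence.  The canonical pulses duplicate grid values on purpose so the
#' family always contains them explicitly.
#'
#' @param dtMs sample interval, ms.
#' @param holdingMv holding potential, mV.
#' @return List of 12 \linkS4class{StimulusProtocol} objects, named by
#'   amplitude; the canonical pair is named "canonical+100" and
#'   "canonical-140".
#' @export
canonicalProtocols <- function(dtMs = 0.02, holdingMv = -70) {
  amps <- c(seq(40, 200, by = 40), seq(-40, -200, by = -40))
  out <- lapply(amps, stepProtocol, dtMs = dtMs, holdingMv = holdingMv)
  names(out) <- sprintf("%+d", amps)
  out[["canonical+100"]] <- stepProtocol(100, dtMs = dtMs, holdingMv = holdingMv)
  out[["canonical-140"]] <- stepProtocol(-140, dtMs = dtMs, holdingMv = holdingMv)
  out
}

#' Chaotic current stimulus
#'
#' A complex, chaotic current waveform: the x-component of a Lorenz system
#' (sigma = 10, rho = 28, beta = 8/3), integrated alongside the trace,
#' mean-subtracted and rescaled so the peak magnitude does not exceed
#' \code{scale}.  The seed sets the Lorenz initial condition, so the waveform
#' is deterministic for a given seed.
#'
#' @param seed integer seed.
#' @param scale peak current magnitude, pA (> 0).
#' @param durationMs stimulus-epoch duration, ms.
#' @param dtMs sample interval, ms.
#' @param preMs,postMs flanking quiescence, ms.
#' @param holdingMv holding potential, mV.
#' @return A \linkS4class{StimulusProtocol} of kind "chaotic" whose
#'   \code{waveform} slot holds the stimulus-epoch current samples.
#' @export
chaoticStimulus <- function(seed, scale, durationMs = 1000, dtMs = 0.02,
                            preMs = 200, postMs = 200, holdingMv = -70) {
  stopifnot(scale > 0, durationMs > 0)
  n <- round(durationMs / dtMs)
  # ~0.04 Lorenz time units per ms gives a few excursions per 100 ms
  h <- 0.04 * dtMs
  x <- numeric(n)
  had <- exists(".Random.seed", envir = globalenv())
  if (had) saved <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  y0 <- c(stats::runif(1, -10, 10), stats::runif(1, -10, 10),
          stats::runif(1, 10, 30))
  if (had) assign(".Random.seed", saved, envir = globalenv())
  s <- 10; r <- 28; b <- 8 / 3
  lorenz <- function(y) c(s * (y[2] - y[1]),
                          y[1] * (r - y[3]) - y[2],
                          y[1] * y[2] - b * y[3])
  y <- y0
  # burn-in onto the attractor
  for (i in seq_len(500)) {
    k1 <- lorenz(y); k2 <- lorenz(y + 0.005 * k1 / 2)
    k3 <- lorenz(y + 0.005 * k2 / 2); k4 <- lorenz(y + 0.005 * k3)
    y <- y + 0.005 / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  for (i in seq_len(n)) {
    k1 <- lorenz(y); k2 <- lorenz(y + h * k1 / 2)
    k3 <- lorenz(y + h * k2 / 2); k4 <- lorenz(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    x[i] <- y[1]
  }
  x <- x - mean(x)
  x <- x * (scale / max(abs(x)))
  new("StimulusProtocol", kind = "chaotic", amplitude = scale,
      preMs = preMs, stimMs = durationMs, postMs = postMs, dtMs = dtMs,
      holdingMv = holdingMv, seed = as.integer(seed), waveform = x)
}

#' Holding equilibrium of the model
#'
#' Finds the state and constant bias current holding the model stationary at
#' a target potential: all gates at their steady-state values, the calcium
#' pool at its fixed point, and the bias equal to the total ionic current at
#' the target voltage.  The returned pair is an exact fixed point of the
#' model equations, mirroring the experimental practice of bringing every
#' cell to -70 mV before stimulation.
#'
#' @param params an HHParameters object.
#' @param targetMv target holding potential, mV; must lie in [-90, -50].
#' @param maxCurrentPa admissible bias magnitude, pA; beyond it the search
#'   fails (no physiological equilibrium).
#' @return List with \code{state} (V, h, n, b, r, Ca) and
#'   \code{holdingCurrentPa}.
#' @examples
#' eq <- holdingEquilibrium(referenceParameters(), -70)
#' eq$holdingCurrentPa
#' @export
holdingEquilibrium <- function(params, targetMv = -70, maxCurrentPa = 500) {
  stopifnot(is(params, "HHParameters"))
  if (targetMv < -90 || targetMv > -50)
    stop("holding target must lie in [-90, -50] mV")
  ss <- .hh_steady_state(.hhParVector(params), targetMv)
  if (abs(ss$current) > maxCurrentPa)
    stop(sprintf("no holding equilibrium at %g mV within +/-%g pA (needs %.1f pA)",
                 targetMv, maxCurrentPa, ss$current))
  list(state = as.numeric(ss$state), holdingCurrentPa = as.numeric(ss$current))
}

#' Natural resting potential of the model
#'
#' Root of the steady-state current-voltage relation (zero applied current),
#' found by bisection on [-90, -50] mV.
#'
#' @param params an HHParameters object.
#' @return Resting potential, mV.
#' @export
restingPotential <- function(params) {
  P <- .hhParVector(params)
  f <- function(v) .hh_steady_state(P, v)$current
  stats::uniroot(f, c(-90, -50), tol = 1e-6)$root
}

#' Simulate a current-clamp trace
#'
#' Integrates the eight-current balance equation
#' \deqn{C_m dV/dt = -(I_L + I_K + I_{Na} + I_{CaL} + I_{CaT} + I_A + I_{SK}
#' + I_h) + I_{app}}
#' with a fixed-step 4th-order Runge-Kutta scheme.  The applied current is
#' the holding bias (which keeps the cell at the protocol's holding
#' potential) plus the protocol's step or waveform during the stimulus epoch.
#' Deterministic for fixed parameters and protocol.
#'
#' @param params an HHParameters object.
#' @param protocol a StimulusProtocol.
#' @param initialState optional length-6 state (V, h, n, b, r, Ca); defaults
#'   to the holding equilibrium at the protocol's holding potential.
#' @param neuronId,birdId metadata identifiers.
#' @return A \linkS4class{VoltageTrace}.  Fails with an explicit error naming
#'   the conductance set if the integration diverges (|V| > 200 mV or a
#'   non-finite state).
#' @examples
#' tr <- simulateNeuron(referenceParameters(), stepProtocol(100))
#' range(tr@voltageMv)
#' @export
simulateNeuron <- function(params, protocol, initialState = NULL,
                           neuronId = "model", birdId = NA_character_) {
  stopifnot(is(params, "HHParameters"), is(protocol, "StimulusProtocol"))
  dt <- protocol@dtMs
  eq <- holdingEquilibrium(params, protocol@holdingMv)
  if (is.null(initialState)) initialState <- eq$state
  n <- round((protocol@preMs + protocol@stimMs + protocol@postMs) / dt) + 1L
  tms <- (seq_len(n) - 1L) * dt
  iapp <- rep(eq$holdingCurrentPa, n)
  in_stim <- tms >= protocol@preMs & tms < protocol@preMs + protocol@stimMs
  if (protocol@kind == "step") {
    iapp[in_stim] <- iapp[in_stim] + protocol@amplitude
  } else {
    wf <- protocol@waveform
    idx <- which(in_stim)
    if (length(wf) < length(idx))
      wf <- c(wf, rep(0, length(idx) - length(wf)))
    iapp[idx] <- iapp[idx] + wf[seq_along(idx)]
  }
  res <- .hh_integrate(.hhParVector(params), initialState, iapp, dt)
  if (isTRUE(res$diverged)) {
    g <- conductances(params)
    stop(sprintf(
      "integration diverged at t = %.2f ms for conductances %s",
      (res$divergedAt - 1) * dt,
      paste(sprintf("%s=%g", names(g), g), collapse = ", ")))
  }
  new("VoltageTrace", timeMs = tms, voltageMv = as.numeric(res$voltage),
      currentPa = iapp, dtMs = dt,
      metadata = list(neuron_id = neuronId, bird_id = birdId,
                      protocol = protocol, provenance = "simulated",
                      holdingCurrentPa = eq$holdingCurrentPa))
}

#' Add seeded voltage noise to a trace
#'
#' Additive white Gaussian noise on the voltage channel, emulating recording
#' noise on otherwise clean model traces.
#'
#' @param trace a VoltageTrace.
#' @param sdMv noise standard deviation, mV.
#' @param seed integer seed.
#' @return The noisy VoltageTrace (provenance annotated).
#' @export
addTraceNoise <- function(trace, sdMv, seed) {
  stopifnot(is(trace, "VoltageTrace"), sdMv >= 0)
  if (sdMv == 0) return(trace)
  noise <- local({
    set.seed(as.integer(seed))
    stats::rnorm(length(trace@voltageMv), 0, sdMv)
  })
  trace@voltageMv <- trace@voltageMv + noise
  trace@metadata$noiseSdMv <- sdMv
  trace@metadata$noiseSeed <- as.integer(seed)
  trace
}
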