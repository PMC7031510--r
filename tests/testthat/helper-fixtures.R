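# Shared fixtures, built once per test session.
#
# The reference phenotype numbers (spike count, first ISI) were recorded from
# one run of the reference parameter set and frozen here; the tests check the
# simulator still reproduces them.

refParams <- function() referenceParameters()

# reference responses at the default working dt, cached
.fixenv <- new.env()
refTrace <- function(amplitude = 100, dtMs = 0.02) {
  key <- sprintf("tr_%g_%g", amplitude, dtMs)
  if (is.null(.fixenv[[key]]))
    .fixenv[[key]] <- simulateNeuron(refParams(),
                                     stepProtocol(amplitude, dtMs = dtMs))
  .fixenv[[key]]
}

refFeatures <- function() {
  if (is.null(.fixenv$fv))
    .fixenv$fv <- extractFeatures(refTrace(100), refTrace(-140))
  .fixenv$fv
}

# frozen reference phenotype (recorded once from the reference run)
REF_SPIKES <- 7L
REF_FIRST_ISI <- 11.84

# stable mid-range centroid box used for trace-bearing synthetic cohorts
stableBox <- function() list(
  min = c(gNa = 500, gK = 150, gSK = 2, gh = 2, gCaT = 1),
  max = c(gNa = 1500, gK = 450, gSK = 8, gh = 8, gCaT = 6))

# a pure-leak parameter set (all active conductances off)
leakParams <- function(gL = 5, EL = -70) {
  p <- refParams()
  p@conductances[] <- 0
  p@conductances[["gL"]] <- gL
  p@reversals[["EL"]] <- EL
  p
}

# independent 2-cell-group spike-time null generator for the ratio test:
# groups of exactly two cells per spike count, times independent per index
nullRatioBird <- function(sigma = 0.05) {
  cells <- list()
  for (g in 2:6) for (cell in 1:2)
    cells[[length(cells) + 1]] <- (20 * seq_len(g)) * exp(rnorm(g, 0, sigma))
  cells
}
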