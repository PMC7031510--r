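#' @include AllClasses.R hh-simulate.R
NULL

#' Configuration of a synthetic cohort
#'
#' Presets encode the three study populations:
#' \describe{
#'   \item{adult}{tight per-bird clusters: centroids drawn across the
#'     species (published grid) ranges -- log-uniformly for gNa and gK,
#'     whose spans are large, uniformly for the rest -- with within-bird
#'     multiplicative fold-spreads matching the reported per-axis variation
#'     (1.23x gNa, 1.24x gK, 1.14x gSK, 1.17x gh, 1.19x gCaT).}
#'   \item{juvenile}{centroids restricted to the low-gNa/low-gSK sub-box of
#'     the adult space, inflated gh and gK spreads, a fraction of neurons
#'     with gh near zero (little/no sag, no rebound), 75 pF capacitance.}
#'   \item{cdaf}{adult-like centroids with the gSK centroid shifted low, and
#'     per-bird dispersion growing as 1 + log(motifs / 5.9), so the
#'     least-exposed bird sits near the top of the adult range.}
#' }
#' Within-bird jitter is independent per-axis multiplicative log-normal with
#' sigma = log(fold)/2 (so fold = exp(2 sigma)).
#'
#' @param preset "adult", "juvenile" or "cdaf".
#' @param nBirds,neuronsPerBird cohort dimensions.
#' @param seed mandatory integer seed; all cohort randomness flows from it.
#' @param foldSpread named per-axis within-bird fold-spread (>= 1).
#' @param centroidMin,centroidMax named per-axis centroid ranges, nS.
#' @param traceNoiseSdMv additive voltage noise on simulated traces, mV.
#' @param coupling song-feature coupling strength in [0, 1].
#' @param motifs per-bird motif counts (cdaf preset; recycled).
#' @param dispersionSlope b in the cdaf dispersion law 1 + b log(m/5.9).
#' @param ghZeroFraction juvenile fraction of neurons with gh ~ 0.
#' @param simulateTraces simulate the canonical protocol pair per neuron.
#' @param amplitudes extra step amplitudes (pA) to simulate besides the
#'   canonical +100/-140 pair.
#' @param dtMs sample interval of simulated traces, ms.
#' @return List of class "cohortConfig".
#' @export
cohortConfig <- function(preset = c("adult", "juvenile", "cdaf"),
                         nBirds = 8, neuronsPerBird = 8, seed,
                         foldSpread = NULL, centroidMin = NULL,
                         centroidMax = NULL, traceNoiseSdMv = 0.3,
                         coupling = 0.8, motifs = NULL,
                         dispersionSlope = 1, ghZeroFraction = 0.3,
                         simulateTraces = FALSE, amplitudes = numeric(0),
                         dtMs = 0.05) {
  preset <- match.arg(preset)
  if (missing(seed)) stop("a seed is mandatory for cohort generation")
  nm <- conductanceNames()
  defaults <- switch(preset,
    adult = list(
      fold = c(gNa = 1.23, gK = 1.24, gSK = 1.14, gh = 1.17, gCaT = 1.19),
      cmin = c(gNa = 200, gK = 50, gSK = 0, gh = 0, gCaT = 0),
      cmax = c(gNa = 2500, gK = 750, gSK = 15, gh = 15, gCaT = 10)),
    juvenile = list(
      fold = c(gNa = 1.8, gK = 2.8, gSK = 1.8, gh = 3.5, gCaT = 1.3),
      cmin = c(gNa = 250, gK = 100, gSK = 0.5, gh = 0.5, gCaT = 0.5),
      cmax = c(gNa = 700, gK = 600, gSK = 4, gh = 12, gCaT = 2)),
    cdaf = list(
      fold = c(gNa = 1.23, gK = 1.24, gSK = 1.14, gh = 1.17, gCaT = 1.19),
      cmin = c(gNa = 200, gK = 50, gSK = 0, gh = 0, gCaT = 0),
      cmax = c(gNa = 2500, gK = 750, gSK = 7.5, gh = 15, gCaT = 10))
  )
  fold <- (foldSpread %||% defaults$fold)[nm]
  if (any(fold < 1)) stop("fold-spread must be >= 1")
  if (traceNoiseSdMv < 0) stop("trace noise sigma must be >= 0")
  if (preset == "cdaf" && is.null(motifs))
    # exposure ladder: 4 h ... 6 days at ~35 motifs per 4 h of singing
    motifs <- c(35, 105, 105, 210, 210, 210, 315, 630)
  cfg <- list(preset = preset, nBirds = nBirds,
              neuronsPerBird = neuronsPerBird, seed = as.integer(seed),
              foldSpread = fold,
              centroidMin = (centroidMin %||% defaults$cmin)[nm],
              centroidMax = (centroidMax %||% defaults$cmax)[nm],
              traceNoiseSdMv = traceNoiseSdMv, coupling = coupling,
              motifs = motifs, dispersionSlope = dispersionSlope,
              ghZeroFraction = ghZeroFraction,
              simulateTraces = simulateTraces, amplitudes = amplitudes,
              dtMs = dtMs)
  class(cfg) <- "cohortConfig"
  cfg
}

# draw one centroid: gNa/gK log-uniform (large spans, multiplicative
# structure), the small conductances uniform
.drawCentroid <- function(cmin, cmax) {
  nm <- conductanceNames()
  out <- numeric(5); names(out) <- nm
  for (a in nm) {
    lo <- cmin[[a]]; hi <- cmax[[a]]
    out[[a]] <- if (a %in% c("gNa", "gK"))
      exp(runif(1, log(lo), log(hi)))
    else runif(1, lo, hi)
  }
  out
}

#' Generate a synthetic bird cohort
#'
#' Draws per-bird centroid conductances and per-neuron multiplicative
#' jitter according to the preset (see \code{\link{cohortConfig}}), and
#' optionally simulates the canonical current-clamp protocol pair (plus any
#' extra amplitudes) for every neuron, with additive Gaussian voltage
#' noise.  Fully reproducible from the config seed; the true centroids and
#' per-neuron conductances are retained for parameter-recovery tests.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param params base HHParameters (adult capacitance presets use these
#'   as-is; the juvenile preset switches to the juvenile capacitance).
#' @return A \linkS4class{BirdCohort}.
#' @export
generateCohort <- function(config, params = NULL) {
  stopifnot(inherits(config, "cohortConfig"))
  nm <- conductanceNames()
  if (is.null(params))
    params <- referenceParameters(
      if (config$preset == "juvenile") "juvenile" else "adult")
  set.seed(config$seed)
  nb <- config$nBirds
  npb <- config$neuronsPerBird
  sigma0 <- log(config$foldSpread) / 2
  motifs <- if (!is.null(config$motifs)) rep_len(config$motifs, nb)
  noise_seeds <- matrix(sample.int(.Machine$integer.max - 1,
                                   nb * npb * (2 + length(config$amplitudes))),
                        nrow = nb * npb)
  cen_rows <- list(); g_rows <- list()
  for (b in seq_len(nb)) {
    cen <- .drawCentroid(config$centroidMin, config$centroidMax)
    mult <- 1
    if (config$preset == "cdaf")
      mult <- 1 + config$dispersionSlope * log(motifs[b] / 5.9)
    G <- matrix(NA_real_, npb, 5, dimnames = list(NULL, nm))
    for (i in seq_len(npb)) {
      # multiplicative log-normal jitter, with the cdaf dispersion
      # multiplier applied to the linear deviation so that per-axis spread
      # (hence trace volume) scales exactly as 1 + b log(m/5.9); at
      # multiplier 1 this is plain log-normal jitter
      G[i, ] <- cen * pmax(0, 1 + mult * (exp(rnorm(5, 0, sigma0)) - 1))
      if (config$preset == "juvenile" && runif(1) < config$ghZeroFraction)
        G[i, "gh"] <- G[i, "gh"] * 0.02
    }
    bid <- sprintf("bird%02d", b)
    cen_rows[[b]] <- data.frame(bird_id = bid, t(cen),
                                stringsAsFactors = FALSE)
    g_rows[[b]] <- data.frame(
      neuron_id = sprintf("%s_n%02d", bid, seq_len(npb)),
      bird_id = bid, G, stringsAsFactors = FALSE)
  }
  centroids <- do.call(rbind, cen_rows)
  if (!is.null(motifs)) centroids$motifs <- motifs
  conduct <- do.call(rbind, g_rows)
  rownames(centroids) <- rownames(conduct) <- NULL

  traces <- list()
  if (config$simulateTraces) {
    amps <- c(100, -140, config$amplitudes)
    labels <- sprintf("%+d", amps)
    for (r in seq_len(nrow(conduct))) {
      g <- stats::setNames(as.numeric(conduct[r, nm]), nm)
      pc <- withConductances(params, g)
      tl <- list()
      for (k in seq_along(amps)) {
        tr <- tryCatch(
          simulateNeuron(pc, stepProtocol(amps[k], dtMs = config$dtMs),
                         neuronId = conduct$neuron_id[r],
                         birdId = conduct$bird_id[r]),
          error = function(e) stop(sprintf(
            "cohort generation failed for %s (%s): %s",
            conduct$bird_id[r], conduct$neuron_id[r], conditionMessage(e)),
            call. = FALSE))
        if (config$traceNoiseSdMv > 0)
          tr <- addTraceNoise(tr, config$traceNoiseSdMv, noise_seeds[r, k])
        tr@metadata$provenance <- "synthetic-cohort"
        tl[[labels[k]]] <- tr
      }
      traces[[conduct$neuron_id[r]]] <- tl
    }
  }
  new("BirdCohort", conductances = conduct, centroids = centroids,
      traces = traces, similarity = matrix(numeric(0), 0, 0),
      config = unclass(config))
}

#' Synthetic song-similarity matrix coupled to conductance distances
#'
#' Embeds the pairwise Euclidean distances between bird conductance
#' centroids into a percent-like similarity score: pairwise distances are
#' perturbed with seeded Gaussian noise scaled by (1 - coupling) and mapped
#' through a strictly decreasing affine transform onto (0, 100].  At
#' coupling = 1 the similarity is an exact decreasing linear function of
#' centroid distance; at coupling = 0 it is unrelated to it.
#'
#' @param cohort a BirdCohort with at least 3 birds.
#' @param coupling coupling strength in [0, 1].
#' @param seed integer seed for the perturbation.
#' @param noiseScale noise magnitude at coupling = 0, in units of the
#'   distance standard deviation (default 5, giving a correlation near -0.7
#'   at coupling 0.8).
#' @return Symmetric bird-by-bird similarity matrix, diagonal 100.
#' @export
generateSongFeatures <- function(cohort, coupling = 0.8, seed = 1,
                                 noiseScale = 5) {
  stopifnot(is(cohort, "BirdCohort"), coupling >= 0, coupling <= 1)
  nb <- nrow(cohort@centroids)
  if (nb < 3) stop("song-feature generation needs at least 3 birds")
  D <- conductanceDistances(cohort, type = "euclidean")
  lw <- lower.tri(D)
  set.seed(as.integer(seed))
  eps <- matrix(0, nb, nb)
  eps[lw] <- rnorm(sum(lw), 0, (1 - coupling) * noiseScale * sd(D[lw]))
  eps <- eps + t(eps)
  Dn <- D + eps
  rng <- range(Dn[lw])
  if (diff(rng) <= 0) {
    S <- matrix(100, nb, nb)
  } else {
    S <- 100 - 90 * (Dn - rng[1]) / (rng[2] - rng[1])
  }
  diag(S) <- 100
  dimnames(S) <- dimnames(D)
  S
}

#' Generate a sibling pair of birds
#'
#' Two birds drawn around a single shared centroid with within-bird
#' (adult) spread, mimicking adult siblings raised on the same song.
#'
#' @param config a \code{\link{cohortConfig}} giving spreads/ranges (adult
#'   preset recommended).
#' @param seed integer seed.
#' @return A \linkS4class{BirdCohort} with two birds ("sibA", "sibB")
#'   sharing one centroid.
#' @export
siblingPair <- function(config, seed) {
  stopifnot(inherits(config, "cohortConfig"))
  nm <- conductanceNames()
  set.seed(as.integer(seed))
  cen <- .drawCentroid(config$centroidMin, config$centroidMax)
  sigma <- log(config$foldSpread) / 2
  npb <- config$neuronsPerBird
  rows <- list()
  for (b in c("sibA", "sibB")) {
    G <- matrix(NA_real_, npb, 5, dimnames = list(NULL, nm))
    for (i in seq_len(npb)) G[i, ] <- cen * exp(rnorm(5, 0, sigma))
    rows[[b]] <- data.frame(neuron_id = sprintf("%s_n%02d", b, seq_len(npb)),
                            bird_id = b, G, stringsAsFactors = FALSE)
  }
  conduct <- do.call(rbind, rows)
  rownames(conduct) <- NULL
  centroids <- data.frame(bird_id = c("sibA", "sibB"),
                          rbind(cen, cen), stringsAsFactors = FALSE)
  rownames(centroids) <- NULL
  new("BirdCohort", conductances = conduct, centroids = centroids,
      config = unclass(config))
}

#' Within-bird fold-spread of a cohort
#'
#' Measured as exp(2 * sd(log g)) per bird and axis (the convention the
#' generator inverts), averaged over birds.
#'
#' @param cohort a BirdCohort or conductance table.
#' @return Named numeric vector of mean per-axis fold-spreads.
#' @export
withinBirdFold <- function(cohort) {
  tab <- if (is(cohort, "BirdCohort")) cohort@conductances else cohort
  nm <- conductanceNames()
  birds <- unique(tab$bird_id)
  folds <- vapply(birds, function(b) {
    G <- as.matrix(tab[tab$bird_id == b, nm])
    vapply(nm, function(a) {
      g <- G[, a]
      if (any(g <= 0)) return(NA_real_)
      exp(2 * sd(log(g)))
    }, numeric(1))
  }, numeric(5))
  rowMeans(folds, na.rm = TRUE)
}
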