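#' @include AllClasses.R
NULL

#' Same-bird versus across-bird clustering distance test
#'
#' For each neuron in each bird with more than 2 neurons, computes the
#' distance (in a 2-D feature space, e.g. spike amplitude vs spike
#' threshold) to one randomly chosen other neuron of the same bird and to
#' one randomly chosen neuron of another bird, then compares the two
#' distance samples with a two-tailed t-test on the per-neuron differences
#' (each focal neuron contributes one same-bird and one across-bird
#' distance, so the natural test is on the N paired differences, with
#' N - 1 degrees of freedom).  Clustered data give same-bird distances
#' systematically smaller than across-bird distances.
#'
#' @param points data.frame with columns bird_id and two numeric feature
#'   columns (the first two non-bird columns are used).
#' @param seed seed for the random partner choices.
#' @param minNeurons only birds with more than this many neurons contribute
#'   focal neurons (default 2, i.e. N > 2).
#' @return List: t, df, p, mean_same, mean_across, n; \code{degenerate} is
#'   TRUE (with p = NA) when all distances are equal so the test statistic
#'   is undefined.
#' @export
clusteringDistanceTest <- function(points, seed = 1, minNeurons = 2) {
  stopifnot("bird_id" %in% names(points))
  fc <- setdiff(names(points), c("bird_id", "neuron_id"))[1:2]
  X <- as.matrix(points[, fc])
  birds <- as.character(points$bird_id)
  counts <- table(birds)
  if (sum(counts > minNeurons) < 2)
    stop("need at least 2 birds with more than ", minNeurons, " neurons")
  set.seed(as.integer(seed))
  same <- c(); across <- c()
  for (i in seq_len(nrow(X))) {
    b <- birds[i]
    if (counts[[b]] <= minNeurons) next
    mates <- which(birds == b); mates <- mates[mates != i]
    others <- which(birds != b)
    if (!length(mates) || !length(others)) next
    j <- if (length(mates) == 1) mates else sample(mates, 1)
    k <- if (length(others) == 1) others else sample(others, 1)
    same <- c(same, sqrt(sum((X[i, ] - X[j, ])^2)))
    across <- c(across, sqrt(sum((X[i, ] - X[k, ])^2)))
  }
  if (sd(c(same, across)) == 0 || sd(same - across) == 0)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                mean_same = mean(same), mean_across = mean(across),
                n = length(same), degenerate = TRUE))
  tt <- t.test(same - across)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_same = mean(same), mean_across = mean(across),
       n = length(same), degenerate = FALSE)
}

#' Accumulate pairwise spike-time ratios within one bird
#'
#' Cells are grouped by the number of spikes emitted; groups with a single
#' cell are discarded.  Within each remaining group, all pairwise ratios of
#' spike times (relative to stimulus onset) are computed -- first spikes
#' against each other, second spikes against each other, and so on -- and
#' accumulated across groups.
#'
#' @param spikeTimes list of per-cell numeric spike-time vectors (ms,
#'   relative to pulse onset).
#' @return Numeric vector of accumulated ratios (possibly empty).
#' @export
spikeTimeRatios <- function(spikeTimes) {
  counts <- vapply(spikeTimes, length, integer(1))
  out <- c()
  for (k in unique(counts[counts > 0])) {
    cells <- spikeTimes[counts == k]
    if (length(cells) < 2) next
    prs <- utils::combn(length(cells), 2)
    for (c2 in seq_len(ncol(prs))) {
      a <- cells[[prs[1, c2]]]; b <- cells[[prs[2, c2]]]
      out <- c(out, a / b)
    }
  }
  out
}

#' Spike-train timing variability: F tests between birds
#'
#' Accumulates the spike-time ratio distribution of every bird in each
#' cohort (\code{\link{spikeTimeRatios}}), then compares each bird of cohort
#' A against each bird of cohort B with a two-sample F test of variances.
#' More variable spike timing (e.g. juveniles) gives larger ratio variance.
#'
#' @param cohortA,cohortB named lists (by bird) of per-cell spike-time
#'   lists.
#' @return data.frame: birdA, birdB, F, df1, df2, p, varA, varB, testable.
#'   Birds without any ratio group (no spike-count group with >= 2 cells)
#'   are flagged untestable.
#' @export
spikeTimeRatioTest <- function(cohortA, cohortB) {
  rA <- lapply(cohortA, spikeTimeRatios)
  rB <- lapply(cohortB, spikeTimeRatios)
  rows <- list()
  for (a in names(rA) %||% seq_along(rA)) for (b in names(rB) %||% seq_along(rB)) {
    x <- rA[[a]]; y <- rB[[b]]
    if (length(x) < 2 || length(y) < 2) {
      rows[[length(rows) + 1]] <- data.frame(
        birdA = a, birdB = b, F = NA, df1 = NA, df2 = NA, p = NA,
        varA = NA, varB = NA, testable = FALSE)
      next
    }
    vt <- var.test(x, y)
    rows[[length(rows) + 1]] <- data.frame(
      birdA = a, birdB = b, F = unname(vt$statistic),
      df1 = unname(vt$parameter[1]), df2 = unname(vt$parameter[2]),
      p = vt$p.value, varA = var(x), varB = var(y), testable = TRUE)
  }
  do.call(rbind, rows)
}

#' Pairwise mean-squared differences between first-spike waveforms
#'
#' For every waveform of set A and every waveform of set B (peak-aligned
#' snippets of equal length), the mean squared voltage difference.
#'
#' @param A,B numeric matrices, one waveform per row, equal column counts.
#' @return Numeric vector of length nrow(A) * nrow(B).
#' @export
waveformMsd <- function(A, B) {
  A <- rbind(A); B <- rbind(B)
  if (ncol(A) != ncol(B))
    stop("waveform snippets must have equal length (same window and dt)")
  out <- numeric(nrow(A) * nrow(B))
  k <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    k <- k + 1
    out[k] <- mean((A[i, ] - B[j, ])^2)
  }
  out
}

#' Two-sample variance-ratio (F) test
#'
#' Thin, explicit wrapper used by the waveform and spike-timing variability
#' comparisons; two-tailed.
#'
#' @param x,y numeric samples.
#' @return List: F, df1, df2, p.
#' @export
varianceRatioTest <- function(x, y) {
  vt <- var.test(x, y)
  list(F = unname(vt$statistic), df1 = unname(vt$parameter[1]),
       df2 = unname(vt$parameter[2]), p = vt$p.value)
}

#' Waveform variability comparison between two groups
#'
#' Computes the distribution of pairwise first-spike mean-squared
#' differences within each group -- each group is a pair of waveform sets
#' (e.g. the two birds of a sibling pair), or a single set compared with
#' itself (all unordered pairs) -- and compares the two distributions with a
#' two-sample F test.  Used for juvenile-vs-adult sibling comparisons and
#' for the delayed-auditory-feedback analysis (pooled normal-adult pairs vs
#' a manipulated bird).
#'
#' @param groupA,groupB either a list of two waveform matrices (MSDs taken
#'   across the pair) or a single matrix (MSDs over all unordered pairs
#'   within it).
#' @return List: F, df1, df2, p, msdA, msdB.
#' @export
waveformMseTest <- function(groupA, groupB) {
  msd_of <- function(g) {
    if (is.list(g) && !is.data.frame(g)) {
      stopifnot(length(g) == 2)
      waveformMsd(g[[1]], g[[2]])
    } else {
      g <- rbind(g)
      n <- nrow(g)
      stopifnot(n >= 2)
      prs <- utils::combn(n, 2)
      vapply(seq_len(ncol(prs)), function(k)
        mean((g[prs[1, k], ] - g[prs[2, k], ])^2), numeric(1))
    }
  }
  x <- msd_of(groupA); y <- msd_of(groupB)
  c(varianceRatioTest(x, y), list(msdA = x, msdB = y))
}

#' Rundown check on first-spike amplitudes
#'
#' Within each bird, cells are ordered by recording time; the ratios of
#' first-spike amplitude (each later cell / first cell) and (last cell /
#' first cell) are accumulated across birds and tested against a mean of
#' 1.0 with two-tailed t-tests.  Stable recordings give ratios
#' indistinguishable from 1.
#'
#' @param amplitudes data.frame with columns bird_id, order (within-bird
#'   recording order) and amplitude (first-spike amplitude, mV).
#' @return List: \code{later} and \code{last}, each with ratios, mean, t,
#'   df, p (t = 0 and p = 1 when all ratios are exactly 1).
#' @export
rundownCheck <- function(amplitudes) {
  stopifnot(all(c("bird_id", "order", "amplitude") %in% names(amplitudes)))
  later <- c(); last <- c()
  for (b in unique(amplitudes$bird_id)) {
    sub <- amplitudes[amplitudes$bird_id == b, ]
    sub <- sub[order(sub$order), ]
    if (nrow(sub) < 2) next
    first <- sub$amplitude[1]
    later <- c(later, sub$amplitude[-1] / first)
    last <- c(last, sub$amplitude[nrow(sub)] / first)
  }
  test1 <- function(r) {
    if (length(r) < 2 || sd(r) == 0) {
      # constant ratios: exactly 1 is a null result; constant != 1 is a
      # deterministic departure
      dev <- length(r) && any(r != 1)
      return(list(ratios = r, mean = mean(r),
                  t = if (dev) sign(mean(r) - 1) * Inf else 0,
                  df = length(r) - 1, p = if (dev) 0 else 1))
    }
    tt <- t.test(r, mu = 1)
    list(ratios = r, mean = mean(r), t = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value)
  }
  list(later = test1(later), last = test1(last))
}
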