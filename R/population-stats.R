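#' @include AllClasses.R
NULL

# n x 5 conductance matrix of one bird from a cohort-style table
.birdMatrix <- function(x, bird = NULL) {
  if (is(x, "BirdCohort")) x <- x@conductances
  if (is.data.frame(x)) {
    if (!is.null(bird)) x <- x[x$bird_id == bird, , drop = FALSE]
    x <- as.matrix(x[, conductanceNames(), drop = FALSE])
  }
  stopifnot(is.matrix(x))
  x
}

#' Trace volume of a bird's conductance cloud
#'
#' Dispersion of the N neurons of one bird in 5-D conductance space:
#' \deqn{V(B) = \sqrt{ \frac{1}{N-1} \sum_{i=1}^N \| g^i - \bar g \|^2 }}
#' the square root of the summed squared deviations from the per-axis means,
#' normalized by N - 1.  Equivalently the square root of the trace (sum of
#' eigenvalues) of the sample covariance of the conductance matrix -- a
#' dispersion measure that stays well defined when neurons are few.  Units
#' nS.
#'
#' @param x an n-by-5 conductance matrix, a cohort conductance table, or a
#'   BirdCohort (then \code{bird} selects the bird).
#' @param bird bird id when \code{x} is a cohort/table.
#' @return V(B), nS.
#' @export
traceVolume <- function(x, bird = NULL) {
  G <- .birdMatrix(x, bird)
  n <- nrow(G)
  if (n < 2) stop("trace volume is undefined for a single neuron (N = 1)")
  dev <- sweep(G, 2, colMeans(G))
  sqrt(sum(dev^2) / (n - 1))
}

#' Geometric (hyperellipsoid) volume of a bird's conductance cloud
#'
#' Square root of the determinant of the sample covariance matrix (the
#' product of its eigenvalues), so the measure scales as a length^5
#' hyperellipsoid volume.  Rank-deficient clouds (fewer than 6 neurons, or
#' degenerate geometry) return 0 with a degeneracy flag: with few
#' observations relative to the 5 dimensions the determinant collapses and
#' is not biologically informative (use \code{\link{traceVolume}} then).
#'
#' @inheritParams traceVolume
#' @return Volume (nS^5) with attribute \code{degenerate} (logical).
#' @export
geometricVolume <- function(x, bird = NULL) {
  G <- .birdMatrix(x, bird)
  n <- nrow(G)
  if (n < 2) stop("geometric volume is undefined for a single neuron (N = 1)")
  S <- cov(G)
  d <- det(S)
  degenerate <- n <= ncol(G) || d <= .Machine$double.eps * max(diag(S))^5
  v <- if (degenerate) 0 else sqrt(d)
  attr(v, "degenerate") <- degenerate
  v
}

#' Normalized per-bird volumes
#'
#' Per-bird trace and geometric volumes, each divided by the corresponding
#' "species" volume computed from a reference set (all neurons of the
#' supplied non-manipulated reference cohort pooled).  The species volume is
#' always computed from the supplied reference, never hard-coded.
#'
#' @param cohort a BirdCohort or conductance table.
#' @param reference the reference (species) conductance table; defaults to
#'   the cohort itself pooled.
#' @return data.frame: bird_id, n_neurons, trace_volume, geometric_volume,
#'   trace_volume_norm, geometric_volume_norm, degenerate.
#' @export
birdVolumes <- function(cohort, reference = cohort) {
  tab <- if (is(cohort, "BirdCohort")) cohort@conductances else cohort
  ref <- if (is(reference, "BirdCohort")) reference@conductances else reference
  vs_t <- traceVolume(.birdMatrix(ref))
  vs_g <- as.numeric(geometricVolume(.birdMatrix(ref)))
  birds <- unique(tab$bird_id)
  rows <- lapply(birds, function(b) {
    G <- .birdMatrix(tab, b)
    vt <- traceVolume(G)
    vg <- geometricVolume(G)
    data.frame(bird_id = b, n_neurons = nrow(G),
               trace_volume = vt, geometric_volume = as.numeric(vg),
               trace_volume_norm = vt / vs_t,
               geometric_volume_norm = if (vs_g > 0) as.numeric(vg) / vs_g
                                       else NA_real_,
               degenerate = attr(vg, "degenerate"))
  })
  do.call(rbind, rows)
}

#' Mahalanobis distance between two birds' conductance clouds
#'
#' \deqn{D = \sqrt{ x P^{-1} x' }, \quad x = \mu(G_1) - \mu(G_2)}
#' with P the pooled covariance of the two birds' centered conductance
#' matrices.  Unitless and invariant under any common invertible linear
#' transform of both matrices.  A singular pooled covariance fails unless
#' \code{pseudoInverse = TRUE}, in which case the Moore-Penrose inverse is
#' used and the result flagged.
#'
#' @param G1,G2 n-by-5 conductance matrices (or tables with the conductance
#'   columns).
#' @param pseudoInverse allow a pseudo-inverse for singular pooled
#'   covariance.
#' @return D >= 0, with attribute \code{pseudoInverse} when used.
#' @export
mahalanobisDistance <- function(G1, G2, pseudoInverse = FALSE) {
  G1 <- .birdMatrix(G1); G2 <- .birdMatrix(G2)
  stopifnot(ncol(G1) == ncol(G2))
  n1 <- nrow(G1); n2 <- nrow(G2)
  x <- colMeans(G1) - colMeans(G2)
  P <- ((n1 - 1) * cov(G1) + (n2 - 1) * cov(G2)) / (n1 + n2 - 2)
  Pinv <- tryCatch(solve(P), error = function(e) NULL)
  used_pseudo <- FALSE
  if (is.null(Pinv)) {
    if (!pseudoInverse)
      stop("pooled covariance is singular; set pseudoInverse = TRUE to use the Moore-Penrose inverse")
    s <- svd(P)
    pos <- s$d > max(s$d) * 1e-12
    Pinv <- s$v[, pos, drop = FALSE] %*% diag(1 / s$d[pos], sum(pos)) %*%
      t(s$u[, pos, drop = FALSE])
    used_pseudo <- TRUE
  }
  D <- sqrt(max(0, drop(t(x) %*% Pinv %*% x)))
  if (used_pseudo) attr(D, "pseudoInverse") <- TRUE
  D
}

#' Pairwise centroid distances between birds
#'
#' Euclidean distances between per-bird conductance centroids, or pairwise
#' Mahalanobis distances between the birds' clouds.  A conductance can be
#' excluded (leave-one-conductance-out variant).
#'
#' @param cohort BirdCohort or conductance table.
#' @param type "euclidean" (centroid distance) or "mahalanobis".
#' @param exclude optional conductance name to drop before computing.
#' @param pseudoInverse passed to \code{\link{mahalanobisDistance}}.
#' @return Symmetric bird-by-bird distance matrix.
#' @export
conductanceDistances <- function(cohort, type = c("euclidean", "mahalanobis"),
                                 exclude = NULL, pseudoInverse = TRUE) {
  type <- match.arg(type)
  tab <- if (is(cohort, "BirdCohort")) cohort@conductances else cohort
  nm <- setdiff(conductanceNames(), exclude)
  birds <- unique(tab$bird_id)
  nb <- length(birds)
  M <- matrix(0, nb, nb, dimnames = list(birds, birds))
  mats <- lapply(birds, function(b)
    as.matrix(tab[tab$bird_id == b, nm, drop = FALSE]))
  if (type == "euclidean") {
    cen <- t(vapply(mats, colMeans, numeric(length(nm))))
    M[] <- as.matrix(dist(cen))
  } else {
    for (i in seq_len(nb - 1)) for (j in (i + 1):nb) {
      d <- mahalanobisDistance(mats[[i]], mats[[j]],
                               pseudoInverse = pseudoInverse)
      M[i, j] <- M[j, i] <- as.numeric(d)
    }
  }
  M
}

#' MANOVA across birds with Wilks' lambda
#'
#' One-way MANOVA of per-neuron covariates on bird identity, using the
#' decomposition T = B + W of the total sum of squares and products into
#' between-bird and within-bird parts, and the test statistic
#' \deqn{\Lambda = |W| / |W + B|}
#' (small values reject equality of the bird mean vectors).  The p-value
#' uses Rao's F approximation; an exact seeded permutation p-value is
#' available for small cohorts.  In pairwise mode every bird pair is tested
#' and Bonferroni-corrected over the number of testable pairs (pairs where
#' either bird has fewer neurons than covariates, making W singular, are
#' flagged untestable).
#'
#' The canonical covariate set is spiking frequency and the first three
#' ISIs; use \code{\link{manovaCovariates}} to build it from a features
#' table (cells with fewer than four spikes are removed).
#'
#' @param covariates numeric matrix or data.frame of per-neuron covariates.
#' @param birds factor/character vector of bird labels, one per row.
#' @param permutations if > 0, also compute a permutation p-value with this
#'   many seeded shuffles.
#' @param seed seed for the permutation p-value.
#' @return List of class "hvcxManova": lambda, F, df1, df2, p, n_birds,
#'   n_covariates, and optionally p_perm.
#' @export
birdManova <- function(covariates, birds, permutations = 0, seed = 1) {
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  birds <- as.character(birds)
  stopifnot(nrow(X) == length(birds))
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  birds <- birds[keep]
  g <- length(unique(birds))
  if (g < 2) stop("MANOVA needs at least 2 birds")
  res <- .wilks(X, birds)
  out <- c(res, list(n_birds = g, n_covariates = ncol(X), n = nrow(X)))
  if (permutations > 0) {
    set.seed(as.integer(seed))
    obs <- res$lambda
    cnt <- 0L
    for (r in seq_len(permutations)) {
      lam <- .wilks(X, sample(birds))$lambda
      if (lam <= obs) cnt <- cnt + 1L
    }
    out$p_perm <- (cnt + 1) / (permutations + 1)
  }
  class(out) <- "hvcxManova"
  out
}

# Wilks' lambda + Rao's F approximation for one-way MANOVA
.wilks <- function(X, birds) {
  n <- nrow(X); p <- ncol(X)
  lev <- unique(birds)
  g <- length(lev)
  xbar <- colMeans(X)
  W <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (b in lev) {
    Xb <- X[birds == b, , drop = FALSE]
    nb <- nrow(Xb)
    mb <- colMeans(Xb)
    dev <- sweep(Xb, 2, mb)
    W <- W + crossprod(dev)
    B <- B + nb * tcrossprod(mb - xbar)
  }
  detW <- det(W)
  detT <- det(W + B)
  if (detT <= 0 || !is.finite(detW / detT))
    stop("total SSP matrix is singular; too few neurons for these covariates")
  lambda <- max(min(detW / detT, 1), 0)
  nu_h <- g - 1
  nu_e <- n - g
  tden <- p^2 + nu_h^2 - 5
  tt <- if (tden > 0) sqrt((p^2 * nu_h^2 - 4) / tden) else 1
  df1 <- p * nu_h
  df2 <- tt * (nu_e - (p - nu_h + 1) / 2) - (df1 - 2) / 2
  lam_t <- lambda^(1 / tt)
  Fstat <- ((1 - lam_t) / lam_t) * (df2 / df1)
  pval <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  list(lambda = lambda, F = Fstat, df1 = df1, df2 = df2, p = pval)
}

#' @export
print.hvcxManova <- function(x, ...) {
  cat(sprintf("MANOVA (Wilks): lambda = %.4g, F(%g, %.1f) = %.3g, p = %.3g\n",
              x$lambda, x$df1, x$df2, x$F, x$p))
  if (!is.null(x$p_perm)) cat(sprintf("  permutation p = %.4g\n", x$p_perm))
  invisible(x)
}

#' Pairwise bird MANOVAs with Bonferroni correction
#'
#' @inheritParams birdManova
#' @param alpha family-wise level.
#' @return List: \code{pairs} data.frame (bird1, bird2, lambda, F, p,
#'   p_bonferroni, significant, testable), \code{m_testable} and
#'   \code{m_nominal} (the Bonferroni multipliers actually used and C(n,2)),
#'   \code{n_rejected}.
#' @export
pairwiseManova <- function(covariates, birds, alpha = 0.05) {
  X <- as.matrix(covariates)
  birds <- as.character(birds)
  lev <- unique(birds)
  prs <- utils::combn(lev, 2)
  p_cov <- ncol(X)
  rows <- lapply(seq_len(ncol(prs)), function(k) {
    b1 <- prs[1, k]; b2 <- prs[2, k]
    idx <- birds %in% c(b1, b2)
    n1 <- sum(birds == b1); n2 <- sum(birds == b2)
    if (min(n1, n2) <= p_cov)   # W singular or df exhausted
      return(data.frame(bird1 = b1, bird2 = b2, lambda = NA, F = NA, p = NA,
                        testable = FALSE))
    res <- .wilks(X[idx, , drop = FALSE], birds[idx])
    data.frame(bird1 = b1, bird2 = b2, lambda = res$lambda, F = res$F,
               p = res$p, testable = TRUE)
  })
  tab <- do.call(rbind, rows)
  m <- sum(tab$testable)
  tab$p_bonferroni <- pmin(tab$p * m, 1)
  tab$significant <- !is.na(tab$p_bonferroni) & tab$p_bonferroni < alpha
  list(pairs = tab, m_testable = m, m_nominal = ncol(prs),
       n_rejected = sum(tab$significant))
}

#' Build the canonical MANOVA covariates from a features table
#'
#' Spiking frequency and the first three ISIs; cells with fewer than four
#' spikes (hence without a third ISI) are removed, exactly as in the
#' analysis this reproduces.
#'
#' @param features data.frame from \code{\link{featuresTable}}.
#' @return List with \code{covariates} (matrix) and \code{birds}.
#' @export
manovaCovariates <- function(features) {
  keep <- !is.na(features$isi3_ms) & features$n_spikes >= 4
  f <- features[keep, ]
  list(covariates = as.matrix(f[, c("spike_rate_hz", "isi1_ms", "isi2_ms",
                                    "isi3_ms")]),
       birds = as.character(f$bird_id))
}

#' Variance-explained shares of a principal components analysis
#'
#' Ordered fractions of variance explained, summing to 1.  Columns are
#' standardized by default (zero-variance columns dropped with a warning).
#'
#' @param x numeric matrix (neurons x covariates).
#' @param standardize scale columns to unit variance first.
#' @return Numeric vector of variance shares, one per retained component.
#' @export
pcaSummary <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 2, nrow(x) >= 3)
  v <- apply(x, 2, var)
  if (any(v == 0)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(x)[v == 0], collapse = ", "))
    x <- x[, v > 0, drop = FALSE]
  }
  pc <- prcomp(x, center = TRUE, scale. = standardize)
  pc$sdev^2 / sum(pc$sdev^2)
}

#' Regression of per-bird volumes on a covariate
#'
#' Ordinary least squares of volume on a covariate (e.g. age) or on its
#' logarithm (e.g. number of motifs sung), with the correlation coefficient
#' and the slope t-test p-value.
#'
#' @param volumes numeric per-bird volumes.
#' @param covariate numeric per-bird covariate.
#' @param model "linear" or "log" (regress on log(covariate)).
#' @return List: slope, intercept, R, p, n.
#' @export
volumeVsCovariate <- function(volumes, covariate, model = c("linear", "log")) {
  model <- match.arg(model)
  stopifnot(length(volumes) == length(covariate), length(volumes) >= 4)
  x <- if (model == "log") {
    stopifnot(all(covariate > 0))
    log(covariate)
  } else covariate
  fit <- lm(volumes ~ x)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       R = unname(sign(coef(fit)[2]) * sqrt(sm$r.squared)),
       p = unname(sm$coefficients[2, 4]), n = length(volumes))
}

#' Correlation between song similarity and conductance distance
#'
#' Linear regression of pairwise song-similarity scores on pairwise
#' conductance-space distances, over the non-identity lower-triangle entries
#' (pooled mode), or per bird over that bird's pair entries.  The p-value is
#' the t-test on the regression slope.
#'
#' @param similarity symmetric bird-by-bird similarity matrix.
#' @param distances symmetric bird-by-bird distance matrix (same ordering;
#'   see \code{\link{conductanceDistances}}).
#' @param mode "pooled", "per-bird" or "both".
#' @param tol asymmetry tolerance.
#' @return List: \code{pooled} (R, p, n), and with per-bird mode a
#'   data.frame \code{perBird} (bird_id, R, p, n).
#' @export
similarityDistanceCorrelation <- function(similarity, distances,
                                          mode = c("pooled", "per-bird", "both"),
                                          tol = 1e-8) {
  mode <- match.arg(mode)
  stopifnot(all(dim(similarity) == dim(distances)))
  if (max(abs(similarity - t(similarity))) > tol ||
      max(abs(distances - t(distances))) > tol)
    stop("similarity and distance matrices must be symmetric")
  nb <- nrow(similarity)
  lower <- lower.tri(similarity)
  cor1 <- function(s, d) {
    fit <- summary(lm(s ~ d))
    list(R = unname(sign(coef(lm(s ~ d))[2]) * sqrt(fit$r.squared)),
         p = unname(fit$coefficients[2, 4]), n = length(s))
  }
  out <- list()
  if (mode %in% c("pooled", "both"))
    out$pooled <- cor1(similarity[lower], distances[lower])
  if (mode %in% c("per-bird", "both")) {
    ids <- rownames(similarity) %||% as.character(seq_len(nb))
    rows <- lapply(seq_len(nb), function(i) {
      s <- similarity[i, -i]; d <- distances[i, -i]
      r <- cor1(s, d)
      data.frame(bird_id = ids[i], R = r$R, p = r$p, n = r$n)
    })
    out$perBird <- do.call(rbind, rows)
  }
  if (mode == "pooled") out$pooled else out
}
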