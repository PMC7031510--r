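# Volumes, Mahalanobis distance, MANOVA, PCA, regressions.

randCloud <- function(n, scales = c(1, 2, 3, 4, 5), seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 5), n, 5) %*% diag(scales)
  colnames(X) <- conductanceNames()
  X
}

test_that("trace volume matches its defining formula and identities", {
  # identical neurons -> 0
  G0 <- matrix(rep(c(800, 200, 4, 3, 2), each = 4), 4, 5,
               dimnames = list(NULL, conductanceNames()))
  expect_equal(traceVolume(G0), 0)
  # two neurons differing only in gNa by d -> d/sqrt(2)
  G2 <- G0[1:2, ]; G2[2, "gNa"] <- G2[2, "gNa"] + 37
  expect_equal(traceVolume(G2), 37 / sqrt(2))
  # V(B)^2 equals the trace of the (N-1)-normalized covariance
  X <- randCloud(40)
  expect_equal(traceVolume(X)^2, sum(diag(cov(X))), tolerance = 1e-12)
  # translation invariance; linear scaling
  expect_equal(traceVolume(sweep(X, 2, c(100, 50, 1, 2, 3), "+")),
               traceVolume(X))
  expect_equal(traceVolume(X * 7), 7 * traceVolume(X))
  expect_error(traceVolume(X[1, , drop = FALSE]), "single neuron")
})

test_that("geometric volume is the covariance-determinant hyperellipsoid measure", {
  # rank deficiency: n <= 5 -> 0 with degeneracy flag
  v4 <- geometricVolume(randCloud(4))
  expect_identical(as.numeric(v4), 0)
  expect_true(attr(v4, "degenerate"))
  # axis-aligned cloud: volume ~ product of per-axis SDs
  X <- randCloud(4000, scales = c(1, 2, 3, 4, 5), seed = 3)
  sds <- apply(X, 2, sd)
  expect_equal(as.numeric(geometricVolume(X)), prod(sds), tolerance = 0.05)
  # 5th-power scaling and translation invariance
  expect_equal(as.numeric(geometricVolume(X * 2)),
               2^5 * as.numeric(geometricVolume(X)))
  expect_equal(as.numeric(geometricVolume(sweep(X, 2, 1:5, "+"))),
               as.numeric(geometricVolume(X)))
})

test_that("a cloud occupying 0.1 of each axis has normalized volume 1e-5", {
  X <- randCloud(60, seed = 5)
  shrunk <- X * 0.1
  expect_equal(as.numeric(geometricVolume(shrunk)) /
               as.numeric(geometricVolume(X)), 1e-5, tolerance = 1e-12)
})

test_that("Mahalanobis distance: identity, 1-D reduction, scale invariance", {
  X <- randCloud(30, seed = 7)
  expect_equal(as.numeric(mahalanobisDistance(X, X)), 0)
  # 1-D reduction: centroids differing by delta over pooled sd s -> delta/s
  set.seed(8)
  a <- rnorm(50); b <- rnorm(50) + 3
  A <- cbind(gNa = a, gK = 0 * a + 1, gSK = 1, gh = 1, gCaT = 1)
  B <- cbind(gNa = b, gK = 0 * b + 1, gSK = 1, gh = 1, gCaT = 1)
  # only gNa varies; drop constant axes via a 1-column matrix
  d <- mahalanobisDistance(cbind(a), cbind(b))
  s <- sqrt((49 * var(a) + 49 * var(b)) / 98)
  expect_equal(as.numeric(d), abs(mean(a) - mean(b)) / s, tolerance = 1e-12)
  # multiplying every conductance of both birds by 10 leaves D unchanged
  Y <- sweep(X, 2, c(5, 4, 3, 2, 1), "+")
  expect_equal(as.numeric(mahalanobisDistance(X, Y)),
               as.numeric(mahalanobisDistance(X * 10, Y * 10)),
               tolerance = 1e-9)
  # general linear invariance
  set.seed(9); M <- matrix(rnorm(25), 5, 5)
  expect_equal(as.numeric(mahalanobisDistance(X %*% M, Y %*% M)),
               as.numeric(mahalanobisDistance(X, Y)), tolerance = 1e-6)
})

test_that("Wilks' lambda MANOVA matches the classical references", {
  # equal group means by construction -> lambda = 1
  set.seed(10)
  X0 <- matrix(rnorm(60), 20, 3)
  m0 <- birdManova(rbind(X0, X0), rep(c("a", "b"), each = 20))
  expect_equal(m0$lambda, 1)
  # agreement with stats::manova Wilks on a general data set
  set.seed(11)
  X <- matrix(rnorm(90 * 4), 90, 4)
  X[31:60, 1] <- X[31:60, 1] + 1
  b <- rep(c("a", "b", "c"), each = 30)
  mine <- birdManova(X, b)
  ref <- summary(stats::manova(X ~ factor(b)), test = "Wilks")$stats
  expect_equal(mine$lambda, unname(ref[1, "Wilks"]), tolerance = 1e-10)
  expect_equal(mine$F, unname(ref[1, "approx F"]), tolerance = 1e-8)
  expect_equal(mine$p, unname(ref[1, "Pr(>F)"]), tolerance = 1e-8)
  # one covariate, two groups: p equals the classical one-way ANOVA p
  set.seed(12)
  y <- rnorm(40); g <- rep(c("a", "b"), each = 20)
  m1 <- birdManova(cbind(y), g)
  a1 <- summary(stats::aov(y ~ factor(g)))[[1]]
  expect_equal(m1$p, a1[["Pr(>F)"]][1], tolerance = 1e-10)
  # invariance of lambda under common invertible transform of covariates
  M <- matrix(rnorm(16), 4, 4)
  expect_equal(birdManova(X %*% M, b)$lambda, mine$lambda, tolerance = 1e-8)
  # permutation p agrees in order of magnitude with the parametric p
  mp <- birdManova(X, b, permutations = 199, seed = 3)
  expect_lt(mp$p_perm, 0.05)
})

test_that("pairwise MANOVA applies Bonferroni over testable pairs", {
  set.seed(13)
  X <- rbind(matrix(rnorm(40), 10, 4),
             matrix(rnorm(40, 2), 10, 4),
             matrix(rnorm(12), 3, 4))   # third bird: n = 3 < 4 covariates
  b <- c(rep("a", 10), rep("b", 10), rep("c", 3))
  pw <- pairwiseManova(X, b)
  expect_identical(pw$m_nominal, 3L)
  expect_identical(pw$m_testable, 1L)   # only a-b testable
  expect_false(pw$pairs$testable[pw$pairs$bird1 == "a" &
                                 pw$pairs$bird2 == "c"])
  ab <- pw$pairs[pw$pairs$bird1 == "a" & pw$pairs$bird2 == "b", ]
  expect_true(ab$significant)
})

test_that("PCA summary: rank-1 share, isotropy, normalization", {
  # rank-1 matrix -> first share = 1
  u <- rnorm(30); v <- c(1, 2, 3)
  m1 <- pcaSummary(outer(u, v), standardize = FALSE)
  expect_equal(m1[1], 1, tolerance = 1e-10)
  # shares sum to one
  X <- randCloud(200, seed = 14)
  sh <- pcaSummary(X)
  expect_equal(sum(sh), 1, tolerance = 1e-10)
  # isotropic noise: all shares near 1/5
  Xi <- matrix(rnorm(4000 * 5), 4000, 5)
  expect_lt(max(abs(pcaSummary(Xi) - 0.2)), 0.03)
  # zero-variance columns are dropped with a warning
  expect_warning(pcaSummary(cbind(X, const = 1)), "zero-variance")
})

test_that("volume-versus-covariate regression recovers exact and null relations", {
  v <- c(10, 8, 6, 4, 2); x <- 1:5
  r <- suppressWarnings(volumeVsCovariate(v, x))  # exact fit warns in summary.lm
  expect_equal(r$R, -1, tolerance = 1e-10)
  expect_equal(r$slope, -2, tolerance = 1e-10)
  # log model: exact logarithmic law is recovered
  motifs <- c(6, 35, 105, 210, 630)
  vol <- 1 + 1.4 * log(motifs)
  rl <- suppressWarnings(volumeVsCovariate(vol, motifs, model = "log"))
  expect_equal(rl$slope, 1.4, tolerance = 1e-10)
  expect_equal(rl$R, 1, tolerance = 1e-10)
  # constant volumes: slope 0, p not significant
  set.seed(15)
  pn <- replicate(50, volumeVsCovariate(rep(3, 6) + rnorm(6, 0, 1e-3),
                                        1:6)$p)
  expect_gt(mean(pn > 0.05), 0.8)
})

test_that("similarity-distance correlation: exact linear case and controls", {
  D <- as.matrix(dist(matrix(rnorm(12), 6, 2)))
  S <- 100 - 10 * D
  r <- suppressWarnings(similarityDistanceCorrelation(S, D))
  expect_equal(r$R, -1, tolerance = 1e-10)
  both <- suppressWarnings(
    similarityDistanceCorrelation(S, D, mode = "both"))
  expect_identical(nrow(both$perBird), 6L)
  expect_true(all(abs(both$perBird$R + 1) < 1e-8))
  # asymmetric input is refused
  S2 <- S; S2[1, 2] <- S2[1, 2] + 1
  expect_error(similarityDistanceCorrelation(S2, D), "symmetric")
})

test_that("rundown check: stable amplitudes give ratios at 1, drift is caught", {
  amp <- data.frame(bird_id = rep(sprintf("b%d", 1:6), each = 5),
                    order = rep(1:5, 6),
                    amplitude = 80)
  rc <- rundownCheck(amp)
  expect_true(all(rc$later$ratios == 1))
  expect_identical(rc$later$t, 0)
  # injected 5%-per-cell monotone drift is detected
  drift <- amp
  drift$amplitude <- 80 * 0.95^(drift$order - 1)
  rd <- rundownCheck(drift)
  expect_lt(rd$later$p, 0.01)
  expect_lt(rd$last$p, 0.01)
  # unstructured 2% noise is not flagged as rundown (most seeds); two cells
  # per bird so the pooled ratios are independent
  amp2 <- data.frame(bird_id = rep(sprintf("b%d", 1:30), each = 2),
                     order = rep(1:2, 30), amplitude = 80)
  ps <- vapply(1:200, function(s) {
    set.seed(s)
    noisy <- amp2
    noisy$amplitude <- 80 * exp(rnorm(nrow(amp2), 0, 0.02))
    rundownCheck(noisy)$later$p
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})
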