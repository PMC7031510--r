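# Synthetic cohort generator: determinism, preset structure, coupling.

test_that("cohort generation is seed-deterministic and seed-mandatory", {
  cc <- cohortConfig("adult", nBirds = 5, neuronsPerBird = 6, seed = 101)
  c1 <- generateCohort(cc)
  c2 <- generateCohort(cc)
  expect_identical(conductances(c1), conductances(c2))
  expect_identical(centroids(c1), centroids(c2))
  c3 <- generateCohort(cohortConfig("adult", nBirds = 5, neuronsPerBird = 6,
                                    seed = 102))
  expect_false(identical(conductances(c1), conductances(c3)))
  expect_error(cohortConfig("adult"), "seed")
})

test_that("zero spread collapses each bird to a point with zero trace volume", {
  cc <- cohortConfig("adult", nBirds = 4, neuronsPerBird = 5, seed = 103,
                     foldSpread = c(gNa = 1, gK = 1, gSK = 1, gh = 1,
                                    gCaT = 1))
  coh <- generateCohort(cc)
  vols <- birdVolumes(coh)
  expect_true(all(vols$trace_volume == 0))
  expect_error(cohortConfig("adult", seed = 1,
                            foldSpread = c(gNa = 0.5, gK = 1, gSK = 1,
                                           gh = 1, gCaT = 1)), ">= 1")
})

test_that("adult preset reproduces the target within-bird fold-variations", {
  folds <- rowMeans(vapply(1:5, function(s)
    withinBirdFold(generateCohort(cohortConfig("adult", nBirds = 8,
                                               neuronsPerBird = 8,
                                               seed = 400 + s))),
    numeric(5)))
  target <- c(gNa = 1.23, gK = 1.24, gSK = 1.14, gh = 1.17, gCaT = 1.19)
  expect_lt(max(abs(folds - target) / (target - 1)), 0.35)
})

test_that("presets order dispersion as adult < juvenile < cdaf and shift the right axes", {
  adult <- generateCohort(cohortConfig("adult", 8, 8, seed = 111))
  juv <- generateCohort(cohortConfig("juvenile", 8, 8, seed = 112))
  cdaf <- generateCohort(cohortConfig("cdaf", 8, 8, seed = 113))
  va <- birdVolumes(adult)$trace_volume
  vj <- birdVolumes(juv)$trace_volume
  vc <- birdVolumes(cdaf)$trace_volume
  expect_lt(mean(va), mean(vj))
  expect_lt(mean(vj), mean(vc))
  # juveniles are confined to the low-gNa/low-gSK adult sub-box
  expect_lt(max(centroids(juv)$gNa), min(2500, 800))
  expect_lt(max(centroids(juv)$gSK), 5)
  # juvenile gh spread inflated relative to adult
  expect_gt(withinBirdFold(juv)[["gh"]], withinBirdFold(adult)[["gh"]] * 1.5)
  # cdaf gSK centroids shifted low relative to adult ranges
  expect_lt(max(centroids(cdaf)$gSK), 7.6)
})

test_that("cdaf dispersion law slope is recovered from trace volumes", {
  # fix all centroids so between-bird volume variation reflects only the
  # dispersion multiplier 1 + b log(motifs/5.9)
  cen <- c(gNa = 900, gK = 250, gSK = 4, gh = 4, gCaT = 3)
  fold <- c(gNa = 1.1, gK = 1.1, gSK = 1.1, gh = 1.1, gCaT = 1.1)
  motifs <- c(6, 12, 25, 50, 100, 200, 400, 800)  # ladder spanning the anchor
  b_true <- 1
  bhat <- vapply(1:8, function(s) {
    coh <- generateCohort(cohortConfig("cdaf", nBirds = 8,
                                       neuronsPerBird = 40, seed = 500 + s,
                                       centroidMin = cen, centroidMax = cen,
                                       foldSpread = fold, motifs = motifs,
                                       dispersionSlope = b_true))
    vb <- birdVolumes(coh)
    m <- centroids(coh)$motifs
    fit <- lm(vb$trace_volume ~ log(m))
    B <- unname(coef(fit)[2]); A <- unname(coef(fit)[1])
    B / (A + B * log(5.9))   # volume ~ K (1 + b log(m/5.9)) => b = B/K
  }, numeric(1))
  expect_lt(abs(mean(bhat) - b_true) / b_true, 0.2)
  # and the regression itself reports a clearly positive log-slope
  coh <- generateCohort(cohortConfig("cdaf", nBirds = 8, neuronsPerBird = 24,
                                     seed = 555, centroidMin = cen,
                                     centroidMax = cen))
  r <- volumeVsCovariate(birdVolumes(coh)$trace_volume,
                         centroids(coh)$motifs, model = "log")
  expect_gt(r$slope, 0)
  expect_lt(r$p, 0.05)
})

test_that("song similarity embeds centroid distances at the set coupling", {
  coh <- generateCohort(cohortConfig("adult", nBirds = 12,
                                     neuronsPerBird = 6, seed = 120))
  D <- conductanceDistances(coh, "euclidean")
  S1 <- generateSongFeatures(coh, coupling = 1, seed = 1)
  expect_true(all(S1 > 0 & S1 <= 100))
  expect_equal(unname(diag(S1)), rep(100, 12))
  r1 <- suppressWarnings(similarityDistanceCorrelation(S1, D))
  expect_equal(r1$R, -1, tolerance = 1e-8)
  # coupling 0: similarity unrelated to distance in >= 90% of seeds
  r0 <- vapply(1:20, function(s)
    similarityDistanceCorrelation(generateSongFeatures(coh, 0, s), D)$R,
    numeric(1))
  expect_gte(mean(abs(r0) < 0.3), 0.9)
  expect_error(generateSongFeatures(
    generateCohort(cohortConfig("adult", 2, 4, seed = 5))), "3 birds")
})

test_that("sibling pairs share a centroid and sit closer than unrelated birds", {
  cc <- cohortConfig("adult", neuronsPerBird = 8, seed = 130)
  # zero spread: the two siblings coincide
  cc0 <- cohortConfig("adult", neuronsPerBird = 8, seed = 130,
                      foldSpread = c(gNa = 1, gK = 1, gSK = 1, gh = 1,
                                     gCaT = 1))
  sib0 <- siblingPair(cc0, seed = 7)
  cen0 <- centroids(sib0)
  expect_equal(unlist(cen0[1, conductanceNames()]),
               unlist(cen0[2, conductanceNames()]))
  # adult spread: sibling Mahalanobis distance below the unrelated median
  sibd <- vapply(1:20, function(s) {
    sib <- siblingPair(cc, seed = s)
    tab <- conductances(sib)
    as.numeric(mahalanobisDistance(
      tab[tab$bird_id == "sibA", ], tab[tab$bird_id == "sibB", ],
      pseudoInverse = TRUE))
  }, numeric(1))
  unrel <- generateCohort(cohortConfig("adult", nBirds = 10,
                                       neuronsPerBird = 8, seed = 131))
  Dm <- conductanceDistances(unrel, "mahalanobis")
  expect_lt(median(sibd), median(Dm[lower.tri(Dm)]))
})

test_that("trace-bearing cohorts carry the canonical protocol pair with noise", {
  box <- stableBox()
  cc <- cohortConfig("adult", nBirds = 2, neuronsPerBird = 2, seed = 140,
                     centroidMin = box$min, centroidMax = box$max,
                     simulateTraces = TRUE)
  coh <- generateCohort(cc)
  expect_length(cohortTraces(coh), 4L)
  trs <- cohortTraces(coh, conductances(coh)$neuron_id[1])
  expect_named(trs, c("+100", "-140"))
  expect_identical(trs[["+100"]]@metadata$provenance, "synthetic-cohort")
  expect_identical(trs[["+100"]]@metadata$noiseSdMv, 0.3)
  # determinism extends to the noisy traces
  coh2 <- generateCohort(cc)
  expect_identical(trs[["+100"]]@voltageMv,
                   cohortTraces(coh2, conductances(coh)$neuron_id[1])[["+100"]]@voltageMv)
})
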