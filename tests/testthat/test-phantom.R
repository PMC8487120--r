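# Synthetic arch phantom: analytic geometry, voxelization consistency and
# cohort sampling.

test_that("the arch centerline lies in a plane perpendicular to the stated LAO ray", {
  scene <- generatePhantom(smallPhantomSpec(archPlaneLao = 45))
  pts <- as.matrix(centerline(scene, "aorta"))
  # drop the straight limbs: their points keep constant (x, y); arch points
  # vary in the horizontal plane
  horiz <- pts[, 1:2]
  onLimb <- duplicated(round(horiz, 6)) | duplicated(round(horiz, 6), fromLast = TRUE)
  arch <- pts[!onLimb, ]
  expect_gt(nrow(arch), 50)
  normal <- fitPlaneNormal(arch)
  ray45 <- c(sin(pi / 4), cos(pi / 4), 0)
  expect_equal(abs(sum(normal * ray45)), 1, tolerance = 1e-6)
})

test_that("phantom labels and closed-form lengths are consistent", {
  spec <- smallPhantomSpec()
  scene <- generatePhantom(spec)
  counts <- table(factor(as.vector(labelVolume(scene)), levels = 0:3))
  expect_gt(counts[["2"]], 0)  # LCCA voxels exist
  expect_gt(counts[["3"]], 0)  # LSA voxels exist
  closed <- pi * spec@archRadius + spec@ascendingLength + spec@descendingLength
  expect_equal(arcLength(centerline(scene, "aorta")), closed,
               tolerance = 5e-3)
  # every aorta centerline point's nearest voxel carries the aorta label
  idx <- round(sweep(sweep(as.matrix(centerline(scene, "aorta")), 2,
                           sceneOrigin(scene)), 2, voxelSpacing(scene), "/")) + 1
  vals <- labelVolume(scene)[idx]
  expect_true(all(vals == 1L))
})

test_that("phantom generation is deterministic and respects grid bounds", {
  spec <- smallPhantomSpec()
  s1 <- generatePhantom(spec)
  s2 <- generatePhantom(spec)
  expect_identical(labelVolume(s1), labelVolume(s2))
  expect_error(PhantomSpec(gridShape = c(24L, 24L, 24L), spacing = rep(1, 3)),
               "exceeds grid")
})

test_that("near-coincident branches overlap except at the seam-parallel view", {
  # with exclusive voxel labels two near-coincident tubes split along their
  # bisector plane, so their silhouettes overlap at every angle except where
  # the ray runs inside that seam (the arch-perpendicular view)
  spec <- smallPhantomSpec(branchAngles = c(89.5, 90.5), branchTilt = 0)
  scene <- generatePhantom(spec)
  profile <- sweepAngles(scene, thetas = seq(0, 90, by = 5))
  away <- abs(profile@thetas - spec@archPlaneLao) > 10
  expect_true(all(profile@pOverlap[away] > 0))
  expect_true(all(abs(noOverlapSet(profile) - spec@archPlaneLao) <= 10))
})

test_that("a coaxial-shell branch pair overlaps at every sweep angle", {
  profile <- sweepAngles(shellScene(), thetas = seq(0, 90, by = 10))
  expect_true(all(profile@pOverlap > 0))
  expect_length(noOverlapSet(profile), 0)
})

test_that("wider branch separation never shrinks the overlap-free set", {
  sizes <- sapply(c(3, 6.5, 10), function(half) {
    spec <- smallPhantomSpec(branchAngles = c(90 - half, 90 + half))
    profile <- sweepAngles(generatePhantom(spec), thetas = seq(0, 90, by = 5))
    length(noOverlapSet(profile))
  })
  expect_true(all(diff(sizes) >= 0))
})

test_that("cohort sampling is seeded, uniform and validated", {
  base <- smallPhantomSpec()
  jit <- list(archPlaneLao = c(35, 55), archRadius = c(33, 37))
  c1 <- sampleCohort(base, n = 5, seed = 7, jitter = jit)
  c2 <- sampleCohort(base, n = 5, seed = 7, jitter = jit)
  expect_identical(lapply(c1, function(s) s@archPlaneLao),
                   lapply(c2, function(s) s@archPlaneLao))
  # degenerate ranges reproduce the base spec
  copies <- sampleCohort(base, n = 3, seed = 1,
                         jitter = list(archPlaneLao = c(45, 45)))
  expect_true(all(sapply(copies, function(s) identical(s@archPlaneLao, 45))))
  # n = 35 draws of lao ~ U(35, 55): sample mean within 45 +/- 5
  big <- sampleCohort(base, n = 35, seed = 11,
                      jitter = list(archPlaneLao = c(35, 55)))
  laos <- sapply(big, function(s) s@archPlaneLao)
  expect_true(mean(laos) > 40 && mean(laos) < 50)
  expect_true(all(laos >= 35 & laos <= 55))
  # jitter that can only produce invalid specs errors out after retries
  expect_error(sampleCohort(base, n = 1, seed = 1,
                            jitter = list(archRadius = c(500, 600))),
               "100 retries")
  # caller RNG state untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(sampleCohort(base, n = 2, seed = 9,
                                        jitter = list(archPlaneLao = c(40, 50))))
  expect_identical(runif(1), before)
})
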