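# Parallel-beam projector: geometry frames, silhouette fidelity against
# analytic shapes, centerline projection, rendered views.

# minimal scene: one labeled block in an otherwise empty grid
blockScene <- function(dims, lo, hi, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  vol <- array(0L, dims)
  vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1L
  mid <- (lo + hi) / 2 * spacing + origin
  cl <- Centerline(rbind(mid - c(0.25, 0, 0), mid + c(0.25, 0, 0)), "aorta")
  VesselScene(vol, spacing = spacing, origin = origin,
              labels = c(background = 0L, aorta = 1L),
              centerlines = list(aorta = cl))
}

test_that("geometry frames follow the LAO convention and stay orthonormal", {
  g0 <- geometryForAngle(0, 1, c(4L, 4L))
  expect_equal(g0@rayDir, c(0, 1, 0))
  g90 <- geometryForAngle(90, 1, c(4L, 4L))
  expect_equal(g90@rayDir, c(1, 0, 0), tolerance = 1e-15)
  for (theta in seq(0, 90, by = 7.5)) {
    g <- geometryForAngle(theta, 0.8, c(10L, 12L))
    expect_equal(sum(g@rayDir^2), 1, tolerance = 1e-12)
    expect_lt(abs(sum(g@rayDir * g@detectorU)), 1e-12)
    expect_lt(abs(sum(g@rayDir * g@detectorV)), 1e-12)
    expect_lt(abs(sum(g@detectorU * g@detectorV)), 1e-12)
  }
  expect_error(geometryForAngle(-1, 1, c(4L, 4L)), "\\[0, 90\\]")
  expect_error(geometryForAngle(91, 1, c(4L, 4L)), "\\[0, 90\\]")
})

test_that("axis-aligned cuboid projects to the exact rectangle", {
  scene <- blockScene(c(20, 30, 25), lo = c(4, 6, 5), hi = c(10, 17, 13))
  # theta = 0: ray along +y, u = x (7 voxels), v = -z (9 voxels)
  m0 <- projectLabel(scene, "aorta", theta = 0)@mask
  expect_identical(sum(m0), 7L * 9L)
  expect_identical(dim(which(m0, arr.ind = TRUE)), c(63L, 2L))
  rows <- range(which(rowSums(m0) > 0)); cols <- range(which(colSums(m0) > 0))
  expect_identical(diff(rows) + 1L, 7L)
  expect_identical(diff(cols) + 1L, 9L)
  # theta = 90: ray along +x, u = -y gives 12 voxels across
  m90 <- projectLabel(scene, "aorta", theta = 90)@mask
  expect_identical(sum(m90), 12L * 9L)
})

test_that("sphere silhouette area approaches the analytic disk", {
  r <- 12
  dims <- c(40, 40, 40)
  ctr <- c(20, 20, 20)
  g <- expand.grid(x = 1:40, y = 1:40, z = 1:40)
  vol <- array(0L, dims)
  vol[as.matrix(g[(g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2 <= r^2, ])] <- 1L
  cl <- Centerline(rbind(ctr - 1.5, ctr + 1.5), "aorta")
  scene <- VesselScene(vol, spacing = c(1, 1, 1),
                       labels = c(background = 0L, aorta = 1L),
                       centerlines = list(aorta = cl))
  areas <- sapply(c(0, 17, 45), function(th) {
    m <- projectLabel(scene, "aorta", theta = th)
    sum(m@mask) * m@pixelSize^2
  })
  expect_true(all(abs(areas - pi * r^2) / (pi * r^2) < 0.03))
  # refinement: mask area error decreases with finer pixels
  errs <- sapply(c(2, 1, 0.5), function(ps) {
    m <- projectLabel(scene, "aorta", sceneGeometry(scene, 30, pixelSize = ps))
    abs(sum(m@mask) * ps^2 - pi * r^2)
  })
  expect_true(all(diff(errs) < 0))
})

test_that("empty labels, missing labels and translation invariance behave", {
  scene <- blockScene(c(16, 16, 16), lo = c(4, 4, 4), hi = c(9, 9, 9))
  # a mapped-but-absent label projects to an all-zero mask
  scene2 <- VesselScene(labelVolume(scene), voxelSpacing(scene),
                        sceneOrigin(scene),
                        labels = c(background = 0L, aorta = 1L, LCCA = 2L),
                        centerlines = centerlines(scene))
  expect_identical(sum(projectLabel(scene2, "LCCA", theta = 10)@mask), 0L)
  expect_error(projectLabel(scene, "LSA", theta = 0), "available")

  # translating the scene along the ray leaves the mask bit-identical
  for (theta in c(0, 30, 90)) {
    g <- sceneGeometry(scene, theta)
    m1 <- projectLabel(scene, "aorta", g)@mask
    step <- min(voxelSpacing(scene)) / 2
    shift <- g@rayDir * 8 * step
    moved <- VesselScene(labelVolume(scene), voxelSpacing(scene),
                         sceneOrigin(scene) + shift,
                         labels = labelMap(scene),
                         centerlines = list(aorta = Centerline(
                           sweep(as.matrix(centerline(scene, "aorta")), 2,
                                 shift, "+"), "aorta")))
    m2 <- projectLabel(moved, "aorta", g)@mask
    expect_identical(m1, m2)
  }
})

test_that("centerline projection is the orthographic map", {
  g <- geometryForAngle(25, 1, c(8L, 8L))
  # segment along the ray: projects to a point
  alongRay <- Centerline(rbind(c(0, 0, 0), 30 * g@rayDir), "aorta")
  expect_equal(arcLength(projectCenterline(alongRay, g)), 0, tolerance = 1e-12)
  # segment along detectorU: in-plane isometry
  inPlane <- Centerline(rbind(c(0, 0, 0), 30 * g@detectorU), "aorta")
  expect_equal(arcLength(projectCenterline(inPlane, g)), 30, tolerance = 1e-12)
  # semicircle in the plane normal to the ray: isometric projection
  ang <- seq(0, pi, length.out = 2000)
  pts <- t(sapply(ang, function(a) 40 * cos(a) * g@detectorU + 40 * sin(a) * g@detectorV))
  semi <- Centerline(pts, "aorta")
  proj <- projectCenterline(semi, g)
  expect_identical(nrow(as.matrix(proj)), nrow(pts))
  expect_equal(arcLength(proj), arcLength(semi), tolerance = 1e-9)
})

test_that("projected centerline support lies within the vessel silhouette", {
  scene <- generatePhantom(smallPhantomSpec())
  for (theta in c(0, 40, 75)) {
    g <- sceneGeometry(scene, theta)
    m <- projectLabel(scene, "aorta", g)@mask
    p2 <- as.matrix(projectCenterline(centerline(scene, "aorta"), g))
    iu <- ceiling((p2[, 1] - g@detectorOrigin[1]) / g@pixelSize)
    iv <- ceiling((p2[, 2] - g@detectorOrigin[2]) / g@pixelSize)
    near <- mapply(function(i, j) {
      any(m[max(1, i - 1):min(nrow(m), i + 1),
            max(1, j - 1):min(ncol(m), j + 1)])
    }, iu, iv)
    expect_true(all(near))
  }
})

test_that("rendered views are normalized thickness maps", {
  scene <- blockScene(c(16, 16, 16), lo = c(4, 4, 4), hi = c(9, 9, 11))
  v <- renderView(scene, theta = 0)
  expect_true(all(v >= 0 & v <= 1))
  # constant path length across the interior: block is 6 voxels thick along y
  interior <- v[v > 0]
  expect_true(all(abs(interior - 1) < 1e-9))
  expect_equal(attr(v, "max_mm"), 6, tolerance = 0.51)
  # absolute difference of a view with itself vanishes
  expect_identical(max(abs(v - renderView(scene, theta = 0))), 0)
  # empty scene renders to all zeros
  empty <- VesselScene(array(0L, c(8, 8, 8)), c(1, 1, 1),
                       labels = c(background = 0L, aorta = 1L),
                       centerlines = list(aorta = Centerline(
                         rbind(c(2, 2, 2), c(5, 5, 5)), "aorta")))
  expect_identical(max(renderView(empty, theta = 33)), 0)
})
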