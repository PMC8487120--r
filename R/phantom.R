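# Parametric aortic-arch phantom. The arch midline is an exact semicircle of
# radius R in the plane spanned by e1 (horizontal, in-plane) and z (superior),
# whose normal n is the ray direction of the arch-perpendicular LAO view;
# straight vertical ascending/descending limbs join the semicircle ends C0.
# Geometry is closed-form throughout, so arc lengths, the optimal plane and
# the branch-overlap regime are all known analytically.

phantomFrame <- function(lao) {
  a <- lao * pi / 180
  list(e1 = c(cos(a), -sin(a), 0),   # in-plane horizontal axis
       n  = c(sin(a),  cos(a), 0),   # arch-plane normal = ray at theta = lao
       ez = c(0, 0, 1))
}

# Branch axis origin/direction in arch-frame components (e1, n, z).
# LCCA tilts anteriorly (-n), LSA posteriorly (+n): opposed out-of-plane
# divergence, which sets where in the sweep the silhouettes separate.
phantomBranchAxes <- function(spec) {
  phi <- spec@branchAngles * pi / 180
  tl <- spec@branchTilt * pi / 180
  sgn <- c(-1, 1)
  lapply(1:2, function(b) {
    list(origin = spec@archRadius * c(cos(phi[b]), 0, sin(phi[b])),
         dir = c(cos(tl) * cos(phi[b]), sgn[b] * sin(tl), cos(tl) * sin(phi[b])))
  })
}

# Analytic centerlines in arch-frame (e1, n, z) components, arch center at 0,
# sampled at `step` mm. Returns a named list of coordinate matrices.
phantomCenterlinesLocal <- function(spec, step = 1) {
  R <- spec@archRadius
  nseg <- function(L) max(2L, ceiling(L / step) + 1L)
  # ascending limb: proximal (inferior) end first
  za <- seq(-spec@ascendingLength, 0, length.out = nseg(spec@ascendingLength))
  asc <- cbind(R, 0, za)
  # semicircle, phi 0 -> pi (ascending end to descending end over the apex)
  nphi <- max(2L, ceiling(pi * R / step) + 1L)
  phi <- seq(0, pi, length.out = nphi)
  arch <- cbind(R * cos(phi), 0, R * sin(phi))
  zd <- seq(0, -spec@descendingLength, length.out = nseg(spec@descendingLength))
  desc <- cbind(-R, 0, zd)
  aorta <- rbind(asc, arch[-1L, ], desc[-1L, ])
  axes <- phantomBranchAxes(spec)
  br <- lapply(axes, function(ax) {
    s <- seq(0, spec@branchLength, length.out = nseg(spec@branchLength))
    cbind(ax$origin[1L] + s * ax$dir[1L],
          ax$origin[2L] + s * ax$dir[2L],
          ax$origin[3L] + s * ax$dir[3L])
  })
  list(aorta = aorta, LCCA = br[[1L]], LSA = br[[2L]])
}

# World-frame physical extent (mm) of the phantom, padded by tube radii.
phantomExtent <- function(spec) {
  fr <- phantomFrame(spec@archPlaneLao)
  B <- rbind(fr$e1, fr$n, fr$ez)  # local -> world: t(B) %*% local
  cls <- phantomCenterlinesLocal(spec, step = 2)
  pad <- c(aorta = spec@tubeRadiusAorta, LCCA = spec@tubeRadiusBranch,
           LSA = spec@tubeRadiusBranch)
  lo <- rep(Inf, 3L); hi <- rep(-Inf, 3L)
  for (v in names(cls)) {
    w <- cls[[v]] %*% B
    lo <- pmin(lo, apply(w, 2L, min) - pad[[v]])
    hi <- pmax(hi, apply(w, 2L, max) + pad[[v]])
  }
  hi - lo
}

#' Create an aortic-arch phantom specification
#'
#' Defaults describe an adult-sized thoracic aortic arch: a 35 mm-radius
#' semicircular arch midline with a 14 mm aortic tube radius, 40 mm straight
#' ascending/descending limbs, and two 4 mm-radius branches (LCCA, LSA)
#' leaving the arch 13 degrees apart near its apex with opposed 40-degree
#' out-of-plane tilts. With these defaults the branch silhouettes overlap at
#' shallow (AP-ward) sweep angles and separate a few degrees below the
#' arch-perpendicular view, the regime in which viewing-angle planning is
#' clinically non-trivial. The default grid is 128^3 voxels at 1.25 mm.
#'
#' @param archRadius,tubeRadiusAorta,tubeRadiusBranch,archPlaneLao,branchAngles,branchLength,branchTilt,ascendingLength,descendingLength,gridShape,spacing
#'   see [PhantomSpec-class] for slot meanings and units.
#' @return a validated [PhantomSpec-class].
#' @examples
#' spec <- PhantomSpec(archPlaneLao = 50, gridShape = c(64, 64, 64),
#'                     spacing = rep(2.5, 3))
#' spec
#' @export
PhantomSpec <- function(archRadius = 35, tubeRadiusAorta = 14,
                        tubeRadiusBranch = 4, archPlaneLao = 45,
                        branchAngles = c(83.5, 96.5), branchLength = 40,
                        branchTilt = 40, ascendingLength = 40,
                        descendingLength = 40,
                        gridShape = c(128L, 128L, 128L),
                        spacing = c(1.25, 1.25, 1.25)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(gridShape) == 1L) gridShape <- rep(gridShape, 3L)
  new("PhantomSpec", archRadius = archRadius,
      tubeRadiusAorta = tubeRadiusAorta, tubeRadiusBranch = tubeRadiusBranch,
      archPlaneLao = archPlaneLao, branchAngles = as.numeric(branchAngles),
      branchLength = branchLength, branchTilt = branchTilt,
      ascendingLength = ascendingLength, descendingLength = descendingLength,
      gridShape = as.integer(gridShape), spacing = as.numeric(spacing))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0(
    "PhantomSpec: arch R = %.1f mm (tube %.1f mm), perpendicular view at LAO %.1f deg\n",
    "  branches at %.1f / %.1f deg, radius %.1f mm, length %.1f mm, tilt %.1f deg\n",
    "  grid %d x %d x %d @ %.3g x %.3g x %.3g mm\n"),
    object@archRadius, object@tubeRadiusAorta, object@archPlaneLao,
    object@branchAngles[1L], object@branchAngles[2L],
    object@tubeRadiusBranch, object@branchLength, object@branchTilt,
    object@gridShape[1L], object@gridShape[2L], object@gridShape[3L],
    object@spacing[1L], object@spacing[2L], object@spacing[3L]))
})

#' Generate a labeled voxel phantom from a specification
#'
#' Deterministically voxelizes the analytic arch + branch geometry: a voxel
#' is labeled aorta if its center lies within the aorta tube radius of the
#' arch midline (semicircle plus straight limbs), else LCCA/LSA if within the
#' branch tube radius of the respective branch axis (the nearer axis wins
#' where both qualify). The aorta label wins wherever tubes meet, so branch
#' labels only cover the portions emerging from the aortic wall. The analytic
#' centerlines (sampled at `centerlineStep` mm) are attached for all three
#' vessels, and the phantom is centered in the voxel grid.
#'
#' @param spec a [PhantomSpec-class].
#' @param centerlineStep sampling step (mm) for the analytic centerlines.
#' @return a validated [VesselScene-class] with labels
#'   background/aorta/LCCA/LSA = 0/1/2/3.
#' @examples
#' scene <- generatePhantom(PhantomSpec(gridShape = c(48, 48, 48),
#'                                      spacing = rep(3.4, 3)))
#' scene
#' @export
generatePhantom <- function(spec, centerlineStep = 1) {
  validObject(spec)
  fr <- phantomFrame(spec@archPlaneLao)
  B <- rbind(fr$e1, fr$n, fr$ez)
  clsLocal <- phantomCenterlinesLocal(spec, step = centerlineStep)
  pad <- c(aorta = spec@tubeRadiusAorta, LCCA = spec@tubeRadiusBranch,
           LSA = spec@tubeRadiusBranch)
  lo <- rep(Inf, 3L); hi <- rep(-Inf, 3L)
  clsWorld <- lapply(names(clsLocal), function(v) clsLocal[[v]] %*% B)
  names(clsWorld) <- names(clsLocal)
  for (v in names(clsWorld)) {
    lo <- pmin(lo, apply(clsWorld[[v]], 2L, min) - pad[[v]])
    hi <- pmax(hi, apply(clsWorld[[v]], 2L, max) + pad[[v]])
  }
  d <- spec@gridShape; sp <- spec@spacing
  origin <- c(0, 0, 0)
  gridCenter <- origin + (d - 1) / 2 * sp
  shift <- gridCenter - (lo + hi) / 2        # world translation of the phantom
  archCenter <- shift                        # arch center was at local 0
  clsWorld <- lapply(clsWorld, function(m) sweep(m, 2L, shift, "+"))

  # voxel centers in arch-frame components, relative to the arch center
  ax <- lapply(1:3, function(k) origin[k] + (seq_len(d[k]) - 1) * sp[k] - archCenter[k])
  px <- rep(ax[[1L]], times = d[2L] * d[3L])
  py <- rep(rep(ax[[2L]], each = d[1L]), times = d[3L])
  pz <- rep(ax[[3L]], each = d[1L] * d[2L])
  q1 <- px * fr$e1[1L] + py * fr$e1[2L]      # e1 and n have zero z-component
  qn <- px * fr$n[1L] + py * fr$n[2L]
  qz <- pz
  rm(px, py, pz)

  R <- spec@archRadius
  rip <- sqrt(q1^2 + qz^2)
  dArc2 <- (rip - R)^2 + qn^2
  dArc2[qz < 0] <- Inf                       # arc spans the upper half-plane
  rm(rip)
  clampExcess <- function(z, zlo, zhi) z - pmin(pmax(z, zlo), zhi)
  dAsc2 <- (q1 - R)^2 + qn^2 + clampExcess(qz, -spec@ascendingLength, 0)^2
  dDesc2 <- (q1 + R)^2 + qn^2 + clampExcess(qz, -spec@descendingLength, 0)^2
  dAorta2 <- pmin(dArc2, dAsc2, dDesc2)
  rm(dArc2, dAsc2, dDesc2)

  axes <- phantomBranchAxes(spec)
  branchDist2 <- function(ax) {
    v1 <- q1 - ax$origin[1L]; vn <- qn; vz <- qz - ax$origin[3L]
    t <- pmin(pmax(v1 * ax$dir[1L] + vn * ax$dir[2L] + vz * ax$dir[3L], 0),
              spec@branchLength)
    (v1 - t * ax$dir[1L])^2 + (vn - t * ax$dir[2L])^2 + (vz - t * ax$dir[3L])^2
  }
  d1 <- branchDist2(axes[[1L]])
  d2 <- branchDist2(axes[[2L]])

  rb2 <- spec@tubeRadiusBranch^2
  lab <- integer(length(q1))
  inB1 <- d1 <= rb2; inB2 <- d2 <= rb2
  lab[inB2] <- 3L
  lab[inB1 & (!inB2 | d1 <= d2)] <- 2L       # nearer axis wins, ties to LCCA
  lab[dAorta2 <= spec@tubeRadiusAorta^2] <- 1L
  vol <- array(lab, dim = d)

  cls <- lapply(names(clsWorld), function(v) Centerline(clsWorld[[v]], v))
  names(cls) <- names(clsWorld)
  VesselScene(vol, spacing = sp, origin = origin, centerlines = cls)
}

#' Sample a cohort of phantom specifications
#'
#' Draws `n` specifications around `base` by independent uniform jitter of
#' the named scalar fields. Reproducible given `seed`; the caller's RNG state
#' is left untouched. A draw violating the specification invariants (e.g. a
#' phantom outgrowing its grid) is rejected and redrawn, up to 100 retries.
#'
#' @param base a [PhantomSpec-class] to perturb.
#' @param n number of specifications (>= 1).
#' @param seed integer seed.
#' @param jitter named list; each element is `c(lo, hi)`, the uniform range
#'   for that scalar slot of [PhantomSpec-class] (e.g.
#'   `list(archPlaneLao = c(35, 55))`). Degenerate ranges (`lo == hi`) pin
#'   the field; an empty list returns `n` copies of `base`.
#' @return a list of `n` validated [PhantomSpec-class] objects.
#' @examples
#' cohort <- sampleCohort(PhantomSpec(), n = 3, seed = 7,
#'                        jitter = list(archPlaneLao = c(40, 50)))
#' sapply(cohort, function(s) s@archPlaneLao)
#' @export
sampleCohort <- function(base, n, seed, jitter = list()) {
  validObject(base)
  if (n < 1L) stop("n must be >= 1")
  bad <- setdiff(names(jitter), methods::slotNames("PhantomSpec"))
  if (length(bad))
    stop(sprintf("unknown jitter field(s): %s", paste(bad, collapse = ", ")))
  for (f in names(jitter)) {
    if (length(slot(base, f)) != 1L)
      stop(sprintf("jitter is only supported for scalar fields (not '%s')", f))
    if (length(jitter[[f]]) != 2L || jitter[[f]][1L] > jitter[[f]][2L])
      stop(sprintf("jitter range for '%s' must be c(lo, hi)", f))
  }
  haveSeed <- exists(".Random.seed", envir = globalenv())
  if (haveSeed) oldSeed <- get(".Random.seed", envir = globalenv())
  on.exit(if (haveSeed) assign(".Random.seed", oldSeed, envir = globalenv())
          else suppressWarnings(rm(list = ".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    for (try in seq_len(100L)) {
      draw <- base
      for (f in names(jitter))
        slot(draw, f) <- stats::runif(1L, jitter[[f]][1L], jitter[[f]][2L])
      ok <- isTRUE(tryCatch(validObject(draw), error = function(e) FALSE))
      if (ok) break
      if (try == 100L)
        stop("could not draw a valid specification in 100 retries; tighten the jitter ranges")
    }
    out[[i]] <- draw
  }
  out
}
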