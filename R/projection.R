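# Parallel-beam projection of a vessel scene. The sweep angle theta is the
# LAO rotation about the superior-inferior axis, zero cranial/caudal
# angulation; projection is orthographic (the C-arm source distance is large
# relative to the arch, so magnification is neglected and closed-form
# oracles exist for the silhouettes).

#' Build the projection geometry for a sweep angle
#'
#' In the LPS frame the ray is `(sin theta, cos theta, 0)`: theta = 0 is the
#' AP view and increasing theta rotates toward LAO about the
#' superior-inferior axis. Detector axes are
#' `detectorU = (cos theta, -sin theta, 0)` and `detectorV = (0, 0, -1)`
#' (image-up = superior).
#'
#' @param theta sweep angle in degrees, in \[0, 90\].
#' @param pixelSize detector pixel size in mm.
#' @param detectorShape integer(2), pixel counts along u and v.
#' @param detectorOrigin numeric(2), detector coordinate (mm) of the lower
#'   corner of pixel (1,1).
#' @return a validated [ProjectionGeometry-class].
#' @seealso [sceneGeometry()] for a detector automatically sized to a scene.
#' @examples
#' g <- geometryForAngle(0, pixelSize = 1, detectorShape = c(64, 64))
#' g@rayDir  # (0, 1, 0): the AP view
#' @export
geometryForAngle <- function(theta, pixelSize, detectorShape,
                             detectorOrigin = c(0, 0)) {
  if (length(theta) != 1L || !is.finite(theta) || theta < 0 || theta > 90)
    stop("theta must be a scalar angle in [0, 90] degrees")
  t <- theta * pi / 180
  new("ProjectionGeometry", theta = as.numeric(theta),
      rayDir = c(sin(t), cos(t), 0),
      detectorU = c(cos(t), -sin(t), 0),
      detectorV = c(0, 0, -1),
      pixelSize = as.numeric(pixelSize),
      detectorShape = as.integer(detectorShape),
      detectorOrigin = as.numeric(detectorOrigin))
}

#' Projection geometry with a detector sized to a scene
#'
#' Sizes and positions the detector so the projection of the scene's
#' bounding box is covered with a two-pixel margin on every side. The
#' detector grid is anchored at integer multiples of `pixelSize` in detector
#' coordinates, so translating the scene along the ray leaves masks
#' bit-identical and axis-aligned scenes project onto pixel centers aligned
#' with voxel centers.
#'
#' @param scene a [VesselScene-class].
#' @param theta sweep angle in degrees.
#' @param pixelSize detector pixel size in mm; defaults to the scene's
#'   minimum voxel spacing.
#' @return a [ProjectionGeometry-class].
#' @export
sceneGeometry <- function(scene, theta, pixelSize = min(voxelSpacing(scene))) {
  g <- geometryForAngle(theta, pixelSize, c(1L, 1L))
  bb <- sceneBoundingBox(scene)
  corners <- as.matrix(expand.grid(bb[, 1L], bb[, 2L], bb[, 3L]))
  pu <- corners %*% g@detectorU
  pv <- corners %*% g@detectorV
  # anchor pixel centers on absolute multiples of pixelSize, so that grids
  # aligned with the detector axes project voxel centers onto pixel centers
  ku <- c(floor(min(pu) / pixelSize) - 2, ceiling(max(pu) / pixelSize) + 2)
  kv <- c(floor(min(pv) / pixelSize) - 2, ceiling(max(pv) / pixelSize) + 2)
  geometryForAngle(theta, pixelSize,
                   c(ku[2L] - ku[1L] + 1, kv[2L] - kv[1L] + 1),
                   c((ku[1L] - 0.5) * pixelSize, (kv[1L] - 0.5) * pixelSize))
}

setMethod("show", "ProjectionGeometry", function(object) {
  cat(sprintf(paste0(
    "ProjectionGeometry: theta = %.1f deg (LAO), parallel beam\n",
    "  ray (%.4f, %.4f, %.4f); detector %d x %d px @ %.3g mm\n"),
    object@theta, object@rayDir[1L], object@rayDir[2L], object@rayDir[3L],
    object@detectorShape[1L], object@detectorShape[2L], object@pixelSize))
})

setMethod("show", "ProjectionMask", function(object) {
  cat(sprintf("ProjectionMask '%s' at theta = %.1f deg: %d x %d px, %d set\n",
              object@label, object@theta, nrow(object@mask),
              ncol(object@mask), sum(object@mask)))
})

#' Project one vessel label to a binary silhouette
#'
#' Casts a parallel ray through the center of every detector pixel and sets
#' the pixel iff the ray passes through at least one voxel carrying the
#' requested label (nearest-neighbor sampling at half the minimum voxel
#' spacing). The result is a binary silhouette, not an attenuation image.
#'
#' @param scene a [VesselScene-class].
#' @param label vessel name present in the scene's label map (e.g.
#'   `"LCCA"`).
#' @param geom a [ProjectionGeometry-class]; defaults to
#'   `sceneGeometry(scene, theta)`.
#' @param theta sweep angle in degrees, used when `geom` is missing.
#' @return a [ProjectionMask-class].
#' @seealso [overlapRate()], [renderView()]
#' @export
projectLabel <- function(scene, label, geom = NULL, theta = NULL) {
  if (is.null(geom)) {
    if (is.null(theta)) stop("provide either a geometry or a theta")
    geom <- sceneGeometry(scene, theta)
  }
  if (!label %in% names(scene@labels))
    stop(sprintf("label '%s' not in scene; available: %s", label,
                 paste(names(scene@labels), collapse = ", ")))
  value <- scene@labels[[label]]
  step <- min(scene@spacing) / 2
  m <- cpp_cast_rays(as.vector(scene@volume), dim(scene@volume),
                     scene@spacing, scene@origin, as.integer(value),
                     geom@rayDir, geom@detectorU, geom@detectorV,
                     geom@detectorOrigin, geom@pixelSize,
                     geom@detectorShape[1L], geom@detectorShape[2L],
                     step, 0L)
  new("ProjectionMask", mask = m > 0, label = label, theta = geom@theta,
      pixelSize = geom@pixelSize)
}

#' Project a centerline into the detector plane
#'
#' Maps each 3D point p to `(p . detectorU, p . detectorV)`; order and point
#' count are preserved, so the projected polyline's [arcLength()] is the
#' projected centerline length entering the foreshortening rate.
#'
#' @param cl a [Centerline-class].
#' @param geom a [ProjectionGeometry-class].
#' @return a [ProjectedCenterline-class].
#' @export
projectCenterline <- function(cl, geom) {
  p2 <- cbind(cl@points %*% geom@detectorU, cl@points %*% geom@detectorV)
  colnames(p2) <- c("u_mm", "v_mm")
  new("ProjectedCenterline", points2d = p2, theta = geom@theta)
}

#' Render a grayscale simulated angiographic view
#'
#' Ray-sum of the foreground indicator (any non-background label): each
#' pixel value is the path length (mm) of its ray through vessel voxels,
#' normalized to \[0, 1\] by the maximum. Used for qualitative inspection and
#' absolute-difference images between views; no attenuation physics.
#'
#' @inheritParams projectLabel
#' @return numeric matrix in \[0, 1\] (u along rows, v along columns); the
#'   raw thickness in mm is attached as attribute `"thickness_mm"` via its
#'   maximum (`max_mm`).
#' @export
renderView <- function(scene, geom = NULL, theta = NULL) {
  if (is.null(geom)) {
    if (is.null(theta)) stop("provide either a geometry or a theta")
    geom <- sceneGeometry(scene, theta)
  }
  step <- min(scene@spacing) / 2
  m <- cpp_cast_rays(as.vector(scene@volume), dim(scene@volume),
                     scene@spacing, scene@origin, 0L,
                     geom@rayDir, geom@detectorU, geom@detectorV,
                     geom@detectorOrigin, geom@pixelSize,
                     geom@detectorShape[1L], geom@detectorShape[2L],
                     step, 1L)
  mx <- max(m)
  out <- if (mx > 0) m / mx else m
  attr(out, "max_mm") <- mx
  out
}

#' Write a mask or rendered view as PNG
#'
#' Binary masks are written as 0/255; grayscale views on their \[0, 1\]
#' scale. Requires the `png` package.
#'
#' @param x a [ProjectionMask-class] or a numeric matrix in \[0, 1\].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeViewPNG <- function(x, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("writeViewPNG requires the 'png' package")
  m <- if (is(x, "ProjectionMask")) x@mask * 1 else x
  # transpose so image rows run along v (top = max v = superior)
  img <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  png::writePNG(img, path)
  invisible(path)
}
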