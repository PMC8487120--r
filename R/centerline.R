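#' Construct a vessel centerline
#'
#' @param points numeric matrix (or data frame) with one row per point and
#'   three columns of physical coordinates in mm (LPS frame), ordered
#'   proximal to distal.
#' @param label which vessel the curve traces; conventionally `"aorta"`,
#'   `"LCCA"` or `"LSA"`.
#' @return a validated [Centerline-class].
#' @examples
#' cl <- Centerline(cbind(x_mm = 0, y_mm = 0, z_mm = seq(0, 50, by = 5)),
#'                  "aorta")
#' arcLength(cl)
#' @export
Centerline <- function(points, label) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  colnames(points) <- c("x_mm", "y_mm", "z_mm")
  new("Centerline", points = points, label = as.character(label))
}

polylineLength <- function(p) {
  if (nrow(p) < 2L) return(0)
  d <- p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

#' @rdname arcLength
#' @export
setMethod("arcLength", "Centerline", function(x) polylineLength(x@points))

#' @rdname arcLength
#' @export
setMethod("arcLength", "ProjectedCenterline", function(x) polylineLength(x@points2d))

#' @rdname arcLength
#' @export
setMethod("arcLength", "matrix", function(x) polylineLength(x))

#' Accessors for scene and centerline objects
#'
#' `vesselLabel()` returns the vessel name a [Centerline-class] traces;
#' `as.matrix()` its point coordinates. For a [VesselScene-class]:
#' `labelVolume()` the 3D integer array, `voxelSpacing()` / `sceneOrigin()`
#' the affine parameters (mm), `labelMap()` the named label-value map,
#' `centerlines()` the named list of centerlines and `centerline(x, vessel)`
#' one of them by name.
#'
#' @param x the object.
#' @param vessel vessel name, e.g. `"aorta"`.
#' @name vesselAccessors
NULL

#' @rdname vesselAccessors
#' @export
setMethod("vesselLabel", "Centerline", function(x) x@label)

#' @rdname vesselAccessors
#' @param ... ignored.
#' @export
setMethod("as.matrix", "Centerline", function(x, ...) x@points)

#' @rdname vesselAccessors
#' @export
setMethod("as.matrix", "ProjectedCenterline", function(x, ...) x@points2d)

setMethod("show", "Centerline", function(object) {
  cat(sprintf("Centerline '%s': %d points, arc length %.2f mm\n",
              object@label, nrow(object@points), arcLength(object)))
})

setMethod("show", "ProjectedCenterline", function(object) {
  cat(sprintf("ProjectedCenterline at theta = %.1f deg: %d points, length %.2f mm\n",
              object@theta, nrow(object@points2d), arcLength(object)))
})
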