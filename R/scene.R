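#' Construct a labeled vessel scene
#'
#' @param volume 3D integer array of label values.
#' @param spacing numeric(3), voxel size in mm.
#' @param origin numeric(3), physical position (mm) of voxel (0,0,0);
#'   default `c(0, 0, 0)`.
#' @param labels named integer vector mapping semantic names to label values;
#'   default `c(background = 0, aorta = 1, LCCA = 2, LSA = 3)`.
#' @param centerlines named list of [Centerline-class] objects; must contain
#'   an `"aorta"` entry.
#' @return a validated [VesselScene-class].
#' @seealso [generatePhantom()] for synthetic scenes, [readScene()] /
#'   [writeScene()] for file I/O.
#' @export
VesselScene <- function(volume, spacing, origin = c(0, 0, 0),
                        labels = c(background = 0L, aorta = 1L,
                                   LCCA = 2L, LSA = 3L),
                        centerlines = list()) {
  storage.mode(volume) <- "integer"
  labels <- vapply(labels, as.integer, integer(1L))
  new("VesselScene", volume = volume, spacing = as.numeric(spacing),
      origin = as.numeric(origin), labels = labels,
      centerlines = centerlines)
}

# Physical bounding box of the voxel grid (outer voxel faces), rows min/max.
sceneBoundingBox <- function(scene) {
  d <- dim(scene@volume)
  lo <- scene@origin - 0.5 * scene@spacing
  hi <- scene@origin + (d - 0.5) * scene@spacing
  rbind(min = lo, max = hi)
}

#' @rdname vesselAccessors
#' @export
setMethod("labelVolume", "VesselScene", function(x) x@volume)

#' @rdname vesselAccessors
#' @export
setMethod("voxelSpacing", "VesselScene", function(x) x@spacing)

#' @rdname vesselAccessors
#' @export
setMethod("sceneOrigin", "VesselScene", function(x) x@origin)

#' @rdname vesselAccessors
#' @export
setMethod("labelMap", "VesselScene", function(x) x@labels)

#' @rdname vesselAccessors
#' @export
setMethod("centerlines", "VesselScene", function(x) x@centerlines)

#' @rdname vesselAccessors
#' @export
setMethod("centerline", "VesselScene", function(x, vessel) {
  if (!vessel %in% names(x@centerlines))
    stop(sprintf("no centerline for vessel '%s'; available: %s", vessel,
                 paste(names(x@centerlines), collapse = ", ")))
  x@centerlines[[vessel]]
})

setMethod("show", "VesselScene", function(object) {
  d <- dim(object@volume)
  counts <- tabulate(match(as.vector(object@volume), object@labels),
                     nbins = length(object@labels))
  cat(sprintf("VesselScene: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1L], d[2L], d[3L],
              object@spacing[1L], object@spacing[2L], object@spacing[3L]))
  cat("  labels:", paste(sprintf("%s=%d (%d vox)", names(object@labels),
                                 object@labels, counts), collapse = ", "), "\n")
  cat("  centerlines:", paste(names(object@centerlines), collapse = ", "), "\n")
})
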