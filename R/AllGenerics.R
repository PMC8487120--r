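#' Arc length of a polyline
#'
#' Sum of Euclidean segment lengths of an ordered polyline. For an aortic
#' centerline this is the 3D reference length against which the projected
#' length is compared by [foreshorteningRate()].
#'
#' @param x a [Centerline-class], a [ProjectedCenterline-class], or a numeric
#'   matrix of ordered point coordinates (one row per point).
#' @return numeric scalar, length in mm.
#' @examples
#' cl <- Centerline(rbind(c(0, 0, 0), c(0, 0, 10)), "aorta")
#' arcLength(cl)  # 10
#' @export
setGeneric("arcLength", function(x) standardGeneric("arcLength"))

#' @rdname vesselAccessors
#' @export
setGeneric("vesselLabel", function(x) standardGeneric("vesselLabel"))

#' @rdname vesselAccessors
#' @export
setGeneric("labelVolume", function(x) standardGeneric("labelVolume"))

#' @rdname vesselAccessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname vesselAccessors
#' @export
setGeneric("sceneOrigin", function(x) standardGeneric("sceneOrigin"))

#' @rdname vesselAccessors
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))

#' @rdname vesselAccessors
#' @export
setGeneric("centerlines", function(x) standardGeneric("centerlines"))

#' @rdname vesselAccessors
#' @export
setGeneric("centerline", function(x, vessel) standardGeneric("centerline"))
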