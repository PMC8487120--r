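# Scene bundle I/O. A bundle is a directory (or explicit file set) holding:
#   volume.nii.gz          integer label volume, axis-aligned affine
#   centerline_<vessel>.csv  one CSV per vessel, header x_mm,y_mm,z_mm
#   meta.json              label mapping + spacing/origin echo
# All coordinates are physical mm in the LPS frame shared with the volume.

#' Describe the files of a scene bundle
#'
#' @param dir bundle directory.
#' @param vessels vessel names with centerline files (used by [writeScene()];
#'   [readScene()] discovers them from the directory).
#' @return a list with elements `volume`, `centerlines` (named character
#'   vector) and `meta`.
#' @seealso [readScene()], [writeScene()]
#' @export
sceneBundlePaths <- function(dir, vessels = character()) {
  list(volume = file.path(dir, "volume.nii.gz"),
       centerlines = if (length(vessels))
         structure(file.path(dir, sprintf("centerline_%s.csv", vessels)),
                   names = vessels)
       else character(),
       meta = file.path(dir, "meta.json"))
}

#' Write a vessel scene to a file bundle
#'
#' Writes the label volume as NIfTI (axis-aligned affine built from spacing
#' and origin), one `centerline_<vessel>.csv` per centerline (header
#' `x_mm,y_mm,z_mm`, ordered proximal to distal) and a `meta.json` carrying
#' the label mapping. [readScene()] recovers the scene exactly up to float
#' round-off.
#'
#' @param scene a valid [VesselScene-class].
#' @param dir output directory (created if missing).
#' @return the bundle path list, invisibly.
#' @export
writeScene <- function(scene, dir) {
  validObject(scene)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop(sprintf("cannot create bundle directory '%s'", dir))
  paths <- sceneBundlePaths(dir, names(scene@centerlines))
  img <- RNifti::asNifti(scene@volume)
  RNifti::pixdim(img) <- scene@spacing
  aff <- rbind(cbind(diag(scene@spacing), scene@origin), c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, paths$volume)
  for (v in names(scene@centerlines)) {
    p <- scene@centerlines[[v]]@points
    utils::write.csv(as.data.frame(p), paths$centerlines[[v]],
                     row.names = FALSE, quote = FALSE)
  }
  meta <- list(labels = as.list(scene@labels),
               spacing = scene@spacing, origin = scene@origin,
               coordinate_frame = "LPS",
               centerline_labels = as.list(
                 vapply(scene@centerlines, vesselLabel, character(1L))))
  jsonlite::write_json(meta, paths$meta, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Read a vessel scene from a file bundle
#'
#' Reads a bundle written by [writeScene()] (or assembled by hand in the same
#' layout) and returns a validated [VesselScene-class]. The NIfTI affine must
#' be axis-aligned; oblique volumes are rejected. The volume must be
#' integer-valued and every label value present must appear in the bundle's
#' label mapping.
#'
#' @param bundle a bundle directory, or a path list as returned by
#'   [sceneBundlePaths()].
#' @return a [VesselScene-class].
#' @export
readScene <- function(bundle) {
  if (is.character(bundle)) {
    dir <- bundle
    cls <- list.files(dir, pattern = "^centerline_.*\\.csv$")
    vessels <- sub("^centerline_(.*)\\.csv$", "\\1", cls)
    bundle <- sceneBundlePaths(dir, vessels)
  }
  for (f in c(bundle$volume, bundle$meta, unname(bundle$centerlines)))
    if (!file.exists(f)) stop(sprintf("bundle file '%s' does not exist", f))
  img <- RNifti::readNifti(bundle$volume)
  aff <- RNifti::xform(img)
  if (max(abs(aff[1:3, 1:3] - diag(diag(aff[1:3, 1:3])))) > 1e-4)
    stop("oblique NIfTI affine: arcview requires axis-aligned volumes")
  if (any(diag(aff[1:3, 1:3]) <= 0))
    stop("NIfTI affine with non-positive scales is not supported")
  vol <- array(as.vector(as.array(img)), dim = dim(img))
  if (!is.integer(vol)) {
    if (max(abs(vol - round(vol))) > 1e-6)
      stop("volume is not integer-valued: not a label volume")
    storage.mode(vol) <- "integer"
  }
  spacing <- diag(aff[1:3, 1:3])
  origin <- aff[1:3, 4L]
  meta <- jsonlite::read_json(bundle$meta, simplifyVector = TRUE)
  if (is.null(meta$labels)) stop("meta.json lacks a 'labels' mapping")
  labels <- vapply(meta$labels, as.integer, integer(1L))
  cls <- lapply(names(bundle$centerlines), function(v) {
    p <- utils::read.csv(bundle$centerlines[[v]])
    if (!all(c("x_mm", "y_mm", "z_mm") %in% names(p)))
      stop(sprintf("centerline file for '%s' lacks x_mm,y_mm,z_mm columns", v))
    if (nrow(p) < 2L)
      stop(sprintf("centerline for vessel '%s' has fewer than 2 points", v))
    Centerline(p[, c("x_mm", "y_mm", "z_mm")], v)
  })
  names(cls) <- names(bundle$centerlines)
  scene <- VesselScene(vol, spacing = spacing, origin = origin,
                       labels = labels, centerlines = cls)
  validObject(scene)
  scene
}
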