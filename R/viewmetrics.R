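# The two per-angle scores. Overlap rate: intersection pixel count of the
# two branch silhouettes over the sum of their pixel counts (range 0..0.5,
# exact integer arithmetic). Foreshortening rate: projected aortic
# centerline length over its 3D length (1 = no foreshortening).

#' Projection overlapping rate of the two branch silhouettes
#'
#' `NP(S_LCCA n S_LSA) / (NP(S_LCCA) + NP(S_LSA))` by exact pixel counting,
#' where `NP` is the number of set pixels. Ranges from 0 (disjoint) to 0.5
#' (identical non-empty masks). When both masks are empty the ratio is
#' undefined; an empty silhouette cannot overlap anything, so 0 is returned
#' with a warning.
#'
#' @param maskLCCA,maskLSA two [ProjectionMask-class] objects of equal shape
#'   and sweep angle.
#' @return a list with elements `pOverlap`, `nLCCA`, `nLSA`,
#'   `nIntersection`, `theta`.
#' @examples
#' m <- new("ProjectionMask", mask = matrix(c(TRUE, TRUE, FALSE, FALSE), 2),
#'          label = "LCCA", theta = 0, pixelSize = 1)
#' overlapRate(m, initialize(m, label = "LSA"))$pOverlap  # identical: 0.5
#' @export
overlapRate <- function(maskLCCA, maskLSA) {
  if (!identical(dim(maskLCCA@mask), dim(maskLSA@mask)))
    stop("masks have different shapes")
  if (maskLCCA@theta != maskLSA@theta)
    stop("masks were projected at different sweep angles")
  nA <- sum(maskLCCA@mask)
  nB <- sum(maskLSA@mask)
  nI <- sum(maskLCCA@mask & maskLSA@mask)
  if (nA + nB == 0L) {
    warning("both silhouettes are empty; overlap rate undefined, returning 0")
    p <- 0
  } else p <- nI / (nA + nB)
  list(pOverlap = p, nLCCA = nA, nLSA = nB, nIntersection = nI,
       theta = maskLCCA@theta)
}

#' Projection foreshortening rate of a centerline
#'
#' Ratio of the projected centerline length at the given view to its 3D
#' length. Both lengths are polyline sums over the centerline's segments.
#' The default numerator is the detector-plane length, i.e. per segment the
#' in-plane tangent component `||t - (t . P)P||` (P the unit ray): the rate
#' is 1 exactly when no segment has a component along the ray, and
#' `sin(alpha)` for a straight segment at angle `alpha` to the ray. The
#' `"alongRay"` variant instead sums the along-ray components `|t . P|`,
#' the literal complement, kept for auditability; the two satisfy a
#' per-segment Pythagorean identity.
#'
#' @param cl a [Centerline-class] (typically the aorta).
#' @param geom a [ProjectionGeometry-class].
#' @param variant `"projected"` (default) or `"alongRay"`.
#' @return a list with elements `pFs`, `projectedLength` (mm, per the chosen
#'   variant), `length3d` (mm), `theta`, `variant`.
#' @examples
#' g <- geometryForAngle(0, 1, c(8L, 8L))
#' seg <- Centerline(rbind(c(0, 0, 0), c(10, 0, 0)), "aorta")
#' foreshorteningRate(seg, g)$pFs  # segment orthogonal to the ray: 1
#' @export
foreshorteningRate <- function(cl, geom, variant = c("projected", "alongRay")) {
  variant <- match.arg(variant)
  len3 <- arcLength(cl)
  if (len3 <= 0) stop("centerline has zero length")
  p <- cl@points
  seg <- p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
  along <- abs(seg %*% geom@rayDir)
  num <- if (variant == "projected") {
    inplane2 <- rowSums(seg^2) - along^2
    sum(sqrt(pmax(inplane2, 0)))
  } else sum(along)
  list(pFs = num / len3, projectedLength = num, length3d = len3,
       theta = geom@theta, variant = variant)
}

#' Assemble a per-angle metric profile
#'
#' @param thetas strictly increasing angles (degrees) in \[0, 90\].
#' @param pOverlap,pFs per-angle metric values.
#' @param counts optional integer matrix of silhouette pixel counts
#'   (columns `nLCCA`, `nLSA`, `nIntersection`).
#' @return an [AngleProfile-class].
#' @seealso [sweepAngles()] computes a profile from a scene.
#' @export
AngleProfile <- function(thetas, pOverlap, pFs,
                         counts = matrix(integer(), 0L, 3L)) {
  colnames(counts) <- c("nLCCA", "nLSA", "nIntersection")
  new("AngleProfile", thetas = as.numeric(thetas),
      pOverlap = as.numeric(pOverlap), pFs = as.numeric(pFs),
      counts = counts)
}

#' @describeIn AngleProfile number of grid angles.
#' @param x an [AngleProfile-class].
#' @export
setMethod("length", "AngleProfile", function(x) length(x@thetas))

#' @describeIn AngleProfile profile as a data frame with columns
#'   `theta_deg`, `p_overlap`, `p_fs`.
#' @param row.names,optional,... passed conventions of
#'   [base::as.data.frame()]; ignored.
#' @export
setMethod("as.data.frame", "AngleProfile",
          function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(theta_deg = x@thetas, p_overlap = x@pOverlap, p_fs = x@pFs)
})

setMethod("show", "AngleProfile", function(object) {
  cat(sprintf("AngleProfile: %d angles in [%.1f, %.1f] deg\n",
              length(object@thetas), min(object@thetas), max(object@thetas)))
  nz <- sum(object@pOverlap == 0)
  cat(sprintf("  overlap-free angles: %d; max p_fs = %.4f at %.1f deg\n",
              nz, max(object@pFs),
              object@thetas[which.max(object@pFs)]))
})

#' Write / read an angle profile as CSV
#'
#' CSV dialect: header `theta_deg,p_overlap,p_fs`, one row per grid angle
#' (pixel counts, if present, are appended as extra columns and recovered on
#' read).
#'
#' @param profile an [AngleProfile-class].
#' @param path CSV file path.
#' @return `writeProfile` returns `path` invisibly; `readProfile` the
#'   profile.
#' @export
writeProfile <- function(profile, path) {
  df <- as.data.frame(profile)
  if (nrow(profile@counts)) df <- cbind(df, profile@counts)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeProfile
#' @export
readProfile <- function(path) {
  df <- utils::read.csv(path)
  need <- c("theta_deg", "p_overlap", "p_fs")
  if (!all(need %in% names(df)))
    stop("profile CSV lacks theta_deg,p_overlap,p_fs columns")
  counts <- if (all(c("nLCCA", "nLSA", "nIntersection") %in% names(df)))
    as.matrix(df[, c("nLCCA", "nLSA", "nIntersection")])
  else matrix(integer(), 0L, 3L)
  AngleProfile(df$theta_deg, df$p_overlap, df$p_fs, counts)
}

#' Tabulate overlap and foreshortening over the C-arm sweep
#'
#' For each grid angle: project the LCCA and LSA silhouettes (one shared
#' detector per angle), compute their overlap rate, and compute the
#' foreshortening rate of the aorta centerline. Deterministic: repeated
#' calls yield bit-identical profiles.
#'
#' @param scene a [VesselScene-class] with both branch labels and an aorta
#'   centerline.
#' @param thetas sweep grid (degrees), default 0-90 in 1-degree steps
#'   (clinical C-arm granularity).
#' @param pixelSize detector pixel size in mm; default the scene's minimum
#'   voxel spacing.
#' @param fsVariant numerator variant for [foreshorteningRate()].
#' @return an [AngleProfile-class] with silhouette pixel counts attached.
#' @export
sweepAngles <- function(scene, thetas = seq(0, 90, by = 1),
                        pixelSize = min(voxelSpacing(scene)),
                        fsVariant = "projected") {
  validObject(scene)
  for (lb in c("LCCA", "LSA"))
    if (!lb %in% names(scene@labels))
      stop(sprintf("scene lacks the '%s' label", lb))
  aorta <- centerline(scene, "aorta")
  n <- length(thetas)
  pov <- numeric(n); pfs <- numeric(n)
  counts <- matrix(0L, n, 3L)
  for (i in seq_len(n)) {
    g <- sceneGeometry(scene, thetas[i], pixelSize)
    ov <- overlapRate(projectLabel(scene, "LCCA", g),
                      projectLabel(scene, "LSA", g))
    pov[i] <- ov$pOverlap
    counts[i, ] <- c(ov$nLCCA, ov$nLSA, ov$nIntersection)
    pfs[i] <- foreshorteningRate(aorta, g, fsVariant)$pFs
  }
  AngleProfile(thetas, pov, pfs, counts)
}
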