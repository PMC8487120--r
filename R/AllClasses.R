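# Central S4 classes. All physical coordinates are millimetres in the LPS
# patient frame (+x left, +y posterior, +z superior); voxel index -> mm is the
# axis-aligned affine  origin + index * spacing  (0-based indices).

#' Vessel centerline
#'
#' An ordered 3D polyline tracing one vessel, in physical millimetres (LPS
#' patient frame). The polyline must have at least two points and no
#' zero-length segment, so its arc length is strictly positive.
#'
#' @slot points numeric matrix, one row per point, columns `x_mm`, `y_mm`,
#'   `z_mm`, ordered proximal to distal.
#' @slot label character scalar, which vessel the curve traces
#'   (`"aorta"`, `"LCCA"` or `"LSA"`).
#' @seealso [Centerline()], [arcLength()], [projectCenterline()]
#' @export
setClass("Centerline",
  representation(points = "matrix", label = "character"))

setValidity("Centerline", function(object) {
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 3L)
    return("points must be a numeric matrix with 3 columns")
  if (anyNA(p) || any(!is.finite(p)))
    return("points must be finite")
  if (nrow(p) < 2L)
    return("a centerline needs at least 2 points")
  seg <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  if (any(seg <= 0))
    return("consecutive centerline points must be distinct")
  if (length(object@label) != 1L || is.na(object@label) || !nzchar(object@label))
    return("label must be a non-empty character scalar")
  TRUE
})

#' Labeled vessel scene
#'
#' A 3D integer label volume together with the vessel centerlines, all in one
#' physical coordinate frame (LPS, millimetres). Label semantics follow the
#' convention background = 0, aorta = 1, LCCA = 2, LSA = 3, carried explicitly
#' in the `labels` map so files remain self-describing.
#'
#' @slot volume 3D integer array of label values.
#' @slot spacing numeric(3), voxel size in mm per axis (all > 0).
#' @slot origin numeric(3), physical position in mm of voxel (0,0,0).
#' @slot labels named integer vector mapping semantic names to label values;
#'   every value present in `volume` must appear here.
#' @slot centerlines named list of [Centerline-class] objects; an `"aorta"`
#'   entry is required and must lie inside the volume's bounding box.
#' @seealso [VesselScene()], [readScene()], [writeScene()], [generatePhantom()]
#' @export
setClass("VesselScene",
  representation(volume = "array", spacing = "numeric", origin = "numeric",
                 labels = "integer", centerlines = "list"))

setValidity("VesselScene", function(object) {
  v <- object@volume
  if (length(dim(v)) != 3L) return("volume must be a 3D array")
  if (!is.integer(v)) return("volume must be integer-valued (storage mode integer)")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite values (mm)")
  if (is.null(names(object@labels)) || any(!nzchar(names(object@labels))))
    return("labels must be a named integer vector")
  present <- sort(unique(as.vector(v)))
  unknown <- setdiff(present, object@labels)
  if (length(unknown))
    return(sprintf("volume contains label value(s) %s absent from the label mapping",
                   paste(unknown, collapse = ", ")))
  cls <- object@centerlines
  if (length(cls)) {
    if (is.null(names(cls)) || any(!nzchar(names(cls))))
      return("centerlines must be a named list")
    ok <- vapply(cls, is, logical(1L), class2 = "Centerline")
    if (!all(ok)) return("centerlines must all be Centerline objects")
  }
  if (!"aorta" %in% names(cls))
    return("an 'aorta' centerline is required")
  bb <- sceneBoundingBox(object)
  pa <- cls[["aorta"]]@points
  eps <- 1e-6
  inside <- all(sweep(pa, 2L, bb[1L, ]) >= -eps) &&
            all(sweep(pa, 2L, bb[2L, ]) <= eps)
  if (!inside)
    return("centerline for vessel 'aorta' lies outside the volume bounding box")
  TRUE
})

#' Parallel-beam projection geometry
#'
#' The C-arm frame for one sweep angle theta (degrees). Theta is the LAO
#' rotation about the patient's superior-inferior axis: theta = 0 is the AP
#' view with ray direction (0, 1, 0) in LPS, theta = 90 views from the
#' patient's left with ray (1, 0, 0). The detector axes are
#' `detectorU = (cos theta, -sin theta, 0)` and `detectorV = (0, 0, -1)`
#' (image-up = superior). Projection is orthographic: a 3D point p maps to
#' detector coordinates (p . detectorU, p . detectorV) in mm.
#'
#' @slot theta numeric scalar, sweep angle in degrees, in \[0, 90\].
#' @slot rayDir numeric(3), unit projection direction.
#' @slot detectorU,detectorV numeric(3), orthonormal detector axes.
#' @slot pixelSize numeric scalar, detector pixel size in mm.
#' @slot detectorShape integer(2), pixel counts along u and v.
#' @slot detectorOrigin numeric(2), detector-plane coordinate (mm) of the
#'   lower corner of pixel (1,1); pixel (i,j) has center
#'   `detectorOrigin + (i - 0.5, j - 0.5) * pixelSize`.
#' @seealso [geometryForAngle()], [sceneGeometry()]
#' @export
setClass("ProjectionGeometry",
  representation(theta = "numeric", rayDir = "numeric", detectorU = "numeric",
                 detectorV = "numeric", pixelSize = "numeric",
                 detectorShape = "integer", detectorOrigin = "numeric"))

setValidity("ProjectionGeometry", function(object) {
  if (length(object@theta) != 1L || object@theta < 0 || object@theta > 90)
    return("theta must be a scalar in [0, 90] degrees")
  for (nm in c("rayDir", "detectorU", "detectorV"))
    if (length(slot(object, nm)) != 3L || any(!is.finite(slot(object, nm))))
      return(sprintf("%s must be a finite 3-vector", nm))
  tol <- 1e-9
  r <- object@rayDir; u <- object@detectorU; v <- object@detectorV
  if (abs(sum(r^2) - 1) > tol || abs(sum(u^2) - 1) > tol || abs(sum(v^2) - 1) > tol)
    return("rayDir, detectorU, detectorV must be unit vectors")
  if (abs(sum(r * u)) > tol || abs(sum(r * v)) > tol || abs(sum(u * v)) > tol)
    return("rayDir, detectorU, detectorV must be mutually orthogonal")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    return("pixelSize must be a positive scalar (mm)")
  if (length(object@detectorShape) != 2L || any(object@detectorShape < 1L))
    return("detectorShape must be two positive pixel counts")
  if (length(object@detectorOrigin) != 2L || any(!is.finite(object@detectorOrigin)))
    return("detectorOrigin must be a finite 2-vector (mm)")
  TRUE
})

#' Binary silhouette of one vessel label
#'
#' The orthographic silhouette of a single label at one sweep angle: detector
#' pixel (i,j) is `TRUE` iff the parallel ray through its center passes
#' through at least one voxel carrying that label.
#'
#' @slot mask logical matrix (u along rows, v along columns).
#' @slot label character scalar, the projected vessel name.
#' @slot theta numeric scalar, sweep angle in degrees.
#' @slot pixelSize numeric scalar, mm.
#' @seealso [projectLabel()], [overlapRate()]
#' @export
setClass("ProjectionMask",
  representation(mask = "matrix", label = "character", theta = "numeric",
                 pixelSize = "numeric"))

setValidity("ProjectionMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be a logical matrix")
  if (anyNA(object@mask)) return("mask must not contain NA")
  if (length(object@theta) != 1L) return("theta must be scalar")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    return("pixelSize must be a positive scalar")
  TRUE
})

#' Projected centerline
#'
#' A [Centerline-class] mapped into detector-plane coordinates (mm) by an
#' orthographic projection; same point count and order as its 3D source.
#'
#' @slot points2d numeric matrix, one row per point, columns `u_mm`, `v_mm`.
#' @slot theta numeric scalar, sweep angle in degrees.
#' @seealso [projectCenterline()], [foreshorteningRate()]
#' @export
setClass("ProjectedCenterline",
  representation(points2d = "matrix", theta = "numeric"))

setValidity("ProjectedCenterline", function(object) {
  if (!is.numeric(object@points2d) || ncol(object@points2d) != 2L)
    return("points2d must be a numeric matrix with 2 columns")
  if (anyNA(object@points2d)) return("points2d must be finite")
  TRUE
})

#' Per-angle metric profile over the C-arm sweep
#'
#' The tabulation produced by [sweepAngles()]: for every angle on the sweep
#' grid, the branch projection overlapping rate and the aortic-centerline
#' projection foreshortening rate, plus the raw silhouette pixel counts the
#' overlap rate was computed from.
#'
#' @slot thetas numeric vector, strictly increasing grid in \[0, 90\] degrees.
#' @slot pOverlap numeric vector, overlap rate per angle (0 to 0.5).
#' @slot pFs numeric vector, foreshortening rate per angle (0 to 1).
#' @slot counts integer matrix with columns `nLCCA`, `nLSA`, `nIntersection`
#'   (silhouette pixel counts per angle); may have zero rows for profiles
#'   assembled directly from metric vectors.
#' @seealso [sweepAngles()], [AngleProfile()], [adaptiveSelect()],
#'   [standardSelect()]
#' @export
setClass("AngleProfile",
  representation(thetas = "numeric", pOverlap = "numeric", pFs = "numeric",
                 counts = "matrix"))

setValidity("AngleProfile", function(object) {
  n <- length(object@thetas)
  if (n < 1L) return("profile must contain at least one angle")
  if (length(object@pOverlap) != n || length(object@pFs) != n)
    return("thetas, pOverlap and pFs must have equal length")
  if (any(!is.finite(object@thetas)) || any(diff(object@thetas) <= 0))
    return("thetas must be strictly increasing")
  if (object@thetas[1L] < 0 || object@thetas[n] > 90)
    return("thetas must lie within [0, 90] degrees")
  if (any(object@pOverlap < 0 | object@pOverlap > 0.5))
    return("pOverlap must lie in [0, 0.5]")
  if (any(object@pFs < -1e-9 | object@pFs > 1 + 1e-9))
    return("pFs must lie in [0, 1] up to discretization tolerance")
  if (nrow(object@counts) && nrow(object@counts) != n)
    return("counts must have one row per angle (or none)")
  TRUE
})

#' Parametric aortic-arch phantom specification
#'
#' Full description of a synthetic arch scene: a semicircular arch midline of
#' radius `archRadius` lying in a plane whose normal is the ray direction at
#' LAO angle `archPlaneLao` (so that sweep angle is the arch-perpendicular,
#' minimum-foreshortening view), joined to straight vertical ascending and
#' descending limbs; two straight branch tubes (LCCA, LSA) leave the arch
#' midline at angular positions `branchAngles` (degrees along the semicircle,
#' 0 = ascending end, 90 = apex, 180 = descending end), directed radially
#' outward and tilted out of the arch plane by `branchTilt` degrees in
#' opposite directions (LCCA anterior, LSA posterior). The opposed tilt
#' controls at which sweep angles the branch silhouettes overlap.
#'
#' @slot archRadius numeric, arch midline radius (mm).
#' @slot tubeRadiusAorta numeric, aorta tube radius (mm).
#' @slot tubeRadiusBranch numeric, branch tube radius (mm), < aorta radius.
#' @slot archPlaneLao numeric, LAO angle (degrees) at which the X-ray is
#'   perpendicular to the arch plane.
#' @slot branchAngles numeric(2), angular positions (degrees) of LCCA and LSA
#'   origins along the arch midline; must be distinct.
#' @slot branchLength numeric, branch tube length (mm).
#' @slot branchTilt numeric, out-of-plane tilt (degrees) of each branch.
#' @slot ascendingLength,descendingLength numeric, straight limb lengths (mm).
#' @slot gridShape integer(3), voxel counts per axis.
#' @slot spacing numeric(3), voxel size (mm) per axis.
#' @seealso [PhantomSpec()], [generatePhantom()], [sampleCohort()]
#' @export
setClass("PhantomSpec",
  representation(archRadius = "numeric", tubeRadiusAorta = "numeric",
                 tubeRadiusBranch = "numeric", archPlaneLao = "numeric",
                 branchAngles = "numeric", branchLength = "numeric",
                 branchTilt = "numeric", ascendingLength = "numeric",
                 descendingLength = "numeric", gridShape = "integer",
                 spacing = "numeric"))

setValidity("PhantomSpec", function(object) {
  sc <- function(x) length(x) == 1L && is.finite(x)
  if (!sc(object@archRadius) || object@archRadius <= 0)
    return("archRadius must be a positive scalar (mm)")
  if (!sc(object@tubeRadiusAorta) || object@tubeRadiusAorta <= 0)
    return("tubeRadiusAorta must be a positive scalar (mm)")
  if (!sc(object@tubeRadiusBranch) || object@tubeRadiusBranch <= 0)
    return("tubeRadiusBranch must be a positive scalar (mm)")
  if (object@tubeRadiusBranch >= object@tubeRadiusAorta)
    return("branch tubes must be thinner than the aorta tube")
  if (!sc(object@archPlaneLao) || object@archPlaneLao < 0 || object@archPlaneLao > 90)
    return("archPlaneLao must be in [0, 90] degrees")
  if (length(object@branchAngles) != 2L || any(!is.finite(object@branchAngles)))
    return("branchAngles must be two finite angles (degrees)")
  if (object@branchAngles[1L] == object@branchAngles[2L])
    return("the two branch origins must be distinct")
  if (any(object@branchAngles < 0 | object@branchAngles > 180))
    return("branchAngles must lie in [0, 180] degrees along the arch")
  if (!sc(object@branchLength) || object@branchLength <= 0)
    return("branchLength must be a positive scalar (mm)")
  if (!sc(object@branchTilt) || abs(object@branchTilt) >= 90)
    return("branchTilt must be a scalar in (-90, 90) degrees")
  if (!sc(object@ascendingLength) || object@ascendingLength <= 0 ||
      !sc(object@descendingLength) || object@descendingLength <= 0)
    return("ascendingLength and descendingLength must be positive (mm)")
  if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
    return("gridShape must be three voxel counts >= 8")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 positive voxel sizes (mm)")
  ext <- phantomExtent(object)
  grid <- object@gridShape * object@spacing
  if (any(ext > grid))
    return(sprintf("phantom extent (%.0f x %.0f x %.0f mm) exceeds grid extent (%.0f x %.0f x %.0f mm)",
                   ext[1L], ext[2L], ext[3L], grid[1L], grid[2L], grid[3L]))
  TRUE
})

#' Result of the standard joint-minimization selector
#'
#' @slot thetaStandard numeric, selected angle (degrees, on the sweep grid).
#' @slot objectiveValue numeric, objective value at the selected angle.
#' @slot objectiveVariant character, `"corrected"` for
#'   `P_overlap + (1 - P_fs)` or `"literal"` for the printed
#'   `P_overlap + P_fs`.
#' @seealso [standardSelect()]
#' @export
setClass("StandardSelection",
  representation(thetaStandard = "numeric", objectiveValue = "numeric",
                 objectiveVariant = "character"))

#' Result of the adaptive overlap-then-foreshortening selector
#'
#' Records the selected angle together with every intermediate set of the
#' two-step rule, which tolerance tier fired, and whether a fallback was
#' needed when the overlap-free and foreshortening-tolerant sets failed to
#' intersect.
#'
#' @slot thetaOptimal numeric, selected angle (degrees, on the sweep grid).
#' @slot thetaNoOverlap numeric vector, grid angles with exactly zero overlap.
#' @slot thetaFsSet numeric vector, grid angles passing the adaptive
#'   foreshortening criterion.
#' @slot thetaFsmin numeric, smallest grid angle attaining the maximum
#'   foreshortening rate.
#' @slot pFsmax numeric, the maximum foreshortening rate on the grid.
#' @slot branch character, which tier of the adaptive rule fired:
#'   `"<=50"`, `"50-60"` or `">60"`.
#' @slot fallbackUsed character, `"none"`, `"tier-relaxation"` or
#'   `"min-overlap"`.
#' @seealso [adaptiveSelect()], [adaptiveFsSet()], [noOverlapSet()]
#' @export
setClass("AdaptiveSelection",
  representation(thetaOptimal = "numeric", thetaNoOverlap = "numeric",
                 thetaFsSet = "numeric", thetaFsmin = "numeric",
                 pFsmax = "numeric", branch = "character",
                 fallbackUsed = "character"))

#' Cohort comparison of two angle sets
#'
#' Output of [compareAngleSets()]: per-group summaries, the normality-gated
#' two-sample test, the paired absolute differences and their proportions in
#' the 0-3, 3-5 and >= 5 degree bins.
#'
#' @slot meanA,meanB,sdA,sdB numeric, per-group mean and SD (degrees).
#' @slot pValue numeric, two-sided p-value of the gated test.
#' @slot testUsed character, `"t-test"` or `"Mann-Whitney U"`.
#' @slot shapiroP numeric(2), Shapiro-Wilk p-values of the two samples
#'   (NA when a sample is constant, which fails the normality gate).
#' @slot absDifferences numeric vector, per-case `|a - b|` (degrees).
#' @slot bins numeric vector, proportions per difference bin (sums to 1).
#' @slot alpha numeric, significance level used for both the gate and the
#'   test.
#' @seealso [compareAngleSets()], [differenceBins()]
#' @export
setClass("AngleComparison",
  representation(meanA = "numeric", meanB = "numeric", sdA = "numeric",
                 sdB = "numeric", pValue = "numeric", testUsed = "character",
                 shapiroP = "numeric", absDifferences = "numeric",
                 bins = "numeric", alpha = "numeric"))
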