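# Angle selection. Two selectors over an AngleProfile:
#  * standardSelect: joint minimization of overlap + foreshortening penalty;
#  * adaptiveSelect: the two-step rule — restrict to exactly-overlap-free
#    angles, bound foreshortening adaptively by where its optimum lies, and
#    take the smallest angle in the intersection.
# All ties break toward the smallest grid angle; angles are reported on the
# grid (clinical C-arm granularity, no sub-grid interpolation).

#' Joint-minimization baseline selector
#'
#' The `"corrected"` variant (default) minimizes
#' `P_overlap(theta) + (1 - P_fs(theta))`, penalizing overlap and
#' foreshortening jointly. The `"literal"` variant minimizes
#' `P_overlap(theta) + P_fs(theta)`; with the length-ratio definition of the
#' foreshortening rate that sum rewards foreshortening, so it is kept only
#' for auditability. Ties break toward the smallest angle. The result
#' carries no overlap-free guarantee — see [adaptiveSelect()].
#'
#' @param profile an [AngleProfile-class].
#' @param variant `"corrected"` or `"literal"`.
#' @return a [StandardSelection-class].
#' @examples
#' pr <- AngleProfile(c(0, 45, 90), pOverlap = c(0.2, 0, 0.1),
#'                    pFs = c(0.9, 0.8, 0.7))
#' standardSelect(pr)@thetaStandard  # 45
#' @export
standardSelect <- function(profile, variant = c("corrected", "literal")) {
  variant <- match.arg(variant)
  if (length(profile@thetas) == 0L) stop("empty profile")
  obj <- if (variant == "corrected") profile@pOverlap + (1 - profile@pFs)
         else profile@pOverlap + profile@pFs
  # ties (at float tolerance) break toward the smallest angle
  i <- which(obj <= min(obj) + 1e-12)[1L]
  new("StandardSelection", thetaStandard = profile@thetas[i],
      objectiveValue = obj[i], objectiveVariant = variant)
}

#' Angles with exactly zero branch overlap
#'
#' The set of grid angles where the overlap rate is exactly 0. Integer pixel
#' counting makes exact zero meaningful; an empty set is a legal return.
#'
#' @param profile an [AngleProfile-class].
#' @return numeric vector of grid angles (possibly empty).
#' @export
noOverlapSet <- function(profile) {
  profile@thetas[profile@pOverlap == 0]
}

#' Adaptive foreshortening-tolerance set
#'
#' Let `thetaFsmin` be the smallest grid angle attaining the maximum
#' foreshortening rate `pFsmax`. The tolerated set depends on where that
#' optimum lies: at or below 50 degrees the set is the singleton
#' `{thetaFsmin}`; between 50 and 60 degrees, all angles with
#' `pFs > 0.98 * pFsmax` (strict); above 60 degrees, all angles with
#' `pFs > 0.95 * pFsmax`. The widening tiers trade a little arch display for
#' a clinically workable gantry angle when the geometrically ideal view is
#' steep.
#'
#' @param profile an [AngleProfile-class].
#' @return a list with `thetaFsSet` (numeric vector), `thetaFsmin`,
#'   `pFsmax`, and `branch` (`"<=50"`, `"50-60"` or `">60"`).
#' @export
adaptiveFsSet <- function(profile) {
  if (length(profile@thetas) == 0L) stop("empty profile")
  pFsmax <- max(profile@pFs)
  thetaFsmin <- profile@thetas[which.max(profile@pFs)]  # first max
  if (thetaFsmin <= 50) {
    branch <- "<=50"
    set <- thetaFsmin
  } else if (thetaFsmin <= 60) {
    branch <- "50-60"
    set <- profile@thetas[profile@pFs > 0.98 * pFsmax]
  } else {
    branch <- ">60"
    set <- profile@thetas[profile@pFs > 0.95 * pFsmax]
  }
  list(thetaFsSet = set, thetaFsmin = thetaFsmin, pFsmax = pFsmax,
       branch = branch)
}

#' Adaptive optimal-view selection
#'
#' Intersects the overlap-free set ([noOverlapSet()]) with the adaptive
#' foreshortening set ([adaptiveFsSet()]) and returns the smallest angle of
#' the intersection. Overlap avoidance is the hard clinical constraint, so
#' when the intersection is empty a conservative fallback ladder keeps the
#' function total:
#'
#' 1. tier relaxation: widen the foreshortening set to the 98% tier, then
#'    the 95% tier (re-intersecting each time); if still empty, take the
#'    overlap-free angle with maximal foreshortening rate. Reported as
#'    `fallbackUsed = "tier-relaxation"`.
#' 2. only when no angle is overlap-free at all: take the angle minimizing
#'    the overlap rate, ties by larger foreshortening rate, then smaller
#'    angle (`fallbackUsed = "min-overlap"`).
#'
#' @param profile an [AngleProfile-class].
#' @return an [AdaptiveSelection-class].
#' @examples
#' pr <- AngleProfile(40:60, pOverlap = c(rep(0.1, 8), rep(0, 13)),
#'                    pFs = 1 - abs(40:60 - 45) / 100)
#' adaptiveSelect(pr)  # fs optimum at 45, first overlap-free angle 48
#' @export
adaptiveSelect <- function(profile) {
  noOv <- noOverlapSet(profile)
  fs <- adaptiveFsSet(profile)
  pick <- intersect(fs$thetaFsSet, noOv)
  fallback <- "none"
  if (!length(pick) && length(noOv)) {
    fallback <- "tier-relaxation"
    for (tier in c(0.98, 0.95)) {
      cand <- intersect(profile@thetas[profile@pFs > tier * fs$pFsmax], noOv)
      if (length(cand)) { pick <- cand; break }
    }
    if (!length(pick)) {
      iNo <- match(noOv, profile@thetas)
      pick <- noOv[which.max(profile@pFs[iNo])]
    }
  }
  if (!length(pick)) {
    fallback <- "min-overlap"
    ord <- order(profile@pOverlap, -profile@pFs, profile@thetas)
    pick <- profile@thetas[ord[1L]]
  }
  new("AdaptiveSelection", thetaOptimal = min(pick),
      thetaNoOverlap = noOv, thetaFsSet = fs$thetaFsSet,
      thetaFsmin = fs$thetaFsmin, pFsmax = fs$pFsmax, branch = fs$branch,
      fallbackUsed = fallback)
}

setMethod("show", "AdaptiveSelection", function(object) {
  cat(sprintf(paste0(
    "AdaptiveSelection: theta_optimal = %.1f deg\n",
    "  overlap-free angles: %d; theta_fsmin = %.1f (p_fsmax = %.4f), tier %s\n",
    "  fallback: %s\n"),
    object@thetaOptimal, length(object@thetaNoOverlap), object@thetaFsmin,
    object@pFsmax, object@branch, object@fallbackUsed))
})

setMethod("show", "StandardSelection", function(object) {
  cat(sprintf("StandardSelection (%s): theta_standard = %.1f deg (objective %.4f)\n",
              object@objectiveVariant, object@thetaStandard,
              object@objectiveValue))
})

#' Run the full per-patient pipeline on a scene
#'
#' Sweeps the metric profile, then applies both selectors: one call
#' reproduces the per-case pipeline end to end (simulate, score, select).
#'
#' @inheritParams sweepAngles
#' @param variant objective variant for [standardSelect()].
#' @return a list with elements `adaptive` ([AdaptiveSelection-class]),
#'   `standard` ([StandardSelection-class]) and `profile`
#'   ([AngleProfile-class]).
#' @export
selectForScene <- function(scene, thetas = seq(0, 90, by = 1),
                           pixelSize = min(voxelSpacing(scene)),
                           variant = "corrected") {
  profile <- sweepAngles(scene, thetas, pixelSize)
  list(adaptive = adaptiveSelect(profile),
       standard = standardSelect(profile, variant),
       profile = profile)
}
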