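# Independent brute-force implementation of the two-step selection logic,
# written as literal set enumeration (loops, no vectorized shortcuts) so it
# shares no code path with adaptiveSelect().
oracleAdaptive <- function(thetas, pov, pfs) {
  noOverlap <- c()
  for (i in seq_along(thetas)) if (pov[i] == 0) noOverlap <- c(noOverlap, thetas[i])
  pmax <- -Inf
  for (i in seq_along(thetas)) if (pfs[i] > pmax) pmax <- pfs[i]
  fsmin <- NA
  for (i in seq_along(thetas)) if (pfs[i] == pmax) { fsmin <- thetas[i]; break }
  collectTier <- function(frac) {
    s <- c()
    for (i in seq_along(thetas)) if (pfs[i] > frac * pmax) s <- c(s, thetas[i])
    s
  }
  if (fsmin <= 50) { fset <- c(fsmin); branch <- "<=50" }
  else if (fsmin <= 60) { fset <- collectTier(0.98); branch <- "50-60" }
  else { fset <- collectTier(0.95); branch <- ">60" }
  inter <- c()
  for (t in fset) if (t %in% noOverlap) inter <- c(inter, t)
  fallback <- "none"
  if (length(inter) == 0 && length(noOverlap) > 0) {
    fallback <- "tier-relaxation"
    for (frac in c(0.98, 0.95)) {
      cand <- collectTier(frac)
      inter <- c()
      for (t in cand) if (t %in% noOverlap) inter <- c(inter, t)
      if (length(inter) > 0) break
    }
    if (length(inter) == 0) {
      best <- noOverlap[1]; bestFs <- -Inf
      for (t in noOverlap) {
        i <- which(thetas == t)
        if (pfs[i] > bestFs) { bestFs <- pfs[i]; best <- t }
      }
      inter <- c(best)
    }
  }
  if (length(inter) == 0) {
    fallback <- "min-overlap"
    best <- thetas[1]; bestOv <- Inf; bestFs <- -Inf
    for (i in seq_along(thetas)) {
      better <- pov[i] < bestOv ||
        (pov[i] == bestOv && pfs[i] > bestFs) ||
        (pov[i] == bestOv && pfs[i] == bestFs && thetas[i] < best)
      if (better) { bestOv <- pov[i]; bestFs <- pfs[i]; best <- thetas[i] }
    }
    inter <- c(best)
  }
  list(theta = min(inter), branch = branch, fallback = fallback)
}

# Randomized synthetic profiles spanning all adaptive branches and fallback
# tiers: unimodal foreshortening curves with a random peak location/width,
# overlap curves that are zero on a random angle window, everywhere positive,
# or zero everywhere; occasional flat/degenerate shapes.
randomProfile <- function() {
  thetas <- seq(0, 90, by = sample(c(1, 2, 3, 5), 1))
  n <- length(thetas)
  shape <- sample(1:4, 1)
  if (shape == 1) {          # smooth unimodal peak anywhere in the sweep
    peak <- runif(1, 0, 90); width <- runif(1, 8, 60)
    pfs <- 0.55 + 0.45 * exp(-((thetas - peak) / width)^2)
  } else if (shape == 2) {   # sharp peak (often a singleton tier)
    peak <- runif(1, 0, 90)
    pfs <- 0.6 + 0.4 / (1 + ((thetas - peak) / 3)^2)
  } else if (shape == 3) {   # constant profile (tie rule)
    pfs <- rep(runif(1, 0.7, 1), n)
  } else {                   # rough profile
    pfs <- runif(n, 0.5, 1)
  }
  ovShape <- sample(1:4, 1)
  if (ovShape == 1) {        # zero on a random window
    a <- sort(runif(2, 0, 90))
    pov <- ifelse(thetas >= a[1] & thetas <= a[2], 0, runif(n, 0.01, 0.5))
  } else if (ovShape == 2) { # overlap everywhere (min-overlap fallback)
    pov <- runif(n, 0.01, 0.5)
  } else if (ovShape == 3) { # overlap-free everywhere
    pov <- rep(0, n)
  } else {                   # zero except a window around the fs peak
    peakTh <- thetas[which.max(pfs)]
    pov <- ifelse(abs(thetas - peakTh) < runif(1, 2, 15), runif(n, 0.01, 0.5), 0)
  }
  AngleProfile(thetas, pov, pmin(pfs, 1))
}

# Least-squares plane normal (total least squares via SVD).
fitPlaneNormal <- function(points) {
  centered <- sweep(points, 2, colMeans(points))
  svd(centered)$v[, 3]
}

# Small, fast phantom for I/O and pipeline tests.
smallPhantomSpec <- function(...) {
  PhantomSpec(gridShape = c(64L, 64L, 64L), spacing = rep(2.5, 3), ...)
}

# Scene whose branch silhouettes overlap at every sweep angle by
# construction: the LSA label is a coaxial shell around a vertical LCCA
# core, so every horizontal ray through the core crosses the shell.
shellScene <- function() {
  vol <- array(0L, c(32, 32, 32))
  for (x in 1:32) for (y in 1:32) {
    r2 <- (x - 16)^2 + (y - 16)^2
    if (r2 <= 9) vol[x, y, 8:24] <- 2L
    else if (r2 >= 16 && r2 <= 36) vol[x, y, 8:24] <- 3L
  }
  vol[4:8, 4:8, 4:28] <- 1L  # a side column of aorta label
  cl <- Centerline(rbind(c(5, 5, 4), c(5, 5, 26)), "aorta")
  VesselScene(vol, c(1, 1, 1),
              labels = c(background = 0L, aorta = 1L, LCCA = 2L, LSA = 3L),
              centerlines = list(aorta = cl))
}
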