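# Angle selectors: joint-minimization baseline and the adaptive two-step
# rule, checked against hand arithmetic and an independent brute-force
# enumeration of the set logic.

test_that("standard selector minimizes the chosen objective with small-theta ties", {
  toy <- AngleProfile(c(0, 45, 90), pOverlap = c(0.2, 0, 0.1),
                      pFs = c(0.9, 0.8, 0.7))
  corr <- standardSelect(toy, "corrected")  # objective 0.3, 0.2, 0.4
  expect_identical(corr@thetaStandard, 45)
  expect_equal(corr@objectiveValue, 0.2)
  lit <- standardSelect(toy, "literal")     # objective 1.1, 0.8, 0.8: tie
  expect_identical(lit@thetaStandard, 45)
  # overlap identically zero: the foreshortening peak decides
  peaked <- AngleProfile(seq(0, 90, 10), pOverlap = rep(0, 10),
                         pFs = c(.5, .6, .7, .8, .95, .9, .8, .7, .6, .5))
  expect_identical(standardSelect(peaked)@thetaStandard, 40)
})

test_that("overlap-free set is the exact-zero filter", {
  pr <- AngleProfile(seq(0, 90, 10),
                     pOverlap = c(.1, .2, 0, 0, 0, 0, 0, .1, 0, .3),
                     pFs = seq(0.5, 0.95, length.out = 10))
  expect_identical(noOverlapSet(pr), c(20, 30, 40, 50, 60, 80))
  allz <- AngleProfile(0:5, rep(0, 6), rep(0.9, 6))
  expect_identical(noOverlapSet(allz), as.numeric(0:5))
  none <- AngleProfile(0:5, rep(0.1, 6), rep(0.9, 6))
  expect_length(noOverlapSet(none), 0)
})

test_that("adaptive foreshortening tiers follow the optimum location", {
  th <- as.numeric(0:90)
  peakAt <- function(p) pmin(1, 0.7 + 0.3 * exp(-((th - p) / 18)^2))
  # unique optimum at 45: singleton
  f45 <- adaptiveFsSet(AngleProfile(th, rep(0, 91), peakAt(45)))
  expect_identical(f45$thetaFsSet, 45)
  expect_identical(f45$branch, "<=50")
  # optimum at 55: the strict 98% tier
  p55 <- peakAt(55)
  f55 <- adaptiveFsSet(AngleProfile(th, rep(0, 91), p55))
  expect_identical(f55$branch, "50-60")
  expect_identical(f55$thetaFsSet, th[p55 > 0.98 * max(p55)])
  # optimum at 70: the strict 95% tier
  p70 <- peakAt(70)
  f70 <- adaptiveFsSet(AngleProfile(th, rep(0, 91), p70))
  expect_identical(f70$branch, ">60")
  expect_identical(f70$thetaFsSet, th[p70 > 0.95 * max(p70)])
  # constant profile: smallest grid angle attains the max
  fc <- adaptiveFsSet(AngleProfile(th, rep(0, 91), rep(0.8, 91)))
  expect_identical(fc$thetaFsmin, 0)
  expect_identical(fc$branch, "<=50")
  expect_identical(fc$thetaFsSet, 0)
})

test_that("adaptive selection takes the smallest angle of the intersection", {
  th <- as.numeric(0:90)
  pfs <- pmin(1, 0.8 + 0.2 * exp(-((th - 55) / 25)^2))
  pov <- ifelse(th >= 55 & th <= 70, 0, 0.2)
  sel <- adaptiveSelect(AngleProfile(th, pov, pfs))
  expect_identical(sel@thetaOptimal, 55)
  expect_identical(sel@fallbackUsed, "none")
  # singleton that is overlap-free
  pfs45 <- pmin(1, 0.7 + 0.3 * exp(-((th - 45) / 18)^2))
  sel45 <- adaptiveSelect(AngleProfile(th, ifelse(th >= 40, 0, 0.3), pfs45))
  expect_identical(sel45@thetaOptimal, 45)
})

test_that("fallbacks are conservative and recorded", {
  th <- as.numeric(0:90)
  # singleton optimum at 45 sits on overlap; 98% tier reaches the zero zone
  pfs <- pmin(1, 0.7 + 0.3 * exp(-((th - 45) / 18)^2))
  pov <- ifelse(th >= 50, 0, 0.25)
  sel <- adaptiveSelect(AngleProfile(th, pov, pfs))
  expect_identical(sel@fallbackUsed, "tier-relaxation")
  expect_identical(sel@thetaOptimal, 50)
  expect_identical(sel@branch, "<=50")
  # the hard constraint holds whenever any overlap-free angle exists
  expect_true(pov[th == sel@thetaOptimal] == 0)
  # no overlap-free angle at all: minimize overlap, ties by larger pFs
  pov2 <- c(rep(0.3, 30), rep(0.05, 31), rep(0.3, 30))
  pfs2 <- pmin(1, 0.7 + 0.3 * exp(-((th - 50) / 20)^2))
  sel2 <- adaptiveSelect(AngleProfile(th, pov2, pfs2))
  expect_identical(sel2@fallbackUsed, "min-overlap")
  expect_identical(sel2@thetaOptimal, 50)  # tie on pov -> max pFs at 50
})

test_that("the adaptive result is overlap-free where the standard one need not be", {
  # overlap-free angles exist but the joint objective prefers an overlapping
  # angle: small overlap penalty outweighed by better foreshortening
  th <- seq(0, 90, 5)
  pov <- ifelse(th == 40, 0.02, ifelse(th >= 60, 0, 0.3))
  pfs <- ifelse(th == 40, 1, ifelse(th >= 60, 0.8, 0.9))
  pr <- AngleProfile(th, pov, pfs)
  std <- standardSelect(pr, "corrected")
  ada <- adaptiveSelect(pr)
  expect_identical(std@thetaStandard, 40)   # objective 0.02 beats 0.2
  expect_gt(pov[th == std@thetaStandard], 0)
  expect_identical(ada@thetaOptimal, 60)
  expect_identical(pov[th == ada@thetaOptimal], 0)
})

test_that("adaptive selection agrees with the brute-force set-logic oracle", {
  set.seed(101)
  branches <- character(0); fallbacks <- character(0)
  for (i in 1:300) {
    pr <- randomProfile()
    got <- adaptiveSelect(pr)
    want <- oracleAdaptive(pr@thetas, pr@pOverlap, pr@pFs)
    expect_identical(got@thetaOptimal, want$theta)
    expect_identical(got@branch, want$branch)
    expect_identical(got@fallbackUsed, want$fallback)
    # tier membership implies the tier's bound
    if (got@fallbackUsed == "none" && got@branch != "<=50")
      expect_gte(pr@pFs[pr@thetas == got@thetaOptimal],
                 0.95 * got@pFsmax)
    branches <- c(branches, got@branch)
    fallbacks <- c(fallbacks, got@fallbackUsed)
  }
  expect_setequal(unique(branches), c("<=50", "50-60", ">60"))
  expect_setequal(unique(fallbacks), c("none", "tier-relaxation", "min-overlap"))
})

test_that("selectForScene reproduces the per-case pipeline deterministically", {
  scene <- generatePhantom(smallPhantomSpec(archPlaneLao = 44))
  r1 <- selectForScene(scene, thetas = seq(0, 90, by = 2))
  r2 <- selectForScene(scene, thetas = seq(0, 90, by = 2))
  expect_identical(r1$adaptive@thetaOptimal, r2$adaptive@thetaOptimal)
  expect_identical(as.data.frame(r1$profile), as.data.frame(r2$profile))
  # separated branches: the adaptive angle is overlap-free
  i <- which(r1$profile@thetas == r1$adaptive@thetaOptimal)
  expect_identical(r1$profile@pOverlap[i], 0)
  # a scene with overlap at every angle forces the min-overlap fallback
  co <- selectForScene(shellScene(), thetas = seq(0, 90, by = 10))
  expect_identical(co$adaptive@fallbackUsed, "min-overlap")
  expect_length(co$adaptive@thetaNoOverlap, 0)
})
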