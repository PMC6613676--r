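test_that("dipole beats have ordered fiducials and an accurate arc-length table", {
  beat <- simulateDipoleBeat()
  a <- beat$annotation
  expect_true(a$p_idx < a$q_idx && a$q_idx < a$j_idx && a$j_idx < a$tend_idx)
  expect_false(beat$degenerate)

  # polyline length of the generated window vs the generator's truth table
  idx <- (a$j_idx + round(0.02 * beat$fs) + 1):(a$tend_idx + 1)
  polyline <- sum(sqrt(rowSums(diff(beat$xyz[idx, ])^2)))
  expect_equal(polyline, beat$arcLength[length(beat$arcLength)],
               tolerance = 0.01)
  # cumulative truth is non-decreasing from 0
  expect_true(all(diff(beat$arcLength) >= -1e-9))
  expect_equal(beat$arcLength[1], 0, tolerance = 1e-6)

  # degenerate repolarization flagged and rejected downstream
  flat <- simulateDipoleBeat(dipoleBeatParams(tAmplitudeUv = 0))
  expect_true(flat$degenerate)
  vcg <- new("Vcg", xyz = flat$xyz * 0, samplingRate = flat$fs)
  expect_error(trajectoryQuantiles(extractTLoop(vcg, flat$annotation)),
               "degenerate trajectory")
})

test_that("repolarization warps re-time the loop but preserve its geometry", {
  beat <- simulateDipoleBeat()
  T0 <- 280

  # re-applying the beat's own timing changes nothing
  same <- applyRepolarizationWarp(beat, function(q) tauBaseline(q, T0))
  expect_equal(same$beat$xyz, beat$xyz, tolerance = 1e-9)
  expect_equal(same$trueTrx, beat$trueTrx, tolerance = 1e-6)

  # quadratic warp: true Tr50 = T/4 in closed form
  warped <- applyRepolarizationWarp(beat, function(q) 200 * q^2)
  expect_equal(unname(warped$trueTrx["Tr50"]), 50)
  expect_equal(unname(warped$trueTrx["Tr100"]), 200)

  # pipeline readback at sub-sample accuracy needs a warp whose speed stays
  # finite (pure q^2 starts with a velocity singularity the 60 ms derivative
  # window cannot resolve); a mixed super-linear warp is resolvable
  tauMix <- function(q) 200 * (0.5 * q + 0.5 * q^2)
  mixed <- applyRepolarizationWarp(beat, tauMix)
  expect_equal(unname(mixed$trueTrx["Tr50"]), 75)
  rec <- cleanBeatRecord(taus = list(tauMix), nBeats = 3)
  measured <- trxValues(recordQuantiles(rec))
  expect_lt(abs(measured["Tr50"] - 75), 2 + 0.01 * 75)

  # the spatial path is unchanged: total arc length within 1%
  aW <- warped$beat$annotation; aB <- beat$annotation
  lenOf <- function(b, a) {
    idx <- (a$j_idx + round(0.02 * b$fs) + 1):(a$tend_idx + 1)
    sum(sqrt(rowSums(diff(b$xyz[idx, ])^2)))
  }
  expect_equal(lenOf(warped$beat, aW), lenOf(beat, aB), tolerance = 0.01)

  expect_error(applyRepolarizationWarp(beat, function(q) 200 * (1 - q)),
               "non-monotone")
  expect_error(applyRepolarizationWarp(beat, function(q) 10 + 200 * q),
               "non-monotone")
})

test_that("the one-compartment PK profile has the closed-form peak and washes out", {
  ka <- 1.2; ke <- 0.25
  t <- seq(0, 48, by = 0.01)
  conc <- simulatePkProfile(500, t, ka, ke, scale = 9)
  expect_equal(conc[1], 0)
  tmax <- log(ka / ke) / (ka - ke)
  expect_equal(t[which.max(conc)], tmax, tolerance = 0.02)
  expect_lt(simulatePkProfile(500, 100 / ke, ka, ke, scale = 9),
            1e-3 * max(conc))
  # superposition over repeated doses
  twice <- simulatePkProfile(500, 10, ka, ke, 9, doseTimesH = c(0, 4))
  expect_equal(twice,
               simulatePkProfile(500, 10, ka, ke, 9) +
                 simulatePkProfile(500, 6, ka, ke, 9), tolerance = 1e-12)
  expect_error(simulatePkProfile(1, 1, -1, 0.2), "positive")
  expect_error(simulatePkProfile(1, 1, 0.5, 0.5), "must differ")
})

test_that("simulated studies are reproducible and carry exact ground truth", {
  des <- studyDesign(nSubjects = 3, timepointsH = c(0, 1, 4), replicates = 3,
                     recordDurationS = 5)
  spec <- list(dofetilide = list(delta = effectShape("herg", 0.004),
                                 sigmaB = 0.2))
  st1 <- simulateStudy(des, spec, seed = 5)
  st2 <- simulateStudy(des, spec, seed = 5)
  expect_identical(st1$truth, st2$truth)
  expect_identical(st1$pk, st2$pk)
  expect_identical(leadSignals(st1$records[[7]]),
                   leadSignals(st2$records[[7]]))
  expect_equal(length(st1$records), 3 * 2 * 3 * 3)

  # placebo truth: no injected effect, and TrX is a pure dilation of the
  # baseline timing (constant ratio across quantiles within each record)
  pla <- st1$truth[st1$truth$treatment == "Placebo", ]
  expect_true(all(pla$true_dd == 0))
  base <- tauBaseline(seq(0.1, 1, 0.1), 1)
  byRec <- split(pla, interaction(pla$subject_id, pla$nominal_time_h,
                                  pla$replicate, drop = TRUE))
  ratios <- vapply(byRec, function(r) {
    rr <- r$value / base
    diff(range(rr)) / mean(rr)
  }, 0)
  expect_lt(max(ratios), 1e-6)

  # active-arm truth equals the composed timing map: value - dilation part
  # is the injected effect scaled by the subject's (1 + b)
  act <- st1$truth[st1$truth$treatment == "Dofetilide" &
                     st1$truth$true_dd != 0, ]
  expect_gt(nrow(act), 0)
  expect_true(all(act$value > 0))
})

test_that("forward projection pairs with the inverse transform", {
  z <- forwardProject12Lead(new("Vcg", xyz = matrix(0, 50, 3),
                                samplingRate = 500))
  expect_true(all(z == 0))
  expect_equal(dim(z), c(50L, 12L))

  beat <- simulateDipoleBeat()
  leads <- forwardProject12Lead(new("Vcg", xyz = beat$xyz,
                                    samplingRate = beat$fs))
  expect_lt(max(abs(leads[, "II"] - leads[, "I"] - leads[, "III"])), 1e-9)
  back <- vcgXyz(inverseDower(EcgRecord(leads, beat$fs)))
  expect_lt(max(abs(back - beat$xyz)), 0.01 * max(computeTvs(beat$xyz)))
})

test_that("written studies are readable and consistent with the in-memory objects", {
  des <- studyDesign(nSubjects = 2, timepointsH = c(0, 2), replicates = 3,
                     recordDurationS = 5)
  st <- simulateStudy(des, seed = 6)
  dir <- file.path(tempdir(), "studyout")
  writeStudy(st, dir)
  rec <- readEcgRecord(file.path(dir, "rec0003.csv"))
  orig <- st$records[[3]]
  expect_identical(beats(rec)[, 1:5], beats(orig)[, 1:5])
  expect_equal(beats(rec)$rr_ms, beats(orig)$rr_ms, tolerance = 1e-9)
  expect_identical(subjectId(rec), subjectId(orig))
  pk <- read.csv(file.path(dir, "pk.csv"))
  expect_equal(nrow(pk), nrow(st$pk))
})
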