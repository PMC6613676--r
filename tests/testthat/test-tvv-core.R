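test_that("inverse Dower reconstruction is linear and inverts the forward projection", {
  sig <- indepLeads(200)
  expect_true(all(vcgXyz(inverseDower(EcgRecord(sig, 500))) == 0))

  set.seed(5)
  sig[] <- rnorm(200 * 8, 0, 200)
  rec <- EcgRecord(sig, 500)
  rec2 <- EcgRecord(2 * sig, 500)
  expect_identical(vcgXyz(inverseDower(rec2)), 2 * vcgXyz(inverseDower(rec)))

  # forward-project a known dipole, then invert: < 1% of dipole magnitude
  dip <- cbind(x = 300 * sin(seq(0, pi, length.out = 400)),
               y = 150 * sin(seq(0, 2 * pi, length.out = 400)),
               z = -200 * sin(seq(0, pi, length.out = 400))^2)
  leads <- forwardProject12Lead(new("Vcg", xyz = dip, samplingRate = 500))
  back <- vcgXyz(inverseDower(EcgRecord(leads, 500)))
  mag <- max(sqrt(rowSums(dip^2)))
  expect_lt(max(abs(back - dip)), 0.01 * mag)
  # Einthoven identity built into the projection
  expect_lt(max(abs(leads[, "II"] - leads[, "I"] - leads[, "III"])), 1e-9)
})

test_that("T-loop extraction window follows J + 20 ms to Tend inclusive", {
  vcg <- new("Vcg", xyz = matrix(rnorm(400 * 3), 400, 3), samplingRate = 500)
  loop <- extractTLoop(vcg, list(j_idx = 175, tend_idx = 300))
  expect_identical(loop@startIdx, 185L)
  expect_identical(loop@endIdx, 300L)
  expect_equal(nrow(vcgXyz(loop)), 116)
  durMs <- (nrow(vcgXyz(loop)) - 1) / 500 * 1000
  expect_equal(durMs, (300 - 175 - 10) / 500 * 1000)
  expect_error(extractTLoop(vcg, list(j_idx = 175, tend_idx = 180)),
               "unusable beat")
})

test_that("TVS is the rotation-invariant dipole magnitude", {
  expect_equal(computeTvs(cbind(3, 4, 0)), 5)
  expect_equal(computeTvs(matrix(c(1, 0, 0), 10, 3, byrow = TRUE)),
               rep(1, 10))
  set.seed(6)
  xyz <- matrix(rnorm(300), 100, 3)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  expect_equal(computeTvs(xyz %*% R), computeTvs(xyz), tolerance = 1e-9)
})

test_that("Savitzky-Golay TVV is exact on cubics, zero on constants, accurate on circles", {
  fs <- 500
  tMs <- (0:999) * (1000 / fs)
  # linear: speed 2 uV/ms everywhere
  lin <- cbind(2 * tMs, 0, 0)
  expect_equal(computeTvv(lin, fs), rep(2, 1000), tolerance = 1e-12)
  # full cubic: the order-3 filter reproduces the derivative exactly
  cub <- cbind(1 + 0.5 * tMs - 3e-3 * tMs^2 + 2e-6 * tMs^3, 0, 0)
  dTrue <- abs(0.5 - 6e-3 * tMs + 6e-6 * tMs^2)
  interior <- 16:984
  expect_lt(max(abs(computeTvv(cub, fs)[interior] - dTrue[interior]) /
                  pmax(dTrue[interior], 1e-6)), 1e-9)
  # static point
  expect_equal(computeTvv(matrix(5, 600, 3), fs), rep(0, 600),
               tolerance = 1e-12)
  # planar circle, radius 500 uV, period 400 ms: speed r*omega
  circ <- cbind(500 * cos(2 * pi * tMs / 400), 500 * sin(2 * pi * tMs / 400), 0)
  vTrue <- 2 * pi * 500 / 400
  expect_equal(mean(computeTvv(circ, fs)[interior]), vTrue,
               tolerance = 0.005)
  expect_error(computeTvv(lin[1:20, ], fs), "too short")
})

test_that("trajectory quantiles reproduce closed-form speed profiles", {
  fs <- 500
  dummy <- new("Vcg", xyz = matrix(1, 160, 3), samplingRate = fs)
  beat <- list(j_idx = 0, tend_idx = 110)  # window [10, 110]: 200 ms loop

  # constant speed: TrX = X% of the duration
  tvv <- rep(3, 160)
  q <- trajectoryQuantiles(extractTLoop(dummy, beat, tvv = tvv))
  expect_equal(unname(q), 2 * seq(10, 100, 10), tolerance = 1e-9)
  expect_equal(unname(q["Tr50"]), 100)

  # two-phase speed 2v then v: half the length is reached at t = 75 ms
  tvv2 <- c(rep(2, 61), rep(1, 99))  # window samples 0..50 fast, rest slow
  q2 <- trajectoryQuantiles(extractTLoop(dummy, beat, tvv = tvv2))
  expect_equal(unname(q2["Tr50"]), 75, tolerance = 1.5)
  expect_equal(unname(q2["Tr100"]), 200)

  # degenerate loop
  zero <- new("Vcg", xyz = matrix(0, 160, 3), samplingRate = fs)
  expect_error(trajectoryQuantiles(extractTLoop(zero, beat)),
               "degenerate trajectory")
})

test_that("record quantiles average the per-beat quantiles of normal sinus beats", {
  taus <- list(function(q) tauBaseline(q, 260),
               function(q) tauBaseline(q, 280),
               function(q) tauBaseline(q, 300))
  rec <- cleanBeatRecord(taus = taus, nBeats = 3)
  tq <- recordQuantiles(rec)
  # oracle: per-beat quantiles on the preprocessed record, averaged
  pre <- besselLowpass(correctIsoelectric(rec))
  vcg <- inverseDower(pre)
  perBeat <- t(vapply(seq_len(3), function(i)
    trajectoryQuantiles(extractTLoop(vcg, beats(rec)[i, ])),
    numeric(10)))
  expect_equal(trxValues(tq), colMeans(perBeat), tolerance = 1e-9)
  expect_equal(tq@nBeatsUsed, 3L)

  # identical beats: record quantiles equal the single-beat quantiles
  recSame <- cleanBeatRecord(nBeats = 3)
  tqSame <- recordQuantiles(recSame)
  preS <- besselLowpass(correctIsoelectric(recSame))
  single <- trajectoryQuantiles(extractTLoop(inverseDower(preS),
                                             beats(recSame)[2, ]))
  expect_equal(trxValues(tqSame), single, tolerance = 0.35)

  expect_error(recordQuantiles(cleanBeatRecord(nBeats = 2)),
               "insufficient normal beats")
})

test_that("Fridericia correction anchors at RR 1000 and rejects nonpositive RR", {
  expect_equal(fridericiaQtc(400, 1000), 400)
  expect_equal(fridericiaQtc(400, 800), 400 / 0.8^(1 / 3), tolerance = 1e-9)
  expect_equal(round(fridericiaQtc(400, 800), 2), 430.89)
  expect_error(fridericiaQtc(400, 0), "RR must be positive")
})

test_that("trajectory quantiles obey geometric invariances on random loops", {
  set.seed(17)
  for (i in 1:25) {
    beat <- randomLoopBeat()
    loop <- loopFromBeat(beat)
    q <- trajectoryQuantiles(loop)
    durMs <- (nrow(vcgXyz(loop)) - 1) / loop@samplingRate * 1000

    expect_true(all(diff(q) >= -1e-9))              # monotone in X
    expect_lte(abs(q["Tr100"] - durMs), 1)          # Tr100 = loop duration

    # cumulative length normalized: 0 at start, 1 at end, non-decreasing
    cl <- loop@cumLengthNorm
    expect_equal(cl[1], 0)
    expect_equal(cl[length(cl)], 1)
    expect_true(all(diff(cl) >= -1e-12))

    # amplitude-scale invariance (normalization cancels the scale exactly)
    k <- runif(1, 0.2, 5)
    vcgK <- new("Vcg", xyz = k * beat$xyz, samplingRate = beat$fs)
    qK <- trajectoryQuantiles(extractTLoop(vcgK, beat$annotation))
    expect_lt(max(abs(qK - q)), 1e-6)

    # 3-D rotation invariance (arc length is rotation-invariant)
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    vcgR <- new("Vcg", xyz = beat$xyz %*% R, samplingRate = beat$fs)
    qR <- trajectoryQuantiles(extractTLoop(vcgR, beat$annotation))
    expect_lt(max(abs(qR - q)), 1e-6)
  }

  # TVV-integrated length vs the polyline oracle, on band-limited loops
  for (i in 1:25) {
    loop <- loopFromBeat(randomLoopBeat(bandLimited = TRUE))
    dtMs <- 1000 / loop@samplingRate
    tvvw <- loop@tvv
    lenTvv <- sum((tvvw[-1] + tvvw[-length(tvvw)]) / 2 * dtMs)
    lenPoly <- sum(sqrt(rowSums(diff(vcgXyz(loop))^2)))
    expect_lt(abs(lenTvv - lenPoly) / lenPoly, 0.01)
  }
})

test_that("time dilation of a loop scales every quantile proportionally", {
  for (T0 in c(200, 240, 280)) {
    k <- 1.3
    b1 <- simulateDipoleBeat(dipoleBeatParams(tDurationMs = T0))
    b2 <- simulateDipoleBeat(dipoleBeatParams(rrMs = 1100,
                                              tDurationMs = k * T0))
    q1 <- trajectoryQuantiles(loopFromBeat(b1))
    q2 <- trajectoryQuantiles(loopFromBeat(b2))
    # 1% relative plus half a sample of absolute slack
    expect_true(all(abs(q2 - k * q1) <= 0.01 * k * q1 + 1))
  }
})
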