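longRow <- function(subject, treatment, t, rep, parameter, value) {
  data.frame(subject_id = subject, treatment = treatment, nominal_time_h = t,
             replicate = rep, parameter = parameter, value = value)
}

test_that("single deltas average replicates and subtract the period baseline", {
  tab <- rbind(
    longRow("A", "Drug", 0, 1:3, "Tr50c", c(239, 240, 241)),
    longRow("A", "Drug", 2, 1:3, "Tr50c", c(248, 250, 252)),
    longRow("A", "Placebo", 0, 1, "Tr50c", 240),
    longRow("A", "Placebo", 2, 1, "Tr50c", 244),
    longRow("B", "Drug", 2, 1, "Tr50c", 250))  # B has no baseline
  d <- suppressMessages(singleDelta(tab))
  expect_equal(d$value[d$subject_id == "A" & d$treatment == "Drug"], 10)
  expect_equal(d$value[d$subject_id == "A" & d$treatment == "Placebo"], 4)
  expect_false("B" %in% d$subject_id)
  expect_true(any(grepl("no baseline", attr(d, "excluded"))))

  # zero change
  z <- singleDelta(rbind(longRow("A", "Drug", 0, 1, "P", 240),
                         longRow("A", "Drug", 1, 1, "P", 240)))
  expect_equal(z$value, 0)
})

test_that("double deltas match placebo within subject and time", {
  tab <- rbind(
    longRow("A", "Drug", 0, 1, "P", 100), longRow("A", "Drug", 2, 1, "P", 110),
    longRow("A", "Placebo", 0, 1, "P", 101),
    longRow("A", "Placebo", 2, 1, "P", 105),
    longRow("B", "Drug", 0, 1, "P", 90), longRow("B", "Drug", 2, 1, "P", 96))
  d <- suppressMessages(doubleDelta(singleDelta(tab)))
  expect_equal(d$value[d$subject_id == "A" & d$treatment == "Drug"], 10 - 4)
  # the placebo arm against itself is identically zero
  expect_equal(d$value[d$treatment == "Placebo"], 0)
  # subject B has no placebo period: excluded with a reason
  expect_false("B" %in% d$subject_id)
  expect_true(any(grepl("no placebo match", attr(d, "excluded"))))
})

simulateDd <- function(nSubj = 22, nTimes = 15, theta = 0.004, bSd = 0.001,
                       noiseSd = 2, seed = 31, parameter = "Tr50c") {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nSubj), function(s) {
    b <- rnorm(1, 0, bSd)
    conc <- runif(nTimes, 0, 3000)
    data.frame(subject_id = sprintf("S%02d", s), parameter = parameter,
               conc = conc,
               value = (theta + b) * conc + rnorm(nTimes, 0, noiseSd))
  }))
}

test_that("the concentration-effect model is origin-anchored, linear and unbiased", {
  d <- simulateDd()
  fit <- fitExposureResponse(d, "conc")
  expect_identical(predictEffect(fit, c(conc = 0)), 0)
  expect_lt(abs(fit$theta[["conc"]] - 0.004), 2 * fit$se[["conc"]])
  expect_equal(predictEffect(fit, c(conc = 2500)), 10, tolerance = 0.15)
  # linearity in concentration (no intercept)
  expect_equal(predictEffect(fit, c(conc = 5000)),
               2 * predictEffect(fit, c(conc = 2500)), tolerance = 1e-12)
  d0 <- d; d0$conc <- 0
  expect_error(fitExposureResponse(d0, "conc"), "all-zero concentrations")
})

test_that("two-drug models recover slopes and the interaction term", {
  set.seed(32)
  th <- c(0.004, -0.003); th12 <- 4e-7
  d <- do.call(rbind, lapply(1:22, function(s) {
    b1 <- rnorm(1, 0, 0.001); b2 <- rnorm(1, 0, 0.001)
    c1 <- runif(15, 0, 3000); c2 <- runif(15, 0, 2000)
    data.frame(subject_id = sprintf("S%02d", s), c1 = c1, c2 = c2,
               value = (th[1] + b1) * c1 + (th[2] + b2) * c2 +
                 th12 * c1 * c2 + rnorm(15, 0, 2))
  }))
  fit <- fitExposureResponse(d, c("c1", "c2"), interaction = TRUE)
  expect_lt(abs(fit$theta[["c1"]] - th[1]), 2 * fit$se[["c1"]])
  expect_lt(abs(fit$theta[["c2"]] - th[2]), 2 * fit$se[["c2"]])
  expect_lt(abs(fit$theta[["c1:c2"]] - th12), 2 * fit$se[["c1:c2"]])
  expect_identical(predictEffect(fit, c(c1 = 0, c2 = 0)), 0)

  # without the interaction on interaction-free data
  d2 <- d; d2$value <- d2$value - th12 * d2$c1 * d2$c2
  fit2 <- fitExposureResponse(d2, c("c1", "c2"), interaction = FALSE)
  expect_lt(abs(fit2$theta[["c1"]] - th[1]), 2 * fit2$se[["c1"]])
  expect_lt(abs(fit2$theta[["c2"]] - th[2]), 2 * fit2$se[["c2"]])
})

test_that("effect profiles echo their concentrations, are seeded, and cover a null drug", {
  pars <- paste0("Tr", seq(10, 100, 10), "c")
  # a true null drug (no effect in any subject) at the design's full size;
  # the ten quantiles of a profile come from the same ECGs, so they share
  # their measurement noise almost entirely
  set.seed(35)
  nSubj <- 22; nTimes <- 15
  conc <- as.vector(t(matrix(runif(nSubj * nTimes, 0, 3000), nSubj)))
  shared <- rnorm(nSubj * nTimes, 0, 2)
  d <- do.call(rbind, lapply(pars, function(p) {
    data.frame(subject_id = rep(sprintf("S%02d", 1:nSubj), each = nTimes),
               parameter = p, conc = conc,
               value = shared + rnorm(nSubj * nTimes, 0, 0.3))
  }))
  prof <- effectProfile(d, repConc = c(conc = 2500), nBoot = 100, seed = 7)
  tab <- profileTable(prof)
  expect_identical(prof@repConc, c(conc = 2500))
  expect_identical(tab$parameter, pars)
  # every quantile's CI covers the true null effect
  expect_true(all(tab$lo <= 0 & 0 <= tab$hi))

  # reproducibility under the seed
  prof2 <- effectProfile(d, repConc = c(conc = 2500), nBoot = 100, seed = 7)
  expect_identical(profileTable(prof2), tab)

  # representative concentrations for a combination are echoed verbatim
  d2 <- do.call(rbind, lapply(pars, function(p) {
    x <- simulateDd(nSubj = 6, nTimes = 6, seed = 34, parameter = p)
    names(x)[names(x) == "conc"] <- "mexiletine"
    x$dofetilide <- runif(nrow(x), 0, 3)
    x
  }))
  prof3 <- effectProfile(d2, repConc = c(mexiletine = 1170, dofetilide = 1.43),
                         nBoot = 20, seed = 8)
  expect_identical(prof3@repConc, c(mexiletine = 1170, dofetilide = 1.43))
})

test_that("geometric mean concentration handles zeros and identities", {
  expect_equal(geometricMeanConcentration(c(4, 9)), 6)
  expect_equal(geometricMeanConcentration(7.3), 7.3)
  expect_equal(geometricMeanConcentration(c(1, 10, 100)), 10)
  expect_message(v <- geometricMeanConcentration(c(0, 4, 9)), "excluded")
  expect_equal(v, 6)
  expect_error(suppressMessages(geometricMeanConcentration(c(0, 0))),
               "no positive")
})
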