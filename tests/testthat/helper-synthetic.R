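# Shared synthetic fixtures, built in code and cached for the session so the
# heavier studies are simulated once even when several files use them.

.fixtures <- new.env(parent = emptyenv())

withFixture <- function(key, expr) {
  if (is.null(.fixtures[[key]])) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

indepLeads <- function(n = 1000, value = 0) {
  matrix(value, n, 8,
         dimnames = list(NULL, c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")))
}

# Record of nBeats synthetic beats (optionally with per-beat timing maps),
# forward-projected to the 12 leads, optionally with additive white noise.
cleanBeatRecord <- function(taus = list(NULL), nBeats = 6,
                            params = dipoleBeatParams(), noiseSd = 0,
                            seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  beats <- lapply(seq_len(nBeats), function(i)
    simulateDipoleBeat(params, tau = taus[[(i - 1) %% length(taus) + 1]]))
  xyz <- do.call(rbind, lapply(beats, `[[`, "xyz"))
  ann <- do.call(rbind, lapply(seq_along(beats), function(i) {
    a <- beats[[i]]$annotation
    off <- (i - 1) * nrow(beats[[1]]$xyz)
    for (cn in c("p_idx", "q_idx", "j_idx", "tend_idx")) a[[cn]] <- a[[cn]] + off
    a
  }))
  leads <- forwardProject12Lead(new("Vcg", xyz = xyz, samplingRate = params$fs))
  if (noiseSd > 0) {
    idx <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")
    noisy <- leads[, idx] + matrix(rnorm(nrow(leads) * 8, 0, noiseSd),
                                   ncol = 8)
    colnames(noisy) <- idx
    leads <- noisy
  }
  EcgRecord(leads, samplingRate = params$fs, beats = ann, ...)
}

# Apply a distortion to the eight independent leads and rebuild the record,
# so the derived limb leads stay consistent (as they would be in real data,
# where III/aVR/aVL/aVF are computed from the measured I and II).
perturbRecord <- function(rec, f) {
  idx <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")
  sig <- leadSignals(rec)[, idx]
  EcgRecord(f(sig), samplingRate = samplingRate(rec), beats = beats(rec))
}

# A randomized smooth loop for the geometry properties: random duration and
# amplitude, the baseline timing perturbed by small random delay/acceleration
# shapes (kept strictly monotone). `bandLimited = TRUE` restricts to longer,
# gentler loops whose TVV content the 60 ms derivative window fully passes.
randomLoopBeat <- function(durationMs = runif(1, 180, 320),
                           amplitude = runif(1, 400, 800),
                           bandLimited = FALSE) {
  if (bandLimited) durationMs <- runif(1, 280, 340)
  a1 <- runif(1, -2, if (bandLimited) 4 else 8)   # herg-like delay at q = 1
  a2 <- runif(1, if (bandLimited) -2 else -6, 2)  # sodium-like acceleration
  tau <- function(q) tauBaseline(q, durationMs) +
    a1 * effectShape("herg", 1)(q) + a2 * effectShape("sodium", 1)(q)
  simulateDipoleBeat(
    dipoleBeatParams(rrMs = max(1000, durationMs + 450),
                     tAmplitudeUv = amplitude, tDurationMs = durationMs),
    tau = tau)
}

loopFromBeat <- function(beat) {
  vcg <- new("Vcg", xyz = beat$xyz, samplingRate = beat$fs)
  extractTLoop(vcg, beat$annotation)
}

# Reduced crossover study with one active arm; the conditions used by the
# statistical recovery checks (12 subjects x 8 timepoints x triplicates,
# between-subject effect-size SD 0.3; see the methods vignette for the
# power reasoning behind these sizes).
recoveryDesign <- function(nSubjects = 12) {
  studyDesign(
    nSubjects = nSubjects,
    arms = list(
      list(name = "Placebo", drugs = list()),
      list(name = "Active",
           drugs = list(drugA = list(dose = 500, ka = 1.2, ke = 0.25,
                                     scale = 9, doseTimesH = 0)))),
    timepointsH = c(0, 1, 2, 3, 4, 6, 8, 12),
    replicates = 3, recordDurationS = 6)
}

recoveryStudy <- function(key, delta, sigmaB = 0.3, seed = 101) {
  withFixture(key, {
    st <- simulateStudy(recoveryDesign(),
                        effectSpecs = list(drugA = list(delta = delta,
                                                        sigmaB = sigmaB)),
                        seed = seed)
    qtab <- suppressMessages(studyQuantileTable(st$records))
    list(study = st, qtab = qtab)
  })
}

recoveryProfile <- function(key, fix, repConc, nBoot = 200, seed = 211) {
  withFixture(key, suppressMessages(
    armEffectProfile(fix$qtab, fix$study$pk, "Active", "drugA",
                     repConc = c(drugA = repConc), nBoot = nBoot,
                     seed = seed)))
}

# Discrimination fixture: pure-hERG arm (group I) vs hERG + late-sodium
# combination arm (group II), observations are post-dose subject x timepoint
# double-delta rows of the corrected trajectory quantiles.
discrimObservations <- function() {
  withFixture("discrim", {
    des <- studyDesign(
      nSubjects = 8,
      arms = list(
        list(name = "Placebo", drugs = list()),
        list(name = "Dofetilide",
             drugs = list(dofetilide = list(dose = 500, ka = 1.2, ke = 0.25,
                                            scale = 9, doseTimesH = 0))),
        list(name = "Dof+Mex",
             drugs = list(dofetilide = list(dose = 500, ka = 1.2, ke = 0.25,
                                            scale = 9, doseTimesH = 0),
                          mexiletine = list(dose = 600, ka = 1.0, ke = 0.12,
                                            scale = 3.3, doseTimesH = 0)))),
      timepointsH = c(0, 1, 2, 3, 4, 6), replicates = 3, recordDurationS = 6)
    st <- simulateStudy(
      des,
      effectSpecs = list(
        dofetilide = list(delta = effectShape("herg", 0.004), sigmaB = 0.3),
        mexiletine = list(delta = effectShape("sodium", 0.005), sigmaB = 0.3)),
      seed = 303)
    qtab <- suppressMessages(studyQuantileTable(st$records))
    rateModel <- suppressMessages(fitRateModel(drugFreeTable(qtab)))
    ctab <- correctBiomarkerTable(qtab, rateModel)
    dd <- suppressMessages(doubleDelta(singleDelta(ctab), "Placebo"))
    wide <- ddWideTable(dd, paste0("Tr", seq(10, 100, 10), "c"))
    wide <- wide[wide$treatment %in% c("Dofetilide", "Dof+Mex"), ]
    wide$block_label <- factor(
      ifelse(wide$treatment == "Dofetilide", "pure_herg", "multichannel"),
      levels = c("pure_herg", "multichannel"))
    wide
  })
}

# brute-force AUC oracle: explicit loop over all positive-negative pairs
aucPairwiseOracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
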