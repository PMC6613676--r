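#' Design of a synthetic crossover ECG study
#'
#' Describes a randomized crossover study of the kind used for ECG biomarker
#' validation: every subject passes through every arm, triplicate 10-second
#' ECGs are extracted at fixed nominal timepoints, and serum drug
#' concentrations follow one-compartment oral kinetics. Defaults mirror a
#' thorough QT-style design: 22 subjects, 16 timepoints over 24 h,
#' triplicates, 500 Hz, supine resting heart rate around 60 bpm with a
#' circadian swing; reduce `nSubjects`/`timepointsH` for quick runs.
#'
#' @param nSubjects number of subjects (>= 2).
#' @param arms list of arms; each `list(name =, drugs = list(<drug> =
#'   list(dose, ka, ke, scale, doseTimesH)))` with an empty `drugs` list for
#'   placebo.
#' @param timepointsH nominal ECG timepoints (h); must include the baseline 0.
#' @param replicates ECG replicates per timepoint (>= 3).
#' @param recordDurationS length of each ECG (s).
#' @param fs sampling rate (Hz).
#' @param rr heart-rate model: mean RR (ms), circadian amplitude, subject SD
#'   and per-record jitter SD.
#' @param noise white noise SD (uV) and baseline-wander amplitude (uV) /
#'   frequency (Hz) added to the independent leads.
#' @param betaDur RR-dependence of the repolarization duration (ms of loop
#'   duration per ms of RR); its per-subject relative SD is `betaSubjSd`.
#' @param betaSubjSd relative SD of the per-subject RR slope.
#' @param tDurationMs,tAmplitudeUv drug-free T-loop duration and amplitude.
#' @return list of class `"StudyDesign"`.
#' @export
studyDesign <- function(
    nSubjects = 22,
    arms = list(
      list(name = "Placebo", drugs = list()),
      list(name = "Dofetilide",
           drugs = list(dofetilide = list(dose = 500, ka = 1.2, ke = 0.25,
                                          scale = 9, doseTimesH = 0)))),
    timepointsH = c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 6, 7, 8, 12, 14, 24),
    replicates = 3,
    recordDurationS = 10,
    fs = 500,
    rr = list(meanMs = 1000, circadianAmpMs = 60, subjectSdMs = 80,
              recordJitterSdMs = 20),
    noise = list(whiteSdUv = 10, wanderAmpUv = 150, wanderFreqHz = 0.33),
    betaDur = 0.1, betaSubjSd = 0.1,
    tDurationMs = 280, tAmplitudeUv = 600) {
  stopifnot(nSubjects >= 2, replicates >= 3, 0 %in% timepointsH,
            length(arms) >= 1)
  structure(list(nSubjects = nSubjects, arms = arms,
                 timepointsH = timepointsH, replicates = replicates,
                 recordDurationS = recordDurationS, fs = fs, rr = rr,
                 noise = noise, betaDur = betaDur, betaSubjSd = betaSubjSd,
                 tDurationMs = tDurationMs, tAmplitudeUv = tAmplitudeUv),
            class = "StudyDesign")
}

.addLeadNoise <- function(leads8, noise, fs, phase) {
  n <- nrow(leads8)
  t <- (seq_len(n) - 1) / fs
  for (j in seq_len(ncol(leads8))) {
    wander <- noise$wanderAmpUv *
      sin(2 * pi * noise$wanderFreqHz * t + phase[j]) +
      cumsum(rnorm(n, 0, noise$whiteSdUv / 50))
    leads8[, j] <- leads8[, j] + wander + rnorm(n, 0, noise$whiteSdUv)
  }
  leads8
}

#' Simulate a synthetic crossover ECG study
#'
#' Generates annotated 12-lead records for every subject x arm x timepoint x
#' replicate of the design, with known ground truth. Drug effects are
#' injected in the arc-length/time domain: the timing map of each beat's
#' T loop is `tau(q) = s_RR * tau0(q) + sum_d C_d * delta_d(q) * (1 + b_d)`,
#' where `s_RR = 1 + betaDur * (RR - 1000) / T0` carries the heart-rate
#' dependence, `delta_d` is the drug's effect shape (see [effectShape()]),
#' `C_d` the subject's concentration at the timepoint, and `b_d` a
#' per-subject random effect-size deviation. The true trajectory quantile at
#' X% is `tau(X/100)` by construction and is emitted in the truth table.
#' Dipoles are projected onto the surface leads with the forward Dower
#' matrix; white noise and baseline wander are added to the independent
#' leads, so derived limb leads remain exactly consistent.
#'
#' @param design a [studyDesign()].
#' @param effectSpecs named list, one entry per drug:
#'   `list(delta = <function of q>, sigmaB = <relative SD of the subject
#'   effect slope>)`. Drugs without a spec have no ECG effect.
#' @param seed RNG seed; the same seed reproduces the study exactly.
#' @return list with `records` (list of [EcgRecord-class]), `pk` (long
#'   data.frame `subject_id`, `treatment`, `nominal_time_h`, `drug`,
#'   `conc`), `truth` (long data.frame with the true TrX per record and the
#'   population-level injected effect `true_dd`), `subjects` (the drawn
#'   per-subject parameters: RR offset, baseline loop duration, RR slope,
#'   effect-size deviation `b_effect` and PK scale per drug), and the
#'   `design`.
#' @export
simulateStudy <- function(design, effectSpecs = list(), seed = 1) {
  stopifnot(inherits(design, "StudyDesign"))
  set.seed(seed)
  fs <- design$fs
  T0 <- design$tDurationMs
  nSamples <- round(design$recordDurationS * fs)
  subjects <- sprintf("S%03d", seq_len(design$nSubjects))
  drugsAll <- unique(unlist(lapply(design$arms, function(a) names(a$drugs))))
  records <- list()
  pkRows <- list()
  truthRows <- list()
  subjRows <- list()
  qx <- seq(0.1, 1, 0.1)
  parNames <- paste0("Tr", seq(10, 100, 10))
  for (s in seq_along(subjects)) {
    sid <- subjects[s]
    rrOff <- rnorm(1, 0, design$rr$subjectSdMs)
    t0Subj <- T0 * (1 + rnorm(1, 0, 0.05))
    betaSubj <- design$betaDur * (1 + rnorm(1, 0, design$betaSubjSd))
    pkVar <- setNames(exp(rnorm(length(drugsAll), 0, 0.15)), drugsAll)
    bSubj <- setNames(vapply(drugsAll, function(d) {
      sb <- effectSpecs[[d]]$sigmaB %||% 0
      rnorm(1, 0, sb)
    }, 0), drugsAll)
    subjRows[[s]] <- data.frame(
      subject_id = sid, rr_offset_ms = rrOff, t0_ms = t0Subj,
      beta_rr = betaSubj,
      drug = if (length(drugsAll)) drugsAll else NA_character_,
      b_effect = if (length(drugsAll)) unname(bSubj) else NA_real_,
      pk_scale = if (length(drugsAll)) unname(pkVar) else NA_real_)
    for (arm in design$arms) {
      concByDrug <- lapply(arm$drugs, function(dg)
        simulatePkProfile(dg$dose, design$timepointsH, dg$ka, dg$ke,
                          dg$scale, dg$doseTimesH %||% 0))
      for (ti in seq_along(design$timepointsH)) {
        th <- design$timepointsH[ti]
        conc <- setNames(rep(0, length(drugsAll)), drugsAll)
        for (d in names(concByDrug))
          conc[d] <- concByDrug[[d]][ti] * pkVar[d]
        for (d in names(arm$drugs))
          pkRows[[length(pkRows) + 1]] <- data.frame(
            subject_id = sid, treatment = arm$name, nominal_time_h = th,
            drug = d, conc = conc[d])
        for (rep_ in seq_len(design$replicates)) {
          rrMs <- design$rr$meanMs + rrOff +
            design$rr$circadianAmpMs * cos(2 * pi * (th - 14) / 24) +
            rnorm(1, 0, design$rr$recordJitterSdMs)
          rrMs <- min(max(rrMs, 700), 1400)
          sRR <- 1 + betaSubj * (rrMs - 1000) / t0Subj
          tau <- local({
            cc <- conc; bb <- bSubj; s0 <- sRR; td <- t0Subj
            function(q) {
              v <- s0 * tauBaseline(q, td)
              for (d in names(effectSpecs))
                if (cc[d] > 0)
                  v <- v + cc[d] * effectSpecs[[d]]$delta(q) * (1 + bb[d])
              v
            }
          })
          # beats share the record's timing map but their fiducial layout
          # jitters a little beat to beat, as in real sinus rhythm; this is
          # what gives replicate ECGs their few-ms parameter spread
          beat1 <- simulateDipoleBeat(
            dipoleBeatParams(rrMs = rrMs, fs = fs,
                             tAmplitudeUv = design$tAmplitudeUv,
                             tDurationMs = T0), tau = tau)
          nBeatS <- nrow(beat1$xyz)
          nBeats <- nSamples %/% nBeatS
          beatsK <- lapply(seq_len(nBeats), function(k) {
            if (k == 1) return(beat1)
            dj <- runif(1, -2, 2)
            simulateDipoleBeat(
              dipoleBeatParams(rrMs = rrMs, fs = fs,
                               tAmplitudeUv = design$tAmplitudeUv,
                               tDurationMs = T0, pEndMs = 120 + dj,
                               qMs = 170 + dj, jMs = 260 + dj), tau = tau)
          })
          xyz <- do.call(rbind, lapply(beatsK, `[[`, "xyz"))
          if (nrow(xyz) < nSamples)
            xyz <- rbind(xyz, matrix(0, nSamples - nrow(xyz), 3))
          ann <- do.call(rbind, lapply(beatsK, function(b) b$annotation))
          offs <- (seq_len(nBeats) - 1) * nBeatS
          for (cn in c("p_idx", "q_idx", "j_idx", "tend_idx"))
            ann[[cn]] <- ann[[cn]] + offs
          ann$rr_ms <- c(NA_real_, rep(rrMs, nBeats - 1))
          beat <- beat1
          leads8 <- vcgXyz(new("Vcg", xyz = xyz, samplingRate = fs)) %*%
            t(forwardDowerMatrix())
          colnames(leads8) <- rownames(forwardDowerMatrix())
          leads8 <- .addLeadNoise(leads8, design$noise, fs,
                                  runif(8, 0, 2 * pi))
          records[[length(records) + 1]] <- EcgRecord(
            leads8, samplingRate = fs, beats = ann, subjectId = sid,
            treatment = arm$name, nominalTimeH = th, replicate = rep_)
          trueDd <- vapply(qx, function(q) {
            v <- 0
            for (d in names(effectSpecs))
              if (conc[d] > 0) v <- v + conc[d] * effectSpecs[[d]]$delta(q)
            v
          }, 0)
          truthRows[[length(truthRows) + 1]] <- data.frame(
            subject_id = sid, treatment = arm$name, nominal_time_h = th,
            replicate = rep_, parameter = parNames,
            value = unname(beat$trueTrx), true_dd = trueDd)
        }
      }
    }
  }
  list(records = records,
       pk = do.call(rbind, pkRows),
       truth = do.call(rbind, truthRows),
       subjects = do.call(rbind, subjRows),
       design = design)
}

#' Write a simulated study to disk
#'
#' Records are written in the `csv_json` dialect (one `recNNNN.csv/.json`
#' pair each), concentrations to `pk.csv` and the ground truth to
#' `truth.csv`, so the command-line pipeline can be exercised end to end.
#'
#' @param study output of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(study$records))
    writeEcgRecord(study$records[[k]],
                   file.path(dir, sprintf("rec%04d.csv", k)))
  utils::write.csv(study$pk, file.path(dir, "pk.csv"), row.names = FALSE)
  utils::write.csv(study$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' End-to-end effect profile of one study arm
#'
#' Convenience chain for simulated or imported studies: biomarker table ->
#' heart-rate correction (model fitted on the drug-free data) -> replicate
#' averaging and single/double deltas -> concentration join -> per-quantile
#' exposure-response models -> [effectProfile()] at the representative
#' concentration(s).
#'
#' @param qtab long biomarker table ([studyQuantileTable()]).
#' @param pk long PK table.
#' @param treatments treatment period(s) pooled into the fit.
#' @param drugs drug name(s) giving the concentration columns.
#' @param repConc named representative concentration(s) (defaults to the
#'   geometric mean of the positive pooled concentrations per drug).
#' @param placebo,baselineTime placebo label and baseline nominal time.
#' @param rateModel optional prefitted [RateCorrectionModel-class]; fitted
#'   on the table's drug-free subset when omitted.
#' @param interaction include the two-drug interaction term.
#' @param nBoot,seed bootstrap settings for [effectProfile()].
#' @return An [EffectProfile-class].
#' @export
armEffectProfile <- function(qtab, pk, treatments, drugs, repConc = NULL,
                             placebo = "Placebo", baselineTime = 0,
                             rateModel = NULL, interaction = TRUE,
                             nBoot = 2000L, seed = NULL) {
  if (is.null(rateModel))
    rateModel <- fitRateModel(drugFreeTable(qtab, placebo, baselineTime))
  ctab <- correctBiomarkerTable(qtab, rateModel)
  dd <- doubleDelta(singleDelta(ctab, baselineTime), placebo)
  dd <- dd[dd$treatment %in% treatments, ]
  dd <- joinConcentrations(dd, pk, drugs)
  if (is.null(repConc))
    repConc <- vapply(drugs, function(d) {
      v <- dd[[d]][dd[[d]] > 0]
      if (!length(v)) stop("all-zero concentrations for drug ", d)
      exp(mean(log(v)))
    }, 0)
  effectProfile(dd, repConc, concCols = drugs, interaction = interaction,
                nBoot = nBoot, seed = seed)
}
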