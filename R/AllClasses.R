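#' @import methods
NULL

#' Standard 12-lead names
#'
#' Lead naming used throughout the package. The eight independent leads are
#' I, II and V1-V6; III, aVR, aVL and aVF are linear combinations of I and II.
#'
#' @format Character vectors.
#' @name lead-names
#' @keywords internal
LEADS_12 <- c("I", "II", "III", "aVR", "aVL", "aVF",
              "V1", "V2", "V3", "V4", "V5", "V6")

#' @rdname lead-names
#' @keywords internal
LEADS_INDEPENDENT <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")

BEAT_CLASSES <- c("normal_sinus", "other")

.emptyBeats <- function() {
  data.frame(p_idx = integer(0), q_idx = integer(0), j_idx = integer(0),
             tend_idx = integer(0), beat_class = character(0),
             rr_ms = numeric(0))
}

#' EcgRecord: an annotated 12-lead ECG
#'
#' Container for one extracted ECG: a samples-by-leads amplitude matrix in
#' microvolts, the sampling rate, per-beat fiducial annotations (P offset,
#' Q onset, J point, T end; 0-based sample indices) and the study metadata
#' needed downstream (subject, treatment, nominal time, replicate).
#'
#' @slot signals numeric matrix, samples x leads, column names are lead names
#'   (at least the eight independent leads I, II, V1-V6), amplitudes in uV.
#' @slot samplingRate sampling rate in Hz.
#' @slot amplitudeResolution amplitude quantization in uV/LSB (informational).
#' @slot subjectId opaque subject identifier.
#' @slot treatment treatment arm label.
#' @slot nominalTimeH nominal time in hours relative to the first morning dose.
#' @slot replicate replicate index (>= 1) within the timepoint.
#' @slot beats data.frame with columns `p_idx`, `q_idx`, `j_idx`, `tend_idx`
#'   (0-based sample indices), `beat_class` ("normal_sinus" or "other") and
#'   `rr_ms` (interval to the previous beat; NA for the first).
#' @slot zeroedLeads character vector of leads that were zeroed out as noisy.
#'
#' @seealso [readEcgRecord()], [validateAnnotations()], [recordQuantiles()]
#' @exportClass EcgRecord
setClass("EcgRecord",
  representation(
    signals = "matrix",
    samplingRate = "numeric",
    amplitudeResolution = "numeric",
    subjectId = "character",
    treatment = "character",
    nominalTimeH = "numeric",
    replicate = "integer",
    beats = "data.frame",
    zeroedLeads = "character"
  ),
  prototype(
    samplingRate = 500,
    amplitudeResolution = 2.5,
    subjectId = NA_character_,
    treatment = NA_character_,
    nominalTimeH = NA_real_,
    replicate = 1L,
    beats = .emptyBeats(),
    zeroedLeads = character(0)
  )
)

setValidity("EcgRecord", function(object) {
  msg <- character(0)
  sig <- object@signals
  if (!is.numeric(sig) || is.null(colnames(sig)))
    return("signals must be a numeric matrix with lead names as colnames")
  if (length(object@samplingRate) != 1 || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  missing <- setdiff(LEADS_INDEPENDENT, colnames(sig))
  if (length(missing))
    msg <- c(msg, paste0("missing lead: ", paste(missing, collapse = ", ")))
  if (all(c("I", "II", "III") %in% colnames(sig)) &&
      !all(c("I", "II", "III") %in% object@zeroedLeads)) {
    dev <- max(abs(sig[, "II"] - sig[, "I"] - sig[, "III"]))
    if (is.finite(dev) && dev > 1)
      msg <- c(msg, sprintf(
        "derived lead inconsistency: max |II - I - III| = %.2f uV (> 1 uV)", dev))
  }
  b <- object@beats
  need <- c("p_idx", "q_idx", "j_idx", "tend_idx", "beat_class", "rr_ms")
  if (!all(need %in% names(b))) {
    msg <- c(msg, "beats must have columns p_idx, q_idx, j_idx, tend_idx, beat_class, rr_ms")
  } else if (nrow(b)) {
    if (any(!(b$beat_class %in% BEAT_CLASSES)))
      msg <- c(msg, "invalid annotation: unknown beat_class")
    if (any(!(b$p_idx < b$q_idx & b$q_idx < b$j_idx & b$j_idx < b$tend_idx)))
      msg <- c(msg, "invalid annotation: fiducials must satisfy p < q < j < tend")
    if (any(b$p_idx < 0) || any(b$tend_idx > nrow(sig) - 1))
      msg <- c(msg, "invalid annotation: fiducial index out of record range")
    if (is.unsorted(b$q_idx, strictly = FALSE))
      msg <- c(msg, "invalid annotation: beats must be sorted by Q index")
  }
  if (length(msg)) msg else TRUE
})

#' Vcg: a vectorcardiographic dipole trajectory
#'
#' Three orthogonal dipole components (x to the body's front, y to the left,
#' z with negative direction toward the feet) sampled at a common rate,
#' typically reconstructed from the 8 independent surface leads with the
#' inverse Dower transform.
#'
#' @slot xyz numeric matrix, samples x 3, columns x, y, z, in uV.
#' @slot samplingRate sampling rate in Hz.
#' @seealso [inverseDower()], [extractTLoop()]
#' @exportClass Vcg
setClass("Vcg",
  representation(xyz = "matrix", samplingRate = "numeric"))

setValidity("Vcg", function(object) {
  if (!is.numeric(object@xyz) || ncol(object@xyz) != 3)
    return("xyz must be a numeric matrix with 3 columns")
  if (object@samplingRate <= 0) return("samplingRate must be positive")
  TRUE
})

#' TLoop: T-vector trajectory of one beat
#'
#' The VCG restricted to the repolarization window [J + 20 ms, Tend]
#' (closed, in samples), with the T-vector strength (TVS), T-vector velocity
#' (TVV) and the normalized cumulative trajectory length alongside.
#'
#' @slot xyz dipole trajectory over the window, samples x 3, uV.
#' @slot samplingRate Hz.
#' @slot startIdx,endIdx 0-based sample indices of the window in the parent
#'   record (startIdx = j_idx + round(0.020 * fs)).
#' @slot tvs Euclidean dipole magnitude per sample (uV).
#' @slot tvv Euclidean dipole speed per sample (uV/ms), Savitzky-Golay
#'   derivatives computed on the full-length VCG and then windowed.
#' @slot cumLengthNorm normalized cumulative trajectory length in [0, 1],
#'   non-decreasing, 0 at the first sample and 1 at the last.
#' @seealso [extractTLoop()], [trajectoryQuantiles()]
#' @exportClass TLoop
setClass("TLoop",
  representation(xyz = "matrix", samplingRate = "numeric",
                 startIdx = "integer", endIdx = "integer",
                 tvs = "numeric", tvv = "numeric",
                 cumLengthNorm = "numeric"))

setValidity("TLoop", function(object) {
  n <- nrow(object@xyz)
  if (length(object@tvs) != n || length(object@tvv) != n)
    return("tvs and tvv must have one value per sample")
  if (length(object@cumLengthNorm)) {
    cl <- object@cumLengthNorm
    if (length(cl) != n) return("cumLengthNorm must have one value per sample")
    if (any(diff(cl) < -1e-12)) return("cumLengthNorm must be non-decreasing")
    if (abs(cl[1]) > 1e-9 || abs(cl[n] - 1) > 1e-9)
      return("cumLengthNorm must start at 0 and end at 1")
  }
  TRUE
})

#' TrajectoryQuantiles: per-record TrX biomarkers
#'
#' The ten T-vector trajectory quantiles Tr10..Tr100 (ms from loop start,
#' averaged over the usable normal sinus beats of one ECG), together with the
#' record's mean RR, QT and Fridericia-corrected QT.
#'
#' @slot trx named numeric vector `Tr10` .. `Tr100`, in ms.
#' @slot rrMs mean beat interval (ms).
#' @slot qtMs mean QT interval (ms).
#' @slot qtcfMs Fridericia-corrected QT (ms).
#' @slot nBeatsUsed number of beats averaged.
#' @seealso [recordQuantiles()]
#' @exportClass TrajectoryQuantiles
setClass("TrajectoryQuantiles",
  representation(trx = "numeric", rrMs = "numeric", qtMs = "numeric",
                 qtcfMs = "numeric", nBeatsUsed = "integer"))

setValidity("TrajectoryQuantiles", function(object) {
  tr <- object@trx
  if (is.null(names(tr))) return("trx must be a named vector")
  if (any(diff(tr) < -1e-9)) return("TrX must be non-decreasing in X")
  TRUE
})

#' RateCorrectionModel: heart-rate dependence of TrX parameters
#'
#' Fixed-effect slopes (ms per ms of RR) of each biomarker against RR,
#' estimated on drug-free data with a linear mixed model with per-subject
#' random intercept and slope. Frozen after fitting; corrections are applied
#' with `TrXc = TrX - beta * (RR - 1000)`.
#'
#' @slot coefficients data.frame with one row per parameter: `parameter`,
#'   `intercept`, `beta`, `se_beta`, `sd_rand_intercept`, `sd_rand_slope`,
#'   `cor_rand`, `singular` (logical: independent random effects fallback
#'   used).
#' @slot nSubjects,nObservations fit sizes.
#' @seealso [fitRateModel()], [applyRateCorrection()]
#' @exportClass RateCorrectionModel
setClass("RateCorrectionModel",
  representation(coefficients = "data.frame", nSubjects = "integer",
                 nObservations = "integer"))

setValidity("RateCorrectionModel", function(object) {
  if (!all(c("parameter", "beta") %in% names(object@coefficients)))
    return("coefficients must contain 'parameter' and 'beta'")
  if (any(!is.finite(object@coefficients$beta)))
    return("beta estimates must be finite")
  if (object@nSubjects < 2) return("at least 2 subjects required")
  TRUE
})

#' EffectProfile: per-quantile drug effect at a representative concentration
#'
#' Model-predicted placebo-corrected change from baseline (ms) of each
#' trajectory quantile at fixed representative drug concentration(s), with
#' percentile 95% confidence intervals from a subject-level bootstrap.
#'
#' @slot profile data.frame: `parameter`, `estimate`, `lo`, `hi` (ms).
#' @slot repConc named numeric vector of representative concentration(s) used.
#' @slot nBoot number of bootstrap replicates.
#' @slot nFailed bootstrap replicates dropped for fit failure.
#' @seealso [effectProfile()]
#' @exportClass EffectProfile
setClass("EffectProfile",
  representation(profile = "data.frame", repConc = "numeric",
                 nBoot = "integer", nFailed = "integer"))

setValidity("EffectProfile", function(object) {
  p <- object@profile
  if (!all(c("parameter", "estimate", "lo", "hi") %in% names(p)))
    return("profile must have parameter, estimate, lo, hi")
  ok <- is.na(p$lo) | is.na(p$hi) | (p$lo <= p$estimate & p$estimate <= p$hi)
  if (!all(ok)) return("confidence bounds must bracket the estimate")
  TRUE
})

#' DiscriminationResult: AUC with stratified-bootstrap CI
#'
#' Area under the ROC curve for separating pure hERG/iKr-block observations
#' from multichannel-block observations, with a percentile confidence
#' interval from class-stratified resampling.
#'
#' @slot features feature names used by the classifier.
#' @slot auc,lo,hi AUC point estimate and 95% CI.
#' @slot nBoot bootstrap replicates.
#' @slot nPos,nNeg observations per class.
#' @seealso [bootstrapAucCi()], [rocAuc()]
#' @exportClass DiscriminationResult
setClass("DiscriminationResult",
  representation(features = "character", auc = "numeric", lo = "numeric",
                 hi = "numeric", nBoot = "integer", nPos = "integer",
                 nNeg = "integer"))

setValidity("DiscriminationResult", function(object) {
  v <- c(object@lo, object@auc, object@hi)
  if (any(v < -1e-9) || any(v > 1 + 1e-9)) return("AUC values must be in [0, 1]")
  if (!(object@lo <= object@auc && object@auc <= object@hi))
    return("must satisfy lo <= AUC <= hi")
  TRUE
})
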