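#' Construct an EcgRecord
#'
#' @param signals samples x leads numeric matrix (uV) with lead names as
#'   column names. Must contain at least I, II and V1-V6; missing derived
#'   limb leads (III, aVR, aVL, aVF) are synthesized from I and II.
#' @param samplingRate sampling rate in Hz.
#' @param beats data.frame of beat annotations (0-based `p_idx`, `q_idx`,
#'   `j_idx`, `tend_idx`, plus `beat_class` and `rr_ms`). `beat_class`
#'   defaults to "normal_sinus", `rr_ms` to successive Q-to-Q intervals.
#' @param subjectId,treatment,nominalTimeH,replicate study metadata.
#' @param amplitudeResolution quantization step in uV/LSB (informational).
#' @param zeroedLeads leads already zeroed as noisy.
#' @return A validated [EcgRecord-class] object.
#' @examples
#' sig <- matrix(0, 1000, 8, dimnames = list(NULL, c("I","II","V1","V2","V3","V4","V5","V6")))
#' rec <- EcgRecord(sig, samplingRate = 500)
#' @export
EcgRecord <- function(signals, samplingRate = 500, beats = NULL,
                      subjectId = NA_character_, treatment = NA_character_,
                      nominalTimeH = NA_real_, replicate = 1L,
                      amplitudeResolution = 2.5, zeroedLeads = character(0)) {
  signals <- as.matrix(signals)
  missing <- setdiff(LEADS_INDEPENDENT, colnames(signals))
  if (length(missing))
    stop("missing lead: ", paste(missing, collapse = ", "))
  signals <- synthesizeDerivedLeads(signals)
  if (is.null(beats)) beats <- .emptyBeats()
  beats <- as.data.frame(beats)
  if (nrow(beats)) {
    if (is.null(beats$beat_class)) beats$beat_class <- "normal_sinus"
    beats <- beats[order(beats$q_idx), , drop = FALSE]
    rownames(beats) <- NULL
    if (is.null(beats$rr_ms))
      beats$rr_ms <- c(NA_real_, diff(beats$q_idx) / samplingRate * 1000)
  } else {
    beats <- .emptyBeats()
  }
  for (col in c("p_idx", "q_idx", "j_idx", "tend_idx"))
    beats[[col]] <- as.integer(beats[[col]])
  beats$rr_ms <- as.numeric(beats$rr_ms)
  beats$beat_class <- as.character(beats$beat_class)
  new("EcgRecord", signals = signals, samplingRate = samplingRate,
      amplitudeResolution = amplitudeResolution, subjectId = subjectId,
      treatment = treatment, nominalTimeH = nominalTimeH,
      replicate = as.integer(replicate), beats = beats,
      zeroedLeads = zeroedLeads)
}

#' Synthesize derived limb leads from I and II
#'
#' Fills in III = II - I, aVR = -(I + II)/2, aVL = I - II/2, aVF = II - I/2
#' for any of those leads absent from the matrix.
#'
#' @param signals samples x leads matrix containing at least I and II.
#' @return matrix with all 12 leads, ordered I, II, III, aVR, aVL, aVF, V1-V6.
#' @keywords internal
synthesizeDerivedLeads <- function(signals) {
  I <- signals[, "I"]; II <- signals[, "II"]
  derived <- list(III = II - I, aVR = -(I + II) / 2, aVL = I - II / 2,
                  aVF = II - I / 2)
  for (nm in names(derived))
    if (!nm %in% colnames(signals)) {
      signals <- cbind(signals, derived[[nm]])
      colnames(signals)[ncol(signals)] <- nm
    }
  signals[, intersect(LEADS_12, colnames(signals)), drop = FALSE]
}

#' @rdname EcgRecord-class
#' @param object,x an `EcgRecord`.
#' @export
setGeneric("leadSignals", function(x) standardGeneric("leadSignals"))
#' @rdname EcgRecord-class
#' @export
setMethod("leadSignals", "EcgRecord", function(x) x@signals)

#' @rdname EcgRecord-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname EcgRecord-class
#' @export
setMethod("samplingRate", "EcgRecord", function(x) x@samplingRate)
#' @rdname EcgRecord-class
#' @export
setMethod("samplingRate", "Vcg", function(x) x@samplingRate)

#' @rdname EcgRecord-class
#' @export
setGeneric("beats", function(x) standardGeneric("beats"))
#' @rdname EcgRecord-class
#' @export
setMethod("beats", "EcgRecord", function(x) x@beats)

#' @rdname EcgRecord-class
#' @export
setGeneric("zeroedLeads", function(x) standardGeneric("zeroedLeads"))
#' @rdname EcgRecord-class
#' @export
setMethod("zeroedLeads", "EcgRecord", function(x) x@zeroedLeads)

#' @rdname EcgRecord-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname EcgRecord-class
#' @export
setMethod("subjectId", "EcgRecord", function(x) x@subjectId)

setMethod("show", "EcgRecord", function(object) {
  cat(sprintf("EcgRecord: %d leads x %d samples @ %g Hz (%.1f s)\n",
              ncol(object@signals), nrow(object@signals),
              object@samplingRate,
              nrow(object@signals) / object@samplingRate))
  cat(sprintf("  subject %s | treatment %s | t = %s h | replicate %d\n",
              object@subjectId, object@treatment,
              format(object@nominalTimeH), object@replicate))
  nb <- nrow(object@beats)
  cat(sprintf("  %d annotated beat%s (%d normal sinus)",
              nb, if (nb == 1) "" else "s",
              sum(object@beats$beat_class == "normal_sinus")))
  if (length(object@zeroedLeads))
    cat(" | zeroed:", paste(object@zeroedLeads, collapse = ","))
  cat("\n")
})

#' Coordinates of a VCG
#' @param x a `Vcg` or `TLoop`.
#' @return samples x 3 matrix with columns x, y, z (uV).
#' @export
setGeneric("vcgXyz", function(x) standardGeneric("vcgXyz"))
#' @rdname vcgXyz
#' @export
setMethod("vcgXyz", "Vcg", function(x) x@xyz)
#' @rdname vcgXyz
#' @export
setMethod("vcgXyz", "TLoop", function(x) x@xyz)

setMethod("show", "Vcg", function(object) {
  cat(sprintf("Vcg: %d samples @ %g Hz\n", nrow(object@xyz),
              object@samplingRate))
})

setMethod("show", "TLoop", function(object) {
  dur <- (nrow(object@xyz) - 1) / object@samplingRate * 1000
  cat(sprintf("TLoop: samples [%d, %d] (%.0f ms), peak TVS %.0f uV, peak TVV %.2f uV/ms\n",
              object@startIdx, object@endIdx, dur,
              max(object@tvs), max(object@tvv)))
})

#' @rdname TrajectoryQuantiles-class
#' @param x a `TrajectoryQuantiles`.
#' @export
setGeneric("trxValues", function(x) standardGeneric("trxValues"))
#' @rdname TrajectoryQuantiles-class
#' @export
setMethod("trxValues", "TrajectoryQuantiles", function(x) x@trx)

setMethod("show", "TrajectoryQuantiles", function(object) {
  cat(sprintf("TrajectoryQuantiles (%d beats): RR %.0f ms, QTcF %.1f ms\n",
              object@nBeatsUsed, object@rrMs, object@qtcfMs))
  print(round(object@trx, 2))
})

#' @rdname RateCorrectionModel-class
#' @param x,object a `RateCorrectionModel`.
#' @export
setGeneric("rateBeta", function(x) standardGeneric("rateBeta"))
#' @rdname RateCorrectionModel-class
#' @export
setMethod("rateBeta", "RateCorrectionModel", function(x) {
  stats::setNames(x@coefficients$beta, x@coefficients$parameter)
})

setMethod("show", "RateCorrectionModel", function(object) {
  cat(sprintf("RateCorrectionModel: %d parameters, %d subjects, %d observations\n",
              nrow(object@coefficients), object@nSubjects,
              object@nObservations))
  print(object@coefficients[, c("parameter", "beta", "se_beta", "singular")],
        row.names = FALSE, digits = 4)
})

#' @rdname EffectProfile-class
#' @param x,object an `EffectProfile`.
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))
#' @rdname EffectProfile-class
#' @export
setMethod("profileTable", "EffectProfile", function(x) x@profile)

setMethod("show", "EffectProfile", function(object) {
  cat(sprintf("EffectProfile at C = (%s), %d bootstrap replicates (%d failed)\n",
              paste(sprintf("%s=%g", names(object@repConc), object@repConc),
                    collapse = ", "),
              object@nBoot, object@nFailed))
  print(object@profile, row.names = FALSE, digits = 3)
})

setMethod("show", "DiscriminationResult", function(object) {
  cat(sprintf("DiscriminationResult [%s]: AUC %.3f (95%% CI %.3f-%.3f), n = %d/%d, %d replicates\n",
              paste(object@features, collapse = " + "), object@auc,
              object@lo, object@hi, object@nPos, object@nNeg, object@nBoot))
})

#' @rdname DiscriminationResult-class
#' @param x a `DiscriminationResult`.
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))
#' @rdname DiscriminationResult-class
#' @export
setMethod("aucValue", "DiscriminationResult", function(x)
  c(auc = x@auc, lo = x@lo, hi = x@hi))
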