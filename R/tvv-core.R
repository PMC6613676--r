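#' T-vector strength
#'
#' Euclidean magnitude of the dipole vector per sample,
#' `TVS(t) = sqrt(x^2 + y^2 + z^2)`. This is the vector-magnitude signal on
#' which conventional T-peak measurements are made.
#'
#' @param x a [TLoop-class], [Vcg-class], or samples x 3 matrix.
#' @return numeric vector (uV), non-negative.
#' @export
computeTvs <- function(x) {
  m <- if (is(x, "TLoop") || is(x, "Vcg")) vcgXyz(x) else as.matrix(x)
  sqrt(rowSums(m^2))
}

#' T-vector velocity
#'
#' Speed of the dipole's progression along its spatial trajectory:
#' each VCG component is differentiated with a Savitzky-Golay filter
#' (polynomial order 3, window of 60 ms -- 31 samples at 500 Hz) and the
#' Euclidean norm of the three derivatives is taken.
#' `TVV(t) = sqrt(xdot^2 + ydot^2 + zdot^2)`, in uV/ms.
#'
#' @param vcg a [Vcg-class] or samples x 3 matrix.
#' @param fs sampling rate in Hz (taken from the object when a `Vcg`).
#' @return numeric vector of speeds (uV/ms), one per sample.
#' @export
computeTvv <- function(vcg, fs = NULL) {
  m <- if (is(vcg, "Vcg")) vcgXyz(vcg) else as.matrix(vcg)
  if (is(vcg, "Vcg")) fs <- vcg@samplingRate
  if (is.null(fs)) stop("sampling rate required")
  n <- sgWindowLength(fs)
  if (nrow(m) < n)
    stop("signal too short for the derivative filter (need >= ", n, " samples)")
  # ts is the sample spacing in ms, so the derivative comes out in uV/ms
  d <- apply(m, 2, function(x)
    signal::sgolayfilt(x, p = 3, n = n, m = 1, ts = 1000 / fs))
  sqrt(rowSums(d^2))
}

#' Extract the T loop of one beat
#'
#' Restricts the VCG to the repolarization window
#' `[j_idx + round(0.020 * fs), tend_idx]` (closed, in samples) and attaches
#' the TVS, TVV and normalized cumulative trajectory-length series. The
#' derivatives are computed on the full-length VCG and then windowed, so no
#' filter edge transients fall inside the loop.
#'
#' @param vcg a [Vcg-class] covering (at least) the whole beat.
#' @param beat one-row data.frame (or list) with `j_idx` and `tend_idx`
#'   (0-based).
#' @param tvv optional precomputed full-length TVV series (saves recomputing
#'   it per beat when several beats share one VCG).
#' @return A [TLoop-class]. Its `cumLengthNorm` is empty when the trajectory
#'   is degenerate (zero total length).
#' @export
extractTLoop <- function(vcg, beat, tvv = NULL) {
  stopifnot(is(vcg, "Vcg"))
  fs <- vcg@samplingRate
  j <- as.integer(beat$j_idx); tend <- as.integer(beat$tend_idx)
  if (tend - j < .minJTendSamples(fs))
    stop("unusable beat: J-to-Tend window too short (",
         tend - j, " samples)")
  start <- j + as.integer(round(0.020 * fs))
  if (tend > nrow(vcg@xyz) - 1) stop("invalid annotation: tend out of range")
  if (is.null(tvv)) tvv <- computeTvv(vcg)
  idx <- (start + 1):(tend + 1)
  xyz <- vcg@xyz[idx, , drop = FALSE]
  tvvw <- tvv[idx]
  dtMs <- 1000 / fs
  # trapezoidal cumulative trajectory length, matching the linear quantile readout
  L <- c(0, cumsum((tvvw[-1] + tvvw[-length(tvvw)]) / 2 * dtMs))
  cl <- if (L[length(L)] > 0) L / L[length(L)] else numeric(0)
  new("TLoop", xyz = xyz, samplingRate = fs, startIdx = as.integer(start),
      endIdx = as.integer(tend), tvs = computeTvs(xyz), tvv = tvvw,
      cumLengthNorm = cl)
}

#' T-vector trajectory quantiles of one loop
#'
#' Normalizes the cumulative trajectory length to 1 and reads off, for each
#' X in the quantile set, the earliest time (ms from loop start) at which
#' X% of the total trajectory length has been reached, with linear
#' interpolation between the bracketing samples. Tr100 equals the loop
#' duration (J + 20 ms to Tend).
#'
#' @param loop a [TLoop-class].
#' @param quantileSet integer percentages, default `seq(10, 100, 10)`.
#' @return named numeric vector (`Tr10` ... `Tr100`), ms from loop start.
#' @export
trajectoryQuantiles <- function(loop, quantileSet = seq(10L, 100L, 10L)) {
  stopifnot(is(loop, "TLoop"))
  cl <- loop@cumLengthNorm
  if (!length(cl)) stop("degenerate trajectory: total length is zero")
  n <- length(cl)
  dtMs <- 1000 / loop@samplingRate
  tMs <- (seq_len(n) - 1) * dtMs
  durMs <- tMs[n]
  vals <- vapply(quantileSet, function(X) {
    if (X >= 100) return(durMs)
    f <- X / 100
    i <- which(cl >= f)[1]
    if (is.na(i)) return(durMs)
    if (i == 1) return(0)
    tMs[i - 1] + (f - cl[i - 1]) / (cl[i] - cl[i - 1]) * dtMs
  }, 0)
  stats::setNames(vals, paste0("Tr", quantileSet))
}

#' Fridericia heart-rate correction of QT
#'
#' `QTcF = QT / (RR / 1000)^(1/3)` with QT and RR in ms.
#'
#' @param qtMs QT interval (ms).
#' @param rrMs average beat interval (ms), must be positive.
#' @return corrected QT (ms).
#' @examples
#' fridericiaQtc(400, 1000)  # 400
#' @export
fridericiaQtc <- function(qtMs, rrMs) {
  if (any(!is.finite(rrMs)) || any(rrMs <= 0))
    stop("RR must be positive")
  qtMs / (rrMs / 1000)^(1 / 3)
}

#' Per-record trajectory quantiles
#'
#' Runs the full per-ECG chain: isoelectric baseline correction, zero-phase
#' Bessel low-pass, inverse Dower VCG reconstruction, per-beat T-loop
#' quantiles for the usable normal sinus beats (minimum 3), and the
#' arithmetic mean of each quantile across beats. Also returns the record's
#' mean RR, mean QT (Q to Tend) and Fridericia-corrected QT.
#'
#' @param record an [EcgRecord-class].
#' @param cutoffHz low-pass cutoff (Hz), default 36.
#' @param preprocess set `FALSE` to skip baseline correction and filtering
#'   (e.g. for already-conditioned signals).
#' @param dowerMatrix inverse transformation matrix, see [inverseDower()].
#' @param quantileSet quantile percentages.
#' @return A [TrajectoryQuantiles-class].
#' @export
recordQuantiles <- function(record, cutoffHz = 36, preprocess = TRUE,
                            dowerMatrix = inverseDowerMatrix(),
                            quantileSet = seq(10L, 100L, 10L)) {
  stopifnot(is(record, "EcgRecord"))
  use <- selectNormalBeats(record)
  if (preprocess) {
    record <- correctIsoelectric(record)
    record <- besselLowpass(record, cutoffHz)
  }
  vcg <- inverseDower(record, matrix = dowerMatrix)
  tvv <- computeTvv(vcg)
  fs <- record@samplingRate
  rows <- list()
  for (i in seq_len(nrow(use))) {
    loop <- extractTLoop(vcg, use[i, ], tvv = tvv)
    q <- tryCatch(trajectoryQuantiles(loop, quantileSet),
                  error = function(e) NULL)
    if (!is.null(q)) rows[[length(rows) + 1]] <- q
  }
  if (!length(rows)) stop("degenerate trajectory: all beats degenerate")
  trx <- colMeans(do.call(rbind, rows))
  rr <- use$rr_ms[is.finite(use$rr_ms)]
  rrMs <- if (length(rr)) mean(rr) else
    mean(diff(use$q_idx)) / fs * 1000
  qtMs <- mean((use$tend_idx - use$q_idx) / fs * 1000)
  new("TrajectoryQuantiles", trx = trx, rrMs = rrMs, qtMs = qtMs,
      qtcfMs = fridericiaQtc(qtMs, rrMs), nBeatsUsed = length(rows))
}

#' Biomarker table for a set of records
#'
#' Applies [recordQuantiles()] to every record and assembles the long-format
#' biomarker table used by all downstream statistics (one row per record and
#' parameter: Tr10..Tr100, RR, QT, QTcF). Records failing validation or with
#' degenerate trajectories are excluded; the reasons are attached as the
#' `"excluded"` attribute and reported via a message.
#'
#' @param records list of [EcgRecord-class] objects.
#' @param ... passed to [recordQuantiles()].
#' @return data.frame with columns `subject_id`, `treatment`,
#'   `nominal_time_h`, `replicate`, `parameter`, `value`.
#' @export
studyQuantileTable <- function(records, ...) {
  out <- vector("list", length(records))
  excluded <- character(0)
  for (k in seq_along(records)) {
    rec <- records[[k]]
    tq <- tryCatch(recordQuantiles(rec, ...), error = function(e) e)
    if (inherits(tq, "error")) {
      excluded <- c(excluded, sprintf("record %d (%s/%s/t=%s/r%d): %s",
                                      k, rec@subjectId, rec@treatment,
                                      format(rec@nominalTimeH),
                                      rec@replicate, conditionMessage(tq)))
      next
    }
    vals <- c(tq@trx, RR = tq@rrMs, QT = tq@qtMs, QTcF = tq@qtcfMs)
    out[[k]] <- data.frame(
      subject_id = rec@subjectId, treatment = rec@treatment,
      nominal_time_h = rec@nominalTimeH, replicate = rec@replicate,
      parameter = names(vals), value = unname(vals))
  }
  if (length(excluded))
    message(length(excluded), " record(s) excluded: ",
            paste(utils::head(excluded, 3), collapse = "; "),
            if (length(excluded) > 3) " ..." else "")
  keep <- !vapply(out, is.null, TRUE)
  if (!any(keep)) stop("no usable records: ",
                       paste(utils::head(excluded, 2), collapse = "; "))
  res <- do.call(rbind, out[keep])
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}
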