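#' Isoelectric baseline correction
#'
#' For every lead, a baseline curve is estimated from one knot per annotated
#' beat -- the median amplitude over the PQ segment `[p_idx, q_idx]`, placed
#' at the PQ midpoint -- interpolated across beats by a natural cubic spline
#' (constant extrapolation beyond the first/last knot) and subtracted. With
#' fewer than two beats the correction degenerates to subtracting a single
#' constant (the PQ median, or the whole-lead median when no beat exists).
#'
#' @param record an [EcgRecord-class].
#' @return corrected [EcgRecord-class] of identical shape.
#' @export
correctIsoelectric <- function(record) {
  stopifnot(is(record, "EcgRecord"))
  b <- record@beats
  sig <- record@signals
  n <- nrow(sig)
  t <- seq_len(n) - 1
  for (j in seq_len(ncol(sig))) {
    x <- sig[, j]
    if (nrow(b) >= 2) {
      knotT <- (b$p_idx + b$q_idx) / 2
      knotV <- vapply(seq_len(nrow(b)), function(i)
        stats::median(x[(b$p_idx[i] + 1):(b$q_idx[i] + 1)]), 0)
      tt <- pmin(pmax(t, min(knotT)), max(knotT))
      base <- stats::spline(knotT, knotV, xout = tt, method = "natural",
                            ties = mean)$y
    } else if (nrow(b) == 1) {
      base <- stats::median(x[(b$p_idx[1] + 1):(b$q_idx[1] + 1)])
    } else {
      base <- stats::median(x)
    }
    sig[, j] <- x - base
  }
  # median baselines are estimated per lead, which would leave the derived
  # limb leads a few uV off their defining identities; recompute them from
  # the corrected I and II
  derived <- intersect(c("III", "aVR", "aVL", "aVF"), colnames(sig))
  if (length(derived) && !any(c("I", "II") %in% record@zeroedLeads))
    sig <- synthesizeDerivedLeads(sig[, setdiff(colnames(sig), derived),
                                      drop = FALSE])
  initialize(record, signals = sig)
}

#' Design the digital low-pass Bessel filter
#'
#' Order-2 analog Bessel prototype (poles of s^2 + 3 s + 3, scaled so the
#' -3 dB point sits at the cutoff), discretized by the bilinear transform.
#' Applied forward and backward the effective order is 4 with exactly zero
#' phase.
#'
#' @param cutoffHz -3 dB cutoff (Hz).
#' @param fs sampling rate (Hz).
#' @return list with transfer-function coefficients `b`, `a`.
#' @keywords internal
designBesselLowpass <- function(cutoffHz, fs) {
  if (cutoffHz >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  # -3 dB frequency of the unit-delay-normalized order-2 prototype
  w3db <- 1.36165412871613
  wc <- 2 * pi * cutoffHz / w3db
  poles <- wc * c(complex(real = -1.5, imaginary =  sqrt(3) / 2),
                  complex(real = -1.5, imaginary = -sqrt(3) / 2))
  zf <- signal::as.Arma(signal::bilinear(Sz = numeric(0), Sp = poles,
                                         Sg = Re(prod(-poles)), T = 1 / fs))
  list(b = zf$b, a = zf$a)
}

.filtfiltReflect <- function(b, a, x) {
  n <- length(x)
  npad <- min(n - 1, max(50L, 3L * length(a) * 10L))
  # odd reflection suppresses startup transients at both ends
  xpad <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  y <- signal::filter(signal::Arma(b = b, a = a), xpad)
  y <- rev(signal::filter(signal::Arma(b = b, a = a), rev(y)))
  y[(npad + 1):(npad + n)]
}

#' Zero-phase Bessel low-pass filtering
#'
#' Applies the bidirectional (forward-backward, hence zero-phase) Bessel
#' low-pass of [designBesselLowpass()] to every lead. Edges are handled by
#' odd reflection padding.
#'
#' @param record an [EcgRecord-class].
#' @param cutoffHz cutoff frequency, default 36 Hz.
#' @return filtered [EcgRecord-class] of identical shape.
#' @export
besselLowpass <- function(record, cutoffHz = 36) {
  stopifnot(is(record, "EcgRecord"))
  flt <- designBesselLowpass(cutoffHz, record@samplingRate)
  sig <- record@signals
  for (j in seq_len(ncol(sig)))
    sig[, j] <- .filtfiltReflect(flt$b, flt$a, sig[, j])
  initialize(record, signals = sig)
}

#' Zero out noisy leads
#'
#' Replaces the named leads by all-zero signals and records them in the
#' `zeroedLeads` slot, so that downstream VCG reconstruction simply receives
#' no contribution from them.
#'
#' @param record an [EcgRecord-class].
#' @param leads character vector of lead names to zero (may be empty).
#' @return updated [EcgRecord-class].
#' @export
zeroNoisyLeads <- function(record, leads) {
  stopifnot(is(record, "EcgRecord"))
  unknown <- setdiff(leads, colnames(record@signals))
  if (length(unknown))
    stop("unknown lead name: ", paste(unknown, collapse = ", "))
  if (!length(leads)) return(record)
  sig <- record@signals
  sig[, leads] <- 0
  initialize(record, signals = sig,
             zeroedLeads = union(record@zeroedLeads, leads))
}

#' Select the usable normal sinus beats
#'
#' Keeps beats of class `normal_sinus` whose repolarization window is long
#' enough for the derivative filter (at least 20 ms plus one Savitzky-Golay
#' half-window past J). At least three such beats per ECG are required.
#'
#' @param record an [EcgRecord-class].
#' @return data.frame of the retained beat annotations, in record order.
#' @export
selectNormalBeats <- function(record) {
  stopifnot(is(record, "EcgRecord"))
  b <- record@beats
  keep <- b$beat_class == "normal_sinus" & .usableBeats(b, record@samplingRate)
  out <- b[keep, , drop = FALSE]
  if (nrow(out) < 3)
    stop("insufficient normal beats: ", nrow(out), " usable (minimum 3)")
  rownames(out) <- NULL
  out
}
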