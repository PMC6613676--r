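#' Dower transformation matrices
#'
#' The inverse Dower matrix maps the eight independent surface leads
#' (ordered V1-V6, I, II) to the orthogonal dipole components (x, y, z);
#' the coefficients are the published Edenbrandt-Pahlm values, which are the
#' Moore-Penrose pseudo-inverse of the forward Dower lead-field matrix.
#' The forward matrix projects a dipole back onto the same eight leads and is
#' used by the synthetic-study generator.
#'
#' @return `inverseDowerMatrix()`: 3 x 8 matrix (rows x, y, z; columns
#'   V1..V6, I, II). `forwardDowerMatrix()`: its 8 x 3 counterpart.
#' @examples
#' round(inverseDowerMatrix() %*% forwardDowerMatrix(), 3)  # ~ identity
#' @export
inverseDowerMatrix <- function() {
  m <- rbind(
    x = c(-0.172, -0.074,  0.122,  0.231,  0.239,  0.194,  0.156, -0.010),
    y = c( 0.057, -0.019, -0.106, -0.022,  0.041,  0.048, -0.227,  0.887),
    z = c(-0.229, -0.310, -0.246, -0.063,  0.055,  0.108,  0.022,  0.102))
  colnames(m) <- c("V1", "V2", "V3", "V4", "V5", "V6", "I", "II")
  m
}

#' @rdname inverseDowerMatrix
#' @export
forwardDowerMatrix <- function() {
  m <- rbind(
    V1 = c(-0.515,  0.157, -0.917),
    V2 = c( 0.044,  0.164, -1.387),
    V3 = c( 0.882,  0.098, -1.277),
    V4 = c( 1.213,  0.127, -0.601),
    V5 = c( 1.125,  0.127, -0.086),
    V6 = c( 0.831,  0.076,  0.230),
    I  = c( 0.632, -0.235,  0.059),
    II = c( 0.235,  1.066, -0.132))
  colnames(m) <- c("x", "y", "z")
  m
}

#' Reconstruct the vectorcardiogram by the inverse Dower transform
#'
#' Applies the 3 x 8 inverse Dower matrix to the independent leads V1-V6, I,
#' II of a record, yielding the dipole components x (front), y (left) and z
#' (negative toward the feet). Leads that were zeroed as noisy simply
#' contribute zero.
#'
#' @param record an [EcgRecord-class].
#' @param matrix optional alternative 3 x 8 matrix (columns V1..V6, I, II)
#'   for sensitivity analyses.
#' @return A [Vcg-class] with one x/y/z sample per input sample.
#' @examples
#' sig <- matrix(rnorm(800), 100, 8,
#'               dimnames = list(NULL, c("I","II","V1","V2","V3","V4","V5","V6")))
#' vcg <- inverseDower(EcgRecord(sig))
#' @export
inverseDower <- function(record, matrix = inverseDowerMatrix()) {
  stopifnot(is(record, "EcgRecord"))
  leads <- colnames(matrix)
  missing <- setdiff(leads, colnames(record@signals))
  if (length(missing))
    stop("missing lead: ", paste(missing, collapse = ", "))
  xyz <- record@signals[, leads, drop = FALSE] %*% t(matrix)
  colnames(xyz) <- rownames(matrix)
  new("Vcg", xyz = xyz, samplingRate = record@samplingRate)
}

#' Project a dipole trajectory onto the 12 surface leads
#'
#' Forward counterpart of [inverseDower()]: multiplies the dipole by the
#' 8 x 3 forward Dower matrix to obtain V1-V6, I and II, then derives III,
#' aVR, aVL and aVF from I and II so the Einthoven/Goldberger identities hold
#' exactly.
#'
#' @param vcg a [Vcg-class].
#' @param matrix optional alternative 8 x 3 forward matrix.
#' @return samples x 12 lead matrix (uV).
#' @export
forwardProject12Lead <- function(vcg, matrix = forwardDowerMatrix()) {
  stopifnot(is(vcg, "Vcg"))
  leads8 <- vcg@xyz %*% t(matrix)
  colnames(leads8) <- rownames(matrix)
  synthesizeDerivedLeads(leads8)
}
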