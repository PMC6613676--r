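#' Savitzky-Golay window length for a sampling rate
#'
#' The derivative filter uses a 60 ms window (31 samples at 500 Hz); for
#' other sampling rates the odd sample count closest to 60 ms is used,
#' polynomial order stays 3.
#'
#' @param fs sampling rate in Hz.
#' @return odd integer window length (>= 5).
#' @keywords internal
sgWindowLength <- function(fs) {
  n0 <- 0.060 * fs
  n <- round(n0)
  if (n %% 2 == 0) n <- if (n0 >= n) n + 1 else n - 1
  max(n, 5L)
}

# smallest usable J-to-Tend span (samples): 20 ms plus one SG half-window
.minJTendSamples <- function(fs) {
  round(0.020 * fs) + (sgWindowLength(fs) - 1) / 2
}

.usableBeats <- function(beats, fs) {
  beats$tend_idx - beats$j_idx >= .minJTendSamples(fs)
}

#' Validate the annotations of an ECG record
#'
#' Report-only check of the fiducial annotations: ordering within each beat,
#' index range, beat ordering, and whether at least three normal sinus beats
#' with usable repolarization windows are present (a usable window spans at
#' least 20 ms plus one Savitzky-Golay half-window past the J point).
#'
#' @param record an [EcgRecord-class].
#' @return character vector of violations; empty when the record is usable.
#' @examples
#' sig <- matrix(0, 5000, 8,
#'               dimnames = list(NULL, c("I","II","V1","V2","V3","V4","V5","V6")))
#' b <- data.frame(p_idx = 100, q_idx = 150, j_idx = 200, tend_idx = 400)
#' validateAnnotations(EcgRecord(sig, beats = b))
#' @export
validateAnnotations <- function(record) {
  stopifnot(is(record, "EcgRecord"))
  b <- record@beats
  fs <- record@samplingRate
  n <- nrow(record@signals)
  out <- character(0)
  if (nrow(b)) {
    bad <- which(!(b$p_idx < b$q_idx & b$q_idx < b$j_idx &
                     b$j_idx < b$tend_idx))
    for (i in bad)
      out <- c(out, sprintf("beat %d: fiducial ordering violated", i))
    oob <- which(b$p_idx < 0 | b$tend_idx > n - 1)
    for (i in oob)
      out <- c(out, sprintf("beat %d: fiducial index out of range", i))
    if (is.unsorted(b$q_idx))
      out <- c(out, "beats not sorted by Q index")
  }
  ok <- if (nrow(b)) {
    b$beat_class == "normal_sinus" & .usableBeats(b, fs) &
      b$p_idx < b$q_idx & b$q_idx < b$j_idx & b$j_idx < b$tend_idx &
      b$p_idx >= 0 & b$tend_idx <= n - 1
  } else logical(0)
  if (sum(ok) < 3)
    out <- c(out, sprintf("insufficient normal beats: %d usable (minimum 3)",
                          sum(ok)))
  out
}

.sidecarPath <- function(path) {
  base <- sub("\\.(csv|hea)$", "", path)
  paste0(base, ".json")
}

#' Read an annotated ECG record
#'
#' Two on-disk dialects are supported.
#'
#' `csv_json`: a wide CSV with one column per lead (amplitudes in uV) plus a
#' JSON sidecar (same base name, `.json`) holding `sampling_rate`,
#' `amplitude_resolution`, `subject_id`, `treatment`, `nominal_time_h`,
#' `replicate_index`, `zeroed_leads` and a `beats` array of
#' `{p_idx, q_idx, j_idx, tend_idx, beat_class, rr_ms}` objects (0-based
#' sample indices).
#'
#' `wfdb`: a WFDB header (`.hea`) plus binary signal file; formats 16 and 212
#' are read, amplitudes are converted to uV with each signal's ADC gain and
#' baseline, and lead names are taken from the description field.
#' Annotations and metadata come from the same JSON sidecar as the CSV
#' dialect.
#'
#' Missing derived limb leads are synthesized from I and II; a record
#' failing structural validation raises an error.
#'
#' @param path path to the `.csv` or `.hea` file (extension optional).
#' @param format `"csv_json"` or `"wfdb"`.
#' @return An [EcgRecord-class].
#' @seealso [writeEcgRecord()]
#' @export
readEcgRecord <- function(path, format = c("csv_json", "wfdb")) {
  format <- match.arg(format)
  if (format == "csv_json") {
    csv <- if (grepl("\\.csv$", path)) path else paste0(path, ".csv")
    if (!file.exists(csv)) stop("format error: no such file ", csv)
    sig <- as.matrix(utils::read.csv(csv, check.names = FALSE))
    meta <- .readSidecar(.sidecarPath(csv))
  } else {
    hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
    if (!file.exists(hea)) stop("format error: no such file ", hea)
    sig <- .readWfdbSignals(hea)
    meta <- .readSidecar(.sidecarPath(hea))
    if (is.null(meta$sampling_rate))
      meta$sampling_rate <- attr(sig, "fs")
  }
  EcgRecord(sig,
            samplingRate = meta$sampling_rate %||% 500,
            beats = meta$beats,
            subjectId = meta$subject_id %||% NA_character_,
            treatment = meta$treatment %||% NA_character_,
            nominalTimeH = meta$nominal_time_h %||% NA_real_,
            replicate = meta$replicate_index %||% 1L,
            amplitudeResolution = meta$amplitude_resolution %||% 2.5,
            zeroedLeads = as.character(meta$zeroed_leads %||% character(0)))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

.readSidecar <- function(path) {
  if (!file.exists(path)) return(list())
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(meta$beats) && length(meta$beats)) {
    meta$beats <- as.data.frame(meta$beats)
    if (is.null(meta$beats$rr_ms)) meta$beats$rr_ms <- NA_real_
  } else meta$beats <- NULL
  meta
}

.readWfdbSignals <- function(hea) {
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  head <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(head[2])
  fs <- if (length(head) >= 3) as.numeric(sub("/.*", "", head[3])) else 250
  nsamp <- if (length(head) >= 4) as.integer(head[4]) else NA_integer_
  specs <- lapply(lines[1 + seq_len(nsig)], function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    gainfield <- f[3]
    gain <- as.numeric(sub("^([-0-9.]+).*", "\\1", gainfield))
    if (!is.finite(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gainfield))
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gainfield)) else 0
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else NA
    list(file = f[1], format = sub("x.*|:.*", "", f[2]), gain = gain,
         baseline = baseline, desc = desc)
  })
  fmt <- unique(vapply(specs, `[[`, "", "format"))
  datafile <- file.path(dirname(hea), specs[[1]]$file)
  if (!file.exists(datafile)) stop("format error: no such file ", datafile)
  if (length(fmt) != 1 || !fmt %in% c("16", "212"))
    stop("format error: unsupported WFDB signal format ",
         paste(fmt, collapse = ","))
  raw <- readBin(datafile, "raw", file.info(datafile)$size)
  adus <- if (fmt == "16") {
    readBin(raw, "integer", n = length(raw) / 2, size = 2, endian = "little")
  } else .decode212(raw)
  n <- length(adus) %/% nsig
  if (is.finite(nsamp) && !is.na(nsamp)) n <- min(n, nsamp)
  m <- matrix(adus[seq_len(n * nsig)], ncol = nsig, byrow = TRUE)
  # physical units: (adu - baseline)/gain gives mV; the package works in uV
  for (j in seq_len(nsig))
    m[, j] <- (m[, j] - specs[[j]]$baseline) / specs[[j]]$gain * 1000
  nm <- vapply(specs, `[[`, "", "desc")
  if (any(is.na(nm))) nm <- paste0("S", seq_len(nsig))
  colnames(m) <- nm
  attr(m, "fs") <- fs
  m
}

.decode212 <- function(raw) {
  b <- as.integer(raw)
  n3 <- (length(b) %/% 3) * 3
  b <- b[seq_len(n3)]
  b1 <- b[seq(1, n3, 3)]; b2 <- b[seq(2, n3, 3)]; b3 <- b[seq(3, n3, 3)]
  s1 <- b1 + bitwAnd(b2, 0x0F) * 256
  s2 <- b3 + bitwAnd(b2, 0xF0) * 16
  s1 <- ifelse(s1 > 2047, s1 - 4096, s1)
  s2 <- ifelse(s2 > 2047, s2 - 4096, s2)
  as.vector(rbind(s1, s2))
}

#' Write an ECG record
#'
#' Writes the `csv_json` dialect described in [readEcgRecord()]; the
#' round-trip preserves annotations and metadata exactly and signals to
#' within half the amplitude resolution (signals are quantized to the
#' record's `amplitudeResolution` grid on write). Only the eight
#' independent leads are stored; the derived limb leads are definitional
#' and resynthesized on read, which keeps the Einthoven/Goldberger
#' identities exact after quantization.
#'
#' @param record an [EcgRecord-class].
#' @param path base path or `.csv` path for the output.
#' @param format only `"csv_json"` is supported for writing.
#' @return invisibly, the signal file path.
#' @export
writeEcgRecord <- function(record, path, format = c("csv_json")) {
  format <- match.arg(format)
  stopifnot(is(record, "EcgRecord"))
  csv <- if (grepl("\\.csv$", path)) path else paste0(path, ".csv")
  res <- record@amplitudeResolution
  keep <- intersect(colnames(record@signals), LEADS_INDEPENDENT)
  sig <- round(record@signals[, keep, drop = FALSE] / res) * res
  utils::write.csv(as.data.frame(sig), csv, row.names = FALSE)
  meta <- list(
    sampling_rate = record@samplingRate,
    amplitude_resolution = record@amplitudeResolution,
    subject_id = record@subjectId,
    treatment = record@treatment,
    nominal_time_h = record@nominalTimeH,
    replicate_index = record@replicate,
    zeroed_leads = as.character(record@zeroedLeads),
    beats = record@beats)
  jsonlite::write_json(meta, .sidecarPath(csv), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", na = "null")
  invisible(csv)
}
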