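#' Fit the heart-rate dependence of each biomarker
#'
#' For every parameter in the table, fits the linear mixed model
#' `value ~ 1 + RR + (1 + RR | subject)` by REML to drug-free data (all
#' placebo-arm records plus the pre-dose baseline records of every arm) and
#' extracts the fixed-effect slope `beta` in ms per ms of RR. A singular fit
#' is refitted with independent random intercept and slope (no covariance)
#' and flagged. RR is centered at 1000 ms and scaled internally for
#' numerical stability; reported coefficients are on the original scale.
#'
#' @param drugFreeTable data.frame with columns `subject_id`, `rr_ms`,
#'   `parameter`, `value` (one row per record and parameter). See
#'   [drugFreeTable()] for assembling it from a biomarker table.
#' @param method `"REML"` (default) or `"ML"`.
#' @return A [RateCorrectionModel-class].
#' @seealso [applyRateCorrection()]
#' @export
fitRateModel <- function(drugFreeTable, method = c("REML", "ML")) {
  method <- match.arg(method)
  need <- c("subject_id", "rr_ms", "parameter", "value")
  stopifnot(all(need %in% names(drugFreeTable)))
  nsub <- length(unique(drugFreeTable$subject_id))
  if (nsub < 2) stop("at least 2 subjects are required")
  reml <- method == "REML"
  rows <- lapply(split(drugFreeTable, drugFreeTable$parameter), function(d) {
    # slope on the /100 scale keeps lme4's optimizer well conditioned
    d$rrs <- (d$rr_ms - 1000) / 100
    fit <- suppressWarnings(
      lme4::lmer(value ~ 1 + rrs + (1 + rrs | subject_id), data = d,
                 REML = reml))
    singular <- lme4::isSingular(fit)
    if (singular)
      fit <- suppressWarnings(
        lme4::lmer(value ~ 1 + rrs + (1 + rrs || subject_id), data = d,
                   REML = reml))
    fe <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    sdint <- vc$sdcor[vc$var1 == "(Intercept)" & is.na(vc$var2)][1]
    sdslp <- vc$sdcor[vc$var1 == "rrs" & is.na(vc$var2)][1] / 100
    corr <- vc$sdcor[!is.na(vc$var2)]
    data.frame(parameter = d$parameter[1],
               intercept = unname(fe["(Intercept)"]),
               beta = unname(fe["rrs"]) / 100,
               se_beta = unname(se["rrs"]) / 100,
               sd_rand_intercept = sdint,
               sd_rand_slope = sdslp,
               cor_rand = if (length(corr)) corr[1] else NA_real_,
               singular = singular)
  })
  coefs <- do.call(rbind, rows)
  rownames(coefs) <- NULL
  if (any(coefs$singular))
    message("singular random-effects fit for ",
            paste(coefs$parameter[coefs$singular], collapse = ", "),
            "; refitted with independent random effects")
  new("RateCorrectionModel", coefficients = coefs, nSubjects = as.integer(nsub),
      nObservations = as.integer(nrow(drugFreeTable) /
                                   max(1, length(unique(drugFreeTable$parameter)))))
}

#' Apply the heart-rate correction
#'
#' `TrXc = TrX - beta * (RR - 1000)`, anchoring the corrected value at an
#' RR of 1000 ms (60 bpm).
#'
#' @param trxMs uncorrected parameter value(s), ms.
#' @param rrMs average beat interval(s), ms.
#' @param beta fixed-effect slope from [fitRateModel()], ms per ms.
#' @return corrected value(s), ms.
#' @examples
#' applyRateCorrection(200, 800, 0.05)  # 210
#' @export
applyRateCorrection <- function(trxMs, rrMs, beta) {
  stopifnot(all(is.finite(trxMs)), all(is.finite(rrMs)), all(is.finite(beta)))
  trxMs - beta * (rrMs - 1000)
}

#' Heart-rate-correct a biomarker table
#'
#' Applies [applyRateCorrection()] to every parameter of a long biomarker
#' table that has a slope in the model, producing new rows with parameter
#' names suffixed `c` (Tr40 becomes Tr40c). Each record's RR is taken from
#' its own `RR` row. Parameters without a slope (RR, QT, QTcF) pass through
#' unchanged.
#'
#' @param table long biomarker table from [studyQuantileTable()].
#' @param model a [RateCorrectionModel-class].
#' @return the table with corrected parameter rows appended.
#' @export
correctBiomarkerTable <- function(table, model) {
  stopifnot(is(model, "RateCorrectionModel"))
  key <- interaction(table$subject_id, table$treatment,
                     table$nominal_time_h, table$replicate, drop = TRUE)
  rrRows <- table[table$parameter == "RR", ]
  rr <- stats::setNames(rrRows$value,
                        as.character(key[table$parameter == "RR"]))
  betas <- rateBeta(model)
  corr <- table[table$parameter %in% names(betas), ]
  ck <- as.character(key[table$parameter %in% names(betas)])
  corr$value <- applyRateCorrection(corr$value, rr[ck],
                                    betas[corr$parameter])
  corr$parameter <- paste0(corr$parameter, "c")
  out <- rbind(table, corr)
  rownames(out) <- NULL
  out
}

#' Extract the drug-free subset of a biomarker table
#'
#' Drug-free data are all placebo-arm records plus the pre-dose baseline
#' records of every arm, reshaped for [fitRateModel()]: one row per record
#' and parameter with the record's RR alongside.
#'
#' @param table long biomarker table from [studyQuantileTable()].
#' @param placebo placebo treatment label.
#' @param baselineTime nominal time (h) of the pre-dose baseline.
#' @param parameters parameters to keep (default the ten TrX).
#' @return data.frame with `subject_id`, `rr_ms`, `parameter`, `value`.
#' @export
drugFreeTable <- function(table, placebo = "Placebo", baselineTime = 0,
                          parameters = paste0("Tr", seq(10, 100, 10))) {
  free <- table[table$treatment == placebo |
                  table$nominal_time_h == baselineTime, ]
  key <- interaction(free$subject_id, free$treatment,
                     free$nominal_time_h, free$replicate, drop = TRUE)
  rr <- stats::setNames(free$value[free$parameter == "RR"],
                        as.character(key[free$parameter == "RR"]))
  keep <- free$parameter %in% parameters
  out <- data.frame(subject_id = free$subject_id[keep],
                    rr_ms = unname(rr[as.character(key[keep])]),
                    parameter = free$parameter[keep],
                    value = free$value[keep])
  out[is.finite(out$rr_ms), ]
}

#' Serialize / restore a rate-correction model
#'
#' The fitted slopes are frozen to JSON so that corrections are reproducible
#' without refitting.
#'
#' @param model a [RateCorrectionModel-class].
#' @param path output / input JSON path.
#' @return `readRateModel()` returns the restored model.
#' @export
writeRateModel <- function(model, path) {
  stopifnot(is(model, "RateCorrectionModel"))
  jsonlite::write_json(
    list(coefficients = model@coefficients, n_subjects = model@nSubjects,
         n_observations = model@nObservations),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname writeRateModel
#' @export
readRateModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("RateCorrectionModel", coefficients = as.data.frame(x$coefficients),
      nSubjects = as.integer(x$n_subjects),
      nObservations = as.integer(x$n_observations))
}
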