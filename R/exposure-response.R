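#' Average replicate ECGs
#'
#' One value per subject x treatment x nominal time x parameter: the mean of
#' the replicate ECG values.
#'
#' @param table long biomarker table (columns `subject_id`, `treatment`,
#'   `nominal_time_h`, `replicate`, `parameter`, `value`).
#' @return aggregated data.frame without the `replicate` column.
#' @keywords internal
replicateAverage <- function(table) {
  stats::aggregate(value ~ subject_id + treatment + nominal_time_h + parameter,
                   data = table, FUN = mean)
}

#' Single-delta change from baseline
#'
#' `dP(t, TR) = P(t, TR) - P(t0, TR)` per subject, treatment and parameter,
#' where P is the replicate-averaged value and t0 the pre-dose baseline
#' timepoint of the treatment period. Rows without a baseline are excluded
#' (reasons in the `"excluded"` attribute).
#'
#' @param table long biomarker table, replicate-level.
#' @param baselineTime nominal time (h) of the baseline, default 0.
#' @return data.frame `subject_id`, `treatment`, `nominal_time_h`,
#'   `parameter`, `value` (the delta), for post-baseline times only.
#' @export
singleDelta <- function(table, baselineTime = 0) {
  p <- replicateAverage(table)
  base <- p[p$nominal_time_h == baselineTime, ]
  post <- p[p$nominal_time_h > baselineTime, ]
  m <- merge(post, base[, c("subject_id", "treatment", "parameter", "value")],
             by = c("subject_id", "treatment", "parameter"),
             suffixes = c("", ".base"), all.x = TRUE)
  miss <- is.na(m$value.base)
  excluded <- character(0)
  if (any(miss)) {
    ex <- unique(m[miss, c("subject_id", "treatment")])
    excluded <- sprintf("no baseline for subject %s treatment %s",
                        ex$subject_id, ex$treatment)
    message(sum(miss), " row(s) without baseline excluded")
    m <- m[!miss, ]
  }
  m$value <- m$value - m$value.base
  out <- m[, c("subject_id", "treatment", "nominal_time_h", "parameter",
               "value")]
  out <- out[order(out$subject_id, out$treatment, out$nominal_time_h,
                   out$parameter), ]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Double-delta (placebo-corrected) change from baseline
#'
#' `ddP(t, Drug) = dP(t, Drug) - dP(t, Placebo)`, matched within subject and
#' nominal time. Rows without a placebo match are excluded (reasons in the
#' `"excluded"` attribute). The placebo arm itself yields identically zero.
#'
#' @param deltaTable output of [singleDelta()].
#' @param placebo placebo treatment label.
#' @return data.frame like the input, `value` now the double delta.
#' @export
doubleDelta <- function(deltaTable, placebo = "Placebo") {
  pla <- deltaTable[deltaTable$treatment == placebo,
                    c("subject_id", "nominal_time_h", "parameter", "value")]
  m <- merge(deltaTable, pla,
             by = c("subject_id", "nominal_time_h", "parameter"),
             suffixes = c("", ".pla"), all.x = TRUE)
  miss <- is.na(m$value.pla)
  excluded <- character(0)
  if (any(miss)) {
    ex <- unique(m[miss, c("subject_id", "nominal_time_h")])
    excluded <- sprintf("no placebo match for subject %s at t=%g h",
                        ex$subject_id, ex$nominal_time_h)
    message(sum(miss), " row(s) without placebo match excluded")
    m <- m[!miss, ]
  }
  m$value <- m$value - m$value.pla
  out <- m[, c("subject_id", "treatment", "nominal_time_h", "parameter",
               "value")]
  out <- out[order(out$subject_id, out$treatment, out$nominal_time_h,
                   out$parameter), ]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

.erFormula <- function(concCols, interaction) {
  fx <- paste(concCols, collapse = " + ")
  if (length(concCols) == 2 && interaction)
    fx <- paste0(fx, " + ", concCols[1], ":", concCols[2])
  re <- paste0("(0 + ", paste(concCols, collapse = " + "), " | subject_id)")
  stats::as.formula(paste("value ~ 0 +", fx, "+", re))
}

.erFormulaIndep <- function(concCols, interaction) {
  fx <- paste(concCols, collapse = " + ")
  if (length(concCols) == 2 && interaction)
    fx <- paste0(fx, " + ", concCols[1], ":", concCols[2])
  re <- paste(sprintf("(0 + %s | subject_id)", concCols), collapse = " + ")
  stats::as.formula(paste("value ~ 0 +", fx, "+", re))
}

#' Fit a concentration-effect mixed model
#'
#' No-intercept linear mixed model of the placebo-corrected change from
#' baseline on drug concentration: `dd ~ 0 + C + (0 + C | subject)` for a
#' single drug, `dd ~ 0 + C1 + C2 + C1:C2 + (0 + (C1 + C2) | subject)` for
#' two (the interaction term is optional). The zero terms force the
#' regression line or plane through the origin, so the prediction at zero
#' concentration is exactly zero. Concentrations are rescaled internally for
#' numerical stability; coefficients are reported per original unit. A
#' singular two-drug fit is refitted with independent random slopes and
#' flagged.
#'
#' @param data data.frame with `subject_id`, `value` (the double delta) and
#'   one or two concentration columns.
#' @param concCols names of the concentration column(s).
#' @param interaction include the `C1:C2` term (two-drug models only).
#' @param method `"REML"` or `"ML"`.
#' @return object of class `"ExposureResponseFit"`: a list with `theta`
#'   (named fixed-effect slopes, original scale), `se`, `singular`,
#'   `concCols`, `interaction` and the underlying `lmerMod` as `fit`.
#' @seealso [predictEffect()], [effectProfile()]
#' @export
fitExposureResponse <- function(data, concCols = "conc", interaction = TRUE,
                                method = c("REML", "ML")) {
  method <- match.arg(method)
  stopifnot(all(c("subject_id", "value", concCols) %in% names(data)),
            length(concCols) %in% 1:2)
  if (length(unique(data$subject_id)) < 2)
    stop("at least 2 subjects are required")
  scales <- vapply(concCols, function(cc) max(abs(data[[cc]])), 0)
  if (any(scales == 0)) stop("all-zero concentrations")
  d <- data
  for (cc in concCols) d[[cc]] <- d[[cc]] / scales[cc]
  reml <- method == "REML"
  fit <- suppressWarnings(
    lme4::lmer(.erFormula(concCols, interaction), data = d, REML = reml))
  singular <- lme4::isSingular(fit)
  if (singular && length(concCols) == 2)
    fit <- suppressWarnings(
      lme4::lmer(.erFormulaIndep(concCols, interaction), data = d,
                 REML = reml))
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  unscale <- vapply(names(fe), function(nm) {
    prod(scales[strsplit(nm, ":", fixed = TRUE)[[1]]])
  }, 0)
  out <- list(theta = fe / unscale, se = se / unscale, singular = singular,
              concCols = concCols, interaction = interaction, fit = fit,
              nSubjects = length(unique(data$subject_id)))
  class(out) <- "ExposureResponseFit"
  out
}

#' @export
print.ExposureResponseFit <- function(x, ...) {
  cat("ExposureResponseFit:", paste(x$concCols, collapse = " + "),
      if (x$singular) "(singular random effects, simplified)" else "", "\n")
  print(data.frame(term = names(x$theta), theta = unname(x$theta),
                   se = unname(x$se)), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Predict the drug effect at given concentration(s)
#'
#' Fixed-effect prediction of the fitted exposure-response model,
#' `theta1*C1 (+ theta2*C2 + theta12*C1*C2)`. Exactly zero at zero
#' concentration.
#'
#' @param object an `ExposureResponseFit`.
#' @param conc named concentration vector (names matching `concCols`; a
#'   single unnamed value is accepted for one-drug models).
#' @return predicted effect (ms).
#' @export
predictEffect <- function(object, conc) {
  stopifnot(inherits(object, "ExposureResponseFit"))
  if (is.null(names(conc)) && length(object$concCols) == 1)
    names(conc) <- object$concCols
  stopifnot(all(object$concCols %in% names(conc)))
  val <- 0
  for (nm in names(object$theta)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    val <- val + object$theta[[nm]] * prod(conc[parts])
  }
  unname(val)
}

#' Drug-effect profile across trajectory quantiles
#'
#' For each parameter (by default the ten heart-rate-corrected trajectory
#' quantiles), fits the concentration-effect model and evaluates the
#' prediction at the representative concentration(s); the 95% confidence
#' interval is the percentile interval of a subject-level (cluster)
#' bootstrap in which subjects are resampled with replacement and every
#' model refitted. The bootstrap is seeded and shares its resamples across
#' parameters.
#'
#' @param ddTable data.frame with `subject_id`, `parameter`, `value` and the
#'   concentration column(s).
#' @param repConc named representative concentration(s).
#' @param parameters parameters to profile, default `Tr10c` ... `Tr100c`.
#' @param concCols concentration column names (default `names(repConc)`).
#' @param interaction include the two-drug interaction term.
#' @param nBoot bootstrap replicates (2000 for reporting; reduce for quick
#'   runs).
#' @param seed RNG seed for the bootstrap.
#' @return An [EffectProfile-class]. A warning is raised when more than 10%
#'   of replicate fits fail.
#' @export
effectProfile <- function(ddTable, repConc,
                          parameters = paste0("Tr", seq(10, 100, 10), "c"),
                          concCols = names(repConc), interaction = TRUE,
                          nBoot = 2000L, seed = NULL) {
  stopifnot(!is.null(concCols), all(concCols %in% names(ddTable)))
  if (!is.null(seed)) set.seed(seed)
  byPar <- lapply(parameters, function(p) {
    d <- ddTable[ddTable$parameter == p, ]
    if (!nrow(d)) stop("no rows for parameter ", p)
    d
  })
  names(byPar) <- parameters
  est <- vapply(byPar, function(d)
    predictEffect(fitExposureResponse(d, concCols, interaction), repConc), 0)
  ids <- unique(ddTable$subject_id)
  boot <- matrix(NA_real_, nBoot, length(parameters),
                 dimnames = list(NULL, parameters))
  for (r in seq_len(nBoot)) {
    take <- sample(ids, replace = TRUE)
    for (p in parameters) {
      d <- byPar[[p]]
      pieces <- lapply(seq_along(take), function(k) {
        dk <- d[d$subject_id == take[k], ]
        dk$subject_id <- paste0("bs", k)
        dk
      })
      db <- do.call(rbind, pieces)
      boot[r, p] <- tryCatch(
        predictEffect(fitExposureResponse(db, concCols, interaction),
                      repConc),
        error = function(e) NA_real_)
    }
  }
  nFailed <- sum(is.na(boot))
  if (nFailed > 0.10 * length(boot))
    warning(sprintf("%.0f%% of bootstrap fits failed",
                    100 * nFailed / length(boot)))
  ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  prof <- data.frame(parameter = parameters, estimate = unname(est),
                     lo = pmin(ci[1, ], est), hi = pmax(ci[2, ], est))
  rownames(prof) <- NULL
  new("EffectProfile", profile = prof, repConc = repConc,
      nBoot = as.integer(nBoot), nFailed = as.integer(nFailed))
}

#' Geometric mean concentration
#'
#' `exp(mean(log(values)))` over the positive values; zeros are excluded
#' with a message. Used to pick representative concentrations from the
#' timepoints at which both drugs of a combination had been administered.
#'
#' @param values concentrations (> 0; zeros dropped).
#' @return geometric mean.
#' @examples
#' geometricMeanConcentration(c(4, 9))  # 6
#' @export
geometricMeanConcentration <- function(values) {
  zero <- values <= 0
  if (any(zero)) {
    message(sum(zero), " non-positive concentration(s) excluded")
    values <- values[!zero]
  }
  if (!length(values)) stop("no positive concentrations")
  exp(mean(log(values)))
}

#' Double-delta table with drug concentrations
#'
#' Joins a double-delta biomarker table to a long PK table (columns
#' `subject_id`, `treatment`, `nominal_time_h`, `drug`, `conc`), producing
#' one concentration column per requested drug (zero when the drug was not
#' given in that period, as for pooled single-drug and combination periods).
#'
#' @param ddTable output of [doubleDelta()], possibly restricted to the
#'   treatment periods being pooled.
#' @param pk long PK table.
#' @param drugs drug names to create columns for.
#' @return `ddTable` with one numeric column per drug.
#' @export
joinConcentrations <- function(ddTable, pk, drugs) {
  out <- ddTable
  for (dg in drugs) {
    p <- pk[pk$drug == dg, c("subject_id", "treatment", "nominal_time_h",
                             "conc")]
    m <- merge(out[, c("subject_id", "treatment", "nominal_time_h")], p,
               by = c("subject_id", "treatment", "nominal_time_h"),
               all.x = TRUE, sort = FALSE)
    # merge(all.x) does not preserve row order; rebuild by key
    keyOut <- paste(out$subject_id, out$treatment, out$nominal_time_h)
    keyM <- paste(m$subject_id, m$treatment, m$nominal_time_h)
    cv <- m$conc[match(keyOut, keyM)]
    cv[is.na(cv)] <- 0
    out[[dg]] <- cv
  }
  out
}
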