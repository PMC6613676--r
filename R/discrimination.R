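#' Area under the ROC curve
#'
#' Rank-sum (Mann-Whitney) formulation:
#' `AUC = P(score_pos > score_neg) + 0.5 * P(tie)`, computed from midranks.
#'
#' @param scores numeric classifier scores.
#' @param labels two-class labels; logical, 0/1, or a factor whose second
#'   level is the positive class.
#' @return AUC in `[0, 1]`.
#' @examples
#' rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
rocAuc <- function(scores, labels) {
  pos <- .asPositive(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.asPositive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) return(labels == levels(labels)[2])
  u <- sort(unique(labels))
  if (length(u) != 2) stop("both classes must be present")
  labels == u[2]
}

#' Fit the block-type logistic classifier
#'
#' Maximum-likelihood logistic regression of the block label on one or more
#' double-delta biomarkers (e.g. `B ~ ddTr40c`, or all ten trajectory
#' quantiles together). Predicted probabilities are returned as scores for
#' ROC analysis. Complete separation yields a warning but scores are still
#' returned.
#'
#' @param data data.frame of labeled observations.
#' @param features column names to use as predictors.
#' @param labelCol name of the label column (two classes; the second factor
#'   level -- multichannel block, by convention -- is the positive class).
#' @return list with `model` (the `glm`), `scores` (fitted probabilities),
#'   `labels`, `features`.
#' @seealso [rocAuc()], [bootstrapAucCi()]
#' @export
fitBlockClassifier <- function(data, features, labelCol = "block_label") {
  stopifnot(length(features) >= 1, all(features %in% names(data)),
            labelCol %in% names(data))
  pos <- .asPositive(data[[labelCol]])
  if (length(unique(pos)) < 2) stop("both classes must be present")
  if (any(!stats::complete.cases(data[, features, drop = FALSE])))
    stop("missing feature values")
  f <- stats::as.formula(paste(".pos ~", paste(features, collapse = " + ")))
  d <- data[, features, drop = FALSE]
  d$.pos <- pos
  sep <- FALSE
  model <- withCallingHandlers(
    stats::glm(f, data = d, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep)
    warning("complete or quasi-complete separation; scores returned unpenalized")
  list(model = model, scores = unname(stats::fitted(model)), labels = pos,
       features = features)
}

#' Stratified-bootstrap AUC confidence interval
#'
#' Resamples observations with replacement within each class, recomputes the
#' AUC per replicate, and reports the percentile 95% interval. Stratification
#' guarantees both classes in every replicate.
#'
#' @param scores classifier scores.
#' @param labels two-class labels (see [rocAuc()]).
#' @param nBoot bootstrap replicates, default 2000.
#' @param seed RNG seed.
#' @param features feature names recorded in the result (informational).
#' @return A [DiscriminationResult-class].
#' @export
bootstrapAucCi <- function(scores, labels, nBoot = 2000L, seed = NULL,
                           features = "score") {
  pos <- .asPositive(labels)
  iPos <- which(pos); iNeg <- which(!pos)
  if (!length(iPos) || !length(iNeg)) stop("both classes must be present")
  if (!is.null(seed)) set.seed(seed)
  auc <- rocAuc(scores, pos)
  reps <- vapply(seq_len(nBoot), function(r) {
    ip <- sample(iPos, replace = TRUE)
    ineg <- sample(iNeg, replace = TRUE)
    rocAuc(c(scores[ip], scores[ineg]),
           c(rep(TRUE, length(ip)), rep(FALSE, length(ineg))))
  }, 0)
  ci <- stats::quantile(reps, c(0.025, 0.975), names = FALSE)
  new("DiscriminationResult", features = features, auc = auc,
      lo = min(ci[1], auc), hi = max(ci[2], auc), nBoot = as.integer(nBoot),
      nPos = length(iPos), nNeg = length(iNeg))
}

#' Classifier AUC with CI in one call
#'
#' Convenience wrapper: fit the logistic model on the given features and
#' return its in-sample AUC with a stratified-bootstrap confidence interval.
#'
#' @inheritParams fitBlockClassifier
#' @inheritParams bootstrapAucCi
#' @return A [DiscriminationResult-class].
#' @export
discriminateBlockType <- function(data, features, labelCol = "block_label",
                                  nBoot = 2000L, seed = NULL) {
  fit <- fitBlockClassifier(data, features, labelCol)
  bootstrapAucCi(fit$scores, fit$labels, nBoot = nBoot, seed = seed,
                 features = features)
}

#' Reshape a double-delta table to one row per observation
#'
#' Turns the long double-delta table into the classifier's observation
#' matrix: one row per subject x treatment x timepoint with one column per
#' parameter.
#'
#' @param ddTable output of [doubleDelta()].
#' @param parameters parameter columns to spread (default all present).
#' @return data.frame with `subject_id`, `treatment`, `nominal_time_h` and
#'   one column per parameter.
#' @export
ddWideTable <- function(ddTable, parameters = unique(ddTable$parameter)) {
  d <- ddTable[ddTable$parameter %in% parameters, ]
  key <- interaction(d$subject_id, d$treatment, d$nominal_time_h, drop = TRUE)
  ids <- !duplicated(key)
  out <- d[ids, c("subject_id", "treatment", "nominal_time_h")]
  rownames(out) <- NULL
  for (p in parameters) {
    sel <- d$parameter == p
    out[[p]] <- d$value[sel][match(key[ids], key[sel])]
  }
  out
}
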