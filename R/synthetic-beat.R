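#' @importFrom stats approx rnorm runif setNames
NULL

# Fixed 3-D T-loop path, parameterized by arc-length fraction.
#
# The base open loop g(u) = (sin(pi u), 0.35 sin(2 pi u), 0.25 sin(pi u)^2),
# rotated into a physiologic T-axis direction, starts and ends at the
# origin. A high-resolution polyline gives the cumulative arc length, from
# which positions at arbitrary arc fractions are interpolated. The table is
# computed once and cached.
.tLoopPathEnv <- new.env(parent = emptyenv())

.tLoopPath <- function(nGrid = 4001L) {
  key <- as.character(nGrid)
  if (!is.null(.tLoopPathEnv[[key]])) return(.tLoopPathEnv[[key]])
  u <- seq(0, 1, length.out = nGrid)
  g <- cbind(x = sin(pi * u),
             y = 0.35 * sin(2 * pi * u),
             z = 0.25 * sin(pi * u)^2)
  # rotate toward left-inferior-anterior, the usual adult T-axis
  th1 <- 0.5; th2 <- -0.65
  Rz <- rbind(c(cos(th1), -sin(th1), 0), c(sin(th1), cos(th1), 0), c(0, 0, 1))
  Ry <- rbind(c(cos(th2), 0, sin(th2)), c(0, 1, 0), c(-sin(th2), 0, cos(th2)))
  g <- g %*% t(Rz %*% Ry)
  colnames(g) <- c("x", "y", "z")
  seg <- sqrt(rowSums(diff(g)^2))
  s <- c(0, cumsum(seg))
  out <- list(q = s / s[length(s)], pos = g, unitLength = s[length(s)])
  .tLoopPathEnv[[key]] <- out
  out
}

.pathAt <- function(q) {
  p <- .tLoopPath()
  cbind(x = approx(p$q, p$pos[, 1], xout = q, rule = 2)$y,
        y = approx(p$q, p$pos[, 2], xout = q, rule = 2)$y,
        z = approx(p$q, p$pos[, 3], xout = q, rule = 2)$y)
}

#' Baseline T-loop timing map
#'
#' The drug-free timing of the repolarization trajectory. The arc-length
#' fraction covered by time t follows `c0(t/T) = s - sin(2 pi s)/(2 pi)`
#' (s = t/T), i.e. traversal speed rises smoothly from zero at the loop
#' onset, peaks mid-loop and tapers back to zero at Tend -- the gentle
#' T-wave onset/offset seen in real ECGs, and band-limited enough for the
#' 60 ms derivative window to resolve. `tauBaseline(q)` returns the inverse:
#' the time at which arc fraction q is reached.
#'
#' @param q arc-length fraction(s) in `[0, 1]`.
#' @param durationMs total loop duration T (ms).
#' @return time(s) in ms; `tauBaseline(0) = 0`, `tauBaseline(1) = T`.
#' @export
tauBaseline <- local({
  s <- seq(0, 1, length.out = 8001)
  cs <- s - sin(2 * pi * s) / (2 * pi)
  function(q, durationMs = 280) {
    durationMs * stats::approx(cs, s, xout = q, rule = 2)$y
  }
})

#' Effect-shape functions for the warp generator
#'
#' Per-unit-concentration timing perturbations delta(q) in ms:
#' `"herg"` (outward-current block) delays increasingly across the loop,
#' `delta(q) = scale * q`; `"sodium"` (inward-current block) accelerates the
#' early loop -- negative and falling up to q = 0.4 (a smooth cubic
#' shoulder), then flat at `-scale`; `"none"` is identically zero. Shapes
#' superpose additively.
#'
#' @param type `"herg"`, `"sodium"` or `"none"`.
#' @param scale effect size in ms per concentration unit at q = 1 (herg) or
#'   in the plateau (sodium).
#' @return function of the arc fraction q.
#' @export
effectShape <- function(type = c("herg", "sodium", "none"), scale = 0.004) {
  type <- match.arg(type)
  force(scale)
  switch(type,
    herg = function(q) scale * q,
    sodium = function(q) {
      s <- pmin(q / 0.4, 1)
      -scale * s^2 * (3 - 2 * s)
    },
    none = function(q) rep(0, length(q)))
}

#' Parameters of one synthetic dipole beat
#'
#' Fiducial layout and loop geometry for [simulateDipoleBeat()]. Times are
#' ms from beat onset; the T window runs from `jMs + 20` for the duration of
#' the timing map.
#'
#' @param rrMs beat interval (ms).
#' @param fs sampling rate (Hz).
#' @param tAmplitudeUv spatial scale of the T loop (uV); 0 gives a
#'   degenerate (flat) repolarization.
#' @param tDurationMs drug-free loop duration (ms); must exceed 80 so that
#'   Tend - J > 100 ms.
#' @param pEndMs,qMs,jMs P-offset, Q-onset and J-point times (ms).
#' @return list of class `"DipoleBeatParams"`.
#' @export
dipoleBeatParams <- function(rrMs = 1000, fs = 500, tAmplitudeUv = 600,
                             tDurationMs = 280, pEndMs = 120, qMs = 170,
                             jMs = 260) {
  stopifnot(rrMs > 0, fs > 0, tDurationMs > 80,
            0 < pEndMs, pEndMs < qMs, qMs < jMs,
            jMs + 20 + tDurationMs < rrMs - 20)
  structure(list(rrMs = rrMs, fs = fs, tAmplitudeUv = tAmplitudeUv,
                 tDurationMs = tDurationMs, pEndMs = pEndMs, qMs = qMs,
                 jMs = jMs),
            class = "DipoleBeatParams")
}

.tauTable <- function(tau, nGrid = 1001L) {
  qg <- seq(0, 1, length.out = nGrid)
  tg <- tau(qg)
  if (abs(tg[1]) > 1e-9) stop("non-monotone warp: tau(0) must be 0")
  if (any(diff(tg) <= 0)) stop("non-monotone warp: tau must be strictly increasing")
  list(q = qg, tau = tg)
}

#' Simulate one dipole beat
#'
#' Generates a smooth 3-D dipole trajectory for one beat: a small P bump, a
#' fast QRS loop (Gaussian velocity pulses) and a T loop traced along the
#' fixed spatial path of the generator at the timing given by `tau`
#' (arc-length fraction q is reached `tau(q)` ms after J + 20 ms). The true
#' trajectory quantiles are therefore `tau(X/100)` in closed form.
#'
#' @param params a [dipoleBeatParams()] list.
#' @param tau timing map: function of q with `tau(0) = 0`, strictly
#'   increasing; default [tauBaseline()] over `params$tDurationMs`.
#' @return list of class `"DipoleBeat"`: `xyz` (samples x 3, uV), `fs`,
#'   `annotation` (one-row beat data.frame, 0-based indices), `trueTrx`
#'   (named, ms from loop start), `arcLength` (true cumulative trajectory
#'   length per window sample, uV), `tau` (the timing table), `degenerate`.
#' @export
simulateDipoleBeat <- function(params = dipoleBeatParams(), tau = NULL) {
  stopifnot(inherits(params, "DipoleBeatParams"))
  if (is.null(tau)) {
    T0 <- params$tDurationMs
    tau <- function(q) tauBaseline(q, T0)
  }
  tt <- .tauTable(tau)
  fs <- params$fs
  dtMs <- 1000 / fs
  n <- round(params$rrMs / dtMs)
  tMs <- (seq_len(n) - 1) * dtMs
  xyz <- matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  gauss <- function(c0, w) exp(-((tMs - c0) / w)^2)
  # P wave: small, slow
  pC <- params$pEndMs - 30
  xyz[, 1] <- xyz[, 1] + 45 * gauss(pC, 16)
  xyz[, 2] <- xyz[, 2] + 30 * gauss(pC, 16)
  xyz[, 3] <- xyz[, 3] - 12 * gauss(pC, 16)
  # QRS: large, fast, back to baseline well before J
  qrsC <- (params$qMs + params$jMs) / 2
  xyz[, 1] <- xyz[, 1] + 900 * gauss(qrsC - 4, 11)
  xyz[, 2] <- xyz[, 2] + 650 * gauss(qrsC, 12)
  xyz[, 3] <- xyz[, 3] - 500 * gauss(qrsC + 5, 12)
  # T loop along the arc-length parameterized path
  tStartMs <- params$jMs + 20
  tDur <- tt$tau[length(tt$tau)]
  tendMs <- tStartMs + tDur
  if (tendMs > params$rrMs - 20)
    stop("warp pushes Tend beyond the beat (", round(tendMs), " ms)")
  inWin <- tMs >= tStartMs - 1e-9 & tMs <= tendMs + 1e-9
  degenerate <- params$tAmplitudeUv == 0
  qOf <- approx(tt$tau, tt$q, xout = pmin(tMs[inWin] - tStartMs, tDur),
                rule = 2)$y
  xyz[inWin, ] <- xyz[inWin, ] + params$tAmplitudeUv * .pathAt(qOf)
  ann <- data.frame(p_idx = as.integer(round(params$pEndMs / dtMs)),
                    q_idx = as.integer(round(params$qMs / dtMs)),
                    j_idx = as.integer(round(params$jMs / dtMs)),
                    tend_idx = as.integer(round(tendMs / dtMs)),
                    beat_class = "normal_sinus", rr_ms = params$rrMs)
  trueTrx <- setNames(approx(tt$q, tt$tau, xout = seq(0.1, 1, 0.1))$y,
                      paste0("Tr", seq(10, 100, 10)))
  trueTrx["Tr100"] <- tDur
  arcLength <- params$tAmplitudeUv * .tLoopPath()$unitLength * qOf
  structure(list(xyz = xyz, fs = fs, annotation = ann, trueTrx = trueTrx,
                 arcLength = arcLength, tau = tt, degenerate = degenerate,
                 params = params),
            class = "DipoleBeat")
}

#' Re-time the repolarization of a synthetic beat
#'
#' Replaces the timing map of a beat's T loop: the spatial path is
#' unchanged, but arc fraction q is now reached at `tau(q)`. Tend moves to
#' `J + 20 ms + tau(1)`. Returns the warped beat together with the true
#' trajectory quantiles `tau(X/100)`.
#'
#' @param beat a `"DipoleBeat"` from [simulateDipoleBeat()].
#' @param tau new timing map (function of q, strictly increasing,
#'   `tau(0) = 0`).
#' @return list with elements `beat` (the warped `"DipoleBeat"`) and
#'   `trueTrx`.
#' @export
applyRepolarizationWarp <- function(beat, tau) {
  stopifnot(inherits(beat, "DipoleBeat"))
  warped <- simulateDipoleBeat(beat$params, tau = tau)
  list(beat = warped, trueTrx = warped$trueTrx)
}

#' One-compartment oral PK profile
#'
#' `C(t) = scale * dose * (exp(-ke t) - exp(-ka t))` after each dose, with
#' superposition over repeated doses.
#'
#' @param dose administered dose (arbitrary units).
#' @param timesH evaluation times (h, relative to the first morning dose).
#' @param ka,ke absorption and elimination rate constants (1/h), positive
#'   and distinct.
#' @param scale concentration scale (concentration units per dose unit).
#' @param doseTimesH dosing times (h).
#' @return concentrations at `timesH` (0 before the first dose).
#' @export
simulatePkProfile <- function(dose, timesH, ka, ke, scale = 1,
                              doseTimesH = 0) {
  if (!is.finite(ka) || !is.finite(ke) || ka <= 0 || ke <= 0)
    stop("rate constants must be positive")
  if (ka == ke) stop("ka and ke must differ")
  conc <- rep(0, length(timesH))
  for (d in doseTimesH) {
    dt <- timesH - d
    on <- dt > 0
    conc[on] <- conc[on] + scale * dose * (exp(-ke * dt[on]) - exp(-ka * dt[on]))
  }
  conc
}
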