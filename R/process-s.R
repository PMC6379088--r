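#' @include AllClasses.R core-records.R
NULL

#' Construct a Process S parameter set
#'
#' @param tauI increase time constant, hours (waking and REM sleep).
#' @param tauD decrease time constant, hours (NREM sleep).
#' @param ua,la upper and lower asymptotes, % of reference (`la < ua`).
#' @param s0 warm-up starting value, % (default 150).
#' @param dt iteration step, seconds (default 4).
#' @return a validated [ProcessSParams-class].
#' @export
ProcessSParams <- function(tauI, tauD, ua, la, s0 = 150, dt = 4) {
  new("ProcessSParams", tauI = tauI, tauD = tauD, ua = ua, la = la,
      s0 = s0, dt = dt)
}

.wake_like <- function(st) st != "NREM"

#' One iteration step of Process S
#'
#' During waking and REM sleep S relaxes exponentially toward the upper
#' asymptote, `S' = UA - (UA - S) exp(-dt/tauI)`; during NREM sleep it
#' decays toward the lower asymptote, `S' = LA + (S - LA) exp(-dt/tauD)`.
#' Artefact epochs use their underlying state. S is clamped to
#' `[la, ua]` on entry to guard against floating-point overshoot.
#'
#' @param S current value(s), % of reference.
#' @param state state label(s), recycled against `S`.
#' @param p a [ProcessSParams-class].
#' @return next S value(s).
#' @export
stepS <- function(S, state, p) {
  validObject(p)
  S <- pmin(pmax(S, p@la), p@ua)
  up <- .wake_like(state)
  bi <- exp(-p@dt / (p@tauI * 3600))
  bd <- exp(-p@dt / (p@tauD * 3600))
  out <- ifelse(up, p@ua - (p@ua - S) * bi, p@la + (S - p@la) * bd)
  pmin(pmax(out, p@la), p@ua)
}

## Warm-up over the first 24 h, iterated to its fixed point. A single pass
## only contracts the dependence on S0 by exp(-(t_wake/tauI + t_nrem/tauD)),
## which for realistic constants leaves a visible S0 footprint; repeating the
## pass realizes the steady-state assumption behind using baseline day 1 as
## the initial condition. Works on run-length-compressed states for speed.
.warmup_s <- function(runs, s0, la, ua, ci, cd, tol = 1e-9, maxPasses = 50L) {
  S <- pmin(pmax(s0, la), ua)
  for (pass in seq_len(maxPasses)) {
    Sprev <- S
    for (i in seq_along(runs$lengths)) {
      if (runs$values[i]) {
        S <- ua + (S - ua) * exp(runs$lengths[i] * ci)
      } else {
        S <- la + (S - la) * exp(runs$lengths[i] * cd)
      }
    }
    if (max(abs(S - Sprev)) < tol) break
  }
  S
}

#' Simulate Process S over a hypnogram
#'
#' Runs the exponential Process S dynamics epoch by epoch over the scored
#' hypnogram. The simulation is preceded by a warm-up over the first 24 h
#' starting from `s0`; the warm-up pass is repeated until the value at the
#' start of the day converges (tolerance `warmupTol`), so the reported trace
#' is independent of `s0` and reflects the steady state of the baseline
#' day. Artefact flags are ignored (they affect delta-power availability,
#' not state dynamics).
#'
#' @param hyp a [Hypnogram-class] covering at least 24 h.
#' @param p a [ProcessSParams-class]; `p@dt` must equal the epoch length.
#' @param warmupTol convergence tolerance of the warm-up fixed point.
#' @return numeric vector, S at the end of each epoch, % of reference.
#' @export
simulateProcessS <- function(hyp, p, warmupTol = 1e-9) {
  validObject(p)
  st <- states(hyp)
  eps <- epochSeconds(hyp)
  if (abs(p@dt - eps) > 1e-9)
    stop("p@dt (", p@dt, " s) must equal the epoch length (", eps, " s)")
  n24 <- as.integer(round(24 * 3600 / eps))
  if (length(st) < n24)
    stop("recording shorter than the 24-h warm-up window")
  ci <- -eps / (p@tauI * 3600)
  cd <- -eps / (p@tauD * 3600)

  wl <- .wake_like(st)
  runs0 <- rle(wl[seq_len(n24)])
  S <- .warmup_s(runs0, p@s0, p@la, p@ua, ci, cd, tol = warmupTol)

  runs <- rle(wl)
  out <- numeric(length(st))
  pos <- 0L
  for (i in seq_along(runs$lengths)) {
    len <- runs$lengths[i]
    k <- seq_len(len)
    if (runs$values[i]) {
      seg <- p@ua + (S - p@ua) * exp(k * ci)
    } else {
      seg <- p@la + (S - p@la) * exp(k * cd)
    }
    seg <- pmin(pmax(seg, p@la), p@ua)
    out[pos + k] <- seg
    S <- seg[len]
    pos <- pos + len
  }
  out
}

#' Grid specification for the Process S fit
#'
#' The default exhaustive grid spans `tauI` 1-25 h in steps of 0.125 h and
#' `tauD` 0.1-5.0 h in steps of 0.025 h, endpoints inclusive on both sides:
#' 193 x 197 = 38,021 combinations. `coarse = TRUE` widens both steps by a
#' factor of four (2,450 combinations) for fast exploratory fits and CI.
#'
#' @param tauIRange,tauIStep increase-constant range (h) and step.
#' @param tauDRange,tauDStep decrease-constant range (h) and step.
#' @param coarse use the 4x-coarsened steps.
#' @return an object of class `"GridSpec"`: list with `tauI` and `tauD`
#'   grid vectors.
#' @export
gridSpec <- function(tauIRange = c(1, 25), tauIStep = 0.125,
                     tauDRange = c(0.1, 5.0), tauDStep = 0.025,
                     coarse = FALSE) {
  if (coarse) {
    tauIStep <- tauIStep * 4
    tauDStep <- tauDStep * 4
  }
  if (tauIStep <= 0 || tauDStep <= 0) stop("grid steps must be positive")
  if (diff(tauIRange) < 0 || diff(tauDRange) < 0) stop("ranges must be ordered")
  nI <- as.integer(round(diff(tauIRange) / tauIStep)) + 1L
  nD <- as.integer(round(diff(tauDRange) / tauDStep)) + 1L
  structure(list(
    tauI = round(tauIRange[1] + (seq_len(nI) - 1L) * tauIStep, 10),
    tauD = round(tauDRange[1] + (seq_len(nD) - 1L) * tauDStep, 10)
  ), class = "GridSpec")
}

#' Number of parameter combinations in a grid
#'
#' @param grid a `"GridSpec"` from [gridSpec()].
#' @return integer combination count.
#' @export
gridCombinations <- function(grid) {
  length(grid$tauI) * length(grid$tauD)
}

#' Estimate the Process S asymptotes from delta-power distributions
#'
#' The upper asymptote is the 99th percentile of the delta-power values of
#' all NREM epochs of the recording. The lower asymptote is the delta value
#' at which the normalized frequency distributions of NREM and REM delta
#' power intersect between their modes: both samples are binned on a common
#' grid (bin width `binWidthFrac` of the NREM median), the crossing is the
#' first bin above the REM mode where the NREM frequency exceeds the REM
#' frequency, refined by linear interpolation; when the distributions are
#' separated by a run of empty bins the midpoint of that run is used.
#'
#' @param deltaNrem delta-power values of NREM epochs.
#' @param deltaRem delta-power values of REM epochs.
#' @param binWidthFrac histogram bin width as a fraction of the NREM median.
#' @return list with `la` and `ua`.
#' @export
estimateAsymptotes <- function(deltaNrem, deltaRem, binWidthFrac = 0.02) {
  deltaNrem <- deltaNrem[is.finite(deltaNrem)]
  deltaRem <- deltaRem[is.finite(deltaRem)]
  if (!length(deltaNrem) || !length(deltaRem))
    stop("both NREM and REM delta samples must be non-empty")
  ua <- stats::quantile(deltaNrem, 0.99, names = FALSE)

  h <- binWidthFrac * stats::median(deltaNrem)
  lo <- min(deltaNrem, deltaRem)
  hi <- max(deltaNrem, deltaRem)
  breaks <- seq(lo - h, hi + h, by = h)
  fN <- graphics::hist(deltaNrem, breaks = breaks, plot = FALSE)$counts /
    length(deltaNrem)
  fR <- graphics::hist(deltaRem, breaks = breaks, plot = FALSE)$counts /
    length(deltaRem)
  ctr <- breaks[-length(breaks)] + h / 2
  mR <- which.max(fR)
  mN <- which.max(fN)
  if (mR >= mN)
    stop("REM delta mode does not lie below the NREM mode; ",
         "supply LA manually")
  d <- fN - fR
  cand <- seq(mR, mN)
  iHigh <- cand[which(d[cand] > 0)[1]]
  if (is.na(iHigh))
    stop("NREM and REM delta distributions never cross between their ",
         "modes; supply LA manually")
  below <- cand[cand < iHigh & d[cand] < 0]
  if (!length(below))
    stop("NREM and REM delta distributions never cross between their ",
         "modes; supply LA manually")
  iLow <- max(below)
  if (iHigh - iLow == 1L) {
    la <- ctr[iLow] - d[iLow] * (ctr[iHigh] - ctr[iLow]) /
      (d[iHigh] - d[iLow])
  } else {
    la <- (ctr[iLow] + ctr[iHigh]) / 2
  }
  if (!(la < ua))
    stop("estimated LA is not below UA; supply asymptotes manually")
  list(la = as.numeric(la), ua = as.numeric(ua))
}

#' Remove a linear day-to-day drift from a delta-power time course
#'
#' Fits a straight line through the time-course means of the three low
#' sleep-pressure reference windows (ZT8-12 of each baseline day and of the
#' last recovery day) against recording time, divides it out and re-anchors
#' so the reference level is 100%. Detrending is multiplicative because
#' delta power is a positive relative quantity.
#'
#' @param tc a `"DeltaTimecourse"` from [deltaTimecourse()].
#' @param referenceZt ZT window of the reference periods (default 8-12 h).
#' @return the detrended time course, same shape, with attribute
#'   `"trend"` carrying the fitted intercept and slope (% per hour).
#' @export
detrendDelta <- function(tc, referenceZt = c(8, 12)) {
  proto <- attr(tc, "protocol")
  if (is.null(proto)) stop("time course lacks protocol metadata")
  refDays <- c(seq_len(proto@sdDay - 1), proto@nDays)
  m <- t0 <- numeric(length(refDays))
  for (j in seq_along(refDays)) {
    w0 <- (refDays[j] - 1) * 24 + referenceZt[1]
    w1 <- (refDays[j] - 1) * 24 + referenceZt[2]
    sel <- tc$time_h >= w0 & tc$time_h < w1
    if (!any(sel))
      stop("no time-course bins in reference window of day ", refDays[j])
    m[j] <- mean(tc$value[sel])
    t0[j] <- mean(tc$time_h[sel])
  }
  fit <- stats::lm(m ~ t0)
  line <- stats::predict(fit, newdata = data.frame(t0 = tc$time_h))
  if (any(line <= 0)) stop("fitted trend line crosses zero; cannot detrend")
  out <- tc
  out$value <- tc$value * 100 / line
  attr(out, "trend") <- stats::coef(fit)
  out
}

#' Fit Process S time constants by exhaustive grid search
#'
#' For every `(tauI, tauD)` combination of the grid, simulates Process S
#' over the hypnogram (with converged 24-h warm-up), averages the simulated
#' S over the same NREM epochs that contribute to each time-course bin, and
#' scores the combination by the mean squared difference between simulated
#' and observed bin values. The global minimum is returned; ties break
#' toward the smaller `(tauI, tauD)` lexicographically. The grid sweep is
#' vectorized across all combinations with run-length-compressed dynamics,
#' so the full default grid completes in well under a minute on one core.
#'
#' @param hyp a [Hypnogram-class].
#' @param tc a `"DeltaTimecourse"` (typically detrended) whose bins carry
#'   their member epoch indices.
#' @param asymptotes list with `la` and `ua`, e.g. from
#'   [estimateAsymptotes()]. With `asymptoteUnits = "absolute"` (default)
#'   they are given in the raw delta units and converted to % of the
#'   time-course reference; `"percent"` takes them as already on the
#'   time-course scale.
#' @param grid a `"GridSpec"` (default: the full 38,021-point grid).
#' @param s0 warm-up start, % (default 150).
#' @param surface also return the full MSE surface (matrix tauI x tauD).
#' @param warmupTol warm-up fixed-point tolerance.
#' @return an object of class `"FitResult"`: list with `best`
#'   ([ProcessSParams-class]), `mse`, `sTrace`, `nCombos`, `grid` and
#'   optionally `surface`.
#' @export
fitGrid <- function(hyp, tc, asymptotes, grid = gridSpec(), s0 = 150,
                    surface = FALSE, warmupTol = 1e-9,
                    asymptoteUnits = c("absolute", "percent")) {
  asymptoteUnits <- match.arg(asymptoteUnits)
  la <- asymptotes$la
  ua <- asymptotes$ua
  if (asymptoteUnits == "absolute") {
    ref <- attr(tc, "reference")
    if (is.null(ref)) stop("time course lacks its reference value")
    la <- la / ref * 100
    ua <- ua / ref * 100
  }
  stopifnot(is.finite(la), is.finite(ua), la < ua)
  if (!length(grid$tauI) || !length(grid$tauD)) stop("empty grid")
  eps <- epochSeconds(hyp)
  st <- states(hyp)
  n <- length(st)

  binEpochs <- attr(tc, "epochs")
  if (is.null(binEpochs)) stop("time course lacks bin epoch indices")
  nb <- length(binEpochs)
  binId <- rep(NA_integer_, n)
  for (b in seq_len(nb)) binId[binEpochs[[b]]] <- b
  binCount <- lengths(binEpochs)
  obs <- tc$value

  ## grid vectors, tauI slowest so the first minimum is the lexicographic one
  tauIv <- rep(grid$tauI, each = length(grid$tauD))
  tauDv <- rep(grid$tauD, times = length(grid$tauI))
  G <- length(tauIv)
  ci <- -eps / (tauIv * 3600)
  cd <- -eps / (tauDv * 3600)

  wl <- .wake_like(st)
  n24 <- as.integer(round(24 * 3600 / eps))
  if (n < n24) stop("recording shorter than the 24-h warm-up window")

  ## converged warm-up over the first 24 h, all grid points at once
  runs0 <- rle(wl[seq_len(n24)])
  S <- rep(min(max(s0, la), ua), G)
  for (pass in 1:50) {
    Sprev <- S
    for (i in seq_along(runs0$lengths)) {
      len <- runs0$lengths[i]
      if (runs0$values[i]) {
        S <- ua + (S - ua) * exp(len * ci)
      } else {
        S <- la + (S - la) * exp(len * cd)
      }
    }
    if (max(abs(S - Sprev)) < warmupTol) break
  }

  ## main sweep with per-bin accumulation of S over member NREM epochs
  runs <- rle(wl)
  binSum <- matrix(0, nrow = nb, ncol = G)
  pos <- 0L
  for (i in seq_along(runs$lengths)) {
    len <- runs$lengths[i]
    if (runs$values[i]) {
      S <- ua + (S - ua) * exp(len * ci)
    } else {
      ids <- binId[(pos + 1L):(pos + len)]
      segs <- rle(ifelse(is.na(ids), 0L, ids))
      a <- 1L
      for (j in seq_along(segs$lengths)) {
        l <- segs$lengths[j]
        b <- segs$values[j]
        if (b > 0L) {
          ## sum_{k=a..a+l-1} S_k with S_k = la + (S_in - la) exp(k*cd)
          gsum <- (exp(a * cd) - exp((a + l) * cd)) / (1 - exp(cd))
          binSum[b, ] <- binSum[b, ] + l * la + (S - la) * gsum
        }
        a <- a + l
      }
      S <- la + (S - la) * exp(len * cd)
    }
    pos <- pos + len
  }

  mse <- colMeans((obs - binSum / binCount)^2)
  bestIdx <- which.min(mse)
  best <- ProcessSParams(tauI = tauIv[bestIdx], tauD = tauDv[bestIdx],
                         ua = ua, la = la, s0 = s0, dt = eps)
  res <- list(
    best = best,
    mse = mse[bestIdx],
    sTrace = simulateProcessS(hyp, best, warmupTol = warmupTol),
    nCombos = G,
    grid = grid
  )
  if (surface)
    res$surface <- matrix(mse, nrow = length(grid$tauD),
                          ncol = length(grid$tauI),
                          dimnames = list(tauD = grid$tauD,
                                          tauI = grid$tauI))
  class(res) <- "FitResult"
  res
}

#' @method print FitResult
#' @export
print.FitResult <- function(x, ...) {
  cat(sprintf(
    "Process S grid fit: %d combinations evaluated\n  best: tauI %.3f h, tauD %.3f h (UA %.1f%%, LA %.1f%%), MSE %.3f\n",
    x$nCombos, x$best@tauI, x$best@tauD, x$best@ua, x$best@la, x$mse))
  invisible(x)
}
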