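#' @include AllClasses.R core-records.R
NULL

#' Accumulated recovery-minus-baseline time in a state
#'
#' For each 1-h interval from the end of the sleep deprivation, the minutes
#' spent in `state` during recovery minus the minutes at the matched
#' baseline hour, accumulated over time. Matched hours are taken from the
#' baseline day two days earlier (REC1 vs BL1, REC2 vs BL2) or, with
#' `baseline = "mean"`, from the average of both baseline days.
#'
#' @param hyp a [Hypnogram-class].
#' @param state `"WAKE"`, `"NREM"`, `"REM"` or `"TDW"`.
#' @param baseline `"matched"` or `"mean"`.
#' @param recoverySpan hours since recording start, default SD end to the
#'   end of the recording.
#' @return data frame with `time_h` (hours since SD end, starting at 0) and
#'   `cum_diff` (minutes), attribute `state`.
#' @export
accumulatedDifference <- function(hyp, state,
                                  baseline = c("matched", "mean"),
                                  recoverySpan = NULL) {
  baseline <- match.arg(baseline)
  proto <- protocol(hyp)
  sdEnd <- sdWindowHours(proto)[2]
  if (is.null(recoverySpan))
    recoverySpan <- c(sdEnd, proto@nDays * 24)
  if (abs(recoverySpan[1] %% 1) > 1e-9 || abs(recoverySpan[2] %% 1) > 1e-9)
    stop("recovery span must be aligned to whole hours")
  hours <- seq(recoverySpan[1], recoverySpan[2] - 1)
  nBase <- proto@sdDay - 1
  diffs <- vapply(hours, function(h) {
    rec <- minutesInState(hyp, state, c(h, h + 1))
    bl <- if (baseline == "matched") {
      hb <- h - 48
      if (hb < 0 || hb + 1 > nBase * 24)
        stop("matched baseline hour ", hb, " outside the baseline days")
      minutesInState(hyp, state, c(hb, hb + 1))
    } else {
      zt <- h %% 24
      mean(vapply(seq_len(nBase), function(d)
        minutesInState(hyp, state, (d - 1) * 24 + c(zt, zt + 1)),
        numeric(1)))
    }
    rec - bl
  }, numeric(1))
  out <- data.frame(time_h = c(0, hours + 1 - recoverySpan[1]),
                    cum_diff = c(0, cumsum(diffs)))
  attr(out, "state") <- state
  out
}

#' Locomotor activity per unit of waking, in equal-waking percentiles
#'
#' Within each lights-phase block, per-minute locomotor counts are summed
#' into bins whose boundaries equalize the accumulated waking time, and
#' expressed per waking minute. Light phases get 6 bins and dark phases 12;
#' on the sleep-deprivation day the SD window gets 6 and the remaining
#' light hours 3. Counts in minutes without any waking carry zero weight.
#'
#' @param hyp a [Hypnogram-class].
#' @param lma a [SampledTrace-class] of per-minute counts.
#' @param nbinsLight,nbinsDark,nbinsSd,nbinsRecRest bins per block type.
#' @return data frame with `day`, `phase`, `bin`, `time_h`,
#'   `lma_per_wake_min`, `waking_min`.
#' @export
lmaPerWakingTimecourse <- function(hyp, lma, nbinsLight = 6, nbinsDark = 12,
                                   nbinsSd = 6, nbinsRecRest = 3) {
  if (abs(samplingInterval(lma) - 60) > 1e-9)
    stop("lma must be sampled per minute")
  proto <- protocol(hyp)
  eps <- epochSeconds(hyp)
  epm <- as.integer(round(60 / eps))
  st <- states(hyp)
  nmin <- length(st) %/% epm
  minuteOf <- rep(seq_len(nmin), each = epm)[seq_len(nmin * epm)]
  wakeMin <- tabulate(minuteOf[st[seq_len(nmin * epm)] == "WAKE"],
                      nbins = nmin) * eps / 60
  counts <- traceValues(lma)[seq_len(nmin)]

  blocks <- list()
  for (d in seq_len(proto@nDays)) {
    off <- (d - 1) * 24
    if (d == proto@sdDay) {
      sdw <- proto@sdWindowZt
      blocks <- c(blocks,
                  list(list(day = d, phase = "SD", h = off + sdw,
                            nb = nbinsSd),
                       list(day = d, phase = "light", h = c(off + sdw[2],
                                                            off + proto@lightsOffZt),
                            nb = nbinsRecRest)))
    } else {
      blocks <- c(blocks,
                  list(list(day = d, phase = "light",
                            h = c(off + proto@lightsOnZt,
                                  off + proto@lightsOffZt),
                            nb = nbinsLight)))
    }
    blocks <- c(blocks, list(list(day = d, phase = "dark",
                                  h = c(off + proto@lightsOffZt, off + 24),
                                  nb = nbinsDark)))
  }

  rows <- list()
  for (bl in blocks) {
    mins <- (bl$h[1] * 60 + 1):(bl$h[2] * 60)
    mins <- mins[mins <= nmin]
    w <- wakeMin[mins]
    cts <- counts[mins]
    cts[w <= 0] <- 0  # sleep-minute counts carry no weight
    W <- sum(w)
    if (W <= 0)
      stop(sprintf("block day %d %s contains no waking", bl$day, bl$phase))
    ## assign each minute by its cumulative-waking midpoint so every bin's
    ## waking total deviates from the equal share by less than one minute
    cw <- cumsum(w) - w / 2
    binOf <- pmin(pmax(ceiling(cw / (W / bl$nb) - 1e-12), 1L), bl$nb)
    binOf[w <= 0] <- NA  # zero-weight minutes join no bin
    for (k in seq_len(bl$nb)) {
      sel <- which(binOf == k)
      wk <- sum(w[sel])
      tmid <- sum(((mins[sel] - 0.5) / 60) * w[sel]) / wk
      rows[[length(rows) + 1L]] <- data.frame(
        day = bl$day, phase = bl$phase, bin = k, time_h = tmid,
        lma_per_wake_min = sum(cts[sel]) / wk, waking_min = wk
      )
    }
  }
  do.call(rbind, rows)
}

#' Median-absolute-deviation outlier flags
#'
#' Flags values whose distance from the median exceeds `threshold` robust
#' standard deviations (`1.4826 * MAD`). When the MAD is zero but values
#' differ, any value off the median is flagged.
#'
#' @param values numeric, length at least 3.
#' @param threshold number of robust SDs (default 3).
#' @return logical flags.
#' @export
madOutliers <- function(values, threshold = 3) {
  if (length(values) < 3) stop("need at least three values")
  med <- stats::median(values, na.rm = TRUE)
  dev <- abs(values - med)
  s <- stats::median(dev, na.rm = TRUE) * 1.4826
  if (s == 0) return(!is.na(dev) & dev > 0)
  !is.na(dev) & dev / s > threshold
}
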