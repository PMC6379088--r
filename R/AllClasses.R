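#' @import methods
NULL

#' Vigilance-state labels
#'
#' The three scored vigilance states, in the fixed order used throughout the
#' package (also the tie-break priority when collapsing epochs to minutes).
#'
#' @export
stateLevels <- c("WAKE", "NREM", "REM")

#' Recording protocol metadata
#'
#' Describes the light-dark schedule and the enforced-wakefulness (sleep
#' deprivation, SD) window of a recording. Zeitgeber time (ZT) is expressed
#' in decimal hours, with ZT0 = lights on.
#'
#' @slot lightsOnZt hour of lights on (ZT0 by definition).
#' @slot lightsOffZt hour of lights off.
#' @slot nDays number of recorded days.
#' @slot sdDay 1-based index of the sleep-deprivation day.
#' @slot sdWindowZt numeric length-2, SD window in ZT hours `[start, end)`.
#'
#' @export
setClass("ProtocolMeta",
  representation(
    lightsOnZt = "numeric",
    lightsOffZt = "numeric",
    nDays = "numeric",
    sdDay = "numeric",
    sdWindowZt = "numeric"
  ),
  prototype(
    lightsOnZt = 0, lightsOffZt = 12, nDays = 4, sdDay = 3,
    sdWindowZt = c(0, 6)
  )
)

setValidity("ProtocolMeta", function(object) {
  msg <- character()
  if (!(object@lightsOnZt >= 0 && object@lightsOnZt < object@lightsOffZt &&
        object@lightsOffZt <= 24))
    msg <- c(msg, "need 0 <= lightsOnZt < lightsOffZt <= 24")
  if (object@nDays < 1 || object@nDays != round(object@nDays))
    msg <- c(msg, "nDays must be a positive integer")
  if (length(object@sdWindowZt) != 2 ||
      object@sdWindowZt[1] >= object@sdWindowZt[2] ||
      object@sdWindowZt[1] < 0 || object@sdWindowZt[2] > 24)
    msg <- c(msg, "sdWindowZt must lie within one day, start < end")
  if (object@sdDay < 1 || object@sdDay > object@nDays)
    msg <- c(msg, "sdDay outside recorded days")
  if (length(msg)) msg else TRUE
})

#' Epoch-scored hypnogram
#'
#' An ordered sequence of 4-s (by default) epoch vigilance-state labels with
#' per-epoch artefact flags, an optional theta-dominated-waking (TDW)
#' sub-state flag for wake epochs, and the recording protocol. The first
#' epoch is anchored at ZT0 of day 1 unless `zt0Index` says otherwise.
#'
#' @slot states character, one of `"WAKE"`, `"NREM"`, `"REM"` per epoch.
#' @slot artefact logical per epoch; artefact epochs keep their state label,
#'   are excluded from spectral computations but included in state-time
#'   accounting.
#' @slot tdw logical per epoch; `TRUE` only allowed where `states == "WAKE"`.
#' @slot epochS epoch duration in seconds.
#' @slot zt0Index 1-based index of the epoch at ZT0 of day 1.
#' @slot protocol a [ProtocolMeta-class].
#'
#' @export
setClass("Hypnogram",
  representation(
    states = "character",
    artefact = "logical",
    tdw = "logical",
    epochS = "numeric",
    zt0Index = "integer",
    protocol = "ProtocolMeta"
  ),
  prototype(epochS = 4, zt0Index = 1L)
)

setValidity("Hypnogram", function(object) {
  msg <- character()
  n <- length(object@states)
  bad <- !(object@states %in% stateLevels)
  if (any(bad))
    msg <- c(msg, sprintf("unknown state label '%s' at epoch %d",
                          object@states[which(bad)[1]], which(bad)[1]))
  if (length(object@artefact) != n)
    msg <- c(msg, "length(artefact) != length(states)")
  if (length(object@tdw) != n)
    msg <- c(msg, "length(tdw) != length(states)")
  if (any(object@tdw & object@states != "WAKE", na.rm = TRUE))
    msg <- c(msg, "tdw may be TRUE only on WAKE epochs")
  if (object@epochS <= 0)
    msg <- c(msg, "epochS must be > 0")
  tot_h <- n * object@epochS / 3600
  if (n > 0 && abs(tot_h - round(tot_h)) > 1e-9)
    msg <- c(msg, "recording must cover an integer number of hours")
  if (length(msg)) msg else TRUE
})

#' Regularly sampled physiological trace
#'
#' A uniformly sampled numeric series (cortical temperature in deg C,
#' locomotor-activity counts, ...) aligned to the same ZT clock as the
#' hypnogram it accompanies.
#'
#' @slot values numeric series.
#' @slot dtS sampling interval in seconds.
#' @slot zt0Index 1-based index of the sample at ZT0 of day 1.
#' @slot unit unit label, e.g. `"degC"` or `"counts"`.
#'
#' @export
setClass("SampledTrace",
  representation(
    values = "numeric",
    dtS = "numeric",
    zt0Index = "integer",
    unit = "character"
  ),
  prototype(dtS = 4, zt0Index = 1L, unit = "")
)

setValidity("SampledTrace", function(object) {
  if (object@dtS <= 0) return("dtS must be > 0")
  TRUE
})

#' Per-epoch EEG power spectra
#'
#' Power densities on a fixed frequency grid (0-100 Hz in 0.25-Hz bins for
#' standard recordings), one row per scored epoch.
#'
#' @slot freqs strictly increasing, uniformly spaced frequency grid in Hz.
#' @slot power numeric matrix, epochs x frequencies, non-negative.
#' @slot normalized `TRUE` once expressed in % of the weighted baseline
#'   reference (see [spectralReference()]).
#'
#' @export
setClass("EpochSpectra",
  representation(
    freqs = "numeric",
    power = "matrix",
    normalized = "logical"
  ),
  prototype(normalized = FALSE)
)

setValidity("EpochSpectra", function(object) {
  msg <- character()
  f <- object@freqs
  if (length(f) < 2 || any(diff(f) <= 0))
    msg <- c(msg, "freqs must be strictly increasing")
  if (length(f) > 2 && diff(range(diff(f))) > 1e-9)
    msg <- c(msg, "freqs must be uniformly spaced")
  if (ncol(object@power) != length(f))
    msg <- c(msg, "ncol(power) != length(freqs)")
  if (any(object@power < 0, na.rm = TRUE))
    msg <- c(msg, "power must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Process S parameter set
#'
#' The complete parameterization of the homeostatic Process S dynamics:
#' S rises exponentially toward the upper asymptote `ua` with time constant
#' `tauI` during waking and REM sleep, and decays toward the lower asymptote
#' `la` with time constant `tauD` during NREM sleep. All S values are in %
#' of the delta-power reference.
#'
#' @slot tauI increase time constant in hours (waking and REM sleep).
#' @slot tauD decrease time constant in hours (NREM sleep).
#' @slot ua upper asymptote, % of reference.
#' @slot la lower asymptote, % of reference.
#' @slot s0 warm-up starting value, % (default 150).
#' @slot dt iteration step in seconds (default 4, one epoch).
#'
#' @export
setClass("ProcessSParams",
  representation(
    tauI = "numeric", tauD = "numeric",
    ua = "numeric", la = "numeric",
    s0 = "numeric", dt = "numeric"
  ),
  prototype(s0 = 150, dt = 4)
)

setValidity("ProcessSParams", function(object) {
  msg <- character()
  if (object@tauI <= 0 || object@tauD <= 0)
    msg <- c(msg, "time constants must be > 0")
  if (!(object@la < object@ua))
    msg <- c(msg, "need la < ua")
  if (object@la <= 0)
    msg <- c(msg, "asymptotes must be positive")
  if (object@dt <= 0)
    msg <- c(msg, "dt must be > 0")
  if (length(msg)) msg else TRUE
})

#' NTC thermistor calibration
#'
#' Calibration of a negative-temperature-coefficient thermistor from the two
#' manufacturer calibration resistances, via the material-constant (beta)
#' equation. Temperatures are held in kelvin internally.
#'
#' @slot r25 resistance in ohm at 25 deg C.
#' @slot r37 resistance in ohm at 37 deg C (must be `< r25` for an NTC).
#' @slot iConst constant measuring current in ampere (default 100 uA).
#' @slot beta derived material constant in kelvin.
#' @slot t25,t37 the calibration temperatures in kelvin (298.15, 310.15).
#'
#' @export
setClass("ThermistorCalibration",
  representation(
    r25 = "numeric", r37 = "numeric", iConst = "numeric",
    beta = "numeric", t25 = "numeric", t37 = "numeric"
  ),
  prototype(iConst = 1e-4, t25 = 298.15, t37 = 310.15)
)

setValidity("ThermistorCalibration", function(object) {
  msg <- character()
  if (object@r25 <= 0 || object@r37 <= 0)
    msg <- c(msg, "resistances must be positive")
  if (object@r37 >= object@r25)
    msg <- c(msg, "NTC requires r37 < r25 (resistance falls with temperature)")
  if (object@iConst <= 0)
    msg <- c(msg, "iConst must be positive")
  if (length(object@beta) == 1 && object@beta <= 0)
    msg <- c(msg, "beta must be positive")
  if (length(msg)) msg else TRUE
})
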