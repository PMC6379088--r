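#' @include AllClasses.R
NULL

#' Accessors for somnokit data objects
#'
#' Slot access for the S4 containers goes through these generics; user code
#' should never reach into slots directly.
#'
#' @param x a somnokit object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("states", function(x) standardGeneric("states"))

#' @rdname accessors
#' @export
setGeneric("artefacts", function(x) standardGeneric("artefacts"))

#' @rdname accessors
#' @export
setGeneric("tdwFlags", function(x) standardGeneric("tdwFlags"))

#' @rdname accessors
#' @export
setGeneric("epochSeconds", function(x) standardGeneric("epochSeconds"))

#' @rdname accessors
#' @export
setGeneric("protocol", function(x) standardGeneric("protocol"))

#' @rdname accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname accessors
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))

#' @rdname accessors
#' @export
setGeneric("samplingInterval", function(x) standardGeneric("samplingInterval"))

#' @rdname accessors
#' @export
setGeneric("traceUnit", function(x) standardGeneric("traceUnit"))

#' @rdname accessors
#' @export
setGeneric("freqs", function(x) standardGeneric("freqs"))

#' @rdname accessors
#' @export
setGeneric("powerMatrix", function(x) standardGeneric("powerMatrix"))

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname accessors
#' @export
setMethod("states", "Hypnogram", function(x) x@states)

#' @rdname accessors
#' @export
setMethod("artefacts", "Hypnogram", function(x) x@artefact)

#' @rdname accessors
#' @export
setMethod("tdwFlags", "Hypnogram", function(x) x@tdw)

#' @rdname accessors
#' @export
setMethod("epochSeconds", "Hypnogram", function(x) x@epochS)

#' @rdname accessors
#' @export
setMethod("protocol", "Hypnogram", function(x) x@protocol)

#' @rdname accessors
#' @export
setMethod("nEpochs", "Hypnogram", function(x) length(x@states))

#' @rdname accessors
#' @export
setMethod("nEpochs", "EpochSpectra", function(x) nrow(x@power))

#' @rdname accessors
#' @export
setMethod("traceValues", "SampledTrace", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("samplingInterval", "SampledTrace", function(x) x@dtS)

#' @rdname accessors
#' @export
setMethod("traceUnit", "SampledTrace", function(x) x@unit)

#' @rdname accessors
#' @export
setMethod("freqs", "EpochSpectra", function(x) x@freqs)

#' @rdname accessors
#' @export
setMethod("powerMatrix", "EpochSpectra", function(x) x@power)

#' @rdname accessors
#' @export
setMethod("isNormalized", "EpochSpectra", function(x) x@normalized)

setMethod("show", "ProtocolMeta", function(object) {
  cat(sprintf(
    "ProtocolMeta: LD %g:%g, %d days, SD on day %d ZT%g-%g\n",
    object@lightsOffZt - object@lightsOnZt,
    24 - (object@lightsOffZt - object@lightsOnZt),
    as.integer(object@nDays), as.integer(object@sdDay),
    object@sdWindowZt[1], object@sdWindowZt[2]
  ))
})

setMethod("show", "Hypnogram", function(object) {
  n <- length(object@states)
  cat(sprintf("Hypnogram: %d epochs of %g s (%g h)\n",
              n, object@epochS, n * object@epochS / 3600))
  tab <- table(factor(object@states, levels = stateLevels))
  cat("  ", paste(sprintf("%s %.1f%%", names(tab), 100 * tab / max(n, 1)),
                  collapse = ", "), "\n")
  cat(sprintf("  artefacts: %.1f%%; TDW (of wake): %.1f%%\n",
              100 * mean(object@artefact),
              100 * sum(object@tdw) / max(sum(object@states == "WAKE"), 1)))
  show(object@protocol)
})

setMethod("show", "SampledTrace", function(object) {
  cat(sprintf("SampledTrace: %d samples every %g s [%s], range %.3g..%.3g\n",
              length(object@values), object@dtS, object@unit,
              suppressWarnings(min(object@values, na.rm = TRUE)),
              suppressWarnings(max(object@values, na.rm = TRUE))))
})

setMethod("show", "EpochSpectra", function(object) {
  cat(sprintf(
    "EpochSpectra: %d epochs x %d bins (%.2f-%.2f Hz, step %.2g Hz)%s\n",
    nrow(object@power), length(object@freqs),
    min(object@freqs), max(object@freqs), diff(object@freqs[1:2]),
    if (object@normalized) ", normalized (% of reference)" else ""
  ))
})

setMethod("show", "ProcessSParams", function(object) {
  cat(sprintf(
    "ProcessSParams: tauI %.3f h, tauD %.3f h, UA %.1f%%, LA %.1f%%, S0 %.1f%%, dt %g s\n",
    object@tauI, object@tauD, object@ua, object@la, object@s0, object@dt
  ))
})

setMethod("show", "ThermistorCalibration", function(object) {
  cat(sprintf(
    "ThermistorCalibration: R25 %.1f ohm, R37 %.1f ohm, beta %.1f K, I %.3g A\n",
    object@r25, object@r37, object@beta, object@iConst
  ))
})
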