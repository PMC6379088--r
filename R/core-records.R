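#' @include AllClasses.R AllGenerics.R
NULL

#' Construct protocol metadata
#'
#' @param lightsOnZt,lightsOffZt light schedule in ZT hours (ZT0 = lights on).
#' @param nDays number of recorded days.
#' @param sdDay 1-based day index of the sleep deprivation.
#' @param sdWindowZt SD window within that day, ZT hours `[start, end)`.
#' @return a validated [ProtocolMeta-class].
#' @export
ProtocolMeta <- function(lightsOnZt = 0, lightsOffZt = 12, nDays = 4,
                         sdDay = 3, sdWindowZt = c(0, 6)) {
  new("ProtocolMeta", lightsOnZt = lightsOnZt, lightsOffZt = lightsOffZt,
      nDays = nDays, sdDay = sdDay, sdWindowZt = sdWindowZt)
}

#' Construct a hypnogram
#'
#' @param states character vector of epoch labels (`"WAKE"`, `"NREM"`,
#'   `"REM"`).
#' @param artefact logical per epoch (default all `FALSE`).
#' @param tdw logical per epoch, theta-dominated waking flags (default all
#'   `FALSE`); may be `TRUE` only on wake epochs.
#' @param epochS epoch length in seconds.
#' @param zt0Index 1-based index of the epoch at ZT0 of day 1.
#' @param protocol a [ProtocolMeta-class].
#' @return a validated [Hypnogram-class].
#' @export
Hypnogram <- function(states, artefact = NULL, tdw = NULL, epochS = 4,
                      zt0Index = 1L, protocol = ProtocolMeta()) {
  states <- as.character(states)
  if (is.null(artefact)) artefact <- rep(FALSE, length(states))
  if (is.null(tdw)) tdw <- rep(FALSE, length(states))
  new("Hypnogram", states = states, artefact = artefact, tdw = tdw,
      epochS = epochS, zt0Index = as.integer(zt0Index), protocol = protocol)
}

#' Construct a sampled trace
#'
#' @param values numeric series.
#' @param dtS sampling interval in seconds.
#' @param zt0Index 1-based index of the sample at ZT0 of day 1.
#' @param unit unit label.
#' @return a validated [SampledTrace-class].
#' @export
SampledTrace <- function(values, dtS = 4, zt0Index = 1L, unit = "") {
  new("SampledTrace", values = as.numeric(values), dtS = dtS,
      zt0Index = as.integer(zt0Index), unit = unit)
}

#' Construct per-epoch spectra
#'
#' @param freqs uniform frequency grid in Hz.
#' @param power epochs x frequencies matrix of power densities.
#' @param normalized whether `power` is in % of the baseline reference.
#' @return a validated [EpochSpectra-class].
#' @export
EpochSpectra <- function(freqs, power, normalized = FALSE) {
  new("EpochSpectra", freqs = as.numeric(freqs), power = as.matrix(power),
      normalized = normalized)
}

#' Epoch start times in hours since ZT0 of day 1
#'
#' @param hyp a [Hypnogram-class].
#' @return numeric vector, one start time per epoch (decimal hours).
#' @export
epochTimesH <- function(hyp) {
  (seq_along(states(hyp)) - hyp@zt0Index) * epochSeconds(hyp) / 3600
}

#' Epoch indices falling in a recording-time window
#'
#' Windows are half-open `[startH, endH)` in decimal hours since ZT0 of
#' day 1 (the recording start for standard protocols).
#'
#' @param hyp a [Hypnogram-class].
#' @param startH,endH window bounds in hours.
#' @return integer epoch indices.
#' @export
ztWindowEpochs <- function(hyp, startH, endH) {
  t <- epochTimesH(hyp)
  dur <- length(t) * epochSeconds(hyp) / 3600
  if (startH < t[1] - 1e-9 || endH > t[1] + dur + 1e-9)
    stop("window [", startH, ", ", endH, ") outside recording")
  which(t >= startH - 1e-9 & t < endH - 1e-9)
}

#' Absolute recording hours of the sleep-deprivation window
#'
#' @param protocol a [ProtocolMeta-class].
#' @return numeric length-2, hours since ZT0 day 1.
#' @export
sdWindowHours <- function(protocol) {
  (protocol@sdDay - 1) * 24 + protocol@sdWindowZt
}

#' Time spent in a state within a window
#'
#' Counts matching epochs inside a half-open recording-time window and
#' converts to minutes. Artefact epochs keep their state label and are
#' counted by default, matching standard sleep-state accounting; set
#' `countArtefacts = FALSE` to drop them. The pseudo-state `"TDW"` counts
#' wake epochs flagged as theta-dominated waking.
#'
#' @param hyp a [Hypnogram-class].
#' @param state one of `"WAKE"`, `"NREM"`, `"REM"`, `"TDW"`.
#' @param window numeric length-2, hours since recording start, `[start, end)`.
#' @param countArtefacts include artefact epochs (default `TRUE`).
#' @return minutes spent in `state`.
#' @export
minutesInState <- function(hyp, state,
                           window = c(0, nEpochs(hyp) * epochSeconds(hyp) / 3600),
                           countArtefacts = TRUE) {
  state <- match.arg(state, c(stateLevels, "TDW"))
  idx <- ztWindowEpochs(hyp, window[1], window[2])
  sel <- if (state == "TDW") tdwFlags(hyp)[idx] else states(hyp)[idx] == state
  if (!countArtefacts) sel <- sel & !artefacts(hyp)[idx]
  sum(sel) * epochSeconds(hyp) / 60
}

#' Collapse a hypnogram to per-minute states
#'
#' Assigns to each whole minute the modal state of its epochs; ties are
#' broken by the fixed priority WAKE > NREM > REM. Used for display-style
#' summaries and for gating per-minute traces on behavioral state.
#'
#' @param hyp a [Hypnogram-class]; `epochS` must divide 60.
#' @return character vector of per-minute state labels.
#' @export
perMinuteStates <- function(hyp) {
  eps <- epochSeconds(hyp)
  epm <- 60 / eps
  if (abs(epm - round(epm)) > 1e-9)
    stop("epoch length must divide 60 s")
  epm <- as.integer(round(epm))
  st <- states(hyp)
  nmin <- length(st) %/% epm
  st <- st[seq_len(nmin * epm)]
  minute <- rep(seq_len(nmin), each = epm)
  counts <- vapply(stateLevels, function(s)
    tabulate(minute[st == s], nbins = nmin), integer(nmin))
  if (nmin == 1L) counts <- matrix(counts, nrow = 1)
  stateLevels[max.col(counts, ties.method = "first")]
}

## ---------------------------------------------------------------------------
## Tabular I/O: tab-separated, one row per epoch/sample, deterministic output.
## ---------------------------------------------------------------------------

.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con, sep = "\n")
  rows <- do.call(paste, c(unname(as.list(df)), sep = "\t"))
  if (length(rows)) writeLines(rows, con, sep = "\n")
  invisible(path)
}

#' Write a record bundle to a directory
#'
#' Emits the plain-text file set: `hypnogram.tsv` (epoch, state, artefact,
#' tdw), one `trace_<name>.tsv` per trace (t_s, value), optional
#' `delta.tsv` (epoch, delta) and `spectra.tsv` (epoch plus one column per
#' frequency bin), and `protocol.yaml` with the protocol and alignment
#' metadata. Output is deterministic: two writes of the same bundle are
#' byte-identical, and [readRecords()] is an exact inverse.
#'
#' @param bundle a list with elements `hypnogram` ([Hypnogram-class]),
#'   optionally `traces` (named list of [SampledTrace-class]), `delta`
#'   (numeric per epoch, `NA` where undefined) and `spectra`
#'   ([EpochSpectra-class] or `NULL`).
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeRecords <- function(bundle, dir) {
  hyp <- bundle$hypnogram
  stopifnot(is(hyp, "Hypnogram"))
  validObject(hyp)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory ", dir)
  paths <- character()

  hdf <- data.frame(
    epoch = seq_len(nEpochs(hyp)) - 1L,
    state = states(hyp),
    artefact = as.integer(artefacts(hyp)),
    tdw = as.integer(tdwFlags(hyp))
  )
  paths <- c(paths, .write_tsv(hdf, file.path(dir, "hypnogram.tsv")))

  meta <- list(
    epoch_s = epochSeconds(hyp),
    zt0_index = hyp@zt0Index,
    protocol = list(
      lights_on_zt = hyp@protocol@lightsOnZt,
      lights_off_zt = hyp@protocol@lightsOffZt,
      n_days = hyp@protocol@nDays,
      sd_day = hyp@protocol@sdDay,
      sd_window_zt = hyp@protocol@sdWindowZt
    ),
    traces = lapply(bundle$traces, function(tr)
      list(dt_s = samplingInterval(tr), zt0_index = tr@zt0Index,
           unit = traceUnit(tr)))
  )
  yaml::write_yaml(meta, file.path(dir, "protocol.yaml"))
  paths <- c(paths, file.path(dir, "protocol.yaml"))

  for (nm in names(bundle$traces)) {
    tr <- bundle$traces[[nm]]
    tdf <- data.frame(
      t_s = .fmt_num((seq_along(traceValues(tr)) - 1) * samplingInterval(tr)),
      value = .fmt_num(traceValues(tr))
    )
    paths <- c(paths,
               .write_tsv(tdf, file.path(dir, paste0("trace_", nm, ".tsv"))))
  }

  if (!is.null(bundle$delta)) {
    ddf <- data.frame(epoch = seq_along(bundle$delta) - 1L,
                      delta = .fmt_num(bundle$delta))
    paths <- c(paths, .write_tsv(ddf, file.path(dir, "delta.tsv")))
  }

  if (!is.null(bundle$spectra)) {
    sp <- bundle$spectra
    pm <- powerMatrix(sp)
    sdf <- data.frame(epoch = seq_len(nrow(pm)) - 1L)
    body <- apply(pm, 1, function(r) paste(.fmt_num(r), collapse = "\t"))
    con <- file(file.path(dir, "spectra.tsv"), open = "wb")
    writeLines(paste(c("epoch", sprintf("f%.2f", freqs(sp))), collapse = "\t"),
               con, sep = "\n")
    writeLines(paste(sdf$epoch, body, sep = "\t"), con, sep = "\n")
    close(con)
    paths <- c(paths, file.path(dir, "spectra.tsv"))
  }
  invisible(paths)
}

#' Read a record bundle from a directory
#'
#' Exact inverse of [writeRecords()]. Validates state labels (with the
#' offending row in the error message), mutual epoch-count consistency of
#' hypnogram, delta, spectra and epoch-resolution traces, and returns a
#' validated, ZT-aligned bundle. Artefact epochs are retained with flags.
#'
#' @param dir directory containing the file set.
#' @return a list with `hypnogram`, `traces`, `delta`, `spectra`.
#' @export
readRecords <- function(dir) {
  hp <- file.path(dir, "hypnogram.tsv")
  pp <- file.path(dir, "protocol.yaml")
  if (!file.exists(hp)) stop("missing hypnogram.tsv in ", dir)
  if (!file.exists(pp)) stop("missing protocol.yaml in ", dir)
  meta <- yaml::read_yaml(pp)
  hdf <- utils::read.delim(hp, sep = "\t", stringsAsFactors = FALSE)
  bad <- !(hdf$state %in% stateLevels)
  if (any(bad))
    stop(sprintf("unknown state label '%s' at hypnogram row %d",
                 hdf$state[which(bad)[1]], which(bad)[1]))
  proto <- ProtocolMeta(
    lightsOnZt = meta$protocol$lights_on_zt,
    lightsOffZt = meta$protocol$lights_off_zt,
    nDays = meta$protocol$n_days,
    sdDay = meta$protocol$sd_day,
    sdWindowZt = as.numeric(unlist(meta$protocol$sd_window_zt))
  )
  hyp <- Hypnogram(hdf$state, artefact = hdf$artefact == 1,
                   tdw = hdf$tdw == 1, epochS = meta$epoch_s,
                   zt0Index = meta$zt0_index, protocol = proto)
  dur_s <- nEpochs(hyp) * epochSeconds(hyp)

  traces <- list()
  for (nm in names(meta$traces)) {
    f <- file.path(dir, paste0("trace_", nm, ".tsv"))
    if (!file.exists(f)) stop("protocol.yaml lists trace '", nm,
                              "' but ", f, " is missing")
    tm <- meta$traces[[nm]]
    tdf <- utils::read.delim(f, sep = "\t", stringsAsFactors = FALSE)
    if (abs(nrow(tdf) * tm$dt_s - dur_s) > tm$dt_s / 2 + 1e-9)
      stop("alignment error: trace '", nm, "' covers ",
           nrow(tdf) * tm$dt_s, " s but hypnogram covers ", dur_s, " s")
    traces[[nm]] <- SampledTrace(as.numeric(tdf$value), dtS = tm$dt_s,
                                 zt0Index = tm$zt0_index, unit = tm$unit)
  }

  delta <- NULL
  df <- file.path(dir, "delta.tsv")
  if (file.exists(df)) {
    ddf <- utils::read.delim(df, sep = "\t", stringsAsFactors = FALSE)
    if (nrow(ddf) != nEpochs(hyp))
      stop("alignment error: delta.tsv has ", nrow(ddf),
           " rows for ", nEpochs(hyp), " epochs")
    delta <- as.numeric(ddf$delta)
  }

  spectra <- NULL
  sf <- file.path(dir, "spectra.tsv")
  if (file.exists(sf)) {
    sdf <- utils::read.delim(sf, sep = "\t", stringsAsFactors = FALSE,
                             check.names = FALSE)
    fr <- as.numeric(sub("^f", "", setdiff(colnames(sdf), "epoch")))
    pm <- as.matrix(sdf[, setdiff(colnames(sdf), "epoch"), drop = FALSE])
    dimnames(pm) <- NULL
    if (nrow(pm) != nEpochs(hyp))
      stop("alignment error: spectra.tsv has ", nrow(pm),
           " rows for ", nEpochs(hyp), " epochs")
    spectra <- EpochSpectra(fr, pm)
  }

  list(hypnogram = hyp, traces = traces, delta = delta, spectra = spectra)
}
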