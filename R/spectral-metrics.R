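#' @include AllClasses.R core-records.R
NULL

#' Standard EEG frequency bands
#'
#' Band edges in Hz: delta 0.75-4.0; theta 6.5-12.0 for theta-dominated
#' waking and 5.5-12.0 for REM sleep; slow gamma 32-45; fast gamma 55-80;
#' and the 0.75-45 Hz total used as the normalization reference. Band
#' membership is by bin-center inclusion on closed intervals, so the 4.0 Hz
#' bin belongs to delta exactly once.
#'
#' @return named list of length-2 numeric vectors.
#' @export
bandSpec <- function() {
  list(
    delta = c(0.75, 4.0),
    thetaTdw = c(6.5, 12.0),
    thetaRem = c(5.5, 12.0),
    slowGamma = c(32, 45),
    fastGamma = c(55, 80),
    referenceTotal = c(0.75, 45)
  )
}

.band_cols <- function(spectra, band) {
  if (band[1] > band[2]) stop("band must be ordered low < high")
  sel <- which(freqs(spectra) >= band[1] - 1e-9 &
                 freqs(spectra) <= band[2] + 1e-9)
  if (!length(sel)) stop("band [", band[1], ", ", band[2],
                         "] contains no frequency bins")
  sel
}

#' Mean band power per epoch
#'
#' Mean of the power-density bins whose centers fall in the closed band.
#'
#' @param spectra an [EpochSpectra-class].
#' @param band numeric length-2, Hz.
#' @return numeric vector, one value per epoch.
#' @export
bandPower <- function(spectra, band) {
  sel <- .band_cols(spectra, band)
  rowMeans(powerMatrix(spectra)[, sel, drop = FALSE])
}

## integrated power over a band (density x bin width summed)
.band_total <- function(spectra, band) {
  sel <- .band_cols(spectra, band)
  df <- diff(freqs(spectra)[1:2])
  rowSums(powerMatrix(spectra)[, sel, drop = FALSE]) * df
}

#' Per-epoch power spectra from a raw EEG signal
#'
#' Splits the signal into consecutive non-overlapping epochs, applies a
#' Hamming window and a discrete Fourier transform, and returns one-sided
#' power densities on the uniform frequency grid up to `maxFreq` (0.25 Hz
#' resolution for 4-s epochs).
#'
#' @param signal numeric samples.
#' @param fs sampling frequency in Hz.
#' @param epochS epoch length in seconds; `fs * epochS` must be an integer.
#' @param maxFreq highest frequency bin kept, Hz.
#' @return an [EpochSpectra-class].
#' @export
epochSpectra <- function(signal, fs, epochS = 4, maxFreq = 100) {
  nper <- fs * epochS
  if (abs(nper - round(nper)) > 1e-9)
    stop("fs * epochS must be an integer number of samples")
  nper <- as.integer(round(nper))
  nEp <- length(signal) %/% nper
  if (nEp < 1) stop("signal shorter than one epoch")
  x <- matrix(signal[seq_len(nEp * nper)], nrow = nper)
  w <- signal::hamming(nper)
  X <- stats::mvfft(x * w)
  nf <- nper %/% 2 + 1L
  P <- (Mod(X[seq_len(nf), , drop = FALSE])^2) / (fs * sum(w^2))
  P[2:(nf - 1L), ] <- 2 * P[2:(nf - 1L), ]
  fr <- (seq_len(nf) - 1L) / epochS
  keep <- fr <= maxFreq + 1e-9
  EpochSpectra(fr[keep], t(P[keep, , drop = FALSE]))
}

#' State-weighted spectral reference value
#'
#' The individual normalization reference: mean over the three vigilance
#' states of the state-mean total EEG power (0.75-45 Hz) across all
#' artefact-free epochs of the baseline window. Equal state weighting makes
#' the reference insensitive to how much time an animal spends in each
#' state.
#'
#' @param spectra an [EpochSpectra-class] aligned to `hyp`.
#' @param hyp a [Hypnogram-class].
#' @param baselineH baseline window in hours since recording start.
#' @param totalBand band of the total-power integral, Hz.
#' @return the scalar reference (absolute power units).
#' @export
spectralReference <- function(spectra, hyp, baselineH = c(0, 48),
                              totalBand = bandSpec()$referenceTotal) {
  if (nEpochs(spectra) != nEpochs(hyp))
    stop("spectra and hypnogram differ in epoch count")
  idx <- ztWindowEpochs(hyp, baselineH[1], baselineH[2])
  tot <- .band_total(spectra, totalBand)
  st <- states(hyp)
  ok <- !artefacts(hyp)
  means <- vapply(stateLevels, function(s) {
    sel <- intersect(idx, which(st == s & ok))
    if (!length(sel))
      stop("state ", s, " absent from the baseline window; ",
           "cannot form the weighted reference")
    mean(tot[sel])
  }, numeric(1))
  mean(means)
}

#' Express spectra in % of a reference value
#'
#' @param spectra an [EpochSpectra-class].
#' @param reference scalar from [spectralReference()].
#' @return a normalized [EpochSpectra-class].
#' @export
normalizeSpectra <- function(spectra, reference) {
  if (reference <= 0) stop("reference must be positive")
  EpochSpectra(freqs(spectra), powerMatrix(spectra) / reference * 100,
               normalized = TRUE)
}

.day_blocks <- function(proto, nbinsLight, nbinsDark, nbinsSdRecovery) {
  lOn <- proto@lightsOnZt
  lOff <- proto@lightsOffZt
  blocks <- list()
  for (d in seq_len(proto@nDays)) {
    off <- (d - 1) * 24
    if (d == proto@sdDay) {
      blocks[[length(blocks) + 1L]] <- list(
        day = d, phase = "light", startH = off + proto@sdWindowZt[2],
        endH = off + lOff, nbins = nbinsSdRecovery)
    } else {
      blocks[[length(blocks) + 1L]] <- list(
        day = d, phase = "light", startH = off + lOn, endH = off + lOff,
        nbins = nbinsLight)
    }
    blocks[[length(blocks) + 1L]] <- list(
      day = d, phase = "dark", startH = off + lOff, endH = off + 24,
      nbins = nbinsDark)
  }
  blocks
}

#' NREM delta-power percentile time course
#'
#' Within each lights-phase block the artefact-free NREM epochs carrying a
#' delta value are split into bins holding an equal number of epochs (within
#' one), so bin timing follows the prevalence of NREM sleep. Baseline and
#' late-recovery light periods get 12 bins, the post-deprivation remainder
#' of the SD-day light period 8, and every dark period 6. Bin values are
#' mean delta in % of the reference: the mean delta over NREM epochs in
#' ZT8-12 of the baseline days, the daily low of sleep pressure.
#'
#' @param hyp a [Hypnogram-class].
#' @param delta per-epoch delta power (numeric, `NA` where undefined) or an
#'   [EpochSpectra-class] from which delta band power is taken.
#' @param nbinsLight,nbinsDark,nbinsSdRecovery bins per block type.
#' @param referenceZt ZT window of the reference periods.
#' @return a `"DeltaTimecourse"`: data frame with columns `day`, `phase`,
#'   `bin`, `time_h`, `value` (% of reference), `n_epochs`, `start_h`,
#'   `end_h`; attributes `reference` (absolute units), `epochs` (member
#'   epoch indices per bin) and `protocol`.
#' @export
deltaTimecourse <- function(hyp, delta, nbinsLight = 12, nbinsDark = 6,
                            nbinsSdRecovery = 8, referenceZt = c(8, 12)) {
  if (is(delta, "EpochSpectra")) {
    if (nEpochs(delta) != nEpochs(hyp))
      stop("spectra and hypnogram differ in epoch count")
    delta <- bandPower(delta, bandSpec()$delta)
  }
  if (length(delta) != nEpochs(hyp))
    stop("delta must have one value per epoch")
  proto <- protocol(hyp)
  usable <- states(hyp) == "NREM" & !artefacts(hyp) & !is.na(delta)
  tH <- epochTimesH(hyp)

  refIdx <- integer()
  for (d in seq_len(proto@sdDay - 1)) {
    w <- (d - 1) * 24 + referenceZt
    refIdx <- c(refIdx, intersect(ztWindowEpochs(hyp, w[1], w[2]),
                                  which(usable)))
  }
  if (!length(refIdx)) stop("no usable NREM delta in the reference windows")
  reference <- mean(delta[refIdx])

  blocks <- .day_blocks(proto, nbinsLight, nbinsDark, nbinsSdRecovery)
  rows <- list()
  epochsPerBin <- list()
  for (bl in blocks) {
    idx <- intersect(ztWindowEpochs(hyp, bl$startH, bl$endH), which(usable))
    nb <- bl$nbins
    if (length(idx) < nb)
      stop(sprintf("block day %d %s has %d usable NREM epochs for %d bins",
                   bl$day, bl$phase, length(idx), nb))
    bounds <- floor(seq_len(nb) * length(idx) / nb)
    lo <- c(0L, bounds[-nb]) + 1L
    for (k in seq_len(nb)) {
      mem <- idx[lo[k]:bounds[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        day = bl$day, phase = bl$phase, bin = k,
        time_h = mean(tH[mem]),
        value = mean(delta[mem]) / reference * 100,
        n_epochs = length(mem),
        start_h = bl$startH, end_h = bl$endH
      )
      epochsPerBin[[length(epochsPerBin) + 1L]] <- mem
    }
  }
  tc <- do.call(rbind, rows)
  attr(tc, "reference") <- reference
  attr(tc, "epochs") <- epochsPerBin
  attr(tc, "protocol") <- proto
  class(tc) <- c("DeltaTimecourse", "data.frame")
  tc
}

#' Theta-peak frequency of a theta state
#'
#' Frequency of the per-epoch spectral maximum within the state's theta
#' band (6.5-12 Hz for theta-dominated waking, 5.5-12 Hz for REM sleep),
#' averaged over all artefact-free epochs of the state.
#'
#' @param spectra an [EpochSpectra-class] aligned to `hyp`.
#' @param hyp a [Hypnogram-class].
#' @param state `"TDW"` or `"REM"`.
#' @param band override the default band, Hz.
#' @param windowH optional recording-time window in hours.
#' @return list with `perEpoch` (Hz, named by epoch index) and `mean`.
#' @export
thetaPeakFrequency <- function(spectra, hyp, state = c("TDW", "REM"),
                               band = NULL, windowH = NULL) {
  state <- match.arg(state)
  if (is.null(band))
    band <- if (state == "TDW") bandSpec()$thetaTdw else bandSpec()$thetaRem
  if (nEpochs(spectra) != nEpochs(hyp))
    stop("spectra and hypnogram differ in epoch count")
  sel <- if (state == "TDW") tdwFlags(hyp) else states(hyp) == "REM"
  sel <- sel & !artefacts(hyp)
  idx <- which(sel)
  if (!is.null(windowH))
    idx <- intersect(idx, ztWindowEpochs(hyp, windowH[1], windowH[2]))
  if (!length(idx)) stop("no qualifying artefact-free ", state, " epochs")
  cols <- .band_cols(spectra, band)
  sub <- powerMatrix(spectra)[idx, cols, drop = FALSE]
  pk <- freqs(spectra)[cols][max.col(sub, ties.method = "first")]
  list(perEpoch = stats::setNames(pk, idx), mean = mean(pk))
}

## Otsu threshold on a numeric sample: minimizes within-class variance.
.otsu <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  cum <- cumsum(xs)
  cum2 <- cumsum(xs^2)
  k <- seq_len(n - 1)
  vl <- cum2[k] - cum[k]^2 / k
  vr <- (cum2[n] - cum2[k]) - (cum[n] - cum[k])^2 / (n - k)
  i <- which.min(vl + vr)
  (xs[i] + xs[i + 1]) / 2
}

## Valley of a bimodal sample: kernel density minimum between the two
## dominant modes, with an Otsu fallback when the density is not bimodal.
.bimodal_valley <- function(x) {
  d <- stats::density(x, n = 512)
  y <- d$y
  locmax <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(locmax) >= 2) {
    top <- locmax[order(y[locmax], decreasing = TRUE)[1:2]]
    top <- sort(top)
    valley <- top[1] + which.min(y[top[1]:top[2]]) - 1L
    d$x[valley]
  } else {
    .otsu(x)
  }
}

#' Classify theta-dominated waking epochs
#'
#' A wake epoch is theta-dominated when the share of its 6.5-12 Hz power in
#' the total 0.75-45 Hz power exceeds the threshold. When no threshold is
#' given, it is derived from the wake-epoch ratio distribution itself as
#' the valley between its two modes (quiet vs theta-dominated waking).
#'
#' @param spectra an [EpochSpectra-class] aligned to `hyp`.
#' @param hyp a [Hypnogram-class].
#' @param threshold theta-ratio threshold in (0, 1), or `NULL` to derive it.
#' @param thetaBand,totalBand bands in Hz.
#' @return logical per epoch (`FALSE` outside artefact-free wake), with
#'   attributes `threshold` and `ratio` (per-epoch theta ratio, `NA`
#'   off-wake).
#' @export
classifyTdw <- function(spectra, hyp, threshold = NULL,
                        thetaBand = bandSpec()$thetaTdw,
                        totalBand = bandSpec()$referenceTotal) {
  if (nEpochs(spectra) != nEpochs(hyp))
    stop("spectra and hypnogram differ in epoch count")
  wake <- which(states(hyp) == "WAKE" & !artefacts(hyp))
  if (!length(wake)) stop("no artefact-free wake epochs")
  ratio <- rep(NA_real_, nEpochs(hyp))
  ratio[wake] <- .band_total(spectra, thetaBand)[wake] /
    .band_total(spectra, totalBand)[wake]
  if (is.null(threshold)) threshold <- .bimodal_valley(ratio[wake])
  out <- !is.na(ratio) & ratio > threshold
  attr(out, "threshold") <- threshold
  attr(out, "ratio") <- ratio
  out
}
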