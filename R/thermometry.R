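#' @include AllClasses.R core-records.R recovery-stats.R
NULL

#' Calibrate an NTC thermistor from its two calibration resistances
#'
#' Derives the material constant `beta = T25*T37 / (T25 - T37) * ln(R37/R25)`
#' (kelvin) from the manufacturer resistances at 25 and 37 deg C. `beta`
#' depends only on the resistance ratio, so any common scaling of the two
#' resistances leaves it unchanged.
#'
#' @param r25,r37 resistances in ohm at 25 and 37 deg C; `r37 < r25`.
#' @param iConst constant measuring current in ampere (default 100 uA).
#' @return a [ThermistorCalibration-class].
#' @export
calibrateThermistor <- function(r25, r37, iConst = 1e-4) {
  if (r25 <= 0 || r37 <= 0) stop("resistances must be positive")
  if (r37 >= r25)
    stop("degenerate calibration: need r37 < r25 for an NTC thermistor")
  t25 <- 298.15
  t37 <- 310.15
  beta <- (t25 * t37) / (t25 - t37) * log(r37 / r25)
  new("ThermistorCalibration", r25 = r25, r37 = r37, iConst = iConst,
      beta = beta, t25 = t25, t37 = t37)
}

#' @rdname calibrateThermistor
#' @param cal a [ThermistorCalibration-class].
#' @export
thermistorBeta <- function(cal) cal@beta

#' Convert thermistor resistance to temperature
#'
#' Inverts the beta equation: `t = 1 / (ln(Rt/R25)/beta + 1/T25) - 273.15`
#' (deg C, natural logarithm). Exact at both calibration points: `Rt = R25`
#' gives 25 deg C and `Rt = R37` gives 37 deg C to machine precision.
#'
#' @param rt resistance(s) in ohm.
#' @param cal a [ThermistorCalibration-class].
#' @return temperature(s) in deg C.
#' @export
temperatureFromResistance <- function(rt, cal) {
  if (any(rt <= 0)) stop("resistance must be positive")
  1 / (log(rt / cal@r25) / cal@beta + 1 / cal@t25) - 273.15
}

#' Convert measured voltage to temperature
#'
#' With a constant measuring current, `Rt = V / I`. When `sampleHz` is
#' given, the voltage stream is blocked into epochs of `epochS` seconds and
#' the per-epoch median voltage (hence median resistance) is converted,
#' reproducing the standard 10-Hz acquisition with one temperature per 4-s
#' epoch.
#'
#' @param v voltage(s) in volt, all positive.
#' @param cal a [ThermistorCalibration-class].
#' @param sampleHz sampling rate of `v`; `NULL` converts sample-wise.
#' @param epochS epoch length in seconds for the median blocks.
#' @return temperature(s) in deg C (per sample, or per epoch).
#' @export
temperatureFromVoltage <- function(v, cal, sampleHz = NULL, epochS = 4) {
  if (any(v <= 0)) stop("voltage must be positive")
  if (!is.null(sampleHz)) {
    nper <- sampleHz * epochS
    if (abs(nper - round(nper)) > 1e-9)
      stop("sampleHz * epochS must be an integer")
    nper <- as.integer(round(nper))
    nEp <- length(v) %/% nper
    v <- apply(matrix(v[seq_len(nEp * nper)], nrow = nper), 2, stats::median)
  }
  temperatureFromResistance(v / cal@iConst, cal)
}

.hourly_means <- function(values, dtS) {
  per <- as.integer(round(3600 / dtS))
  nh <- length(values) %/% per
  colMeans(matrix(values[seq_len(nh * per)], nrow = per))
}

#' Cortical-temperature quality control and offset correction
#'
#' For each animal, computes the daily temperature amplitude (mean over the
#' baseline days of the highest minus lowest hourly mean) and the mean
#' temperature over the sleep-deprivation window (a state-controlled level
#' estimate, since all animals are awake throughout). Animals whose
#' SD-window mean is a median-absolute-deviation outlier are offset-corrected
#' by adding the difference to the cohort mean of the remaining animals;
#' amplitude outliers are flagged for exclusion but never silently removed.
#'
#' @param traces named list of [SampledTrace-class], one per animal, all
#'   aligned to `hyp`'s clock.
#' @param hyp a [Hypnogram-class] supplying the protocol (baseline days and
#'   SD window).
#' @param correct `"auto"` (correct detected offset outliers), `"none"`, or
#'   a character vector of animal names to correct.
#' @param madThreshold threshold of the MAD outlier test.
#' @return list with `report` (data frame: animal, amplitude, sdMean,
#'   amplitudeOutlier, offsetOutlier, correction) and `traces` (corrected).
#' @export
temperatureQc <- function(traces, hyp, correct = "auto", madThreshold = 3) {
  if (length(traces) < 2) stop("need at least two animals")
  proto <- protocol(hyp)
  nBase <- proto@sdDay - 1
  sdH <- sdWindowHours(proto)
  amp <- sdMean <- numeric(length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    hm <- .hourly_means(traceValues(tr), samplingInterval(tr))
    if (length(hm) < nBase * 24)
      stop("trace ", i, " lacks hourly coverage of the baseline days")
    amp[i] <- mean(vapply(seq_len(nBase), function(d) {
      h <- hm[((d - 1) * 24 + 1):(d * 24)]
      max(h) - min(h)
    }, numeric(1)))
    per <- as.integer(round(3600 / samplingInterval(tr)))
    sel <- (sdH[1] * per + 1):(sdH[2] * per)
    if (max(sel) > length(traceValues(tr)))
      stop("trace ", i, " does not cover the SD window")
    sdMean[i] <- mean(traceValues(tr)[sel])
  }
  nm <- names(traces)
  if (is.null(nm)) nm <- paste0("animal", seq_along(traces))
  ampOut <- madOutliers(amp, madThreshold)
  offOut <- madOutliers(sdMean, madThreshold)
  toCorrect <- if (identical(correct, "auto")) nm[offOut]
  else if (identical(correct, "none")) character()
  else correct
  correction <- numeric(length(traces))
  cohort <- !(nm %in% toCorrect)
  if (length(toCorrect)) {
    if (!any(cohort)) stop("no reference animals left for offset correction")
    target <- mean(sdMean[cohort])
    for (i in which(nm %in% toCorrect)) {
      correction[i] <- target - sdMean[i]
      traces[[i]]@values <- traces[[i]]@values + correction[i]
    }
  }
  list(
    report = data.frame(animal = nm, amplitude = amp, sdMean = sdMean,
                        amplitudeOutlier = ampOut, offsetOutlier = offOut,
                        correction = correction),
    traces = traces
  )
}

#' Transition-aligned cortical-temperature profiles
#'
#' Locates transitions between consolidated bouts (both flanking states at
#' least `minBoutEpochs` epochs long) of the four kinds wake->NREM,
#' NREM->REM, REM->wake and NREM->wake, and averages temperature relative
#' to the transition anchor (mean of the last pre- and first post-transition
#' epoch). Each transition contributes only within its own flanking bouts,
#' and profile points supported by fewer than `minTraces` transitions are
#' truncated, so sparse transition kinds yield naturally shorter profiles.
#'
#' @param hyp a [Hypnogram-class].
#' @param temperature a [SampledTrace-class] at epoch resolution.
#' @param minBoutEpochs minimum flanking bout length in epochs.
#' @param windowS half-window around the transition in seconds.
#' @param minTraces minimum transitions per reported time point.
#' @param windowH recording-time window searched for transitions; default
#'   the baseline days (before the SD day).
#' @return list with `profiles` (named list of data frames: `time_s`,
#'   `mean_dT`, `n`) and `census` (transition counts per kind; kinds with
#'   no qualifying transitions are omitted with a message).
#' @export
transitionProfiles <- function(hyp, temperature, minBoutEpochs = 8,
                               windowS = 90, minTraces = 10,
                               windowH = NULL) {
  eps <- epochSeconds(hyp)
  if (abs(samplingInterval(temperature) - eps) > 1e-9)
    stop("temperature must be sampled at epoch resolution")
  tv <- traceValues(temperature)
  if (length(tv) != nEpochs(hyp))
    stop("temperature length does not match the hypnogram")
  if (is.null(windowH))
    windowH <- c(0, (protocol(hyp)@sdDay - 1) * 24)
  st <- states(hyp)
  runs <- rle(st)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  K <- as.integer(floor(windowS / eps))
  tH <- epochTimesH(hyp)

  kinds <- list("W->N" = c("WAKE", "NREM"), "N->R" = c("NREM", "REM"),
                "R->W" = c("REM", "WAKE"), "N->W" = c("NREM", "WAKE"))
  profiles <- list()
  census <- integer(0)
  for (nmk in names(kinds)) {
    pre <- kinds[[nmk]][1]
    post <- kinds[[nmk]][2]
    i <- which(runs$values[-length(runs$values)] == pre &
                 runs$values[-1] == post &
                 runs$lengths[-length(runs$lengths)] >= minBoutEpochs &
                 runs$lengths[-1] >= minBoutEpochs)
    if (length(i)) {
      t0 <- starts[i + 1L]  # first epoch of the post-state bout
      inWin <- tH[t0] >= windowH[1] & tH[t0] < windowH[2]
      i <- i[inWin]
      t0 <- t0[inWin]
    }
    if (!length(i)) {
      message("no qualifying ", nmk, " transitions; kind omitted")
      next
    }
    census[nmk] <- length(i)
    preLen <- pmin(runs$lengths[i], K)
    postLen <- pmin(runs$lengths[i + 1L], K)
    offsets <- c(-(K:1), 1:K)
    acc <- cnt <- numeric(length(offsets))
    for (j in seq_along(i)) {
      anchor <- (tv[t0[j] - 1L] + tv[t0[j]]) / 2
      offs <- c(-(preLen[j]:1), 1:postLen[j])
      epo <- t0[j] + ifelse(offs < 0, offs, offs - 1L)
      pos <- match(offs, offsets)
      acc[pos] <- acc[pos] + (tv[epo] - anchor)
      cnt[pos] <- cnt[pos] + 1
    }
    keep <- cnt >= minTraces
    profiles[[nmk]] <- data.frame(
      time_s = (offsets[keep] + ifelse(offsets[keep] < 0, 0.5, -0.5)) * eps,
      mean_dT = acc[keep] / cnt[keep],
      n = as.integer(cnt[keep])
    )
  }
  list(profiles = profiles, census = census)
}

#' Waking, locomotion and cortical temperature: correlation structure
#'
#' Quantifies how hourly time awake and hourly locomotor activity (LMA)
#' each relate to hourly cortical temperature: ordinary least-squares R2
#' for each predictor alone, and the partial correlation of temperature
#' with each predictor controlling for the other (closed-form from the
#' pairwise correlations; equivalent to correlating the two sets of
#' regression residuals). Fisher Z transforms (`atanh`) are supplied for
#' cross-animal comparison, and the residuals of the wake-only regression
#' are returned for circadian residual analysis.
#'
#' @param wake hourly minutes awake.
#' @param lma hourly locomotor activity (typically `log2(counts + 1)`).
#' @param temp hourly cortical temperature, deg C.
#' @return list with `r2Wake`, `r2Lma`, `pcorWakeGivenLma`,
#'   `pcorLmaGivenWake`, their Fisher Z values, and `residualsWake`.
#' @export
wakeTemperatureAssociation <- function(wake, lma, temp) {
  ok <- stats::complete.cases(wake, lma, temp)
  wake <- wake[ok]; lma <- lma[ok]; temp <- temp[ok]
  if (length(temp) < 3) stop("need at least three complete hourly triplets")
  if (stats::sd(wake) == 0 || stats::sd(lma) == 0)
    stop("zero-variance predictor")
  rtw <- stats::cor(temp, wake)
  rtl <- stats::cor(temp, lma)
  rwl <- stats::cor(wake, lma)
  if (1 - rwl^2 < 1e-12)
    stop("waking and LMA are collinear; partial correlations undefined")
  ## when one predictor already explains the response exactly, nothing is
  ## left for the other: its partial correlation is reported as 0
  pW <- if (1 - rtl^2 < 1e-12) 0 else
    (rtw - rtl * rwl) / sqrt((1 - rtl^2) * (1 - rwl^2))
  pL <- if (1 - rtw^2 < 1e-12) 0 else
    (rtl - rtw * rwl) / sqrt((1 - rtw^2) * (1 - rwl^2))
  pW <- max(-1, min(1, pW))
  pL <- max(-1, min(1, pL))
  fitW <- stats::lm(temp ~ wake)
  list(
    r2Wake = rtw^2,
    r2Lma = rtl^2,
    pcorWakeGivenLma = pW,
    pcorLmaGivenWake = pL,
    fisherZWake = atanh(pW),
    fisherZLma = atanh(pL),
    residualsWake = stats::residuals(fitW)
  )
}

#' Fixed-period sine fit to hourly residuals
#'
#' Least-squares fit of `b + A sin(2 pi t / period + phi)` with the period
#' fixed (24 h by default), linear in `(b, A cos phi, A sin phi)`. The
#' amplitude is reported non-negative with the phase normalized to
#' `[0, period)` hours.
#'
#' @param residuals numeric series (deg C for temperature residuals).
#' @param timesH sample times in hours (default 0, 1, 2, ...).
#' @param periodH fixed period in hours.
#' @return list with `amplitude`, `phaseH`, `baseline`.
#' @export
residualSineFit <- function(residuals, timesH = seq_along(residuals) - 1,
                            periodH = 24) {
  ok <- stats::complete.cases(residuals, timesH)
  residuals <- residuals[ok]; timesH <- timesH[ok]
  if (length(residuals) < 3) stop("need at least three points")
  if (diff(range(timesH)) < periodH - 1e-9)
    stop("need at least one full period of data")
  w <- 2 * pi / periodH
  X <- cbind(1, sin(w * timesH), cos(w * timesH))
  cf <- stats::lm.fit(X, residuals)$coefficients
  A <- sqrt(cf[2]^2 + cf[3]^2)
  phi <- atan2(cf[3], cf[2]) %% (2 * pi)
  list(amplitude = unname(A), phaseH = unname(phi / w),
       baseline = unname(cf[1]))
}

## Nakagawa variance decomposition for a random-intercept lmer fit
.r2_mixed <- function(m) {
  varF <- stats::var(as.vector(lme4::getME(m, "X") %*% lme4::fixef(m)))
  vc <- lme4::VarCorr(m)
  varR <- sum(vapply(vc, function(v) sum(diag(v)), numeric(1)))
  varE <- attr(vc, "sc")^2
  tot <- varF + varR + varE
  c(marginal = varF / tot, conditional = (varF + varR) / tot)
}

#' Nested mixed-model comparison of temperature predictors
#'
#' Fits three nested linear mixed models of hourly cortical temperature
#' with a per-animal random intercept (maximum likelihood): Model 1 uses
#' waking alone, Model 2 adds LMA per unit waking, Model 3 adds their
#' interaction. Successive models are compared by likelihood-ratio
#' chi-squared tests, and marginal / conditional R2 (fixed effects only vs
#' fixed plus random) are reported. Singular fits are flagged, not dropped.
#'
#' @param data data frame with columns `animal`, `temp`, `wake`,
#'   `lmaPerWake` (one row per animal-hour).
#' @return list with `table` (model, marginalR2, conditionalR2, chisq, df,
#'   p, singular) and `models` (the three fits).
#' @export
mixedModelCompare <- function(data) {
  need <- c("animal", "temp", "wake", "lmaPerWake")
  if (!all(need %in% colnames(data)))
    stop("data must have columns ", paste(need, collapse = ", "))
  if (length(unique(data$animal)) < 2) stop("need at least two animals")
  m1 <- lme4::lmer(temp ~ wake + (1 | animal), data = data, REML = FALSE)
  m2 <- lme4::lmer(temp ~ wake + lmaPerWake + (1 | animal), data = data,
                   REML = FALSE)
  m3 <- lme4::lmer(temp ~ wake * lmaPerWake + (1 | animal), data = data,
                   REML = FALSE)
  lrt <- stats::anova(m1, m2, m3)
  r2 <- t(vapply(list(m1, m2, m3), .r2_mixed, numeric(2)))
  tab <- data.frame(
    model = c("Model1", "Model2", "Model3"),
    marginalR2 = r2[, "marginal"],
    conditionalR2 = r2[, "conditional"],
    chisq = lrt$Chisq,
    df = lrt$Df,
    p = lrt$`Pr(>Chisq)`,
    singular = vapply(list(m1, m2, m3), lme4::isSingular, logical(1))
  )
  list(table = tab, models = list(m1, m2, m3))
}
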