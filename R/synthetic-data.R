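#' @include AllClasses.R core-records.R process-s.R spectral-metrics.R
NULL

#' Configuration of the synthetic study generator
#'
#' Bundles every parameter of the synthetic 96-h LD12:12 study: semi-Markov
#' bout structure with phase-dependent dwell times calibrated to published
#' baseline state budgets (per 12 h: NREM 389/189 min, REM 70/19 min, wake
#' 260/512 min in light/dark), a forced-wake block on the SD day, the true
#' Process S generating NREM delta power, state-dependent spectral
#' templates, state-driven temperature relaxation with locomotion coupling,
#' and a qPCR plate with known fold changes. The same configuration and
#' seed always produce the identical bundle.
#'
#' @param seed integer seed governing all generator randomness.
#' @param protocol a [ProtocolMeta-class].
#' @param trueProcessS the [ProcessSParams-class] generating delta power.
#' @param deltaNoiseCv coefficient of variation of the multiplicative
#'   lognormal delta-power noise.
#' @param boutParams per-phase dwell means (epochs) and branching
#'   probabilities of the semi-Markov state process.
#' @param sdIntrusionHazard per-epoch hazard of a brief NREM intrusion
#'   during the forced-wake window (gentle handling is not perfect).
#' @param rebound post-SD sleep-rebound scaling: `sleepFactor` multiplies
#'   NREM dwell (and divides wake dwell), `remFactor` multiplies the
#'   NREM-to-REM branching probability, decaying linearly over `hours`.
#' @param artefactRates per-state fraction of epochs flagged as artefact.
#' @param tdwParams theta-dominated-waking fractions of wake per phase and
#'   the within-bout persistence of the TDW sub-state.
#' @param tempParams per-state temperature asymptotes (deg C), relaxation
#'   time constants (s), locomotion coupling (deg C per count/min) and
#'   epoch noise SD.
#' @param lmaParams per-phase mean counts per waking minute.
#' @param spectralParams template peak positions (Hz) and lognormal jitter.
#' @param qpcrParams reference genes, target fold changes per group, the
#'   ext/comm pair's true delta-Ct, efficiencies and Ct noise.
#' @return an object of class `"SyntheticStudyConfig"`.
#' @export
syntheticStudyConfig <- function(
    seed = 1L,
    protocol = ProtocolMeta(),
    trueProcessS = ProcessSParams(tauI = 13.0, tauD = 3.0, ua = 290, la = 45),
    deltaNoiseCv = 0.1,
    boutParams = list(
      light = list(meanW = 25.0, meanN = 33.6, meanR = 16.5,
                   pNR = 0.33, pRW = 0.6),
      dark = list(meanW = 100.0, meanN = 34.3, meanR = 23.3,
                  pNR = 0.155, pRW = 0.6),
      shortFracWake = 0.85, shortFracNrem = 0.35, meanShort = 2.0,
      remShape = 3
    ),
    sdIntrusionHazard = 0.002,
    rebound = list(sleepFactor = 1.35, remFactor = 1.8, hours = 18),
    artefactRates = c(WAKE = 0.07, NREM = 0.021, REM = 0.025),
    tdwParams = list(fracLight = 0.173, fracDark = 0.35, persistence = 0.93),
    tempParams = list(
      asymptote = c(WAKE = 36.3, NREM = 35.4, REM = 36.2),
      tauS = c(WAKE = 180, NREM = 200, REM = 75),
      lmaGain = 0.15, noiseSd = 0.02, t0 = 35.8
    ),
    lmaParams = list(ratePerWakeMin = c(light = 0.46, dark = 1.6)),
    spectralParams = list(
      thetaPeakRem = 7.5, thetaPeakTdw = 8.1, deltaPeak = 2.0,
      epochJitterSd = 0.25, binJitterSd = 0.3
    ),
    qpcrParams = list(
      referenceGenes = c("Eef1a2", "Gapdh"),
      targets = list(
        Per2 = c(ZT0 = 1, ZT6_NSD = 1.4, ZT6_SD = 2.2),
        Nr1d1 = c(ZT0 = 1, ZT6_NSD = 1.8, ZT6_SD = 0.9),
        Dbp = c(ZT0 = 1, ZT6_NSD = 2.5, ZT6_SD = 0.9)
      ),
      extComDeltaCt = -1,
      efficiency = 2.0,
      ctNoiseSd = 0.15,
      nPerGroup = 5
    )) {
  cfg <- list(
    seed = as.integer(seed), protocol = protocol,
    trueProcessS = trueProcessS, deltaNoiseCv = deltaNoiseCv,
    boutParams = boutParams, sdIntrusionHazard = sdIntrusionHazard,
    rebound = rebound, artefactRates = artefactRates,
    tdwParams = tdwParams, tempParams = tempParams, lmaParams = lmaParams,
    spectralParams = spectralParams, qpcrParams = qpcrParams
  )
  stopifnot(all(unlist(lapply(boutParams[c("light", "dark")], function(p)
    c(p$meanW, p$meanN, p$meanR))) > 0))
  class(cfg) <- "SyntheticStudyConfig"
  cfg
}

## dwell draw: 1 + geometric, mean `m` epochs
.dwell <- function(m) 1L + stats::rgeom(1L, min(1, 1 / m))

## wake/NREM dwells are a short/long mixture: mouse sleep is fragmented, with
## many brief (<32 s) bouts interleaved with consolidated ones. The mixture
## keeps the requested mean `m` so state budgets are unchanged, while only a
## minority of bouts reach the 8-epoch consolidation criterion, as observed.
.dwell_mix <- function(m, shortFrac, meanShort) {
  if (m <= meanShort || shortFrac <= 0) return(.dwell(m))
  if (stats::runif(1) < shortFrac) {
    .dwell(meanShort)
  } else {
    .dwell((m - shortFrac * meanShort) / (1 - shortFrac))
  }
}

#' Generate a synthetic hypnogram
#'
#' Semi-Markov alternation of wake and NREM sleep with NREM -> REM ->
#' (wake | NREM) branching. Dwell-time means depend on the lights phase at
#' bout onset (light-phase sleep dominance, dark-phase wake dominance); the
#' SD window is forced to wakefulness apart from rare brief NREM
#' intrusions, and the hours after SD carry a multiplicative increase in
#' sleep-bout propensity that decays linearly (a phenomenological rebound,
#' deliberately not fed back from Process S). Wake epochs receive
#' theta-dominated-waking flags from a persistent two-state sub-process
#' with phase-dependent prevalence, and per-state artefact flags are drawn
#' independently.
#'
#' @param cfg a `"SyntheticStudyConfig"`.
#' @param seed overrides `cfg$seed`.
#' @return a [Hypnogram-class].
#' @export
generateHypnogram <- function(cfg, seed = cfg$seed) {
  proto <- cfg$protocol
  set.seed(seed)
  eps <- 4
  eph <- as.integer(3600 / eps)
  n <- as.integer(proto@nDays * 24 * eph)
  sdH <- sdWindowHours(proto)
  sdIdx <- c(sdH[1] * eph + 1, sdH[2] * eph)
  reb <- cfg$rebound

  st <- character(n)
  pos <- 1L
  cur <- "WAKE"
  while (pos <= n) {
    ztH <- ((pos - 1) / eph) %% 24
    absH <- (pos - 1) / eph
    p <- if (ztH < proto@lightsOffZt) cfg$boutParams$light
         else cfg$boutParams$dark
    hrsPost <- absH - sdH[2]
    boost <- if (hrsPost >= 0 && hrsPost < reb$hours)
      1 + (reb$sleepFactor - 1) * (1 - hrsPost / reb$hours) else 1
    remBoost <- if (hrsPost >= 0 && hrsPost < reb$hours)
      1 + (reb$remFactor - 1) * (1 - hrsPost / reb$hours) else 1
    len <- switch(cur,
      WAKE = .dwell_mix(p$meanW / boost, cfg$boutParams$shortFracWake,
                        cfg$boutParams$meanShort),
      NREM = .dwell_mix(p$meanN * boost, cfg$boutParams$shortFracNrem,
                        cfg$boutParams$meanShort),
      ## REM bouts cluster around a typical ~1-min length: long enough to
      ## qualify as consolidated (>= 8 epochs) yet usually split across
      ## clock minutes, reproducing the slight per-minute REM deficit
      REM = 1L + stats::rnbinom(1L, size = cfg$boutParams$remShape,
                                mu = p$meanR - 1))
    end <- min(pos + len - 1L, n)
    st[pos:end] <- cur
    pos <- end + 1L
    cur <- switch(cur,
      WAKE = "NREM",
      NREM = if (stats::runif(1) < min(1, p$pNR * remBoost)) "REM" else "WAKE",
      REM = if (stats::runif(1) < p$pRW) "WAKE" else "NREM")
  }

  ## forced-wake window with rare brief NREM intrusions
  st[sdIdx[1]:sdIdx[2]] <- "WAKE"
  i <- sdIdx[1]
  while (i <= sdIdx[2]) {
    if (stats::runif(1) < cfg$sdIntrusionHazard) {
      l <- sample.int(3L, 1L)
      st[i:min(i + l - 1L, sdIdx[2])] <- "NREM"
      i <- i + l
    }
    i <- i + 1L
  }

  ## TDW sub-state within wake: persistent two-state chain with
  ## phase-dependent stationary prevalence
  tdw <- logical(n)
  p11 <- cfg$tdwParams$persistence
  wakeIdx <- which(st == "WAKE")
  u <- stats::runif(length(wakeIdx))
  prev <- FALSE
  lastIdx <- -10L
  for (j in seq_along(wakeIdx)) {
    i <- wakeIdx[j]
    frac <- if (((i - 1) / eph) %% 24 < proto@lightsOffZt)
      cfg$tdwParams$fracLight else cfg$tdwParams$fracDark
    p01 <- frac * (1 - p11) / (1 - frac)
    if (i != lastIdx + 1L) prev <- stats::runif(1) < frac
    else prev <- u[j] < (if (prev) p11 else p01)
    tdw[i] <- prev
    lastIdx <- i
  }

  rate <- unname(cfg$artefactRates[st])
  art <- stats::runif(n) < rate
  Hypnogram(st, artefact = art, tdw = tdw & !art, epochS = eps,
            protocol = proto)
}

#' Generate per-epoch NREM delta power from a known Process S
#'
#' Simulates the configured true Process S over the hypnogram and emits
#' `delta = S * noise` on artefact-free NREM epochs, with multiplicative
#' lognormal noise of mean 1 and the configured coefficient of variation.
#' With `includeRem = TRUE`, artefact-free REM epochs additionally receive
#' low delta values drawn from a lognormal calibrated so the NREM/REM
#' distribution intersection falls near the true lower asymptote (REM
#' sleep has weak but nonzero delta activity), enabling end-to-end
#' asymptote estimation.
#'
#' @param hyp a [Hypnogram-class].
#' @param cfg a `"SyntheticStudyConfig"`.
#' @param seed overrides `cfg$seed + 1`.
#' @param includeRem also emit REM-epoch delta values.
#' @return list with `delta` (per-epoch, `NA` where not emitted) and
#'   `sTrue` (the generating S trace).
#' @export
generateDeltaPower <- function(hyp, cfg, seed = cfg$seed + 1L,
                               includeRem = FALSE) {
  sTrue <- simulateProcessS(hyp, cfg$trueProcessS)
  set.seed(seed)
  n <- nEpochs(hyp)
  delta <- rep(NA_real_, n)
  nrem <- which(states(hyp) == "NREM" & !artefacts(hyp))
  cv <- cfg$deltaNoiseCv
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    delta[nrem] <- sTrue[nrem] *
      stats::rlnorm(length(nrem), -sdlog^2 / 2, sdlog)
  } else {
    delta[nrem] <- sTrue[nrem]
  }
  if (includeRem) {
    rem <- which(states(hyp) == "REM" & !artefacts(hyp))
    delta[rem] <- stats::rlnorm(length(rem),
                                log(0.62 * cfg$trueProcessS@la), 0.35)
  }
  list(delta = delta, sTrue = sTrue)
}

.spectral_template <- function(fr, cfg) {
  sp <- cfg$spectralParams
  base <- 40 / (fr + 1) + 0.5
  list(
    NREM = base + 150 * stats::dnorm(fr, sp$deltaPeak, 1.2),
    REM = base + 70 * stats::dnorm(fr, sp$thetaPeakRem, 0.5),
    TDW = base + 60 * stats::dnorm(fr, sp$thetaPeakTdw, 0.6),
    QW = base + 6 * stats::dnorm(fr, sp$thetaPeakRem, 1.0)
  )
}

#' Generate per-epoch spectra from state templates
#'
#' Each epoch's spectrum is its state's template (1/f background plus a
#' state-typical peak: delta for NREM sleep, theta at 7.5 Hz for REM sleep
#' and quiet-wake remnant, theta at 8.1 Hz for theta-dominated waking)
#' multiplied by a per-epoch and a per-bin lognormal jitter. Generating a
#' full 4-day study at 0.25-Hz resolution is memory-hungry, so a subset of
#' epochs can be requested.
#'
#' @param hyp a [Hypnogram-class].
#' @param cfg a `"SyntheticStudyConfig"`.
#' @param seed overrides `cfg$seed + 2`.
#' @param epochIdx epoch indices to generate (default: all).
#' @return an [EpochSpectra-class] with attribute `epochIndex`.
#' @export
generateSpectra <- function(hyp, cfg, seed = cfg$seed + 2L, epochIdx = NULL) {
  set.seed(seed)
  if (is.null(epochIdx)) epochIdx <- seq_len(nEpochs(hyp))
  fr <- seq(0, 100, by = 0.25)
  tpl <- .spectral_template(fr, cfg)
  st <- states(hyp)[epochIdx]
  cls <- ifelse(st == "NREM", "NREM",
                ifelse(st == "REM", "REM",
                       ifelse(tdwFlags(hyp)[epochIdx], "TDW", "QW")))
  sp <- cfg$spectralParams
  m <- matrix(0, nrow = length(epochIdx), ncol = length(fr))
  for (cl in unique(cls)) {
    rows <- which(cls == cl)
    jEpoch <- exp(stats::rnorm(length(rows), 0, sp$epochJitterSd))
    jBin <- matrix(exp(stats::rnorm(length(rows) * length(fr), 0,
                                    sp$binJitterSd)),
                   nrow = length(rows))
    m[rows, ] <- (jEpoch %o% tpl[[cl]]) * jBin
  }
  out <- EpochSpectra(fr, m)
  attr(out, "epochIndex") <- epochIdx
  out
}

#' Generate cortical temperature and locomotor activity
#'
#' Locomotor activity is drawn per minute as Poisson counts proportional to
#' the waking time in that minute, with phase-dependent rates (dark-phase
#' activity dominance); sleep-only minutes are exactly zero. Temperature
#' follows a first-order relaxation toward the current state's asymptote --
#' raised in proportion to the minute's locomotor count -- with
#' state-specific time constants; the REM asymptote sits above NREM's so
#' REM entries produce the characteristic fast temperature rise.
#'
#' @param hyp a [Hypnogram-class].
#' @param cfg a `"SyntheticStudyConfig"`.
#' @param seed overrides `cfg$seed + 3`.
#' @param noiseSd overrides the configured epoch temperature noise SD.
#' @return list with `temperature` (epoch-resolution
#'   [SampledTrace-class], deg C) and `lma` (per-minute counts).
#' @export
generateTemperatureLma <- function(hyp, cfg, seed = cfg$seed + 3L,
                                   noiseSd = cfg$tempParams$noiseSd) {
  set.seed(seed)
  proto <- protocol(hyp)
  eps <- epochSeconds(hyp)
  eph <- as.integer(round(3600 / eps))
  epm <- as.integer(round(60 / eps))
  st <- states(hyp)
  n <- length(st)
  nmin <- n %/% epm

  minuteOf <- rep(seq_len(nmin), each = epm)[seq_len(nmin * epm)]
  wakeMin <- tabulate(minuteOf[st[seq_len(nmin * epm)] == "WAKE"],
                      nbins = nmin) * eps / 60
  ztMin <- (((seq_len(nmin) - 1) / 60) %% 24)
  rate <- ifelse(ztMin < proto@lightsOffZt,
                 cfg$lmaParams$ratePerWakeMin["light"],
                 cfg$lmaParams$ratePerWakeMin["dark"])
  lmaCounts <- stats::rpois(nmin, rate * wakeMin)
  lmaCounts[wakeMin == 0] <- 0L

  tp <- cfg$tempParams
  A <- tp$asymptote[st]
  decay <- exp(-eps / tp$tauS[st])
  lmaOfEpoch <- lmaCounts[minuteOf]
  Aeff <- A + tp$lmaGain * lmaOfEpoch
  noise <- if (noiseSd > 0) stats::rnorm(n, 0, noiseSd) else numeric(n)
  temp <- numeric(n)
  Tcur <- tp$t0
  for (i in seq_len(n)) {
    Tcur <- Aeff[i] + (Tcur - Aeff[i]) * decay[i] + noise[i]
    temp[i] <- Tcur
  }
  list(
    temperature = SampledTrace(temp, dtS = eps, unit = "degC"),
    lma = SampledTrace(as.numeric(lmaCounts), dtS = 60, unit = "counts")
  )
}

#' Generate a qPCR Ct/efficiency table with known truth
#'
#' Builds a long-format plate of reference and target genes across the
#' three sacrifice groups (ZT0, ZT6 non-sleep-deprived, ZT6 sleep-deprived)
#' with Ct values derived from the configured true fold changes plus
#' Gaussian Ct noise, and an extended/common primer pair with a known
#' cycle offset.
#'
#' @param cfg a `"SyntheticStudyConfig"`.
#' @param seed overrides `cfg$seed + 4`.
#' @param ctNoiseSd overrides the configured Ct noise SD.
#' @return data frame with columns `gene`, `sample`, `group`, `Ct`, `E`,
#'   `is_reference`; attribute `truth` lists the generating fold changes
#'   and the true ext/comm ratio.
#' @export
generateQpcrTable <- function(cfg, seed = cfg$seed + 4L,
                              ctNoiseSd = cfg$qpcrParams$ctNoiseSd) {
  qp <- cfg$qpcrParams
  if (length(qp$referenceGenes) < 2)
    stop("need at least two reference genes")
  set.seed(seed)
  groups <- c("ZT0", "ZT6_NSD", "ZT6_SD")
  E <- qp$efficiency
  samples <- paste0(rep(groups, each = qp$nPerGroup), "_",
                    seq_len(qp$nPerGroup))
  groupOf <- rep(groups, each = qp$nPerGroup)

  rows <- list()
  addGene <- function(gene, baseCt, foldByGroup, isRef) {
    q <- foldByGroup[groupOf]
    ct <- baseCt - log(q) / log(E) + stats::rnorm(length(samples), 0,
                                                  ctNoiseSd)
    rows[[length(rows) + 1L]] <<- data.frame(
      gene = gene, sample = samples, group = groupOf, Ct = ct, E = E,
      is_reference = isRef)
  }
  for (g in qp$referenceGenes)
    addGene(g, 20, stats::setNames(rep(1, 3), groups), TRUE)
  for (g in names(qp$targets))
    addGene(g, 24, qp$targets[[g]], FALSE)
  ## ext/comm alternative-polyadenylation pair with a fixed cycle offset
  addGene("Sfpq_Comm", 25, stats::setNames(rep(1, 3), groups), FALSE)
  addGene("Sfpq_Ext", 25 - qp$extComDeltaCt,
          stats::setNames(rep(1, 3), groups), FALSE)

  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(
    foldChanges = qp$targets,
    extComRatio = E^qp$extComDeltaCt
  )
  out
}

#' Generate a complete synthetic study bundle
#'
#' Runs every generator with seeds derived from the configuration seed and
#' returns the full record set plus the generating ground truth.
#'
#' @param cfg a `"SyntheticStudyConfig"`.
#' @param includeSpectra also generate per-epoch spectra (memory-hungry for
#'   full 4-day studies); may be an epoch-index vector.
#' @param includeRemDelta emit REM-epoch delta values too.
#' @return list with `hypnogram`, `delta`, `sTrue`, `traces` (temperature,
#'   lma), `qpcr`, optional `spectra`, and `groundTruth`.
#' @export
generateStudy <- function(cfg = syntheticStudyConfig(),
                          includeSpectra = FALSE, includeRemDelta = FALSE) {
  hyp <- generateHypnogram(cfg)
  dp <- generateDeltaPower(hyp, cfg, includeRem = includeRemDelta)
  tl <- generateTemperatureLma(hyp, cfg)
  qp <- generateQpcrTable(cfg)
  out <- list(
    hypnogram = hyp, delta = dp$delta, sTrue = dp$sTrue,
    traces = list(temperature = tl$temperature, lma = tl$lma),
    qpcr = qp,
    groundTruth = list(processS = cfg$trueProcessS,
                       deltaNoiseCv = cfg$deltaNoiseCv,
                       qpcr = attr(qp, "truth"))
  )
  if (!identical(includeSpectra, FALSE)) {
    idx <- if (isTRUE(includeSpectra)) NULL else includeSpectra
    out$spectra <- generateSpectra(hyp, cfg, epochIdx = idx)
  }
  out
}
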