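test_that("4-s epochs at 200 Hz give the standard 401-bin 0.25-Hz grid", {
  sp <- epochSpectra(stats::rnorm(800), fs = 200, epochS = 4)
  expect_identical(length(freqs(sp)), 401L)
  expect_equal(freqs(sp)[2] - freqs(sp)[1], 0.25)
  expect_equal(range(freqs(sp)), c(0, 100))
  expect_error(epochSpectra(stats::rnorm(100), fs = 33.3, epochS = 4),
               "integer")
})

test_that("a pure sinusoid peaks in its own frequency bin", {
  x <- sin(2 * pi * 8 * seq(1 / 200, 120, by = 1 / 200))
  sp <- epochSpectra(x, fs = 200, epochS = 4)
  m <- colMeans(powerMatrix(sp))
  expect_equal(freqs(sp)[which.max(m)], 8)
})

test_that("white noise yields a flat mean spectrum", {
  set.seed(2)
  sp <- epochSpectra(stats::rnorm(800 * 1500), fs = 200, epochS = 4)
  m <- colMeans(powerMatrix(sp))
  inner <- m[2:400]  # one-sided scaling differs at DC and Nyquist
  expect_lt(stats::sd(inner) / mean(inner), 0.05)
})

test_that("the spectral reference weights the three states equally", {
  # one flat-spectrum state at total power 1, 2 and 3, with very unequal
  # prevalence: equal weighting must still give 2
  fr <- seq(0, 100, 0.25)
  nsel <- sum(fr >= 0.75 & fr <= 45)
  df <- 0.25
  mk <- function(total) total / (nsel * df)
  pw <- rbind(
    matrix(mk(1), nrow = 600, ncol = length(fr)),
    matrix(mk(2), nrow = 250, ncol = length(fr)),
    matrix(mk(3), nrow = 50, ncol = length(fr))
  )
  hyp <- Hypnogram(rep(c("WAKE", "NREM", "REM"), c(600, 250, 50)),
                   epochS = 4, protocol = ProtocolMeta(nDays = 1, sdDay = 1))
  sp <- EpochSpectra(fr, pw)
  ref <- spectralReference(sp, hyp, baselineH = c(0, 1))
  expect_equal(ref, 2, tolerance = 1e-12)

  norm <- normalizeSpectra(sp, ref)
  expect_true(isNormalized(norm))
  # weighted grand mean of the state totals is 100% after normalization
  tot <- rowSums(powerMatrix(norm)[, fr >= 0.75 & fr <= 45]) * df
  stateMeans <- tapply(tot, states(hyp), mean)
  expect_equal(mean(stateMeans), 100, tolerance = 1e-12)

  hyp2 <- Hypnogram(rep(c("WAKE", "NREM"), c(450, 450)), epochS = 4,
                    protocol = ProtocolMeta(nDays = 1, sdDay = 1))
  expect_error(spectralReference(sp, hyp2, baselineH = c(0, 1)), "REM")
})

test_that("band power averages exactly the covered bins", {
  fr <- seq(0, 100, 0.25)
  pw <- matrix(rep(7, length(fr)), nrow = 1)
  sp <- EpochSpectra(fr, pw)
  expect_equal(bandPower(sp, c(0.75, 4)), 7)
  one <- pw
  one[1, fr == 10] <- 99
  sp1 <- EpochSpectra(fr, one)
  expect_equal(bandPower(sp1, c(10, 10)), 99)
  # mean equals the sum/count oracle on a random spectrum
  set.seed(1)
  pw2 <- matrix(stats::runif(length(fr)), nrow = 1)
  sp2 <- EpochSpectra(fr, pw2)
  sel <- fr >= 0.75 & fr <= 4
  expect_equal(bandPower(sp2, c(0.75, 4)), sum(pw2[1, sel]) / sum(sel))
  expect_error(bandPower(sp2, c(101, 102)), "no frequency bins")
})

test_that("delta time-course blocks carry the prescribed bin counts", {
  st <- cachedStudy(1)
  tc <- deltaTimecourse(st$hypnogram, st$delta)
  counts <- with(tc, tapply(bin, paste(day, phase), length))
  expect_identical(as.integer(counts[c("1 light", "2 light", "4 light")]),
                   c(12L, 12L, 12L))
  expect_identical(as.integer(counts["3 light"]), 8L)  # post-SD remainder
  expect_identical(as.integer(counts[paste(1:4, "dark")]), rep(6L, 4))
  # equal NREM-epoch counts within one, and conservation per block
  for (key in unique(paste(tc$day, tc$phase))) {
    n <- tc$n_epochs[paste(tc$day, tc$phase) == key]
    expect_lte(diff(range(n)), 1)
  }
  usable <- states(st$hypnogram) == "NREM" & !artefacts(st$hypnogram) &
    !is.na(st$delta)
  block3d <- ztWindowEpochs(st$hypnogram, 54, 60)  # day 3 ZT6-12
  expect_identical(sum(tc$n_epochs[tc$day == 3 & tc$phase == "light"]),
                   sum(usable[block3d]))
  # bin values are positive and the reference window sits near 100%
  expect_true(all(tc$value > 0))
  ref <- tc$value[tc$day %in% 1:2 & tc$phase == "light" & tc$bin >= 9]
  expect_lt(abs(mean(ref) - 100), 10)
})

test_that("bin boundaries ignore everything but NREM epochs", {
  # moving wake/REM epochs around must not change which NREM epochs
  # belong to which bin
  set.seed(99)
  st <- cachedStudy(1)
  hyp <- st$hypnogram
  tc1 <- deltaTimecourse(hyp, st$delta)
  stLab <- states(hyp)
  nonNrem <- stLab != "NREM"
  stLab[nonNrem] <- sample(c("WAKE", "REM"), sum(nonNrem), replace = TRUE)
  hyp2 <- Hypnogram(stLab, artefact = artefacts(hyp),
                    protocol = protocol(hyp))
  tc2 <- deltaTimecourse(hyp2, st$delta)
  expect_identical(attr(tc1, "epochs"), attr(tc2, "epochs"))
})

test_that("theta-peak frequency averages per-epoch spectral maxima", {
  fr <- seq(0, 100, 0.25)
  mk <- function(peak) 1 + 10 * stats::dnorm(fr, peak, 0.4)
  pw <- rbind(mk(7), mk(9), mk(7), mk(9))
  hyp <- Hypnogram(rep("REM", 900), epochS = 4,
                   protocol = ProtocolMeta(nDays = 1, sdDay = 1))
  sp <- EpochSpectra(fr, pw[rep(1:4, 225), ])
  tpf <- thetaPeakFrequency(sp, hyp, "REM")
  expect_equal(tpf$mean, 8)
  expect_true(all(tpf$perEpoch %in% c(7, 9)))

  # generator truth: jittered 7.5-Hz REM template recovered within 0.25 Hz
  st <- cachedStudy(5)
  idx <- 1:21600
  spg <- generateSpectra(st$hypnogram, syntheticStudyConfig(seed = 5),
                         epochIdx = idx)
  sub <- Hypnogram(states(st$hypnogram)[idx],
                   artefact = artefacts(st$hypnogram)[idx],
                   tdw = tdwFlags(st$hypnogram)[idx],
                   protocol = ProtocolMeta(nDays = 1, sdDay = 1))
  expect_lt(abs(thetaPeakFrequency(spg, sub, "REM")$mean - 7.5), 0.25)
  expect_lt(abs(thetaPeakFrequency(spg, sub, "TDW")$mean - 8.1), 0.25)
})

test_that("TDW classification is thresholded, monotone and recovers truth", {
  st <- cachedStudy(5)
  idx <- 1:21600
  sub <- Hypnogram(states(st$hypnogram)[idx],
                   artefact = artefacts(st$hypnogram)[idx],
                   tdw = tdwFlags(st$hypnogram)[idx],
                   protocol = ProtocolMeta(nDays = 1, sdDay = 1))
  sp <- generateSpectra(st$hypnogram, syntheticStudyConfig(seed = 5),
                        epochIdx = idx)
  td <- classifyTdw(sp, sub)
  wake <- which(states(sub) == "WAKE" & !artefacts(sub))
  agree <- mean(td[wake] == tdwFlags(sub)[wake])
  expect_gte(agree, 0.95)

  # raising the threshold can only shrink the TDW set
  thr <- attr(td, "threshold")
  tdHigh <- classifyTdw(sp, sub, threshold = thr + 0.1)
  expect_lte(sum(tdHigh), sum(td))
  # zero theta ratio yields no TDW at all
  fr <- freqs(sp)
  flat <- powerMatrix(sp)
  flat[, fr >= 5 & fr <= 13] <- 0
  tdNone <- classifyTdw(EpochSpectra(fr, flat), sub, threshold = 0.2)
  expect_identical(sum(tdNone), 0L)
})
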