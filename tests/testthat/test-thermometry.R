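test_that("the material constant follows from the calibration pair", {
  expect_error(calibrateThermistor(1000, 1000), "degenerate")
  expect_error(calibrateThermistor(657.2, 1000), "degenerate")
  cal <- calibrateThermistor(1000, 657.2)
  # frozen from direct evaluation: (298.15*310.15)/(298.15-310.15)*ln(0.6572)
  expect_equal(thermistorBeta(cal), 3234.696, tolerance = 1e-6)
  expect_gt(thermistorBeta(cal), 0)
  # beta depends only on the resistance ratio
  cal2 <- calibrateThermistor(1000 * 3.7, 657.2 * 3.7)
  expect_equal(thermistorBeta(cal2), thermistorBeta(cal))
})

test_that("conversion inverts the calibration at both fixed points", {
  for (pair in list(c(1000, 657.2), c(5300, 2950), c(12, 7))) {
    cal <- calibrateThermistor(pair[1], pair[2])
    expect_lt(abs(temperatureFromResistance(pair[1], cal) - 25), 1e-9)
    expect_lt(abs(temperatureFromResistance(pair[2], cal) - 37), 1e-9)
    # monotone between the calibration points
    mid <- temperatureFromResistance(sqrt(pair[1] * pair[2]), cal)
    expect_gt(mid, 25)
    expect_lt(mid, 37)
  }
})

test_that("voltage conversion is NTC-monotone and medians per epoch", {
  cal <- calibrateThermistor(1000, 657.2)
  v <- seq(0.05, 0.12, by = 0.005)
  t <- temperatureFromVoltage(v, cal)
  expect_true(all(diff(t) < 0))  # higher resistance, lower temperature
  expect_error(temperatureFromVoltage(-1, cal), "positive")

  # 10 Hz stream with an outlier sample: the median shrugs it off
  vEpoch <- rep(1000 * cal@iConst, 40)
  vEpoch[7] <- 5
  tEp <- temperatureFromVoltage(vEpoch, cal, sampleHz = 10, epochS = 4)
  expect_length(tEp, 1)
  expect_lt(abs(tEp - 25), 1e-9)
})

test_that("temperature QC measures amplitude and recovers known offsets", {
  st <- cachedStudy(2)
  base <- traceValues(st$traces$temperature)
  flat <- SampledTrace(rep(36, length(base)), dtS = 4, unit = "degC")
  offsets <- c(0, 0, -1.3, 0.0)
  traces <- lapply(offsets, function(o)
    SampledTrace(base + o, dtS = 4, unit = "degC"))
  names(traces) <- paste0("m", 1:4)
  qc <- temperatureQc(traces, st$hypnogram)
  expect_true(qc$report$offsetOutlier[3])
  expect_false(any(qc$report$offsetOutlier[-3]))
  expect_equal(qc$report$correction[3], 1.3, tolerance = 1e-9)
  expect_equal(traceValues(qc$traces$m3), traceValues(qc$traces$m1),
               tolerance = 1e-12)
  # identical shapes, identical amplitudes; a constant trace has none
  expect_lt(diff(range(qc$report$amplitude)), 1e-12)
  qc2 <- temperatureQc(list(a = flat, b = traces$m1, c = traces$m2),
                       st$hypnogram, correct = "none")
  expect_equal(qc2$report$amplitude[1], 0)
})

test_that("transition profiles step through the anchor and obey the bout rule", {
  proto <- ProtocolMeta(nDays = 1, sdDay = 1, sdWindowZt = c(0, 1))
  # alternating 8-epoch bouts: +1 in wake, -1 in NREM
  st <- rep(rep(c("WAKE", "NREM"), each = 8), length.out = 21600)
  hyp <- Hypnogram(st, protocol = proto)
  temp <- SampledTrace(ifelse(st == "WAKE", 1, -1), dtS = 4, unit = "degC")
  pr <- transitionProfiles(hyp, temp, windowH = c(0, 24))
  p <- pr$profiles[["W->N"]]
  expect_true(all(p$mean_dT[p$time_s < 0] == 1))
  expect_true(all(p$mean_dT[p$time_s > 0] == -1))
  # 8-epoch bouts truncate the profile at +/- 8 epochs
  expect_equal(range(p$time_s), c(-30, 30))

  # 7-epoch bouts never qualify
  st7 <- rep(rep(c("WAKE", "NREM"), each = 7), length.out = 12600)
  hyp7 <- Hypnogram(st7, epochS = 4, protocol = ProtocolMeta(
    nDays = 1, sdDay = 1, sdWindowZt = c(0, 1)))
  temp7 <- SampledTrace(rep(0, 12600), dtS = 4)
  expect_message(
    pr7 <- transitionProfiles(hyp7, temp7, windowH = c(0, 14)),
    "no qualifying")
  expect_length(pr7$profiles, 0)
})

test_that("profile points disappear exactly where support drops below 10", {
  st <- cachedStudy(1)
  pr <- transitionProfiles(st$hypnogram, st$traces$temperature)
  for (p in pr$profiles) {
    expect_true(all(p$n >= 10))
  }
  # rerunning without the support rule exposes the truncated points
  prAll <- transitionProfiles(st$hypnogram, st$traces$temperature,
                              minTraces = 1)
  for (k in names(pr$profiles)) {
    full <- prAll$profiles[[k]]
    kept <- full$n >= 10
    expect_identical(pr$profiles[[k]]$time_s, full$time_s[kept])
  }
})

test_that("baseline transition census matches the published order", {
  cen <- vapply(1:2, function(s) {
    st <- cachedStudy(s)
    transitionProfiles(st$hypnogram, st$traces$temperature)$census[["W->N"]]
  }, numeric(1))
  # 38 wake-to-NREM transitions per animal over two baseline days,
  # generator calibrated to within +/-50%
  expect_true(all(cen >= 19 & cen <= 57))
})

test_that("partial correlations attribute variance to the true driver", {
  set.seed(21)
  wake <- stats::runif(96, 0, 60)
  lma <- stats::rnorm(96)
  tempExact <- 35 + 0.02 * wake
  a <- wakeTemperatureAssociation(wake, lma, tempExact)
  expect_equal(a$pcorWakeGivenLma, 1, tolerance = 1e-9)
  expect_lt(abs(a$pcorLmaGivenWake), 0.2)
  expect_equal(a$r2Wake, 1, tolerance = 1e-12)
  expect_error(wakeTemperatureAssociation(wake, wake, tempExact),
               "collinear")
  # translation invariance in the response
  a2 <- wakeTemperatureAssociation(wake, lma, tempExact + 5)
  expect_equal(a2$pcorWakeGivenLma, a$pcorWakeGivenLma)
  expect_equal(a2$r2Lma, a$r2Lma)
})

test_that("partial correlation equals the residual-regression oracle", {
  for (s in 1:10) {
    set.seed(s)
    w <- stats::rnorm(96)
    l <- 0.4 * w + stats::rnorm(96)
    tp <- 0.3 * w + 0.2 * l + stats::rnorm(96)
    a <- wakeTemperatureAssociation(w, l, tp)
    oW <- stats::cor(stats::residuals(stats::lm(tp ~ l)),
                     stats::residuals(stats::lm(w ~ l)))
    oL <- stats::cor(stats::residuals(stats::lm(tp ~ w)),
                     stats::residuals(stats::lm(l ~ w)))
    expect_lt(abs(a$pcorWakeGivenLma - oW), 1e-12)
    expect_lt(abs(a$pcorLmaGivenWake - oL), 1e-12)
  }
})

test_that("the fixed-period sine fit inverts constructed rhythms", {
  t <- 0:47
  expect_equal(residualSineFit(rep(0, 48), t)$amplitude, 0)
  r <- -0.05 + 0.29 * sin(2 * pi * t / 24 + 2.1)
  f <- residualSineFit(r, t)
  expect_lt(abs(f$amplitude - 0.29), 1e-9)
  expect_lt(abs(f$phaseH - 2.1 / (2 * pi) * 24), 1e-9)
  expect_lt(abs(f$baseline + 0.05), 1e-9)
  # with noise, the amplitude is still recovered closely
  amps <- vapply(1:20, function(s) {
    set.seed(s)
    residualSineFit(r + stats::rnorm(48, 0, 0.1), t)$amplitude
  }, numeric(1))
  expect_lt(mean(abs(amps - 0.29)), 0.05)
  expect_lt(max(abs(amps - 0.29)), 0.1)
  expect_error(residualSineFit(r[1:10], t[1:10]), "full period")
})

test_that("mixed-model table is well-formed with conditional >= marginal", {
  set.seed(3)
  d <- do.call(rbind, lapply(1:4, function(a) {
    wake <- stats::runif(48, 0, 60)
    lpw <- stats::runif(48, 0, 3)
    data.frame(animal = factor(a),
               temp = 35 + 0.1 * a / 4 + 0.02 * wake +
                 stats::rnorm(48, 0, 0.1),
               wake = wake, lmaPerWake = lpw)
  }))
  mm <- mixedModelCompare(d)
  expect_identical(mm$table$model, c("Model1", "Model2", "Model3"))
  expect_true(all(mm$table$conditionalR2 >= mm$table$marginalR2 - 1e-12))
  expect_true(all(mm$table$marginalR2 >= 0 & mm$table$conditionalR2 <= 1))
  expect_true(is.na(mm$table$chisq[1]))
  expect_error(mixedModelCompare(d[d$animal == 1, ]), "two animals")
})
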