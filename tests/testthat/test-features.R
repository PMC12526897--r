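test_that("voltage and pressure conversions are exact inverses", {
  cal <- hydrophone_cal()
  expect_equal(voltage_to_pressure(1, cal), 10^(164.6 / 20))
  expect_equal(20 * log10(voltage_to_pressure(1, cal)), 164.6)
  expect_equal(voltage_to_pressure(0, cal), 0)
  p <- c(1e3, 5e5, 2e7)
  expect_equal(voltage_to_pressure(pressure_to_voltage(p, cal), cal), p,
               tolerance = 1e-12)
  ## gain participates
  cal2 <- hydrophone_cal(gain = 20)
  expect_equal(voltage_to_pressure(1, cal2), 10^((164.6 - 20) / 20))
})

test_that("zero-to-peak SPL is the dB of the absolute peak", {
  expect_equal(compute_spl0pk(waveform(c(0, 1, 0), unit = "uPa")), 0)
  expect_equal(compute_spl0pk(waveform(c(0, -10^(154.99 / 20)), unit = "uPa")),
               154.99, tolerance = 1e-9)
  w1 <- waveform(c(0.5, 2), unit = "uPa")
  w2 <- waveform(c(0.5, 4), unit = "uPa")
  expect_equal(compute_spl0pk(w2) - compute_spl0pk(w1), 20 * log10(2),
               tolerance = 1e-12)
  expect_error(compute_spl0pk(waveform(numeric(4), unit = "uPa")), "all-zero")
})

test_that("pulse detection finds impulses and is translation-equivariant", {
  fs <- 48000
  x <- numeric(fs)
  x[c(1000, 2008)] <- 1
  x <- x + rnorm(fs, sd = 1e-4)
  pk <- detect_pulses(waveform(x, fs))
  expect_equal(nrow(pk), 2L)
  expect_equal(diff(pk$peak_index) / fs * 1000, 21, tolerance = 0.05)

  ## translation equivariance
  k <- 480L
  xs <- c(numeric(k), x[seq_len(fs - k)])
  pks <- detect_pulses(waveform(xs, fs))
  expect_equal(pks$peak_index, pk$peak_index + k)
})

test_that("pure noise rarely triggers detections at 6 MAD", {
  fs <- 48000
  n_empty <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    pk <- detect_pulses(waveform(rnorm(fs), fs))
    if (nrow(pk) == 0L) n_empty <- n_empty + 1L
  }
  expect_gte(n_empty, 18L)
})

test_that("clipped pulses are flagged", {
  fs <- 48000
  x <- numeric(fs)
  x[1000] <- 0.995
  x[25000] <- 0.5
  pk <- detect_pulses(waveform(x + rnorm(fs, sd = 1e-4), fs), full_scale = 1)
  expect_equal(nrow(pk), 2L)
  expect_true(pk$clipped[pk$peak_index == 1000])
  expect_false(pk$clipped[pk$peak_index == 25000])
})

test_that("IPIs are grouped into trains at the configured gap", {
  fs <- 48000
  expect_equal(extract_ipi(c(1, 1009, 2017), fs)$ipi_ms, c(21, 21),
               tolerance = 1e-9)
  peaks <- cumsum(c(1, 21, 250, 21) * 48)
  out <- extract_ipi(peaks, fs)
  expect_equal(out$ipi_ms, c(21, 21), tolerance = 1e-9)
  expect_equal(out$train_id, c(1L, 2L))
  expect_equal(nrow(extract_ipi(c(500), fs)), 0L)
  ## spacings 20/21/22 ms: median 21
  pk3 <- cumsum(c(1, 20, 21, 22) * 48)
  expect_equal(median(extract_ipi(pk3, fs)$ipi_ms), 21, tolerance = 1e-9)
})

test_that("ESD localizes tones and conserves energy", {
  fs <- 48000
  n <- 1536
  tt <- seq_len(n) / fs
  tone <- waveform(sin(2 * pi * 500 * tt), fs, "uPa")
  e <- esd(tone)
  expect_lt(abs(e$frequency[which.max(e$esd_linear)] - 500), fs / n + 1e-9)

  for (seed in 1:5) {
    set.seed(seed)
    w <- waveform(rnorm(n), fs, "uPa")
    e <- esd(w)
    lhs <- sum(e$esd_linear) * fs / n
    rhs <- sum(w$samples^2) / fs
    expect_equal(lhs, rhs, tolerance = 1e-6)
  }
  expect_error(esd(waveform(numeric(8), fs)), "all-zero")
})

test_that("ESD percentile summaries are ordered and coincide when identical", {
  calls <- lapply(1:5, function(i) ref_call_unit)
  sm <- esd_percentiles(calls)
  pc <- sm$percentiles
  expect_equal(pc$p1, pc$p99)
  set.seed(1)
  calls2 <- lapply(1:20, function(i)
    waveform(ref_call_unit$samples * runif(1, 0.5, 2) + rnorm(1536, sd = 0.01),
             48000))
  sm2 <- esd_percentiles(calls2)
  pc2 <- sm2$percentiles
  expect_true(all(pc2$p1 <= pc2$p5 + 1e-12))
  expect_true(all(pc2$p5 <= pc2$p50 + 1e-12))
  expect_true(all(pc2$p50 <= pc2$p95 + 1e-12))
  expect_true(all(pc2$p95 <= pc2$p99 + 1e-12))
  ## 50% curve inside the 5/95 envelope
  expect_true(all(pc2$p50 >= pc2$p5 - 1e-12 & pc2$p50 <= pc2$p95 + 1e-12))
  ## density columns sum to one per frequency bin
  dsum <- tapply(sm2$density$density, sm2$density$frequency, sum)
  expect_equal(unname(as.vector(dsum)), rep(1, length(dsum)), tolerance = 1e-9)
  expect_error(esd_percentiles(list(ref_call_unit,
                                    waveform(rnorm(100), 48000))),
               "length")
  expect_s3_class(autoplot(sm2), "ggplot")
})

test_that("the full extraction chain produces per-pulse features", {
  set.seed(11)
  tr <- assemble_train(ref_call, draw_quartile_model(default_ipi_model(), 4),
                       draw_quartile_model(default_spl_model(), 5))
  ft <- extract_features(tr$assembled)
  expect_equal(nrow(ft), 5L)
  expect_equal(sum(is.na(ft$ipi_ms)), 1L)  # first pulse of the train
  expect_equal(ft$spl_0pk_db, tr$spl_per_pulse, tolerance = 0.2)
  expect_true(all(ft$train_id == 1L))
})
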