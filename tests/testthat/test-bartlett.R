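test_that("bartlett power matches, scales and separates as a similarity", {
  s <- ref_call
  expect_equal(bartlett_power(s, s), 1, tolerance = 1e-12)
  ## invariant to positive rescaling of either argument
  scaled <- waveform(0.37 * s$samples, s$fs)
  expect_equal(bartlett_power(s, scaled), 1, tolerance = 1e-12)
  expect_equal(bartlett_power(scaled, s), 1, tolerance = 1e-12)
  ## symmetric in its arguments for a single snapshot
  other <- suppressWarnings(synthesize_call(
    synthesis_spec(list(wavelet_component(0.5, -20, 500)))))
  expect_equal(bartlett_power(s, other), bartlett_power(other, s),
               tolerance = 1e-12)
  expect_gte(bartlett_power(s, other), 0)
  expect_lte(bartlett_power(s, other), 1)

  ## spectrally disjoint tones are orthogonal under the processor
  n <- 4800
  fs <- 48000
  tt <- seq_len(n) / fs
  tone <- function(f) waveform(sin(2 * pi * f * tt), fs)
  b <- bartlett_power(tone(1000), tone(2000))
  expect_lt(b, 1e-3)

  expect_error(bartlett_power(tone(100000 / 48), waveform(numeric(n), fs)),
               "length|zero")
})

test_that("band limiting excludes out-of-band structure", {
  n <- 4800
  fs <- 48000
  tt <- seq_len(n) / fs
  in_band <- sin(2 * pi * 500 * tt)
  hf <- sin(2 * pi * 10000 * tt)   # outside the default 50-5000 Hz band
  a <- waveform(in_band, fs)
  b <- waveform(in_band + 3 * hf, fs)
  expect_equal(bartlett_power(a, b), 1, tolerance = 1e-9)
})

test_that("multi-snapshot references average the cross-spectral matrix", {
  s <- ref_call
  other <- suppressWarnings(synthesize_call(
    synthesis_spec(list(wavelet_component(0.5, -20, 500)))))
  b_each <- c(bartlett_power(s, s), bartlett_power(other, s))
  b_multi <- bartlett_power(list(s, other), s)
  expect_equal(b_multi, mean(b_each), tolerance = 1e-12)
})

test_that("parameter sweeps peak at the optimum and bracket it", {
  cfg <- sensitivity_config(grid_points = 61L)
  cv <- sweep_parameter(ref_spec, 4L, "amplitude", config = cfg)
  opt <- attr(cv, "optimum")
  expect_equal(opt, 0.22)
  expect_equal(cv$similarity[which.min(abs(cv$grid_value - opt))], 1,
               tolerance = 1e-9)
  iv <- attr(cv, "valid_interval")
  expect_lte(iv[1], opt)
  expect_gte(iv[2], opt)
  ## this component's amplitude interval ends strictly inside the [0, 1]
  ## search range (weak-component amplitudes can roam further, so not every
  ## component is amplitude-bounded on both sides)
  expect_true(iv[1] > 0 || iv[2] < 1)
  expect_error(sweep_parameter(ref_spec, 9L, "amplitude"), "out of range")
  expect_s3_class(autoplot(cv), "ggplot")
})

test_that("valid_interval interpolates and nests monotonically", {
  ## synthetic three-point curve: linear interpolation arithmetic
  cv <- tibble::tibble(grid_value = c(-1, 0, 1), similarity = c(0.9, 1, 0.9))
  attr(cv, "optimum") <- 0
  class(cv) <- c("croaker_sensitivity", class(cv))
  iv <- valid_interval(cv, 0.98)
  expect_equal(iv, c(-0.2, 0.2), tolerance = 1e-12)

  ## raising the threshold never widens the interval
  cfg <- sensitivity_config(grid_points = 61L)
  cv2 <- sweep_parameter(ref_spec, 1L, "delay", config = cfg)
  iv95 <- valid_interval(cv2, 0.95)
  iv98 <- valid_interval(cv2, 0.98)
  iv995 <- valid_interval(cv2, 0.995)
  expect_gte(iv98[1], iv95[1])
  expect_lte(iv98[2], iv95[2])
  expect_gte(iv995[1], iv98[1])
  expect_lte(iv995[2], iv98[2])

  ## identically-1 curve spans the whole range
  cv3 <- tibble::tibble(grid_value = 0:10, similarity = rep(1, 11))
  attr(cv3, "optimum") <- 5
  class(cv3) <- c("croaker_sensitivity", class(cv3))
  expect_equal(valid_interval(cv3, 0.98), c(0, 10))

  ## inconsistent curve: optimum below threshold
  cv4 <- tibble::tibble(grid_value = 0:2, similarity = c(0.5, 0.6, 0.5))
  attr(cv4, "optimum") <- 1
  class(cv4) <- c("croaker_sensitivity", class(cv4))
  expect_error(valid_interval(cv4, 0.98), "inconsistent")
})

test_that("delay intervals are narrower than amplitude intervals", {
  cfg <- sensitivity_config(grid_points = 81L)
  sw <- sweep_all_parameters(ref_spec, config = cfg)
  iv <- sw$intervals
  bounds <- search_bounds()
  for (ci in 1:5) {
    wa <- diff(unlist(iv[iv$component == ci & iv$field == "amplitude",
                         c("lo", "hi")])) / diff(bounds$amplitude)
    wd <- diff(unlist(iv[iv$component == ci & iv$field == "delay",
                         c("lo", "hi")])) / diff(bounds$delay)
    expect_lt(wd / wa, 1)
  }
  expect_true(all(iv$similarity_at_optimum >= 1 - 1e-9))
  expect_true(all(iv$lo <= iv$optimum & iv$optimum <= iv$hi))
})
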