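test_that("fk14 filter satisfies the orthonormal quadrature identities", {
  h <- fk14_filter()
  expect_length(h, 14L)
  expect_equal(sum(h), sqrt(2), tolerance = 1e-12)
  expect_equal(sum(h^2), 1, tolerance = 1e-12)
  ## vanishing transfer at Nyquist
  expect_lt(abs(sum(h * (-1)^(seq_along(h) - 1))), 1e-12)
  ## even-shift orthogonality
  for (m in 1:6) {
    expect_lt(abs(sum(h[seq_len(14 - 2 * m)] * h[(2 * m + 1):14])), 1e-10)
  }
})

test_that("mother wavelet has the right grid, normalization and zero mean", {
  for (lev in c(6L, 8L)) {
    mw <- build_mother_wavelet(lev)
    expect_length(mw$samples, 13L * 2L^lev + 1L)
    expect_equal(max(abs(mw$samples)), 1)
    expect_true(all(is.finite(mw$samples)))
    dx <- 13 / (length(mw$samples) - 1L)
    expect_lt(abs(sum(mw$samples) * dx), 1e-3)
  }
  expect_error(build_mother_wavelet(8, family = "db4"), "fk14")
  expect_error(build_mother_wavelet(2), "refinement_level")
})

test_that("cascade refinements agree across levels on the common grid", {
  m6 <- build_mother_wavelet(6L)
  m10 <- build_mother_wavelet(10L)
  sub <- m10$samples[seq(1, length(m10$samples), by = 2L^4)]
  expect_length(sub, length(m6$samples))
  expect_lt(max(abs(sub - m6$samples)), 0.01)
})

test_that("component rendering honours amplitude, alignment and dilation", {
  ## zero amplitude renders silence
  z <- render_component(wavelet_component(0, 10, 300), ref_mother)
  expect_true(all(z$samples == 0))

  ## reference component: extremum 0.59 at window_midpoint + delay
  w <- render_component(wavelet_component(0.59, 67, 397), ref_mother)
  expect_equal(which.max(abs(w$samples)), 768L + 67L)
  expect_equal(max(abs(w$samples)), 0.59, tolerance = 1e-12)

  ## doubling the length halves the energy-spectral peak frequency
  ## (zero-padded FFT oracle for sub-bin resolution)
  peak_freq <- function(sig) {
    w <- render_component(wavelet_component(1, 0, sig), ref_mother)
    n <- 16384L
    sp <- Mod(stats::fft(c(w$samples, numeric(n - 1536L))))[1:(n / 2)]
    (which.max(sp) - 1L) * 48000 / n
  }
  ## lengths chosen well above the mother's resolution floor: below ~150
  ## samples the linear resampling of the (limitedly regular) fk14 shape
  ## biases the spectral peak by a few percent
  f200 <- peak_freq(200)
  f400 <- peak_freq(400)
  expect_lt(abs(f400 - f200 / 2), 2 * 48000 / 16384 + 1e-9)

  expect_error(render_component(wavelet_component(1, 0, 1), ref_mother),
               "length")
})

test_that("synthesis is linear, covariant and deterministic", {
  one <- synthesis_spec(list(wavelet_component(0.4, 20, 300)))
  expect_equal(synthesize_call(one, ref_mother)$samples,
               render_component(one$components[[1]], ref_mother)$samples)

  ## linearity: union of component sets = sum of separate syntheses
  a <- synthesis_spec(list(wavelet_component(0.3, -30, 250),
                           wavelet_component(0.8, 15, 400)))
  b <- synthesis_spec(list(wavelet_component(0.5, 60, 350)))
  ab <- synthesis_spec(c(a$components, b$components))
  expect_identical(synthesize_call(ab, ref_mother)$samples,
                   synthesize_call(a, ref_mother)$samples +
                     synthesize_call(b, ref_mother)$samples)

  ## scale covariance
  a2 <- synthesis_spec(lapply(a$components, function(cc)
    wavelet_component(cc$amplitude * 0.25, cc$delay, cc$length)))
  expect_equal(synthesize_call(a2, ref_mother)$samples,
               0.25 * synthesize_call(a, ref_mother)$samples,
               tolerance = 1e-14)

  ## time covariance: shifting every delay by k shifts the output by k
  k <- 37L
  ash <- synthesis_spec(lapply(a$components, function(cc)
    wavelet_component(cc$amplitude, cc$delay + k, cc$length)))
  s0 <- synthesize_call(a, ref_mother)$samples
  s1 <- synthesize_call(ash, ref_mother)$samples
  expect_equal(s1[(k + 1):1536], s0[1:(1536 - k)], tolerance = 1e-14)

  ## determinism
  expect_identical(synthesize_call(a, ref_mother)$samples,
                   synthesize_call(a, ref_mother)$samples)

  expect_error(synthesis_spec(list()), "at least one")
})

test_that("the reference call concentrates its energy in the croaker band", {
  e <- esd(ref_call_unit)
  fpk <- e$frequency[which.max(e$esd_linear)]
  expect_gte(fpk, 300)
  expect_lte(fpk, 900)
})

test_that("components straddling the window edge are truncated with a warning", {
  expect_warning(render_component(wavelet_component(0.5, 90, 1600), ref_mother),
                 "truncated")
})

test_that("synthesis specs round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  write_spec_json(ref_spec, path)
  back <- read_spec_json(path)
  expect_equal(as_tibble(back), as_tibble(ref_spec))
  expect_equal(back$fs, ref_spec$fs)
  expect_equal(back$window_samples, ref_spec$window_samples)
})
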