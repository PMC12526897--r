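## shared fixtures for the test suite (all generated in code)

ref_spec <- croaker_reference_spec()
ref_mother <- build_mother_wavelet(8L)
ref_call <- suppressWarnings(synthesize_call(ref_spec, ref_mother))
ref_call_unit <- waveform(ref_call$samples / max(abs(ref_call$samples)),
                          ref_call$fs)

## a small PSO configuration for fast structural tests
quick_pso <- function(seed = 1L, ...) {
  pso_config(population = 60L, max_iterations = 15L, seed = seed, ...)
}

## draw a random 5-component spec whose unit-peak normalization keeps the
## true amplitudes inside the search bounds (a well-posed recovery problem)
draw_feasible_target <- function() {
  repeat {
    A <- runif(5)
    tau <- runif(5, -100, 100)
    sig <- runif(5, 10, 1000)
    sp <- synthesis_spec(data.frame(amplitude = A, delay = tau, length = sig))
    tw <- suppressWarnings(synthesize_call(sp))
    pk <- max(abs(tw$samples))
    if (pk > 0 && all(A / pk <= 1)) {
      return(list(target = waveform(tw$samples / pk, 48000), spec = sp))
    }
  }
}

## assemble a croaker-like pulse train from the fitted quartile models,
## scaled so spectrogram levels sit inside the default 60-120 dB window
train_wave <- function(n_pulses, gain_db = -62) {
  tr <- assemble_train(ref_call,
                       draw_quartile_model(default_ipi_model(),
                                           max(n_pulses - 1L, 0L)),
                       draw_quartile_model(default_spl_model(), n_pulses))
  waveform(tr$assembled$samples * 10^(gain_db / 20), tr$assembled$fs, "uPa")
}
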