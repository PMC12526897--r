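#' Fit a two-parameter distribution to printed quartiles
#'
#' Turns published quartile statistics (q1, median, q3) into a sampling
#' model. For the lognormal family `mu = log(median)` and
#' `sigma = log(sqrt(q3 / q1)) / qnorm(0.75)`; for the normal family
#' `mean = median` and `sd = (q3 - q1) / (2 * qnorm(0.75))`. The model's
#' quartiles reproduce the inputs exactly.
#'
#' @param q1,median,q3 Quartiles, `q1 < median < q3`.
#' @param family `"lognormal"` or `"normal"`.
#' @return A `croaker_qmodel`.
#' @export
#' @examples
#' m <- fit_quartile_model(19.75, 20.95, 22.21, "lognormal")
#' quantile(m, c(0.25, 0.5, 0.75))
fit_quartile_model <- function(q1, median, q3,
                               family = c("lognormal", "normal")) {
  family <- match.arg(family)
  if (!(q1 < median && median < q3)) abort("need q1 < median < q3")
  z75 <- qnorm(0.75)
  if (family == "lognormal") {
    if (q1 <= 0) abort("lognormal family needs positive quartiles")
    par <- c(mu = log(median), sigma = log(sqrt(q3 / q1)) / z75)
  } else {
    par <- c(mean = median, sd = (q3 - q1) / (2 * z75))
  }
  structure(list(family = family, q1 = q1, median = median, q3 = q3,
                 par = par),
            class = "croaker_qmodel")
}

#' @export
print.croaker_qmodel <- function(x, ...) {
  cat("<croaker_qmodel>", x$family, paste(names(x$par), "=",
                                          signif(x$par, 5), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
quantile.croaker_qmodel <- function(x, probs = c(0.25, 0.5, 0.75), ...) {
  if (x$family == "lognormal") {
    stats::qlnorm(probs, x$par[["mu"]], x$par[["sigma"]])
  } else {
    stats::qnorm(probs, x$par[["mean"]], x$par[["sd"]])
  }
}

#' Draw random values from a quartile model
#'
#' @param model A `croaker_qmodel`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_quartile_model <- function(model, n) {
  if (model$family == "lognormal") {
    rlnorm(n, model$par[["mu"]], model$par[["sigma"]])
  } else {
    rnorm(n, model$par[["mean"]], model$par[["sd"]])
  }
}

#' Default IPI and SPL variability models for croaker calls
#'
#' The inter-pulse-interval model is lognormal fitted to the published IPI
#' quartiles (19.75 / 20.95 / 22.21 ms); the zero-to-peak SPL model is
#' normal in dB fitted to the published SPL quartiles (154.30 / 154.99 /
#' 156.06 dB re 1 uPa).
#'
#' @return A `croaker_qmodel`.
#' @export
default_ipi_model <- function() fit_quartile_model(19.75, 20.95, 22.21, "lognormal")

#' @rdname default_ipi_model
#' @export
default_spl_model <- function() fit_quartile_model(154.30, 154.99, 156.06, "normal")

#' Scale a waveform to a target zero-to-peak SPL
#'
#' @param w A `croaker_waveform`.
#' @param spl_db Target SPL, dB re 1 uPa.
#' @return A `croaker_waveform` in uPa with `compute_spl0pk()` equal to the
#'   target.
#' @export
scale_to_spl <- function(w, spl_db) {
  w <- as_waveform(w)
  pk <- max(abs(w$samples))
  if (pk == 0) abort("cannot scale an all-zero waveform")
  waveform(w$samples / pk * 10^(spl_db / 20), w$fs, "uPa")
}

#' Assemble a multipulse train from single pulses
#'
#' Scales each pulse to its target zero-to-peak SPL and places the pulses
#' with peak-to-peak spacings equal to the rounded IPIs, overlap-adding
#' where supports intersect. An IPI shorter than the pulse support produces
#' a warning but the train is still assembled.
#'
#' @param pulse A `croaker_waveform`, or a list of them (recycled to the
#'   number of pulses).
#' @param ipis Inter-pulse intervals, ms (length = pulses - 1; empty for a
#'   single-pulse train).
#' @param spl_targets Target per-pulse SPL_0pk values, dB re 1 uPa
#'   (length = `length(ipis) + 1`).
#' @param fs Sampling rate, Hz; defaults to the pulse's.
#' @return A `croaker_train`: list with `pulses`, `ipis`, `spl_per_pulse`,
#'   and `assembled` (a `croaker_waveform` in uPa).
#' @export
#' @examples
#' p <- synthesize_call(croaker_reference_spec())
#' tr <- assemble_train(p, ipis = c(21, 21), spl_targets = c(155, 155, 155))
assemble_train <- function(pulse, ipis, spl_targets, fs = NULL) {
  pulses <- if (inherits(pulse, "croaker_waveform")) list(pulse) else pulse
  n_pulse <- length(ipis) + 1L
  if (length(spl_targets) != n_pulse) {
    abort("length(spl_targets) must equal length(ipis) + 1")
  }
  pulses <- rep_len(pulses, n_pulse)
  pulses <- lapply(pulses, as_waveform)
  if (is.null(fs)) fs <- pulses[[1]]$fs
  scaled <- purrr::map2(pulses, spl_targets, scale_to_spl)
  peak_at <- vapply(scaled, function(w) which.max(abs(w$samples)), integer(1))
  lens <- vapply(scaled, function(w) length(w$samples), integer(1))
  spacing <- round(ipis * fs / 1000)
  if (length(spacing) && any(spacing < lens[-length(lens)] / 2)) {
    warn("some IPIs are shorter than the pulse support; pulses overlap")
  }
  peak_pos <- cumsum(c(max(peak_at[1], 1L), spacing))  # absolute peak samples
  total <- max(peak_pos + lens - peak_at) # leave the window tail after the last peak
  out <- numeric(total)
  for (i in seq_len(n_pulse)) {
    start <- peak_pos[i] - peak_at[i] + 1L
    idx <- seq.int(start, start + lens[i] - 1L)
    out[idx] <- out[idx] + scaled[[i]]$samples
  }
  structure(list(pulses = scaled, ipis = as.numeric(ipis),
                 spl_per_pulse = as.numeric(spl_targets),
                 assembled = waveform(out, fs, "uPa")),
            class = "croaker_train")
}

#' @export
print.croaker_train <- function(x, ...) {
  cat("<croaker_train>", length(x$pulses), "pulses,",
      length(x$assembled$samples), "samples @", x$assembled$fs, "Hz\n")
  invisible(x)
}

#' Noise specification for SNR degradation
#'
#' @param snr_db Target signal-to-noise ratio, dB.
#' @param kind Noise model; white Gaussian only.
#' @param power_window `"pulse_active"` measures the signal power over
#'   samples exceeding 1% of the peak (the active pulse region);
#'   `"full"` uses the whole record.
#' @param seed RNG seed.
#' @return A `croaker_noise_spec`.
#' @export
noise_spec <- function(snr_db, kind = "white_gaussian",
                       power_window = c("pulse_active", "full"),
                       seed = NULL) {
  if (!is.finite(snr_db)) abort("snr_db must be finite")
  kind <- match.arg(kind, "white_gaussian")
  structure(list(snr_db = snr_db, kind = kind,
                 power_window = match.arg(power_window), seed = seed),
            class = "croaker_noise_spec")
}

active_window <- function(x, frac = 0.01) {
  which(abs(x) > frac * max(abs(x)))
}

#' Degrade a waveform to a target SNR
#'
#' Adds white Gaussian noise scaled so that
#' `10 log10(P_signal / P_noise) = snr_db`, with the signal power measured
#' over the configured window (active pulse region by default).
#'
#' @param clean A `croaker_waveform`.
#' @param spec A `croaker_noise_spec`.
#' @return A `croaker_waveform` of the same length and unit.
#' @export
add_noise_at_snr <- function(clean, spec) {
  clean <- as_waveform(clean)
  stopifnot(inherits(spec, "croaker_noise_spec"))
  x <- clean$samples
  win <- if (spec$power_window == "pulse_active") active_window(x) else seq_along(x)
  psig <- mean(x[win]^2)
  if (psig == 0) abort("zero signal power in the measurement window")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  sigma <- sqrt(psig / 10^(spec$snr_db / 10))
  waveform(x + rnorm(length(x), 0, sigma), clean$fs, clean$unit)
}

#' Measure the SNR of a degraded waveform against its clean original
#'
#' `10 log10(P_clean / P_{noisy - clean})` over the chosen window. Identical
#' signals return `Inf`.
#'
#' @param clean,noisy Equal-length `croaker_waveform`s.
#' @param window `"pulse_active"` or `"full"` (see [noise_spec()]).
#' @return SNR in dB (`Inf` when the residual is zero).
#' @export
measure_snr <- function(clean, noisy, window = c("pulse_active", "full")) {
  window <- match.arg(window)
  clean <- as_waveform(clean)
  noisy <- as_waveform(noisy)
  if (length(clean$samples) != length(noisy$samples)) {
    abort("clean and noisy waveforms must have equal length")
  }
  x <- clean$samples
  win <- if (window == "pulse_active") active_window(x) else seq_along(x)
  pn <- mean((noisy$samples - x)^2)     # noise power is stationary: full record
  psig <- mean(x[win]^2)
  if (pn == 0) return(Inf)
  10 * log10(psig / pn)
}
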