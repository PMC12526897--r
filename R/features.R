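#' Hydrophone calibration
#'
#' Receiving voltage sensitivity and gain used to convert recorded voltage
#' to acoustic pressure. Defaults match a typical autonomous recorder
#' deployment: sensitivity -164.6 dB re 1 V/uPa, 0 dB gain, 48 kHz.
#'
#' @param sensitivity Receiving voltage sensitivity, dB re 1 V/uPa.
#' @param gain Recorder gain, dB.
#' @param fs Sampling rate, Hz.
#' @return A `croaker_cal`.
#' @export
hydrophone_cal <- function(sensitivity = -164.6, gain = 0, fs = 48000) {
  if (fs <= 0) abort("fs must be positive")
  structure(list(sensitivity = sensitivity, gain = gain, fs = fs),
            class = "croaker_cal")
}

#' Voltage / pressure conversion
#'
#' `p = v * 10^(-(sensitivity + gain) / 20)` in micropascal;
#' `pressure_to_voltage()` is its exact inverse.
#'
#' @param v Voltage vector (V).
#' @param p Pressure vector (uPa).
#' @param cal A `croaker_cal`.
#' @return Numeric vector (uPa or V).
#' @export
#' @examples
#' voltage_to_pressure(1, hydrophone_cal())  # 10^(164.6/20) uPa
voltage_to_pressure <- function(v, cal = hydrophone_cal()) {
  v * 10^(-(cal$sensitivity + cal$gain) / 20)
}

#' @rdname voltage_to_pressure
#' @export
pressure_to_voltage <- function(p, cal = hydrophone_cal()) {
  p * 10^((cal$sensitivity + cal$gain) / 20)
}

#' Zero-to-peak sound pressure level
#'
#' `SPL_0pk = 20 log10(max |p|)` in dB re 1 uPa for a waveform in
#' micropascal.
#'
#' @param w A `croaker_waveform` in uPa (or numeric vector of pressures).
#' @return SPL in dB re 1 uPa.
#' @export
#' @examples
#' compute_spl0pk(waveform(c(0, 1, 0), unit = "uPa"))  # 0 dB
compute_spl0pk <- function(w) {
  p <- if (inherits(w, "croaker_waveform")) w$samples else w
  pk <- max(abs(p))
  if (pk == 0) abort("all-zero waveform: SPL undefined")
  20 * log10(pk)
}

#' Pulse-detection configuration
#'
#' Numeric thresholds for pulse picking; the defaults are tuned for croaker
#' pulses in the ~21 ms inter-pulse regime.
#'
#' @param min_height Detection threshold as a multiple of the record's
#'   median absolute deviation (noise proxy).
#' @param min_separation Minimum peak separation, ms.
#' @param train_gap Gap above which a new pulse train starts, ms.
#' @param clip_level Full-scale fraction above which a pulse is flagged as
#'   clipped.
#' @return A `croaker_detect_config`.
#' @export
detection_config <- function(min_height = 6, min_separation = 10,
                             train_gap = 100, clip_level = 0.99) {
  if (!(min_separation < train_gap)) {
    abort("min_separation must be smaller than train_gap")
  }
  structure(list(min_height = min_height, min_separation = min_separation,
                 train_gap = train_gap, clip_level = clip_level),
            class = "croaker_detect_config")
}

#' Detect pulses in a waveform
#'
#' Local maxima of `|p|` exceeding `min_height` times the record's median
#' absolute deviation, separated by at least `min_separation` ms (greedy
#' suppression, strongest peaks first). Peaks at or above `clip_level` of
#' the record's full scale are flagged `clipped`; peaks closer than twice
#' the minimum separation to a neighbour are flagged `overlapping`.
#' Detection is translation-equivariant: shifting the waveform shifts all
#' peak indices by the same amount.
#'
#' @param w A `croaker_waveform`.
#' @param cfg A `croaker_detect_config`.
#' @param full_scale Full-scale amplitude for clip flagging. Defaults to 1
#'   for normalized waveforms; for pressure waveforms the recorder's full
#'   scale is unknown, so no peak is flagged unless a value is supplied.
#' @return A tibble: `peak_index`, `peak_value`, `clipped`, `overlapping`.
#' @export
detect_pulses <- function(w, cfg = detection_config(), full_scale = NULL) {
  w <- as_waveform(w)
  x <- abs(w$samples)
  n <- length(x)
  min_sep <- round(cfg$min_separation * w$fs / 1000)
  noise <- mad(w$samples)
  thr <- cfg$min_height * noise
  ## candidate local maxima (plateau-safe: strictly greater than one side)
  cand <- which(x > thr)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[x[cand] >= x[cand - 1L] & x[cand] > x[cand + 1L]]
  if (length(cand) == 0L) {
    return(tibble(peak_index = integer(0), peak_value = numeric(0),
                  clipped = logical(0), overlapping = logical(0)))
  }
  ## greedy suppression within min_sep, strongest first
  ord <- cand[order(-x[cand], cand)]
  keep <- logical(0)
  sel <- integer(0)
  for (i in ord) {
    if (all(abs(sel - i) >= min_sep)) sel <- c(sel, i)
  }
  sel <- sort(sel)
  fs_amp <- if (!is.null(full_scale)) {
    full_scale
  } else if (w$unit == "normalized") 1 else Inf
  clipped <- x[sel] >= cfg$clip_level * fs_amp
  gaps <- diff(sel)
  overlapping <- rep(FALSE, length(sel))
  if (length(sel) > 1L) {
    close <- gaps < 2L * min_sep
    overlapping[which(close)] <- TRUE
    overlapping[which(close) + 1L] <- TRUE
  }
  tibble(peak_index = sel, peak_value = w$samples[sel],
         clipped = clipped, overlapping = overlapping)
}

#' Extract inter-pulse intervals grouped into trains
#'
#' Consecutive peak-to-peak intervals in ms; a gap larger than
#' `cfg$train_gap` ms starts a new train. Single-pulse trains contribute no
#' IPI.
#'
#' @param peaks Integer peak indices (samples), or the tibble returned by
#'   [detect_pulses()].
#' @param fs Sampling rate, Hz.
#' @param cfg A `croaker_detect_config`.
#' @return A tibble: `train_id`, `ipi_ms` (one row per interval).
#' @export
#' @examples
#' extract_ipi(c(1, 1009, 2017), fs = 48000)  # two 21 ms intervals
extract_ipi <- function(peaks, fs, cfg = detection_config()) {
  if (is.data.frame(peaks)) peaks <- peaks$peak_index
  peaks <- sort(as.numeric(peaks))
  if (length(peaks) < 2L) {
    return(tibble(train_id = integer(0), ipi_ms = numeric(0)))
  }
  gaps_ms <- diff(peaks) / fs * 1000
  train_id <- cumsum(c(1L, as.integer(gaps_ms > cfg$train_gap)))
  keep <- gaps_ms <= cfg$train_gap
  tibble(train_id = train_id[-length(train_id)][keep], ipi_ms = gaps_ms[keep])
}

#' Energy spectral density of a transient waveform
#'
#' One-sided ESD `2 |X(f) dt|^2` (factor 2 on strictly positive
#' frequencies), where `X` is the DFT of the pressure series; reported both
#' on the linear scale (uPa^2 s / Hz) and in dB re 1 uPa^2 s / Hz. Satisfies
#' Parseval: `sum(esd_linear) * df` equals the time-domain energy
#' `sum(p^2) * dt`.
#'
#' @param w A `croaker_waveform`.
#' @return A tibble: `frequency`, `esd_linear`, `esd_db`.
#' @export
esd <- function(w) {
  w <- as_waveform(w)
  p <- w$samples
  if (all(p == 0)) abort("all-zero waveform: ESD undefined")
  n <- length(p)
  dt <- 1 / w$fs
  X <- fft(p)
  m <- floor(n / 2) + 1L
  vals <- (Mod(X[seq_len(m)]) * dt)^2
  fac <- rep(2, m)
  fac[1] <- 1
  if (n %% 2 == 0) fac[m] <- 1   # Nyquist bin is unpaired
  vals <- vals * fac             # sum(esd_linear) * df == sum(p^2) * dt
  tibble(frequency = (seq_len(m) - 1L) * w$fs / n,
         esd_linear = vals,
         esd_db = 10 * log10(pmax(vals, .Machine$double.xmin)))
}

#' ESD percentile summary across an ensemble of calls
#'
#' Per-frequency-bin empirical percentiles of the ESD (dB) across calls,
#' plus a per-bin density map (column-normalized histogram of dB levels)
#' and the ensemble RMS level.
#'
#' @param calls List of `croaker_waveform`s with equal length and fs.
#' @param percents Percentile levels.
#' @param density_breaks Number of dB bins for the density map.
#' @return A `croaker_esd_summary`: list with `percentiles` (tibble:
#'   frequency, p1, p5, ...), `density` (tibble: frequency, esd_db_mid,
#'   density), `rms_level`.
#' @export
esd_percentiles <- function(calls, percents = c(1, 5, 50, 95, 99),
                            density_breaks = 40L) {
  stopifnot(length(calls) >= 2L)
  lens <- vapply(calls, function(w) length(as_waveform(w)$samples), integer(1))
  fss <- vapply(calls, function(w) as_waveform(w)$fs, numeric(1))
  if (length(unique(lens)) != 1L) abort("calls must all have the same length")
  if (length(unique(fss)) != 1L) abort("calls must all share a sampling rate")
  mats <- vapply(calls, function(w) esd(w)$esd_db, numeric(floor(lens[1] / 2) + 1L))
  freq <- esd(calls[[1]])$frequency
  qs <- t(apply(mats, 1, quantile, probs = percents / 100, type = 7))
  colnames(qs) <- paste0("p", percents)
  perc <- dplyr::bind_cols(tibble(frequency = freq), as_tibble(qs))
  ## density map
  rng <- range(mats)
  brk <- seq(rng[1], rng[2], length.out = density_breaks + 1L)
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  dens <- apply(mats, 1, function(row) {
    h <- tabulate(findInterval(row, brk, rightmost.closed = TRUE),
                  nbins = density_breaks)
    h / sum(h)
  })
  density <- tibble(
    frequency = rep(freq, each = density_breaks),
    esd_db_mid = rep(mids, times = length(freq)),
    density = as.vector(dens))
  rms <- sqrt(mean(vapply(calls, function(w) mean(as_waveform(w)$samples^2),
                          numeric(1))))
  structure(list(percentiles = perc, density = density,
                 rms_level = 20 * log10(max(rms, .Machine$double.xmin))),
            class = "croaker_esd_summary")
}

#' @export
print.croaker_esd_summary <- function(x, ...) {
  cat("<croaker_esd_summary>", nrow(x$percentiles), "bins, rms",
      signif(x$rms_level, 5), "dB\n")
  invisible(x)
}

#' Plot an ESD percentile summary
#'
#' @param object A `croaker_esd_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.croaker_esd_summary <- function(object, ...) {
  pc <- object$percentiles
  long <- dplyr::bind_rows(lapply(setdiff(names(pc), "frequency"), function(nm)
    tibble(frequency = pc$frequency, percentile = nm, esd_db = pc[[nm]])))
  ggplot2::ggplot(object$density,
                  ggplot2::aes(x = .data$frequency, y = .data$esd_db_mid)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$density)) +
    ggplot2::geom_line(data = long,
                       ggplot2::aes(y = .data$esd_db,
                                    group = .data$percentile),
                       colour = "white", linewidth = 0.3) +
    ggplot2::labs(x = "frequency (Hz)", y = "ESD (dB)", fill = "probability")
}

#' Full feature-extraction chain for one record
#'
#' Converts a voltage record to pressure, detects pulses, groups them into
#' trains and extracts per-pulse SPL and IPI.
#'
#' @param w A `croaker_waveform` (unit `"uPa"`), or a voltage waveform with
#'   `cal` supplied.
#' @param cal Optional `croaker_cal` to convert voltage to pressure first.
#' @param cfg A `croaker_detect_config`.
#' @return A tibble: `peak_index`, `spl_0pk_db`, `train_id`, `ipi_ms`
#'   (IPI to the previous pulse in the train; `NA` for the first),
#'   `clipped`, `overlapping`.
#' @export
extract_features <- function(w, cal = NULL, cfg = detection_config()) {
  w <- as_waveform(w)
  if (!is.null(cal)) {
    w <- waveform(voltage_to_pressure(w$samples, cal), cal$fs, "uPa")
  }
  pk <- detect_pulses(w, cfg)
  if (nrow(pk) == 0L) {
    return(tibble(peak_index = integer(0), spl_0pk_db = numeric(0),
                  train_id = integer(0), ipi_ms = numeric(0),
                  clipped = logical(0), overlapping = logical(0)))
  }
  gaps_ms <- c(Inf, diff(pk$peak_index) / w$fs * 1000)
  train_id <- cumsum(as.integer(gaps_ms > cfg$train_gap))
  tibble(peak_index = pk$peak_index,
         spl_0pk_db = 20 * log10(abs(pk$peak_value)),
         train_id = train_id,
         ipi_ms = ifelse(gaps_ms > cfg$train_gap, NA_real_, gaps_ms),
         clipped = pk$clipped, overlapping = pk$overlapping)
}
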