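#' Synthetic-dataset configuration
#'
#' Describes a labeled synthetic croaker-call dataset shaped like the
#' reference field recordings: pulse trains grouped by "chain" (the number
#' of pulses in the train), with per-chain counts matching the reference
#' composition of 1023 calls, per-pulse wavelet parameters drawn within the
#' published similarity-preserving intervals, and SPL/IPI drawn from the
#' fitted quartile models. Every measured-like record also gets degraded
#' copies at 15 and 10 dB SNR, plus `per_chain_reconstructed` additional
#' reconstructed trains per chain.
#'
#' @param chain_counts Named integer vector: chain label (pulses per train)
#'   -> number of measured-like records.
#' @param per_chain_reconstructed Reconstructed records per chain.
#' @param parameter_intervals Tibble with columns `component`, `field`,
#'   `lo`, `hi` (defaults to [croaker_reference_intervals()]).
#' @param spl_model,ipi_model `croaker_qmodel`s.
#' @param snr_levels SNR levels (dB) for the degraded copies.
#' @param fs Sampling rate, Hz.
#' @param window_samples Synthesis window per pulse, samples.
#' @param bartlett_threshold Minimum Bartlett similarity of a drawn pulse
#'   spec against the reference call.
#' @param seed Base RNG seed.
#' @return A `croaker_dataset_config`.
#' @export
dataset_config <- function(chain_counts = c(`1` = 519L, `3` = 158L, `5` = 118L,
                                            `7` = 79L, `9` = 92L, `11` = 53L,
                                            `13` = 4L),
                           per_chain_reconstructed = 500L,
                           parameter_intervals = croaker_reference_intervals(),
                           spl_model = default_spl_model(),
                           ipi_model = default_ipi_model(),
                           snr_levels = c(15, 10),
                           fs = 48000, window_samples = 1536L,
                           bartlett_threshold = 0.98,
                           seed = 1L) {
  stopifnot(all(chain_counts >= 0), per_chain_reconstructed >= 0)
  bounds <- search_bounds()
  for (f in unique(parameter_intervals$field)) {
    iv <- parameter_intervals[parameter_intervals$field == f, ]
    if (any(iv$lo < bounds[[f]][1] - 1e-9) || any(iv$hi > bounds[[f]][2] + 1e-9)) {
      abort(paste0("parameter_intervals for '", f,
                   "' fall outside the search bounds"))
    }
  }
  structure(list(chain_counts = chain_counts,
                 per_chain_reconstructed = as.integer(per_chain_reconstructed),
                 parameter_intervals = parameter_intervals,
                 spl_model = spl_model, ipi_model = ipi_model,
                 snr_levels = snr_levels,
                 fs = fs, window_samples = as.integer(window_samples),
                 bartlett_threshold = bartlett_threshold,
                 seed = as.integer(seed)),
            class = "croaker_dataset_config")
}

#' Draw a pulse spec within the similarity-preserving intervals
#'
#' Each component's amplitude, delay and length are drawn uniformly within
#' its configured interval; the resulting call's Bartlett similarity to the
#' reference call is verified against the configured threshold, redrawing
#' up to `max_redraws` times.
#'
#' @param cfg A `croaker_dataset_config`.
#' @param mother Optional `croaker_mother`.
#' @param reference Optional reference `croaker_waveform` (defaults to the
#'   built-in reference call).
#' @param max_redraws Redraw budget before failing.
#' @return A `croaker_spec`.
#' @export
draw_component_spec <- function(cfg = dataset_config(), mother = NULL,
                                reference = NULL, max_redraws = 100L) {
  if (is.null(mother)) mother <- mother_cache()
  if (is.null(reference)) {
    reference <- synthesize_call(
      croaker_reference_spec(cfg$fs, cfg$window_samples), mother)
  }
  iv <- cfg$parameter_intervals
  n_comp <- max(iv$component)
  sens <- sensitivity_config(threshold = cfg$bartlett_threshold)
  for (try in seq_len(max_redraws)) {
    comps <- lapply(seq_len(n_comp), function(ci) {
      geti <- function(f) {
        row <- iv[iv$component == ci & iv$field == f, ]
        runif(1, row$lo, row$hi)
      }
      wavelet_component(geti("amplitude"), geti("delay"), geti("length"))
    })
    sp <- synthesis_spec(comps, fs = cfg$fs, window_samples = cfg$window_samples)
    cand <- suppressWarnings(synthesize_call(sp, mother))
    if (sum(cand$samples^2) > 0 &&
        bartlett_power(reference, cand, sens) >= cfg$bartlett_threshold) {
      return(sp)
    }
  }
  abort(paste0("no draw satisfied the Bartlett threshold after ",
               max_redraws, " attempts; widen the intervals or lower ",
               "bartlett_threshold"))
}

#' Plan the composition of a synthetic dataset
#'
#' Enumerates every record the generator would produce, without
#' synthesizing audio: one row per file with its chain, role
#' (`measured_like`, `reconstructed`, or `snr<level>`) and per-record seed.
#'
#' @param cfg A `croaker_dataset_config`.
#' @return A tibble: `file`, `chain`, `role`, `seed`.
#' @export
plan_dataset <- function(cfg = dataset_config()) {
  chains <- as.integer(names(cfg$chain_counts))
  rows <- list()
  rid <- 0L
  for (i in seq_along(chains)) {
    ch <- chains[i]
    for (j in seq_len(cfg$chain_counts[i])) {
      rid <- rid + 1L
      base <- sprintf("chain%02d_meas_%04d", ch, j)
      rows[[length(rows) + 1L]] <- tibble(
        file = paste0(base, ".wav"), chain = ch, role = "measured_like",
        seed = cfg$seed + rid)
      for (snr in cfg$snr_levels) {
        rows[[length(rows) + 1L]] <- tibble(
          file = sprintf("chain%02d_snr%02d_%04d.wav", ch, snr, j),
          chain = ch, role = paste0("snr", snr),
          seed = cfg$seed + rid)
      }
    }
    for (j in seq_len(cfg$per_chain_reconstructed)) {
      rid <- rid + 1L
      rows[[length(rows) + 1L]] <- tibble(
        file = sprintf("chain%02d_recon_%04d.wav", ch, j),
        chain = ch, role = "reconstructed", seed = cfg$seed + rid)
    }
  }
  dplyr::bind_rows(rows)
}

## dB full-scale used to store pressure waveforms as normalized float WAVs
DATASET_FULL_SCALE_DB <- 170

synthesize_record <- function(chain, seed, cfg, mother, reference) {
  set.seed(seed)
  spec <- draw_component_spec(cfg, mother, reference)
  pulse <- suppressWarnings(synthesize_call(spec, mother))
  spls <- draw_quartile_model(cfg$spl_model, chain)
  ipis <- if (chain > 1L) draw_quartile_model(cfg$ipi_model, chain - 1L) else numeric(0)
  tr <- assemble_train(pulse, ipis, spls, fs = cfg$fs)
  list(train = tr, spec = spec, spls = spls, ipis = ipis)
}

#' Generate a synthetic croaker-call dataset
#'
#' Synthesizes every record in [plan_dataset()]'s composition and writes it
#' as a mono float32 WAV: per chain, the configured number of measured-like
#' trains (per-pulse parameter draws within the similarity-preserving
#' intervals, SPL and IPI drawn from the quartile models), degraded copies
#' of each measured-like record at the configured SNRs, and reconstructed
#' trains. Pressure (uPa) is stored normalized by a fixed full scale noted
#' in the manifest. Fully seeded: the same configuration reproduces
#' byte-identical files and manifest.
#'
#' @param cfg A `croaker_dataset_config`.
#' @param outdir Output directory (created if needed).
#' @param mother Optional `croaker_mother`.
#' @param write_audio Set `FALSE` to synthesize and manifest without
#'   writing WAV files (the manifest is then returned with `file = NA`).
#' @return The manifest tibble: `file`, `chain`, `role`, `seed`,
#'   `spl_0pk_db`, `n_pulses`, `ipi_ms` (semicolon-joined), and
#'   `full_scale_db`. Also written to `manifest.csv` in `outdir`.
#' @export
generate_dataset <- function(cfg = dataset_config(), outdir,
                             mother = NULL, write_audio = TRUE) {
  if (is.null(mother)) mother <- mother_cache()
  if (write_audio && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  reference <- synthesize_call(
    croaker_reference_spec(cfg$fs, cfg$window_samples), mother)
  plan <- plan_dataset(cfg)
  full_scale <- 10^(DATASET_FULL_SCALE_DB / 20)
  ## synthesize measured-like / reconstructed records once; SNR copies are
  ## derived from the cached measured-like pressure waveform
  cache <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    pl <- plan[i, ]
    key <- paste0("c", pl$chain, "s", pl$seed)
    if (pl$role %in% c("measured_like", "reconstructed")) {
      rec <- synthesize_record(pl$chain, pl$seed, cfg, mother, reference)
      wave <- rec$train$assembled
      if (pl$role == "measured_like") assign(key, wave, envir = cache)
      ipis <- rec$ipis
    } else {
      clean <- get(key, envir = cache)
      snr <- as.numeric(sub("snr", "", pl$role))
      wave <- add_noise_at_snr(clean, noise_spec(snr, seed = pl$seed * 131L))
      ipis <- NA
    }
    spl <- compute_spl0pk(wave)
    if (write_audio) {
      write_wav(waveform(wave$samples / full_scale, wave$fs, "normalized"),
                file.path(outdir, pl$file))
    }
    rows[[i]] <- tibble(
      file = if (write_audio) pl$file else NA_character_,
      chain = pl$chain, role = pl$role, seed = pl$seed,
      spl_0pk_db = spl, n_pulses = pl$chain,
      ipi_ms = if (all(is.na(ipis))) NA_character_ else
        paste(signif(ipis, 8), collapse = ";"),
      full_scale_db = DATASET_FULL_SCALE_DB)
  }
  manifest <- dplyr::bind_rows(rows)
  if (write_audio) {
    write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  }
  manifest
}
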