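#' Sensitivity-analysis configuration
#'
#' @param grid_points Grid resolution per parameter sweep (>= 3).
#' @param threshold Similarity threshold defining the valid interval
#'   (default 0.98).
#' @param band Analysis band in Hz for the spectra; the default
#'   `c(50, 5000)` covers the 300--900 Hz energy band of croaker calls with
#'   margin.
#' @param snapshots Number of reference snapshots L used to build the
#'   cross-spectral matrix (1 for the single-waveform case).
#' @return A `croaker_sens_config`.
#' @export
sensitivity_config <- function(grid_points = 201L, threshold = 0.98,
                               band = c(50, 5000), snapshots = 1L) {
  stopifnot(grid_points >= 3L, threshold > 0, threshold <= 1,
            length(band) == 2L, band[1] < band[2], snapshots >= 1L)
  structure(list(grid_points = as.integer(grid_points), threshold = threshold,
                 band = band, snapshots = as.integer(snapshots)),
            class = "croaker_sens_config")
}

## band-limited magnitude spectrum, unit L2 norm
normalized_spectrum <- function(w, band) {
  x <- w$samples
  n <- length(x)
  mag <- Mod(fft(x))[seq_len(floor(n / 2) + 1L)]
  f <- (seq_len(floor(n / 2) + 1L) - 1L) * w$fs / n
  keep <- f >= band[1] & f <= band[2]
  v <- mag[keep]
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) abort("zero energy in the analysis band")
  list(frequencies = f[keep], values = v / nrm)
}

#' Normalized Bartlett power between two waveforms
#'
#' Matched-spectrum similarity `B = R_c' C_N R_c / (R_c' R_c)`, where `R_c`
#' is the band-limited, unit-norm magnitude spectrum of the candidate and
#' `C_N` the trace-normalized average of outer products of the reference
#' snapshot spectra. With a single reference snapshot this reduces to the
#' squared spectral cosine similarity `|<R_ref, R_cand>|^2`, which is 1 at a
#' perfect match, 0 for spectrally disjoint signals, invariant to positive
#' rescaling of either argument, and symmetric in its arguments. Magnitude
#' (not complex) spectra are used, so `B` is insensitive to a pure time
#' shift of the whole call; sensitivity to component delays arises through
#' inter-component interference.
#'
#' @param reference A `croaker_waveform`, or a list of them (snapshots).
#' @param candidate A `croaker_waveform` with the same sampling rate.
#' @param config A `croaker_sens_config`.
#' @return Similarity in `[0, 1]`.
#' @export
#' @examples
#' s <- synthesize_call(croaker_reference_spec())
#' bartlett_power(s, s)  # 1
bartlett_power <- function(reference, candidate,
                           config = sensitivity_config()) {
  refs <- if (inherits(reference, "croaker_waveform")) list(reference) else reference
  stopifnot(length(refs) >= 1L, inherits(candidate, "croaker_waveform"))
  for (r in refs) {
    stopifnot(inherits(r, "croaker_waveform"))
    if (r$fs != candidate$fs) abort("reference and candidate must share fs")
    if (length(r$samples) != length(candidate$samples)) {
      abort("reference and candidate must have equal length")
    }
  }
  rc <- normalized_spectrum(candidate, config$band)$values
  ## C_N = (1/L) sum_i R_i R_i' (unit-norm snapshots -> trace 1); quadratic
  ## form computed without materializing the matrix
  b <- mean(vapply(refs, function(r) {
    rr <- normalized_spectrum(r, config$band)$values
    sum(rr * rc)^2
  }, numeric(1)))
  min(max(b, 0), 1)
}

#' Sweep one wavelet parameter against a reference call
#'
#' Varies a single component's amplitude, delay or length over a uniform
#' grid spanning its search range, holding every other parameter at its
#' value in `spec` (which should be the optimal fit to `reference`), and
#' evaluates the normalized Bartlett power of each re-synthesis against the
#' reference. The maximal contiguous interval around the optimum where the
#' similarity stays at or above the threshold is attached.
#'
#' @param spec A `croaker_spec` (the optimal fit).
#' @param component_index Component to perturb (1-based).
#' @param field One of `"amplitude"`, `"delay"`, `"length"`.
#' @param bounds A `croaker_bounds` giving the sweep range.
#' @param reference `croaker_waveform` to compare against; defaults to the
#'   synthesis of `spec` itself.
#' @param config A `croaker_sens_config`.
#' @param mother Optional `croaker_mother`.
#' @return A `croaker_sensitivity`: tibble of `grid_value`, `similarity`
#'   with attributes `component`, `field`, `optimum`, `valid_interval`,
#'   `threshold`.
#' @export
sweep_parameter <- function(spec, component_index, field,
                            bounds = search_bounds(), reference = NULL,
                            config = sensitivity_config(), mother = NULL) {
  stopifnot(inherits(spec, "croaker_spec"))
  field <- match.arg(field, c("amplitude", "delay", "length"))
  if (component_index < 1L || component_index > length(spec$components)) {
    abort("component_index out of range")
  }
  if (is.null(mother)) mother <- mother_cache()
  if (is.null(reference)) reference <- suppressWarnings(synthesize_call(spec, mother))
  rng <- bounds[[field]]
  grid <- seq(rng[1], rng[2], length.out = config$grid_points)
  opt <- spec$components[[component_index]][[field]]
  ## include the optimum itself on the grid so the peak is exact
  grid <- sort(unique(c(grid, opt)))
  sims <- vapply(grid, function(v) {
    sp <- spec
    sp$components[[component_index]][[field]] <- v
    cand <- suppressWarnings(synthesize_call(sp, mother))
    if (sum(cand$samples^2) == 0) return(0)
    bartlett_power(reference, cand, config)
  }, numeric(1))
  out <- tibble(grid_value = grid, similarity = sims)
  attr(out, "component") <- component_index
  attr(out, "field") <- field
  attr(out, "optimum") <- opt
  attr(out, "threshold") <- config$threshold
  class(out) <- c("croaker_sensitivity", class(out))
  attr(out, "valid_interval") <- valid_interval(out, config$threshold)
  out
}

#' Similarity-preserving interval of a sensitivity curve
#'
#' The maximal contiguous interval containing the optimum on which the
#' similarity stays at or above the threshold; endpoints are linearly
#' interpolated between grid points. Raising the threshold never widens the
#' interval.
#'
#' @param curve A `croaker_sensitivity` from [sweep_parameter()].
#' @param threshold Similarity threshold.
#' @return Numeric `c(lo, hi)`.
#' @export
valid_interval <- function(curve, threshold = attr(curve, "threshold")) {
  g <- curve$grid_value
  s <- curve$similarity
  opt <- attr(curve, "optimum")
  io <- which.min(abs(g - opt))
  if (s[io] < threshold) {
    abort("similarity at the optimum is below the threshold; inconsistent curve")
  }
  cross <- function(i, j) {
    ## linear interpolation of the threshold crossing between grid i and j
    if (s[j] == s[i]) return(g[j])
    g[i] + (threshold - s[i]) * (g[j] - g[i]) / (s[j] - s[i])
  }
  lo <- g[1]
  for (i in io:1) {
    if (s[i] < threshold) { lo <- cross(i, i + 1L); break }
  }
  hi <- g[length(g)]
  for (i in io:length(g)) {
    if (s[i] < threshold) { hi <- cross(i, i - 1L); break }
  }
  c(lo, hi)
}

#' Sweep all parameters of a spec
#'
#' Runs [sweep_parameter()] for every component and field, returning a
#' combined tibble of curves and a tabulated interval summary.
#'
#' @inheritParams sweep_parameter
#' @return A list with `curves` (tibble: component, field, grid_value,
#'   similarity) and `intervals` (tibble: component, field, optimum, lo, hi,
#'   similarity_at_optimum).
#' @export
sweep_all_parameters <- function(spec, bounds = search_bounds(),
                                 reference = NULL,
                                 config = sensitivity_config(),
                                 mother = NULL) {
  if (is.null(mother)) mother <- mother_cache()
  if (is.null(reference)) reference <- suppressWarnings(synthesize_call(spec, mother))
  fields <- c("amplitude", "delay", "length")
  rows <- list()
  ivs <- list()
  for (ci in seq_along(spec$components)) {
    for (f in fields) {
      cv <- sweep_parameter(spec, ci, f, bounds, reference, config, mother)
      rows[[length(rows) + 1L]] <-
        dplyr::mutate(tibble(grid_value = cv$grid_value,
                             similarity = cv$similarity),
                      component = ci, field = f, .before = 1)
      opt <- attr(cv, "optimum")
      iv <- attr(cv, "valid_interval")
      ivs[[length(ivs) + 1L]] <- tibble(
        component = ci, field = f, optimum = opt,
        lo = iv[1], hi = iv[2],
        similarity_at_optimum = cv$similarity[which.min(abs(cv$grid_value - opt))])
    }
  }
  list(curves = dplyr::bind_rows(rows), intervals = dplyr::bind_rows(ivs))
}

#' @export
print.croaker_sensitivity <- function(x, ...) {
  iv <- attr(x, "valid_interval")
  cat("<croaker_sensitivity> component", attr(x, "component"),
      attr(x, "field"), " optimum", attr(x, "optimum"),
      sprintf(" interval [%.4g, %.4g] @ %.2f\n", iv[1], iv[2],
              attr(x, "threshold")))
  NextMethod()
}

#' Plot a sensitivity curve
#'
#' @param object A `croaker_sensitivity`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.croaker_sensitivity <- function(object, ...) {
  iv <- attr(object, "valid_interval")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$grid_value,
                                       y = .data$similarity)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        linetype = 2) +
    ggplot2::geom_vline(xintercept = iv, colour = "grey50") +
    ggplot2::geom_vline(xintercept = attr(object, "optimum"),
                        colour = "red", linetype = 3) +
    ggplot2::labs(x = paste("component", attr(object, "component"),
                            attr(object, "field")),
                  y = "Bartlett power")
}
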