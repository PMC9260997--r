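# Summarization of clean, epoched EEG into analysis features: component
# amplitudes, band power, load slopes, and the composite-face interaction
# contrast. No preprocessing (filtering, artifact rejection) happens here;
# epochs are assumed clean.

#' Mean component amplitude in a time window
#'
#' Averages epochs over trials (if a matrix is given), subtracts the mean
#' over the pre-stimulus baseline window, and returns the mean amplitude
#' within `window`. Mean amplitude (rather than the peak) is used because it
#' is robust for small-sample ERP work. Conventional windows: N1 80-180 ms,
#' P3 300-500 ms.
#'
#' @param x Numeric vector (trial-averaged waveform) or trials-by-samples
#'   matrix of epochs, in microvolts.
#' @param times Sample times in seconds (e.g. -0.2 ... 0.8).
#' @param window Analysis window in seconds, `c(lo, hi)`.
#' @param baseline Baseline-correction window in seconds, or `NULL` to skip.
#' @returns Mean amplitude in microvolts.
#' @export
erp_component_amplitude <- function(x, times, window,
                                    baseline = c(-0.2, 0)) {
  if (is.matrix(x)) x <- colMeans(x)
  check_number(x, "x")
  if (length(x) != length(times)) abort("`times` must match `x` in length.")
  if (length(window) != 2 || window[1] >= window[2]) {
    abort("`window` must be an increasing interval c(lo, hi).")
  }
  in_win <- times >= window[1] & times <= window[2]
  if (!any(in_win)) abort("`window` contains no samples.")
  if (!is.null(baseline)) {
    in_base <- times >= baseline[1] & times <= baseline[2]
    if (!any(in_base)) abort("`baseline` contains no samples.")
    x <- x - mean(x[in_base])
  }
  mean(x[in_win])
}

# Welch power spectral density: Hann-windowed segments with 50% overlap,
# one-sided density scaled so that sum(psd) * df equals the signal variance
# (a pure sinusoid of amplitude A carries total band power A^2 / 2).
welch_psd <- function(x, fs, seg_len = fs, overlap = 0.5) {
  check_number(x, "x")
  seg_len <- as.integer(seg_len)
  if (length(x) < seg_len) abort("signal shorter than one Welch segment.")
  step <- max(1L, as.integer(seg_len * (1 - overlap)))
  starts <- seq(1L, length(x) - seg_len + 1L, by = step)
  w <- signal::hanning(seg_len)
  scale <- fs * sum(w^2)
  n_freq <- seg_len %/% 2L + 1L
  acc <- numeric(n_freq)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w # per-segment detrend: DC offsets drop out
    spec <- abs(fft(seg)[seq_len(n_freq)])^2 / scale
    # fold two-sided density into one side (DC and Nyquist unpaired)
    spec[-c(1L, if (seg_len %% 2L == 0L) n_freq)] <-
      2 * spec[-c(1L, if (seg_len %% 2L == 0L) n_freq)]
    acc <- acc + spec
  }
  freq <- (seq_len(n_freq) - 1L) * fs / seg_len
  tibble(frequency = freq, psd = acc / length(starts))
}

#' Band power of a signal
#'
#' Welch periodogram (Hann window, 1-s segments, 50% overlap, per-segment
#' mean removal) averaged over the requested frequency band. Conventional
#' bands: alpha 8-12 Hz, gamma 30-45 Hz.
#'
#' @param x Numeric signal (one trial or a concatenated/averaged epoch), in
#'   microvolts.
#' @param fs Sampling rate, Hz.
#' @param band Frequency band `c(lo, hi)` in Hz, or `"alpha"` / `"gamma"`.
#' @param seg_len Welch segment length in samples (default: 1 s).
#' @param overlap Fractional segment overlap.
#' @param total If `TRUE`, return total band power (density summed times the
#'   bin width; a pure sinusoid of amplitude A in-band yields about A^2/2)
#'   instead of the mean density over band bins.
#' @returns Non-negative power (density, or total when `total = TRUE`).
#' @export
erp_band_power <- function(x, fs, band = c("alpha", "gamma"),
                           seg_len = fs, overlap = 0.5, total = FALSE) {
  if (is.character(band)) {
    band <- switch(match.arg(band), alpha = c(8, 12), gamma = c(30, 45))
  }
  if (length(band) != 2 || band[1] >= band[2]) {
    abort("`band` must be an increasing interval c(lo, hi).")
  }
  if (band[2] > fs / 2) abort("`band` exceeds the Nyquist frequency.")
  psd <- welch_psd(x, fs = fs, seg_len = seg_len, overlap = overlap)
  in_band <- psd$frequency >= band[1] & psd$frequency <= band[2]
  if (!any(in_band)) abort("`band` contains no frequency bins.")
  if (total) {
    df <- psd$frequency[2] - psd$frequency[1]
    sum(psd$psd[in_band]) * df
  } else {
    mean(psd$psd[in_band])
  }
}

#' Least-squares slope of a feature against memory load
#'
#' Exact ordinary-least-squares slope of `features` on `loads` (e.g. ERP
#' amplitudes against 50/75/100% visibility coded 1/2/3), in feature units
#' per load step.
#'
#' @param features Numeric feature values.
#' @param loads Numeric load levels, at least two distinct.
#' @returns The slope.
#' @export
erp_load_slope <- function(features, loads) {
  check_number(features, "features")
  check_number(loads, "loads")
  if (length(features) != length(loads)) {
    abort("`features` and `loads` must have equal length.")
  }
  if (length(unique(loads)) < 2) abort("`loads` must take >= 2 distinct values.")
  sum((loads - mean(loads)) * (features - mean(features))) /
    sum((loads - mean(loads))^2)
}

#' Composite-face interaction contrast
#'
#' Double difference of a feature across the 2x2 alignment-by-identity
#' design: `(aligned_diff - aligned_same) - (misaligned_diff -
#' misaligned_same)`. Zero when alignment has no effect on the same/different
#' difference.
#'
#' @param aligned_same,aligned_diff,misaligned_same,misaligned_diff Cell
#'   feature values.
#' @returns The interaction contrast in feature units.
#' @export
cfe_contrast <- function(aligned_same, aligned_diff,
                         misaligned_same, misaligned_diff) {
  args <- list(aligned_same = aligned_same, aligned_diff = aligned_diff,
               misaligned_same = misaligned_same,
               misaligned_diff = misaligned_diff)
  for (nm in names(args)) check_number(args[[nm]], nm)
  (aligned_diff - aligned_same) - (misaligned_diff - misaligned_same)
}
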