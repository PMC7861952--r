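#' Spectrogram (STFT) settings
#'
#' Sliding-window discrete Fourier representation of the raw signal. The
#' defaults are a 200 ms analysis window advanced by 50 ms with a
#' 1024-point DFT. The taper defaults to Hamming (the usual choice for sEMG
#' spectrograms) and the output scale to log-power, which keeps the dynamic
#' range manageable for the downstream autoencoder; both are configurable.
#'
#' @param window_ms analysis window length in milliseconds (default 200).
#' @param increment_ms hop between successive windows in milliseconds
#'   (default 50).
#' @param n_fft DFT length; must be at least the window length in samples
#'   (default 1024).
#' @param window_shape `"hamming"` or `"rectangular"`.
#' @param scale `"magnitude"`, `"power"` or `"log-power"`. Power is scaled
#'   so the one-sided bins of a frame sum to the frame energy divided by
#'   the window length (Parseval-consistent for a rectangular taper);
#'   log-power applies `log()` after flooring at 1e-12.
#' @return an object of class `spectrogram_spec`.
#' @export
spectrogram_spec <- function(window_ms = 200, increment_ms = 50,
                             n_fft = 1024,
                             window_shape = c("hamming", "rectangular"),
                             scale = c("log-power", "power", "magnitude")) {
  window_shape <- match.arg(window_shape)
  scale <- match.arg(scale)
  check_that(window_ms > increment_ms && increment_ms > 0,
             "window_ms must exceed increment_ms, both positive")
  structure(list(window_ms = window_ms, increment_ms = increment_ms,
                 n_fft = as.integer(n_fft), window_shape = window_shape,
                 scale = scale),
            class = "spectrogram_spec")
}

## one-sided spectrogram of a single channel: bins x frames matrix.
## Frames are 0-indexed; frame t covers samples [tH, tH + W) (half-open).
stft_channel <- function(x, w, h, n_fft, taper, scale) {
  n_frames <- floor((length(x) - w) / h) + 1L
  n_bins <- n_fft %/% 2L + 1L
  # doubling weights make one-sided power sums match the two-sided total
  pw <- c(1, rep(2, n_bins - 2L), if (n_fft %% 2L == 0L) 1 else 2)
  out <- matrix(0, n_bins, n_frames)
  for (t in seq_len(n_frames)) {
    seg <- x[((t - 1L) * h + 1L):((t - 1L) * h + w)] * taper
    sp <- stats::fft(c(seg, rep(0, n_fft - w)))[seq_len(n_bins)]
    out[, t] <- switch(scale,
      "magnitude" = Mod(sp),
      "power" = Mod(sp)^2 * pw / (w * n_fft),
      "log-power" = log(pmax(Mod(sp)^2 * pw / (w * n_fft), 1e-12)))
  }
  out
}

#' Spectrogram features of one multichannel trial
#'
#' Computes, per channel and per analysis frame, a one-sided `n_fft/2 + 1`
#' bin spectrum. The frame count is `floor((L - W)/H) + 1` with window
#' length `W = window_ms * fs / 1000` samples and hop
#' `H = increment_ms * fs / 1000`. The result is returned both as a
#' `feature_tensor` with axes (channel, frequency, time) and as a single
#' flat feature row (the tensor flattened in row-major, last-axis-fastest
#' order), the default feed into augmentation.
#'
#' @param trial_signal channels x samples numeric matrix.
#' @param sampling_rate sampling rate in Hz.
#' @param spec a [spectrogram_spec()].
#' @return list with `tensor` (a `feature_tensor`), `row` (flat numeric
#'   vector), `frequencies` (Hz per bin) and `n_frames`.
#' @export
spectrogram_features <- function(trial_signal, sampling_rate,
                                 spec = spectrogram_spec()) {
  trial_signal <- as.matrix(trial_signal)
  check_that(sampling_rate > 0, "sampling_rate must be positive")
  w <- round(spec$window_ms * sampling_rate / 1000)
  h <- round(spec$increment_ms * sampling_rate / 1000)
  check_that(ncol(trial_signal) >= w,
             sprintf("trial too short: %d samples < one %d-sample window",
                     ncol(trial_signal), w))
  check_that(spec$n_fft >= w,
             sprintf("n_fft (%d) must be >= window length in samples (%d)",
                     spec$n_fft, w))
  taper <- if (spec$window_shape == "hamming") {
    as.numeric(signal::hamming(w))
  } else rep(1, w)
  chans <- lapply(seq_len(nrow(trial_signal)), function(ch) {
    stft_channel(trial_signal[ch, ], w, h, spec$n_fft, taper, spec$scale)
  })
  n_bins <- nrow(chans[[1]])
  n_frames <- ncol(chans[[1]])
  arr <- array(0, c(length(chans), n_bins, n_frames))
  for (ch in seq_along(chans)) arr[ch, , ] <- chans[[ch]]
  tens <- feature_tensor(arr, c("channel", "frequency", "time"))
  list(tensor = tens, row = flatten_tensor(tens),
       frequencies = (0:(n_bins - 1L)) * sampling_rate / spec$n_fft,
       n_frames = n_frames)
}

#' Spectrogram feature table for a whole signal set
#'
#' Applies [spectrogram_features()] to every trial (active segment only by
#' default — the classifier targets movements, not rest) and stacks the
#' flat rows into a `feature_table` carrying subject and trial ids. The
#' axis sizes of the per-trial tensor are attached as the `axes` attribute
#' so rows can be re-tensorised downstream.
#'
#' @param dataset a `labeled_signal_set`.
#' @param spec a [spectrogram_spec()].
#' @param include_rest if `TRUE`, the rest segment of each trial is emitted
#'   as an extra trial labeled `"rest"`.
#' @return a `feature_table` with attribute `axes`.
#' @export
extract_spectrogram_features <- function(dataset, spec = spectrogram_spec(),
                                         include_rest = FALSE) {
  rows <- list(); ys <- list(); subs <- list(); ids <- list()
  axes <- NULL
  for (tr in dataset$trials) {
    act <- tr$signal[, seq_len(tr$active_samples), drop = FALSE]
    sf <- spectrogram_features(act, dataset$sampling_rate, spec)
    axes <- sf$tensor$shape
    rows[[length(rows) + 1L]] <- sf$row
    ys[[length(ys) + 1L]] <- as.character(tr$class)
    subs[[length(subs) + 1L]] <- tr$subject
    ids[[length(ids) + 1L]] <- tr$trial_id
    if (include_rest && tr$active_samples < ncol(tr$signal)) {
      rest <- tr$signal[, (tr$active_samples + 1L):ncol(tr$signal),
                        drop = FALSE]
      sfr <- spectrogram_features(rest, dataset$sampling_rate, spec)
      rows[[length(rows) + 1L]] <- sfr$row
      ys[[length(ys) + 1L]] <- "rest"
      subs[[length(subs) + 1L]] <- tr$subject
      ids[[length(ids) + 1L]] <- -tr$trial_id
    }
  }
  ft <- feature_table(do.call(rbind, rows), unlist(ys),
                      subject = unlist(subs), trial_id = unlist(ids))
  attr(ft, "axes") <- axes
  ft
}
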