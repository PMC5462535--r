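# Stimulus-feature extraction and band-limited signal preparation.

#' Construct a uniformly sampled signal
#'
#' Lightweight container for a real time series at a stated sampling rate,
#' used throughout for envelopes, lip trajectories and neural node signals.
#'
#' @param values Numeric vector of samples; all values must be finite.
#' @param rate_hz Sampling rate in Hz (> 0).
#' @param label Optional free-text label.
#' @return An object of class `sampled_signal` (a list with elements
#'   `values`, `rate_hz`, `label`).
#' @export
#' @examples
#' s <- sampled_signal(sin(2 * pi * 5 * seq(0, 1, by = 1 / 150)), 150, "5 Hz tone")
#' length(s$values)
sampled_signal <- function(values, rate_hz, label = "") {
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop_invalid("signal values must be finite")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0) {
    stop_invalid("rate_hz must be a single positive number")
  }
  structure(list(values = values, rate_hz = rate_hz, label = as.character(label)),
            class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %s: %d samples @ %g Hz (%.2f s)\n",
              if (nzchar(x$label)) x$label else "unlabelled",
              length(x$values), x$rate_hz, length(x$values) / x$rate_hz))
  invisible(x)
}

as_signal_values <- function(x) {
  if (inherits(x, "sampled_signal")) x$values else as.numeric(x)
}

#' Frequency band bank for entrainment analysis
#'
#' Returns the ordered set of analysis bands. The default is the
#' eight-band bank spanning 0.25-48 Hz used for band-limited entrainment
#' and coupling analyses; bands partly overlap at the upper end.
#'
#' @param bands Optional list of `c(low_hz, high_hz)` pairs to override
#'   the default bank.
#' @return A data.frame with columns `low_hz`, `high_hz` and a `band`
#'   label of the form "low-high Hz".
#' @export
band_bank <- function(bands = NULL) {
  if (is.null(bands)) {
    bands <- list(c(0.25, 1), c(1, 4), c(4, 8), c(8, 12),
                  c(12, 18), c(18, 24), c(24, 36), c(30, 48))
  }
  lows <- vapply(bands, `[`, numeric(1), 1L)
  highs <- vapply(bands, `[`, numeric(1), 2L)
  if (any(lows >= highs)) stop_invalid("each band must satisfy low < high")
  data.frame(low_hz = lows, high_hz = highs,
             band = sprintf("%g-%g Hz", lows, highs),
             stringsAsFactors = FALSE)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a fourth-order Butterworth band-pass forward and reverse
#' (zero net phase shift; the magnitude response at the band limits is
#' -6 dB in total, -3 dB per pass). Edges are handled by reflecting the
#' signal around its end points before filtering.
#'
#' @param signal A [sampled_signal()] or numeric vector.
#' @param band Numeric pair `c(low_hz, high_hz)`; `high_hz` must lie
#'   below the Nyquist frequency.
#' @param rate_hz Sampling rate, required when `signal` is a bare vector.
#' @param order Filter order per pass (default 4).
#' @return A [sampled_signal()] of the same length.
#' @export
bandpass <- function(signal, band, rate_hz = NULL, order = 4L) {
  x <- as_signal_values(signal)
  fs <- if (inherits(signal, "sampled_signal")) signal$rate_hz else rate_hz
  if (is.null(fs)) stop_invalid("rate_hz required for bare numeric input")
  band <- as.numeric(band)
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2]) {
    stop_invalid("band must be c(low_hz, high_hz) with 0 < low < high")
  }
  if (band[2] >= fs / 2) stop_invalid("band upper edge %.3g Hz is at or above Nyquist (%.3g Hz)", band[2], fs / 2)
  flt <- signal::butter(order, band / (fs / 2), type = "pass")
  y <- filtfilt_reflect(flt, x, fs)
  out <- sampled_signal(y, fs, label = sprintf("%s [%g-%g Hz]",
                                               if (inherits(signal, "sampled_signal")) signal$label else "",
                                               band[1], band[2]))
  out
}

# Forward-reverse filtering with reflect padding (about 1 s or a third of
# the signal, whichever is smaller) to suppress edge transients.
filtfilt_reflect <- function(flt, x, fs) {
  n <- length(x)
  if (n < 8L) stop_invalid("signal too short to filter (%d samples)", n)
  pad <- min(n - 1L, max(32L, round(fs)))
  head_ref <- 2 * x[1] - x[(pad + 1L):2L]
  tail_ref <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xp <- c(head_ref, x, tail_ref)
  yp <- signal::filtfilt(flt, xp)
  yp[(pad + 1L):(pad + n)]
}

# Low-pass variant used by the envelope path and the synthetic generator.
lowpass <- function(x, cutoff_hz, fs, order = 4L) {
  if (cutoff_hz >= fs / 2) stop_invalid("cutoff at or above Nyquist")
  flt <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  filtfilt_reflect(flt, x, fs)
}

#' Analytic signal via the Hilbert transform
#'
#' Computes the discrete analytic signal (FFT construction) and returns
#' its instantaneous amplitude and wrapped phase.
#'
#' @param signal A [sampled_signal()] or numeric vector (length >= 8).
#' @param rate_hz Sampling rate for bare numeric input.
#' @return A list of class `analytic_signal` with elements `amplitude`
#'   (non-negative), `phase` (radians in (-pi, pi]) and `rate_hz`.
#' @export
hilbert_analytic <- function(signal, rate_hz = NULL) {
  x <- as_signal_values(signal)
  fs <- if (inherits(signal, "sampled_signal")) signal$rate_hz else rate_hz
  n0 <- length(x)
  if (n0 < 8L) stop_invalid("need at least 8 samples for the analytic signal")
  # reflect-pad to a 2-3-5-smooth length when the length has a large
  # prime factor: R's mixed-radix FFT degrades to O(n * p) there
  n <- if (largest_factor_over(n0, 127L)) stats::nextn(n0, factors = c(2, 3, 5)) else n0
  pad <- n - n0
  xp <- if (pad > 0) c(x, x[n0 - seq_len(pad)]) else x
  X <- stats::fft(xp)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- (stats::fft(X * h, inverse = TRUE) / n)[seq_len(n0)]
  structure(list(amplitude = Mod(z), phase = Arg(z), rate_hz = fs %||% NA_real_),
            class = "analytic_signal")
}

#' Magnitude-squared coherence between two signals (Welch estimate)
#'
#' Segment-averaged cross-spectral coherence with Hann-tapered segments
#' and 50% overlap. Values lie in \\[0, 1\\] per frequency bin.
#'
#' @param x,y [sampled_signal()] objects (or numeric vectors with
#'   `rate_hz` supplied) of equal rate and length.
#' @param rate_hz Sampling rate for bare numeric input.
#' @param segment_s Welch segment length in seconds (default 10).
#' @return A data.frame with columns `freq_hz` and `coherence`, plus an
#'   attribute `n_segments` (the number of averaged segments, needed for
#'   the analytic chance level).
#' @export
spectral_coherence <- function(x, y, rate_hz = NULL, segment_s = 10) {
  fx <- if (inherits(x, "sampled_signal")) x$rate_hz else rate_hz
  fy <- if (inherits(y, "sampled_signal")) y$rate_hz else rate_hz
  if (is.null(fx) || is.null(fy)) stop_invalid("rate_hz required for bare numeric input")
  if (!isTRUE(all.equal(fx, fy))) stop_invalid("signals must share a sampling rate")
  xv <- as_signal_values(x); yv <- as_signal_values(y)
  if (length(xv) != length(yv)) stop_invalid("signals must have equal length")
  n <- length(xv)
  nseg <- max(16L, min(n, round(segment_s * fx)))
  step <- max(1L, floor(nseg / 2))
  starts <- seq(1L, n - nseg + 1L, by = step)
  if (length(starts) < 2L) {
    # fall back to shorter segments so at least 4 are averaged
    nseg <- max(16L, floor(n / 3))
    step <- max(1L, floor(nseg / 2))
    starts <- seq(1L, n - nseg + 1L, by = step)
  }
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  nf <- floor(nseg / 2)
  sxx <- syy <- numeric(nf)
  sxy <- complex(real = numeric(nf), imaginary = numeric(nf))
  for (s in starts) {
    xs <- xv[s:(s + nseg - 1L)]; ys <- yv[s:(s + nseg - 1L)]
    X <- stats::fft((xs - mean(xs)) * w)[2:(nf + 1L)]
    Y <- stats::fft((ys - mean(ys)) * w)[2:(nf + 1L)]
    sxx <- sxx + Mod(X)^2
    syy <- syy + Mod(Y)^2
    sxy <- sxy + X * Conj(Y)
  }
  coh <- Mod(sxy)^2 / pmax(sxx * syy, .Machine$double.eps)
  out <- data.frame(freq_hz = (1:nf) * fx / nseg, coherence = pmin(coh, 1))
  attr(out, "n_segments") <- length(starts)
  out
}

#' Analytic chance level for Welch coherence
#'
#' The expected `1 - alpha` quantile of magnitude-squared coherence
#' between independent signals given `L` averaged (independent) segments:
#' `1 - alpha^(1/(L-1))`.
#'
#' @param n_segments Number of averaged segments.
#' @param alpha Tail probability (default 0.05).
#' @return Scalar coherence threshold.
#' @export
coherence_chance_level <- function(n_segments, alpha = 0.05) {
  if (n_segments < 2) stop_invalid("need at least 2 segments")
  1 - alpha^(1 / (n_segments - 1))
}

#' Wide-band speech envelope from raw audio
#'
#' Filters the audio into `n_bands` band-pass channels spaced to equal
#' widths on the ERB-rate cochlear scale between `band_range_hz`, takes
#' the Hilbert envelope of each channel, averages the channel envelopes,
#' and resamples the result to `out_rate_hz` (polyphase, anti-aliased).
#'
#' @param audio A [sampled_signal()] at audio rate, or numeric vector with
#'   `rate_hz` supplied.
#' @param n_bands Number of cochlear channels (default 6).
#' @param band_range_hz Frequency range covered, default `c(100, 4000)`.
#' @param out_rate_hz Output rate, default 150 Hz.
#' @param rate_hz Sampling rate for bare numeric input.
#' @return A non-negative [sampled_signal()] at `out_rate_hz`.
#' @export
compute_speech_envelope <- function(audio, n_bands = 6L, band_range_hz = c(100, 4000),
                                    out_rate_hz = 150, rate_hz = NULL) {
  x <- as_signal_values(audio)
  fs <- if (inherits(audio, "sampled_signal")) audio$rate_hz else rate_hz
  if (is.null(fs)) stop_invalid("rate_hz required for bare numeric input")
  if (fs <= 2 * band_range_hz[2]) stop_invalid("audio rate must exceed twice the upper band edge")
  if (length(x) < fs / 10) stop_invalid("audio shorter than filter warm-up")
  edges_erb <- seq(hz_to_erbrate(band_range_hz[1]), hz_to_erbrate(band_range_hz[2]),
                   length.out = n_bands + 1L)
  edges_hz <- erbrate_to_hz(edges_erb)
  env <- numeric(length(x))
  for (b in seq_len(n_bands)) {
    flt <- signal::butter(4L, c(edges_hz[b], edges_hz[b + 1L]) / (fs / 2), type = "pass")
    xb <- filtfilt_reflect(flt, x, fs)
    env <- env + hilbert_analytic(xb, fs)$amplitude
  }
  env <- env / n_bands
  dur <- length(x) / fs
  out <- resample_to(env, fs, out_rate_hz, n_out = round(dur * out_rate_hz))
  sampled_signal(pmax(out, 0), out_rate_hz, label = "speech envelope")
}

# ERB-rate cochlear scale (Glasberg & Moore).
hz_to_erbrate <- function(f) 21.4 * log10(4.37e-3 * f + 1)
erbrate_to_hz <- function(e) (10^(e / 21.4) - 1) / 4.37e-3

# TRUE when n retains a prime factor above `limit` after removing all
# small factors.
largest_factor_over <- function(n, limit = 127L) {
  n <- as.integer(n)
  for (p in c(2L, 3L, 5L, 7L, 11L, 13L)) while (n %% p == 0L) n <- n %/% p
  p <- 17L
  while (p * p <= n && p <= limit) {
    while (n %% p == 0L) n <- n %/% p
    p <- p + 2L
  }
  n > limit
}

# Anti-aliased resampling: staged integer decimation (zero-phase
# low-pass at 0.4 x the intermediate Nyquist before each subsampling)
# followed by interpolation at the target sample times. Staging keeps
# the normalized filter cutoffs well away from the numerically fragile
# near-zero region.
resample_to <- function(x, fs_in, fs_out, n_out) {
  while (fs_in / fs_out > 10) {
    k <- min(8L, floor(fs_in / fs_out / 2))
    x <- lowpass(x, 0.4 * fs_in / k, fs_in)
    x <- x[seq(1L, length(x), by = k)]
    fs_in <- fs_in / k
  }
  if (fs_out < fs_in) x <- lowpass(x, 0.45 * fs_out, fs_in)
  t_in <- (seq_along(x) - 1) / fs_in
  t_out <- (seq_len(n_out) - 1) / fs_out
  stats::approx(t_in, x, xout = pmin(t_out, max(t_in)), rule = 2)$y
}
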