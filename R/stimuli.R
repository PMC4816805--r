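#' @title Spectral rotation of vocal stimuli
#' @name stimuli
#' @description
#' Spectral rotation renders vocal sounds unintelligible while retaining
#' their acoustic complexity: the spectrum is mirrored about 2 kHz by
#' amplitude-modulating the signal with a 4-kHz sinusoid and low-pass
#' filtering at 3.8 kHz, so a narrowband component at `f` Hz reappears at
#' `4000 - f` Hz. Before rotation the signal is shaped by a 33-point FIR
#' equalizing filter (essentially high-pass) designed so that the rotated
#' signal has approximately the same long-term spectrum as the original
#' speech; the underlying long-term-average speech spectrum is
#' approximated by a piecewise log-linear curve that is flat below 420 Hz
#' (the roll-off below 120 Hz is ignored) and falls off log-linearly
#' above. A deterministic synthetic vocalization generator provides
#' category-specific fixture clips (neutral vowels, laughter, screams,
#' pleasure, disgust).
NULL

# Piecewise log-linear long-term-average speech spectrum, in dB relative
# to the low-frequency plateau: flat up to 420 Hz, then -9 dB/octave.
# Shipped as a closure over a swappable breakpoint table.
.ltas_db <- function(freq_hz, slope_db_per_octave = -9, corner_hz = 420) {
  out <- numeric(length(freq_hz))
  hi <- freq_hz > corner_hz
  out[hi] <- slope_db_per_octave * log2(freq_hz[hi] / corner_hz)
  out
}

#' Design the 33-point equalization filter
#'
#' Linear-phase FIR (exactly 33 taps) whose magnitude approximates the
#' gain `LTAS(4000 - f) / LTAS(f)`: applying it before rotation about
#' 2 kHz gives the rotated signal approximately the same long-term
#' spectrum as the original. The response is flat below 420 Hz up to the
#' mirrored-curve variation (< 1 dB between 200 and 400 Hz) and rises
#' toward high frequencies. Designed by frequency sampling.
#'
#' @param sample_rate sampling rate in Hz (>= 16000 so the pre-filter
#'   image components up to ~7.8 kHz are representable).
#' @return object of class `equalization_filter` with fields `taps`
#'   (length 33), `sample_rate`, and the design `target` (data frame of
#'   frequency and linear gain).
#' @details
#' The target gain at frequency `f` is `LTAS(4000 - f) / LTAS(f)`: a
#' component at `f` lands at `4000 - f` after rotation, so this shaping
#' gives the rotated signal the assumed long-term speech spectrum. Below
#' 420 Hz the gain is held constant (the assumed spectrum is flat there,
#' and its mirror image falls in the flattening top of the rotation
#' band). The symmetric 33-tap impulse response is fit by least squares
#' on a dense frequency grid with *relative* (inverse-target) weighting,
#' so the quiet low-frequency end of the ~54 dB-deep target is rendered
#' accurately in dB terms, not just absolutely.
#' @export
build_equalization_filter <- function(sample_rate) {
  if (sample_rate < 16000) stop("sample rate must be at least 16000 Hz", call. = FALSE)
  nyq <- sample_rate / 2
  f <- seq(0, nyq, length.out = 600)
  mirrored <- pmin(pmax(4000 - f, 0), 4000)
  gain_db <- .ltas_db(mirrored) - .ltas_db(f)
  gain_db[f > 4000] <- gain_db[max(which(f <= 4000))]  # hold beyond the rotation band
  gain_db[f < 420] <- gain_db[min(which(f >= 420))]    # flat low region
  g <- 10^(gain_db / 20)
  g <- g / max(g)  # unity peak so filtering cannot explode the scale
  # linear-phase design: H(f) = a0 + 2 sum_m a_m cos(2 pi f m / fs)
  basis <- cbind(1, 2 * cos(2 * pi * outer(f, 1:16) / sample_rate))
  w <- 1 / g
  w[f <= 450] <- 4 * w[f <= 450]  # pin down the flat region
  coef <- qr.solve(basis * w, g * w)
  taps <- c(rev(coef[2:17]), coef[1], coef[2:17])
  structure(list(taps = as.numeric(taps), sample_rate = sample_rate,
                 target = data.frame(freq_hz = f, gain = g)),
            class = "equalization_filter")
}

# Zero-phase application of a linear-phase FIR: full convolution, then
# drop the group delay so output length and alignment match the input.
.fir_apply <- function(x, taps) {
  half <- (length(taps) - 1) / 2
  y <- signal::conv(x, taps)
  y[(half + 1):(half + length(x))]
}

# Linear-phase low-pass with >= 60 dB stopband at `stop_hz` (Blackman
# window; transition band [pass_hz, stop_hz]).
.lowpass_taps <- function(sample_rate, pass_hz = 3800, stop_hz = 4200) {
  nyq <- sample_rate / 2
  ntap <- ceiling(5.5 * sample_rate / (stop_hz - pass_hz))
  if (ntap %% 2 == 0) ntap <- ntap + 1
  wc <- (pass_hz + stop_hz) / 2 / nyq
  signal::fir1(ntap - 1, wc, type = "low", window = signal::blackman(ntap))
}

#' Spectrally rotate an audio clip about 2 kHz
#'
#' `output = lowpass_3.8kHz( equalize(x) * sin(2*pi*4000*t) )`. The
#' modulator phase is zero at sample zero for determinism. If the result
#' exceeds \[-1, 1\] it is peak-normalized and the applied gain is
#' recorded in attribute `"normalization_gain"`. Output duration equals
#' input duration (filters are applied zero-phase with the group delay
#' removed).
#'
#' @param clip an `audio_clip` with `sample_rate >= 16000`.
#' @param filter an `equalization_filter` for this sample rate, or `NULL`
#'   to build one.
#' @param equalize apply the long-term-spectrum equalizer before rotation
#'   (disable when, e.g., rotating twice to recover a signal).
#' @param prefilter also low-pass at 3.8 kHz *before* modulation, as in
#'   classical analogue rotation (off by default).
#' @return rotated `audio_clip` of the same length and rate.
#' @export
spectral_rotate <- function(clip, filter = NULL, equalize = TRUE, prefilter = FALSE) {
  fs <- clip$sample_rate
  if (fs < 16000) stop("sample rate must be at least 16000 Hz for rotation", call. = FALSE)
  x <- clip$samples
  lp <- .lowpass_taps(fs)
  if (prefilter) x <- .fir_apply(x, lp)
  if (equalize) {
    if (is.null(filter)) filter <- build_equalization_filter(fs)
    if (!isTRUE(all.equal(filter$sample_rate, fs)))
      stop("equalization filter was designed for a different sample rate", call. = FALSE)
    x <- .fir_apply(x, filter$taps)
  }
  tt <- (seq_along(x) - 1) / fs
  x <- x * sin(2 * pi * 4000 * tt)
  y <- .fir_apply(x, lp)
  gain <- 1
  pk <- max(abs(y))
  if (pk > 1) {
    gain <- 1 / pk
    y <- y * gain
    message(sprintf("spectral_rotate: peak-normalized by gain %.4f", gain))
  }
  out <- audio_clip(y, fs)
  attr(out, "normalization_gain") <- gain
  out
}

#' Draw stimulus durations
#'
#' Durations (ms) are drawn from the normal distribution matched to the
#' stimulus set (mean 1018 ms, SD 326 ms), truncated below at `min_ms`.
#'
#' @param n number of draws.
#' @param mean_ms,sd_ms,min_ms distribution parameters.
#' @return numeric vector of durations in ms.
#' @export
sample_duration_ms <- function(n, mean_ms = 1018, sd_ms = 326, min_ms = 300) {
  d <- stats::rnorm(n, mean_ms, sd_ms)
  while (any(d < min_ms)) d[d < min_ms] <- stats::rnorm(sum(d < min_ms), mean_ms, sd_ms)
  d
}

# Category parameter table for the vocalization synthesizer: fundamental
# frequency start/end (Hz), harmonic roll-off, noise mix, and amplitude
# modulation rate (Hz; 0 = smooth envelope).
.voc_params <- list(
  neutral  = list(f0 = c(140, 120), rolloff = 0.75, noise = 0.05, am = 0),
  laughter = list(f0 = c(260, 200), rolloff = 0.70, noise = 0.15, am = 5),
  scream   = list(f0 = c(750, 900), rolloff = 0.88, noise = 0.30, am = 0),
  pleasure = list(f0 = c(220, 150), rolloff = 0.72, noise = 0.10, am = 0),
  disgust  = list(f0 = c(95, 80),   rolloff = 0.80, noise = 0.40, am = 3)
)

#' Synthesize a vocalization-like clip
#'
#' Deterministic-per-seed harmonic-stack synthesis with a
#' category-specific fundamental-frequency contour, harmonic roll-off,
#' breath-noise mix and (for pulsed categories such as laughter) amplitude
#' modulation, under a smooth attack/decay envelope. When `duration_ms`
#' is omitted it is drawn from the stimulus-set duration distribution
#' (see [sample_duration_ms()]). Screams have a substantially higher
#' fundamental than neutral vowels by construction.
#'
#' @param category one of `"neutral"`, `"laughter"`, `"scream"`,
#'   `"pleasure"`, `"disgust"`.
#' @param duration_ms clip duration in ms, or `NULL` to draw one.
#' @param seed integer seed; identical `(category, seed, duration_ms)`
#'   give identical samples.
#' @param sample_rate sampling rate in Hz.
#' @return an `audio_clip` with attribute `"category"`.
#' @export
gen_vocalization <- function(category, duration_ms = NULL, seed = 1L,
                             sample_rate = 22050) {
  if (!category %in% names(.voc_params))
    stop("unknown category '", category, "'; expected one of ",
         paste(names(.voc_params), collapse = ", "), call. = FALSE)
  p <- .voc_params[[category]]
  with_seed(seed + 1000L * match(category, names(.voc_params)), {
    if (is.null(duration_ms)) duration_ms <- sample_duration_ms(1)
    if (duration_ms <= 0) stop("duration must be positive", call. = FALSE)
    n <- max(16L, round(sample_rate * duration_ms / 1000))
    tt <- (seq_len(n) - 1) / sample_rate
    # jittered f0 contour, linear between start and end
    f0 <- seq(p$f0[1], p$f0[2], length.out = n) * stats::runif(1, 0.92, 1.08)
    phase <- 2 * pi * cumsum(f0) / sample_rate
    nh <- max(1L, floor((sample_rate / 2 * 0.8) / max(f0)))
    nh <- min(nh, 24L)
    y <- numeric(n)
    for (h in seq_len(nh)) {
      y <- y + p$rolloff^(h - 1) * sin(h * phase + stats::runif(1, 0, 2 * pi))
    }
    y <- y / max(abs(y))
    noise <- stats::rnorm(n)
    noise <- .fir_apply(noise, signal::fir1(64, 0.6, type = "low",
                                            window = signal::hamming(65)))
    y <- (1 - p$noise) * y + p$noise * noise / max(abs(noise))
    # attack/decay envelope; pulsed amplitude modulation for some categories
    atk <- pmin(tt / 0.05, 1)
    dec <- pmin((max(tt) - tt) / 0.08, 1)
    env <- atk * dec
    if (p$am > 0) env <- env * (0.55 + 0.45 * sin(2 * pi * p$am * tt)^2)
    y <- y * env
    out <- audio_clip(0.9 * y / max(abs(y)), sample_rate)
    attr(out, "category") <- category
    out
  })
}
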