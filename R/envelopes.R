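#' Amplitude-modulation envelopes
#'
#' An envelope is the slow modulation profile shared by the auditory stream
#' (amplitude of a pure tone) and the visual stream (size of a blob). It is
#' represented as a tibble with columns `time_s` and `amplitude` (unitless,
#' in \[0, 1\]) plus `sample_rate` and `label` attributes.
#'
#' @name envelope
NULL

new_envelope <- function(amplitude, sample_rate, label) {
  n <- length(amplitude)
  out <- tibble::tibble(
    time_s = seq(0, by = 1 / sample_rate, length.out = n),
    amplitude = amplitude
  )
  attr(out, "sample_rate") <- sample_rate
  attr(out, "label") <- label
  class(out) <- c("av_envelope", class(out))
  out
}

#' Sample rate, label and duration of an envelope
#'
#' @param env An envelope tibble created by [make_sinusoidal_envelope()],
#'   [make_quasi_rhythmic_envelope()] or [extract_envelope()].
#' @return `sample_rate()` and `env_duration()` return a scalar double;
#'   `env_label()` a string.
#' @export
sample_rate <- function(env) attr(env, "sample_rate")

#' @rdname sample_rate
#' @export
env_label <- function(env) attr(env, "label")

#' @rdname sample_rate
#' @export
env_duration <- function(env) nrow(env) / sample_rate(env)

#' Generate a sinusoidally modulated envelope
#'
#' Builds the raised-cosine modulation profile
#' \deqn{e(t) = (1 - \cos(2\pi f t)) / 2,}
#' which starts and ends at zero amplitude and contains exactly
#' `freq_hz * duration_s` pulses (local maxima). This is the regular
#' ("rhythmic") stream: a pure tone whose amplitude, and a blob whose
#' radius, follow `e(t)`.
#'
#' @param freq_hz Modulation frequency in Hz (> 0).
#' @param duration_s Stream duration in seconds (> 0).
#' @param sample_rate Samples per second; must be at least `20 * freq_hz`.
#' @param label Optional label; default `"rhythmic-<freq>Hz"`.
#' @return An envelope tibble (columns `time_s`, `amplitude`).
#' @examples
#' env <- make_sinusoidal_envelope(3, 3)
#' count_pulses(env) # 9
#' @export
make_sinusoidal_envelope <- function(freq_hz, duration_s, sample_rate = 1000,
                                     label = NULL) {
  if (!is.numeric(freq_hz) || length(freq_hz) != 1 || freq_hz <= 0) {
    abort("`freq_hz` must be a positive scalar.", class = "avtbw_invalid_argument")
  }
  if (!is.numeric(duration_s) || length(duration_s) != 1 || duration_s <= 0) {
    abort("`duration_s` must be a positive scalar.", class = "avtbw_invalid_argument")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 ||
      sample_rate < 20 * freq_hz) {
    abort("`sample_rate` must be at least 20 * freq_hz.",
          class = "avtbw_invalid_argument")
  }
  n <- round(duration_s * sample_rate)
  t <- seq(0, by = 1 / sample_rate, length.out = n)
  amp <- (1 - cos(2 * pi * freq_hz * t)) / 2
  if (is.null(label)) label <- sprintf("rhythmic-%gHz", freq_hz)
  new_envelope(amp, sample_rate, label)
}

#' Count envelope pulses
#'
#' A pulse is a strict local maximum of the sampled envelope: a sample
#' greater than both neighbours.
#'
#' @param env An envelope tibble.
#' @return Integer pulse count.
#' @export
count_pulses <- function(env) {
  a <- env$amplitude
  n <- length(a)
  if (n < 3) return(0L)
  mid <- a[2:(n - 1)]
  sum(mid > a[1:(n - 2)] & mid > a[3:n])
}

#' Resolve a stream specification to duration and pulse count
#'
#' Two designs are supported: `fixed_duration` holds the stream duration
#' constant across frequencies so pulse count scales with frequency
#' (3 s streams carry 3/6/9 pulses at 1/2/3 Hz); `fixed_pulses` holds the
#' pulse count constant so duration scales inversely (3 pulses last
#' 3/1.5/1 s at 1/2/3 Hz).
#'
#' @param mode `"fixed_duration"` or `"fixed_pulses"`.
#' @param freq_hz Modulation frequency in Hz.
#' @param value Duration in seconds (`fixed_duration`) or pulse count
#'   (`fixed_pulses`); must be positive, and the implied pulse count must
#'   come out a whole number.
#' @return A one-row tibble with `duration_s` and `n_pulses`.
#' @examples
#' make_stream_spec("fixed_pulses", freq_hz = 2, value = 3) # 1.5 s
#' @export
make_stream_spec <- function(mode = c("fixed_duration", "fixed_pulses"),
                             freq_hz, value) {
  mode <- match.arg(mode)
  if (!is.numeric(freq_hz) || freq_hz <= 0 || !is.numeric(value) || value <= 0) {
    abort("`freq_hz` and `value` must be positive.", class = "avtbw_invalid_argument")
  }
  if (mode == "fixed_duration") {
    duration_s <- value
    n_pulses <- freq_hz * value
  } else {
    n_pulses <- value
    duration_s <- value / freq_hz
  }
  if (abs(n_pulses - round(n_pulses)) > 1e-9 || round(n_pulses) < 1) {
    abort(sprintf("design implies a non-integer pulse count (%g)", n_pulses),
          class = "avtbw_invalid_design")
  }
  tibble::tibble(duration_s = duration_s, n_pulses = as.integer(round(n_pulses)))
}

#' Extract the amplitude envelope of an audio waveform
#'
#' Full-wave rectifies the waveform and applies a zero-phase Butterworth
#' low-pass (forward-backward filtering, so no group delay), then rescales
#' to \[0, 1\]. This recovers the slow modulation contour of, e.g., a
#' recorded sentence, from which speech-like stimuli are built.
#'
#' @param waveform Numeric vector of audio samples.
#' @param sample_rate Samples per second of `waveform`.
#' @param smoothing_cutoff Low-pass cutoff in Hz (default 10); must be
#'   below the Nyquist frequency.
#' @param label Label for the resulting envelope.
#' @return An envelope tibble at the waveform's sample rate.
#' @export
extract_envelope <- function(waveform, sample_rate, smoothing_cutoff = 10,
                             label = "extracted") {
  if (length(waveform) == 0) {
    abort("`waveform` is empty.", class = "avtbw_invalid_argument")
  }
  if (all(waveform == 0)) {
    abort("`waveform` is silent (all zeros); no envelope exists.",
          class = "avtbw_degenerate_input")
  }
  if (smoothing_cutoff >= sample_rate / 2) {
    abort("`smoothing_cutoff` must be below Nyquist (sample_rate / 2).",
          class = "avtbw_invalid_argument")
  }
  rect <- abs(waveform)
  bf <- signal::butter(4, smoothing_cutoff / (sample_rate / 2), type = "low")
  env <- signal::filtfilt(bf, rect)
  env <- pmax(env, 0)
  env <- env / max(env)
  new_envelope(env, sample_rate, label)
}

#' Power spectrum and dominant frequency of an envelope
#'
#' Removes the mean (DC), applies an FFT, and reports the frequency of
#' maximal power within a search band. Ties are broken toward the lower
#' frequency. Frequency resolution is `1 / duration`.
#'
#' @param env An envelope tibble.
#' @param band Two-element numeric, the search band in Hz
#'   (default `c(0.5, 10)`); must lie within `(0, sample_rate / 2)`.
#' @return A tibble (`frequency_hz`, `power`) restricted to positive
#'   frequencies, with attributes `dominant_frequency` (Hz; `NA` for a
#'   degenerate, DC-only spectrum) and `band`.
#' @seealso [dominant_frequency()]
#' @export
fft_dominant_frequency <- function(env, band = c(0.5, 10)) {
  sr <- sample_rate(env)
  dur <- env_duration(env)
  if (length(band) != 2 || band[1] >= band[2] || band[1] <= 0 ||
      band[2] > sr / 2) {
    abort("`band` must be an increasing pair within (0, sample_rate/2).",
          class = "avtbw_invalid_argument")
  }
  # the band is intersected with the resolvable range [1/duration, Nyquist]
  band <- c(max(band[1], 1 / dur), band[2])
  x <- env$amplitude - mean(env$amplitude)
  n <- length(x)
  pw <- Mod(fft(x))^2 / n
  freqs <- (seq_len(n) - 1) / dur
  keep <- seq_len(floor(n / 2)) + 1L  # positive frequencies only
  spec <- tibble::tibble(frequency_hz = freqs[keep], power = pw[keep])
  in_band <- spec$frequency_hz >= band[1] & spec$frequency_hz <= band[2]
  if (!any(in_band) ) {
    abort("search band contains no resolvable frequency bin.",
          class = "avtbw_invalid_argument")
  }
  band_pw <- spec$power[in_band]
  degenerate <- max(band_pw) <= n * 1e-20
  dom <- if (degenerate) {
    NA_real_
  } else {
    # ties (within float jitter) go to the lower frequency; bins ascend
    at_max <- band_pw >= max(band_pw) * (1 - 1e-9)
    spec$frequency_hz[in_band][which(at_max)[1]]
  }
  attr(spec, "dominant_frequency") <- dom
  attr(spec, "band") <- band
  attr(spec, "degenerate") <- degenerate
  class(spec) <- c("av_spectrum", class(spec))
  spec
}

#' @rdname fft_dominant_frequency
#' @param x An envelope or a spectrum returned by [fft_dominant_frequency()].
#' @param ... Passed on to [fft_dominant_frequency()] when `x` is an envelope.
#' @export
dominant_frequency <- function(x, ...) {
  if (inherits(x, "av_spectrum")) return(attr(x, "dominant_frequency"))
  attr(fft_dominant_frequency(x, ...), "dominant_frequency")
}

#' Generate a quasi-rhythmic (speech-like) envelope
#'
#' Emulates the syllabic amplitude contour of natural speech: a pulse train
#' whose inter-pulse intervals are drawn around `1 / mean_freq` with a given
#' coefficient of variation (Gamma-distributed, so always positive), whose
#' pulse amplitudes vary with their own CV, smoothed by a raised-cosine
#' kernel of width `1 / (2 * mean_freq)`. With both CVs at zero it collapses
#' bit-exactly to the regular train under the same kernel.
#'
#' @param mean_freq Mean pulse rate in Hz.
#' @param jitter_cv Coefficient of variation of inter-pulse intervals,
#'   in \[0, 0.5\].
#' @param amp_cv Coefficient of variation of pulse amplitudes, in \[0, 0.5\].
#' @param duration_s Stream duration in seconds.
#' @param sample_rate Samples per second.
#' @param seed Integer seed; the output is a deterministic function of it.
#' @param label Optional label; default `"speech-like-<seed>"`.
#' @return An envelope tibble normalized to peak 1.
#' @examples
#' env <- make_quasi_rhythmic_envelope(3, 0.2, 0.3, 3, seed = 1)
#' dominant_frequency(env)
#' @export
make_quasi_rhythmic_envelope <- function(mean_freq, jitter_cv = 0.2,
                                         amp_cv = 0.3, duration_s = 3,
                                         sample_rate = 1000, seed = 1,
                                         label = NULL) {
  if (mean_freq <= 0 || duration_s <= 0 || sample_rate <= 0) {
    abort("`mean_freq`, `duration_s`, `sample_rate` must be positive.",
          class = "avtbw_invalid_argument")
  }
  if (jitter_cv < 0 || jitter_cv > 0.5 || amp_cv < 0 || amp_cv > 0.5) {
    abort("`jitter_cv` and `amp_cv` must lie in [0, 0.5].",
          class = "avtbw_invalid_argument")
  }
  mean_ipi <- 1 / mean_freq
  n_target <- floor(duration_s * mean_freq)
  draws <- local_rng(seed)(function() {
    # first pulse centred half an interval in, as in the regular train
    ipis <- if (jitter_cv == 0) rep(mean_ipi, n_target) else {
      shape <- 1 / jitter_cv^2
      raw <- rgamma(n_target, shape = shape, scale = mean_ipi / shape)
      # renormalize so the token keeps its overall rate: jitter perturbs
      # individual intervals, not the syllable count of the 3 s token
      raw * (n_target * mean_ipi) / sum(raw)
    }
    centers <- mean_ipi / 2 + c(0, cumsum(ipis[-length(ipis)]))
    centers <- centers[centers < duration_s]
    amps <- if (amp_cv == 0) rep(1, length(centers)) else {
      shape_a <- 1 / amp_cv^2
      rgamma(length(centers), shape = shape_a, scale = 1 / shape_a)
    }
    list(centers = centers, amps = amps)
  })
  centers <- draws$centers
  amps <- draws$amps
  k <- length(centers)
  n <- round(duration_s * sample_rate)
  t <- seq(0, by = 1 / sample_rate, length.out = n)
  width <- 1 / (2 * mean_freq)  # raised-cosine kernel full width
  amp <- numeric(n)
  for (i in seq_len(k)) {
    u <- (t - centers[i]) / width
    in_k <- abs(u) <= 0.5
    amp[in_k] <- amp[in_k] + amps[i] * (1 + cos(2 * pi * u[in_k])) / 2
  }
  if (max(amp) > 0) amp <- amp / max(amp)
  if (is.null(label)) label <- sprintf("speech-like-%02d", seed)
  new_envelope(amp, sample_rate, label)
}

# run fn under a private RNG stream seeded by `seed`
local_rng <- function(seed) {
  function(fn) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    fn()
  }
}

#' Filter envelopes by dominant frequency
#'
#' Keeps exactly those envelopes whose FFT dominant frequency falls within
#' `target_freq +/- tol` (inclusive), preserving input order. This is the
#' selection gate for speech-like tokens with a clear spectral peak near
#' the target modulation rate.
#'
#' @param envelopes A list of envelope tibbles.
#' @param target_freq Target dominant frequency in Hz (default 3).
#' @param tol Acceptance half-width in Hz (default 0.5; `tol = 0` keeps
#'   exact matches only).
#' @param band Search band passed to [fft_dominant_frequency()].
#' @return The accepted sub-list of `envelopes` (possibly empty).
#' @export
select_speech_like <- function(envelopes, target_freq = 3, tol = 0.5,
                               band = c(0.5, 10)) {
  if (tol < 0) abort("`tol` must be nonnegative.", class = "avtbw_invalid_argument")
  if (length(envelopes) == 0) return(list())
  doms <- purrr::map_dbl(envelopes, dominant_frequency, band = band)
  keep <- !is.na(doms) & doms >= target_freq - tol & doms <= target_freq + tol
  envelopes[keep]
}

#' Assemble an SOA-shifted audio-visual envelope pair
#'
#' Produces time-aligned auditory and visual tracks from one envelope,
#' offset by a stimulus onset asynchrony. Negative `soa_ms` means the
#' auditory stream leads (the visual onset is delayed by `|soa_ms|`);
#' positive means the visual stream leads. The leading track is zero-padded
#' at its tail and the lagging at its head, so both tracks span
#' `duration + |soa_ms| / 1000` seconds.
#'
#' @param env An envelope tibble.
#' @param soa_ms Signed stimulus onset asynchrony in milliseconds.
#' @param max_soa_ms Largest admissible `|soa_ms|` (default 500).
#' @return A tibble with columns `time_s`, `audio`, `visual` and attributes
#'   `soa_ms` and `sample_rate`.
#' @export
render_av_pair <- function(env, soa_ms, max_soa_ms = 500) {
  if (abs(soa_ms) > max_soa_ms) {
    abort(sprintf("|soa_ms| exceeds the configured maximum (%g ms).", max_soa_ms),
          class = "avtbw_invalid_argument")
  }
  sr <- sample_rate(env)
  shift <- round(abs(soa_ms) / 1000 * sr)
  a <- env$amplitude
  pad <- numeric(shift)
  if (soa_ms < 0) {        # auditory leads: delay the visual track
    audio <- c(a, pad)
    visual <- c(pad, a)
  } else {                 # visual leads (or zero): delay the auditory track
    audio <- c(pad, a)
    visual <- c(a, pad)
  }
  out <- tibble::tibble(
    time_s = seq(0, by = 1 / sr, length.out = length(audio)),
    audio = audio,
    visual = visual
  )
  attr(out, "soa_ms") <- soa_ms
  attr(out, "sample_rate") <- sr
  class(out) <- c("av_pair", class(out))
  out
}

#' Write an envelope to CSV
#'
#' @param env An envelope tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_envelope_csv <- function(env, path) {
  readr::write_csv(tibble::tibble(time_s = env$time_s, amplitude = env$amplitude),
                   path)
  invisible(path)
}
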