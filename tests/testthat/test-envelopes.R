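test_that("sinusoidal envelopes have f*d pulses, start at zero, peak at one", {
  cases <- expand.grid(f = c(1, 2, 3), d = c(1, 1.5, 3))
  cases <- cases[abs(cases$f * cases$d - round(cases$f * cases$d)) < 1e-9, ]
  for (i in seq_len(nrow(cases))) {
    f <- cases$f[i]; d <- cases$d[i]
    env <- make_sinusoidal_envelope(f, d, 1000)
    expect_equal(count_pulses(env), round(f * d), label = sprintf("f=%g d=%g", f, d))
    expect_equal(env$amplitude[1], 0)
    expect_equal(max(env$amplitude), 1, tolerance = 1e-9)
    expect_gte(min(env$amplitude), 0)
  }
})

test_that("sinusoid vanishes at whole periods and errors on bad arguments", {
  env <- make_sinusoidal_envelope(2, 3, 1000)
  # t = k/f lands on the sample grid at this rate
  at_periods <- env$amplitude[round(seq(0, 2.5, by = 0.5) * 1000) + 1]
  expect_equal(at_periods, rep(0, 6), tolerance = 1e-12)
  expect_error(make_sinusoidal_envelope(-1, 3), class = "avtbw_invalid_argument")
  expect_error(make_sinusoidal_envelope(3, 0), class = "avtbw_invalid_argument")
  expect_error(make_sinusoidal_envelope(3, 3, sample_rate = 30),
               class = "avtbw_invalid_argument")
})

test_that("stream specs resolve duration/pulse arithmetic both ways", {
  expect_equal(make_stream_spec("fixed_pulses", 2, 3)$duration_s, 1.5)
  expect_equal(make_stream_spec("fixed_pulses", 1, 3)$duration_s, 3)
  expect_equal(make_stream_spec("fixed_duration", 3, 3)$n_pulses, 9L)
  expect_equal(make_stream_spec("fixed_duration", 1, 3)$n_pulses, 3L)
  expect_error(make_stream_spec("fixed_duration", 1.5, 3.1),
               class = "avtbw_invalid_design")
  expect_error(make_stream_spec("fixed_pulses", 2, -1),
               class = "avtbw_invalid_argument")
})

test_that("envelope extraction recovers a known modulator", {
  sr <- 8000
  t <- seq(0, 3 - 1 / sr, by = 1 / sr)
  modulator <- (1 - cos(2 * pi * 3 * t)) / 2
  waveform <- modulator * sin(2 * pi * 500 * t)
  env <- extract_envelope(waveform, sr)
  expect_gt(cor(env$amplitude, modulator), 0.99)

  # flat tone -> flat envelope (ignore filter edge transients)
  flat <- extract_envelope(sin(2 * pi * 500 * t), sr)
  core <- flat$amplitude[(sr %/% 2):(length(t) - sr %/% 2)]
  expect_lt(sd(core) / mean(core), 0.01)

  # 2 Hz modulator -> 2 Hz dominant frequency of the extracted envelope
  env2 <- extract_envelope(((1 - cos(2 * pi * 2 * t)) / 2) * sin(2 * pi * 500 * t), sr)
  expect_equal(dominant_frequency(env2), 2, tolerance = 1 / 3)

  expect_error(extract_envelope(numeric(0), sr), class = "avtbw_invalid_argument")
  expect_error(extract_envelope(rep(0, 100), sr), class = "avtbw_degenerate_input")
})

test_that("FFT dominant frequency finds nominal rates and handles ties and DC", {
  for (f in c(1, 2, 3)) {
    for (d in c(1.5, 3)) {
      env <- make_sinusoidal_envelope(f, d, 1000)
      expect_equal(dominant_frequency(env), f, tolerance = 1 / d + 1e-9,
                   label = sprintf("f=%g d=%g", f, d))
    }
  }
  # constant envelope: DC only, removed -> degenerate spectrum
  const <- make_sinusoidal_envelope(1, 3, 1000)
  const$amplitude <- rep(0.5, nrow(const))
  spec <- fft_dominant_frequency(const)
  expect_true(attr(spec, "degenerate"))
  expect_true(is.na(attr(spec, "dominant_frequency")))

  # equal-power 2 Hz + 3 Hz components: tie goes to the lower frequency
  t <- seq(0, 3 - 1e-3, by = 1e-3)
  two <- make_sinusoidal_envelope(1, 3, 1000)
  x <- cos(2 * pi * 2 * t) + cos(2 * pi * 3 * t)
  two$amplitude <- (x - min(x)) / (max(x) - min(x))
  expect_equal(dominant_frequency(two), 2)

  expect_error(fft_dominant_frequency(make_sinusoidal_envelope(3, 3), band = c(20, 10)),
               class = "avtbw_invalid_argument")
})

test_that("quasi-rhythmic generation is seeded, collapses at zero jitter, stays near rate", {
  a <- make_quasi_rhythmic_envelope(3, 0.2, 0.3, 3, seed = 7)
  b <- make_quasi_rhythmic_envelope(3, 0.2, 0.3, 3, seed = 7)
  expect_identical(a$amplitude, b$amplitude)
  expect_false(identical(
    a$amplitude,
    make_quasi_rhythmic_envelope(3, 0.2, 0.3, 3, seed = 8)$amplitude
  ))

  reg <- make_quasi_rhythmic_envelope(3, 0, 0, 3, seed = 1)
  expect_equal(count_pulses(reg), 9)
  peaks <- reg$time_s[-c(1, nrow(reg))][
    reg$amplitude[2:(nrow(reg) - 1)] > reg$amplitude[1:(nrow(reg) - 2)] &
    reg$amplitude[2:(nrow(reg) - 1)] > reg$amplitude[3:nrow(reg)]]
  # spacing regular up to the 1 ms sample grid
  expect_lte(sd(diff(peaks)), 2e-3)
  # seed must not matter when nothing is drawn
  expect_identical(reg$amplitude,
                   make_quasi_rhythmic_envelope(3, 0, 0, 3, seed = 99)$amplitude)

  jit <- make_quasi_rhythmic_envelope(3, 0.2, 0.3, 3, seed = 1)
  expect_gte(dominant_frequency(jit), 2.5)
  expect_lte(dominant_frequency(jit), 3.5)
  expect_equal(max(jit$amplitude), 1)
  expect_gte(min(jit$amplitude), 0)

  expect_error(make_quasi_rhythmic_envelope(3, 0.7, 0, 3),
               class = "avtbw_invalid_argument")
})

test_that("speech-like selection keeps envelopes near the target peak, in order", {
  # 5 s duration makes 3.0 / 3.2 / 5.0 Hz exact FFT bins
  mk <- function(f) {
    env <- make_sinusoidal_envelope(1, 5, 1000)
    env$amplitude <- (1 - cos(2 * pi * f * env$time_s)) / 2
    attr(env, "label") <- sprintf("peak-%g", f)
    env
  }
  envs <- list(mk(3.0), mk(3.2), mk(5.0))
  kept <- select_speech_like(envs, target_freq = 3, tol = 0.5)
  expect_equal(purrr::map_chr(kept, env_label), c("peak-3", "peak-3.2"))

  exact <- select_speech_like(envs, target_freq = 3, tol = 0)
  expect_equal(purrr::map_chr(exact, env_label), "peak-3")

  expect_equal(select_speech_like(list(), 3, 0.5), list())
})

test_that("AV pair rendering shifts, pads with zeros, and conserves energy", {
  env <- make_sinusoidal_envelope(3, 3, 1000)

  zero <- render_av_pair(env, 0)
  expect_identical(zero$audio, zero$visual)

  al <- render_av_pair(env, -500)
  expect_equal(nrow(al), 3500)
  expect_equal(al$visual[1:500], rep(0, 500))
  expect_equal(al$visual[501:3500], env$amplitude)
  expect_equal(al$audio[1:3000], env$amplitude)
  expect_equal(al$audio[3001:3500], rep(0, 500))

  vl <- render_av_pair(env, 500)
  expect_identical(al$audio, vl$visual)
  expect_identical(al$visual, vl$audio)

  for (soa in c(-300, 0, 200)) {
    pair <- render_av_pair(env, soa)
    expect_equal(sum(pair$audio^2), sum(env$amplitude^2))
    expect_equal(sum(pair$visual^2), sum(env$amplitude^2))
  }

  expect_error(render_av_pair(env, 700), class = "avtbw_invalid_argument")
})
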