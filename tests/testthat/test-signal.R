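mk <- function(...) synthesizeEGM(...)

test_that("the filter chain is null on silence and rejects out-of-band tones", {
  z <- new("EGMTrace", t = 0:3999, phi = numeric(4000),
           electrode = electrode(0, 0, 200))
  expect_true(all(abs(preprocessEGM(z)) < 1e-12))
  expect_error(preprocessEGM(new("EGMTrace", t = 0:99, phi = numeric(100),
                                 electrode = electrode(0, 0, 200))),
               "warm-up")

  # a 5 Hz sinusoid sits below the 40 Hz band edge
  tt <- 0:7999
  tone <- new("EGMTrace", t = tt, phi = sin(2 * pi * 5 * tt / 1000),
              electrode = electrode(0, 0, 200))
  y <- preprocessEGM(tone)
  expect_lt(sum(y^2) / sum(tone@phi^2), 0.01)
})

test_that("the chain demodulates burst trains to their repetition rate", {
  # 100 Hz bursts repeating at 5 Hz: the envelope carries the 5 Hz rhythm
  tt <- 0:7999
  burst <- ifelse((tt %% 200) < 30, sin(2 * pi * 100 * tt / 1000), 0)
  eg <- new("EGMTrace", t = tt, phi = burst, electrode = electrode(0, 0, 200))
  sp <- egmSpectrum(eg)
  expect_equal(sp@df, 5, tolerance = 0.07)
})

test_that("periodic trains report their activation rate as DF", {
  # the flutter and ectopic-focus cycle lengths
  expect_equal(egmSpectrum(mk(cl = 200, duration = 8000))@df, 5.0,
               tolerance = 0.07)
  expect_equal(egmSpectrum(mk(cl = 130, duration = 8000))@df, 1000 / 130,
               tolerance = 0.07)

  # exhaustive sweep: DF equals the nearest spectral bin to 1/CL
  sp0 <- egmSpectrum(mk(cl = 200, duration = 8000))
  binw <- diff(sp0@freqs[1:2])
  expect_lte(binw, 0.12)
  for (cl in seq(120, 250, by = 10)) {
    sp <- egmSpectrum(mk(cl = cl, duration = 8000))
    expect_lt(abs(sp@df - 1000 / cl), binw, label = paste("CL", cl))
  }
})

test_that("DF and OI are invariant to amplitude scaling", {
  a <- mk(cl = 160, duration = 8000)
  b <- new("EGMTrace", t = a@t, phi = 10 * a@phi, electrode = a@electrode)
  sa <- egmSpectrum(a); sb <- egmSpectrum(b)
  expect_identical(sa@df, sb@df)
  expect_equal(sa@oi, sb@oi, tolerance = 1e-12)
})

test_that("the organization index is bounded and behaves under noise", {
  sp <- egmSpectrum(mk(cl = 200, duration = 8000))
  expect_gte(sp@oi, 0.9)
  expect_lte(sp@oi, 1)

  # added broadband noise strictly lowers OI (fixed seed)
  noisy <- egmSpectrum(mk(cl = 200, duration = 8000, noiseSd = 0.5, seed = 42))
  expect_lt(noisy@oi, sp@oi)
  expect_gte(noisy@oi, 0)

  # two incommensurate trains split the spectrum
  a <- mk(cl = 130, duration = 8000)
  b <- mk(cl = 190, duration = 8000)
  ab <- new("EGMTrace", t = a@t, phi = a@phi + b@phi, electrode = a@electrode)
  oi_ab <- egmSpectrum(ab)@oi
  expect_lt(oi_ab, egmSpectrum(a)@oi)
  expect_lt(oi_ab, egmSpectrum(b)@oi)
})

test_that("spectral estimates match a direct DFT oracle", {
  eg <- mk(cl = 170, duration = 4000)
  x <- preprocessEGM(eg)
  sp <- egmSpectrum(x)
  n <- 2 * length(sp@freqs)
  xp <- c(x - mean(x), numeric(n - length(x)))
  set.seed(7)
  for (k in sample(seq_along(sp@freqs), 25)) {
    w <- exp(-2i * pi * (k - 1) * (seq_len(n) - 1) / n)
    expect_equal(sp@power[k], Mod(sum(xp * w))^2,
                 tolerance = 1e-9 * max(sp@power))
  }
})

test_that("cycle lengths recover the generator's timing", {
  cl <- cycleLengths(mk(cl = 200, duration = 8000))
  expect_true(all(abs(cl$cl - 200) <= 1))

  jit <- cycleLengths(mk(cl = 200, duration = 8000, jitterSd = 15, seed = 3))
  expect_equal(sd(jit$cl), 15 * sqrt(2), tolerance = 0.3)

  expect_error(cycleLengths(mk(cl = 5000, duration = 4000)), "fewer than 2")
})

test_that("morphology classes match their generators on seeded fixtures", {
  set.seed(20)
  cases <- data.frame(
    morph = sample(c("single", "double", "cfae"), 200, replace = TRUE),
    cl = sample(seq(160, 260, by = 10), 200, replace = TRUE),
    seed = 1:200)
  hit <- logical(nrow(cases))
  for (i in seq_len(nrow(cases))) {
    eg <- mk(cl = cases$cl[i], duration = 3000, morphology = cases$morph[i],
             jitterSd = 4, noiseSd = 0.02, seed = cases$seed[i])
    hit[i] <- classifyMorphology(eg)@morphology == cases$morph[i]
  }
  expect_gte(mean(hit), 0.95)
})

test_that("morphology windows implement the definitions", {
  expect_equal(classifyMorphology(mk(cl = 300, duration = 2000))@morphology,
               "single")
  expect_equal(classifyMorphology(mk(cl = 300, duration = 2000,
                                     morphology = "double"))@morphology,
               "double")
  expect_equal(classifyMorphology(mk(cl = 300, duration = 2000,
                                     morphology = "cfae"))@morphology,
               "cfae")
  flat <- new("EGMTrace", t = 0:999, phi = numeric(1000),
              electrode = electrode(0, 0, 200))
  expect_equal(classifyMorphology(flat)@morphology, "no activity")
})
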