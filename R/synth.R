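## Synthetic electrogram generator: periodic trains of template complexes
## with controllable cycle length, morphology, timing jitter and additive
## noise, for testing the analysis chain without tissue simulations.

# unit-amplitude complex templates sampled at 1 kHz, centred in their support
.egmTemplate <- function(morphology) {
  g <- function(mu, sig, tt) exp(-((tt - mu) / sig)^2)
  switch(morphology,
    single = {
      # biphasic RS complex: derivative-of-Gaussian, positive phase first
      tt <- 0:40
      w <- -(tt - 20) / 6 * g(20, 6, tt)
      w / max(abs(w))
    },
    double = {
      # two negative deflections 40 ms apart, second smaller
      tt <- 0:70
      w <- -g(15, 4, tt) - 0.7 * g(55, 4, tt)
      w / max(abs(w))
    },
    cfae = {
      # five alternating low-amplitude deflections spanning ~60 ms, no gap
      tt <- 0:70
      w <- 0.55 * g(8, 5, tt) - 0.8 * g(21, 5, tt) + 0.6 * g(34, 5, tt) -
        0.9 * g(47, 5, tt) + 0.5 * g(60, 5, tt)
      w / max(abs(w))
    },
    stop("unknown morphology: ", morphology))
}

#' Generate a synthetic electrogram train
#'
#' A periodic train of template activation complexes (single biphasic,
#' double-potential, or fractionated) at a given cycle length, with optional
#' Gaussian timing jitter and additive white noise.  Useful as ground truth
#' for the spectral and morphology pipeline.
#'
#' @param cl cycle length, ms
#' @param duration total duration, ms
#' @param morphology "single", "double" or "cfae"
#' @param jitterSd standard deviation of activation-time jitter, ms
#' @param noiseSd additive white-noise standard deviation, relative to unit
#'   complex amplitude
#' @param seed optional integer seed (local to this call)
#' @param amplitude complex amplitude (arbitrary units)
#' @return an \linkS4class{EGMTrace} at 1 kHz
#' @examples
#' eg <- synthesizeEGM(cl = 200, duration = 8000)
#' egmSpectrum(eg)@df   # 5 Hz
#' @export
synthesizeEGM <- function(cl, duration = 8000, morphology = "single",
                          jitterSd = 0, noiseSd = 0, seed = NULL,
                          amplitude = 1) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  n <- as.integer(duration)
  x <- numeric(n)
  w <- .egmTemplate(morphology) * amplitude
  lw <- length(w)
  t0 <- seq(50, duration - lw - 10, by = cl)
  if (jitterSd > 0) t0 <- t0 + round(stats::rnorm(length(t0), 0, jitterSd))
  t0 <- t0[t0 >= 0 & t0 + lw <= n]
  for (s in t0) x[(s + 1):(s + lw)] <- x[(s + 1):(s + lw)] + w
  if (noiseSd > 0) x <- x + stats::rnorm(n, 0, noiseSd * amplitude)
  new("EGMTrace", t = seq_len(n) - 1, phi = x,
      electrode = electrode(0, 0, 200))
}
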