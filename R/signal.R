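## Electrogram processing chain: 40-250 Hz band-pass -> rectification ->
## 20 Hz low-pass (all zero-phase 4th-order Butterworth), FFT spectrum at
## <= 0.12 Hz resolution, dominant frequency, organization index, cycle
## lengths, and single/double/CFAE morphology classification.

.FS <- 1000  # Hz; the 1 ms sampling cadence of the simulated electrograms

.egmValues <- function(egm) {
  if (is(egm, "EGMTrace")) list(t = egm@t, x = egm@phi)
  else if (is.list(egm)) list(t = egm$t, x = if (!is.null(egm$phi)) egm$phi else egm$x)
  else stop("expected an EGMTrace or a list with t and phi")
}

#' Preprocess an electrogram
#'
#' Band-pass 40-250 Hz, rectify (absolute value), low-pass 20 Hz; both
#' filters are 4th-order Butterworth applied forward-backward for zero
#' phase, so activation timing is preserved for cycle-length extraction.
#' The chain demodulates sharp activation complexes into a smooth
#' activation-rate envelope.
#'
#' @param egm an \linkS4class{EGMTrace} (1 kHz sampling)
#' @return numeric envelope, same length as the input
#' @export
preprocessEGM <- function(egm) {
  v <- .egmValues(egm)
  if (length(v$x) < 500) stop("trace shorter than the filter warm-up (500 ms)")
  bp <- signal::butter(4, c(40, 250) / (.FS / 2), type = "pass")
  lp <- signal::butter(4, 20 / (.FS / 2), type = "low")
  y <- signal::filtfilt(bp, v$x)
  y <- abs(y)
  signal::filtfilt(lp, y)
}

#' Power spectrum of a processed electrogram
#'
#' FFT magnitude-squared with zero-padding to reach the requested spectral
#' resolution (0.12 Hz or finer); rectangular window.  The dominant
#' frequency is the highest spectral peak within the analysis band
#' (2-20 Hz); ties break toward the lower frequency.  The organization
#' index is computed per \code{\link{organizationIndex}}.
#'
#' @param x processed envelope (from \code{\link{preprocessEGM}}) or an
#'   \linkS4class{EGMTrace} to be preprocessed first
#' @param resolution maximum spectral bin width, Hz
#' @param band DF search band and OI total-power band, Hz
#' @return a \linkS4class{SpectralResult}
#' @export
egmSpectrum <- function(x, resolution = 0.12, band = c(2, 20)) {
  if (is(x, "EGMTrace")) x <- preprocessEGM(x)
  if (length(x) < 4 * .FS) stop("need at least 4 s of signal for spectral analysis")
  x <- x - mean(x)
  nfft <- 2^ceiling(log2(.FS / resolution))
  nfft <- max(nfft, length(x))
  X <- fft(c(x, numeric(nfft - length(x))))
  nf <- floor(nfft / 2)
  freqs <- (seq_len(nf) - 1) * .FS / nfft
  power <- Mod(X[seq_len(nf)])^2
  inband <- which(freqs >= band[1] & freqs <= band[2])
  if (max(power[inband]) <= .Machine$double.eps * 100) {
    return(new("SpectralResult", freqs = freqs, power = power,
               df = NA_real_, oi = NA_real_, band = band))
  }
  # ties toward the lower frequency: which.max takes the first maximum
  df <- freqs[inband[which.max(power[inband])]]
  sp <- new("SpectralResult", freqs = freqs, power = power, df = df,
            oi = NA_real_, band = band)
  sp@oi <- organizationIndex(sp)
  sp
}

#' Organization index of a spectrum
#'
#' Ratio of the spectral power under the dominant-frequency peak and its
#' three harmonics (each over a 0.75 Hz window; overlapping windows are
#' merged so power is not double-counted) to the total power in the
#' analysis band.
#'
#' @param spec a \linkS4class{SpectralResult} with a defined DF
#' @param window harmonic window width, Hz
#' @return organization index in [0, 1]
#' @export
organizationIndex <- function(spec, window = 0.75) {
  stopifnot(is(spec, "SpectralResult"))
  if (is.na(spec@df)) stop("DF undefined; cannot compute the organization index")
  f <- spec@freqs; p <- spec@power; band <- spec@band
  inband <- f >= band[1] & f <= band[2]
  total <- sum(p[inband])
  if (total <= 0) return(NA_real_)
  centers <- spec@df * 1:4
  lo <- centers - window / 2; hi <- centers + window / 2
  # merge overlapping harmonic windows
  keep <- rep(FALSE, length(f))
  for (k in seq_along(centers))
    keep <- keep | (f >= lo[k] & f <= hi[k])
  harm <- sum(p[keep & inband])
  min(1, harm / total)
}

#' Activation times and cycle lengths from a processed envelope
#'
#' Activations are detected as local maxima of the envelope above a fraction
#' of its global maximum, separated by a refractory distance; cycle lengths
#' are the successive differences.
#'
#' @param x processed envelope or an \linkS4class{EGMTrace}
#' @param threshold detection threshold as a fraction of the envelope maximum
#' @param refractory minimum separation between activations, ms
#' @return list with \code{times} (ms) and \code{cl} (ms)
#' @export
cycleLengths <- function(x, threshold = 0.3, refractory = 60) {
  if (is(x, "EGMTrace")) x <- preprocessEGM(x)
  n <- length(x)
  thr <- threshold * max(x)
  if (thr <= 0) stop("flat envelope: no activations")
  pk <- which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n] &
              x[2:(n - 1)] >= thr) + 1L
  # enforce refractory separation, keeping the larger peak
  keep <- integer(0)
  for (i in pk) {
    if (length(keep) && i - keep[length(keep)] < refractory) {
      if (x[i] > x[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  if (length(keep) < 2) stop("fewer than 2 activations detected")
  times <- keep - 1  # 1 kHz: sample index -> ms
  list(times = times, cl = diff(times))
}

#' Classify electrogram morphology
#'
#' Works on the raw (unrectified) electrogram.  Activation windows are
#' 90 ms, centred on envelope peaks; complexes closer than 50 ms merge into
#' one window.  Within each window, deflections are signed lobes exceeding
#' 10% of the trace's maximum absolute deflection.  Continuity of activity
#' is judged on the slope magnitude |d phi/dt| (lightly smoothed), where
#' slow repolarization waves vanish and only fast activation deflections
#' remain: isoelectric means the slope stays below 15% of its maximum for
#' at least 10 ms.  A window is CFAE when fast activity is continuous for
#' more than
#' 50 ms without an isoelectric interval; double when it contains exactly
#' two negative deflections; CFAE when it has more than two deflections;
#' single otherwise.  The trace-level class is the most complex window
#' class (cfae > double > single).
#'
#' @param egm an \linkS4class{EGMTrace} (raw)
#' @param deflectionFrac deflection threshold, fraction of max |phi|
#' @param isoFrac isoelectric (slope) threshold, fraction of max slope
#' @param windowMs activation window length, ms
#' @param mergeMs complexes closer than this merge into one window, ms
#' @return a \linkS4class{MorphologyCall}
#' @export
classifyMorphology <- function(egm, deflectionFrac = 0.1, isoFrac = 0.15,
                               windowMs = 90, mergeMs = 50) {
  v <- .egmValues(egm)
  x <- v$x
  amax <- max(abs(x))
  emptycall <- function(cls) new("MorphologyCall", morphology = cls,
    windows = data.frame(), deflections = data.frame())
  if (amax <= .Machine$double.eps * 100) return(emptycall("no activity"))
  env <- preprocessEGM(egm)
  acts <- tryCatch(cycleLengths(env, threshold = 0.25)$times,
                   error = function(e) NULL)
  if (is.null(acts)) {
    pk <- which.max(env) - 1
    acts <- pk
  }
  # build windows centred on activations; complexes closer than 50 ms merge
  # into one window (this is what lets the continuous-activity CFAE rule see
  # them as one episode)
  st <- acts - windowMs / 2; en <- acts + windowMs / 2
  merged <- list()
  last_act <- -Inf
  for (k in seq_along(st)) {
    if (length(merged) && acts[k] - last_act < mergeMs)
      merged[[length(merged)]][2] <- en[k]
    else merged[[length(merged) + 1]] <- c(st[k], en[k])
    last_act <- acts[k]
  }
  thr <- deflectionFrac * amax
  # activity indicator: slope magnitude of the lightly smoothed trace
  xs <- as.numeric(stats::filter(x, rep(1 / 3, 3), sides = 2))
  xs[is.na(xs)] <- x[is.na(xs)]
  xf <- c(abs(diff(xs)), 0)
  iso <- isoFrac * max(xf)
  t0 <- v$t[1]
  win_rows <- list(); defl_rows <- list()
  for (w in merged) {
    i1 <- max(1L, floor(w[1] - t0) + 1L)
    i2 <- min(length(x), ceiling(w[2] - t0) + 1L)
    seg <- x[i1:i2]
    d <- .deflections(seg, thr)
    nneg <- sum(d$polarity == "negative")
    cont <- .longestActiveRun(xf[i1:i2], iso, minGap = 10, signed = FALSE)
    cls <- if (cont > 50) "cfae"
    else if (nneg == 2) "double"
    else if (nrow(d) > 2) "cfae"
    else "single"
    win_rows[[length(win_rows) + 1]] <- data.frame(
      start = v$t[i1], end = v$t[i2], class = cls,
      nDeflections = nrow(d), nNegative = nneg, continuousMs = cont)
    if (nrow(d)) {
      d$t <- v$t[i1] + d$t
      defl_rows[[length(defl_rows) + 1]] <- d
    }
  }
  wins <- do.call(rbind, win_rows)
  defl <- if (length(defl_rows)) do.call(rbind, defl_rows) else
    data.frame(t = numeric(), polarity = character(), amplitude = numeric())
  lev <- c("single", "double", "cfae")
  cls <- lev[max(match(wins$class, lev))]
  new("MorphologyCall", morphology = cls, windows = wins, deflections = defl)
}

# signed lobes exceeding the threshold: contiguous runs of |x| >= thr with a
# single sign; returns peak time (ms, window-relative), polarity, amplitude
# as a fraction of the window maximum.  Same-polarity lobes closer than
# 10 ms are one deflection (noise riding on a slope can split a lobe at the
# threshold boundary); the larger peak is kept.
.deflections <- function(seg, thr) {
  sgn <- ifelse(seg >= thr, 1L, ifelse(seg <= -thr, -1L, 0L))
  out <- data.frame(t = numeric(), polarity = character(),
                    amplitude = numeric(), stringsAsFactors = FALSE)
  n <- length(sgn)
  i <- 1L
  mx <- max(abs(seg))
  while (i <= n) {
    if (sgn[i] == 0L) { i <- i + 1L; next }
    j <- i
    while (j < n && sgn[j + 1L] == sgn[i]) j <- j + 1L
    pk <- i - 1L + which.max(abs(seg[i:j]))
    k <- nrow(out)
    pol <- if (sgn[i] > 0) "positive" else "negative"
    if (k > 0 && out$polarity[k] == pol && (pk - 1) - out$t[k] < 10) {
      if (abs(seg[pk]) / mx > out$amplitude[k]) {
        out$t[k] <- pk - 1
        out$amplitude[k] <- abs(seg[pk]) / mx
      }
    } else {
      out <- rbind(out, data.frame(
        t = pk - 1, polarity = pol,
        amplitude = abs(seg[pk]) / mx, stringsAsFactors = FALSE))
    }
    i <- j + 1L
  }
  out
}

# longest run (ms) of continuous activity: |x| above iso without any
# isoelectric interval of at least minGap ms
.longestActiveRun <- function(seg, iso, minGap = 10, signed = TRUE) {
  quiet <- (if (signed) abs(seg) else seg) < iso
  n <- length(seg)
  # positions where an isoelectric gap (>= minGap quiet samples) occurs
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  breaks <- c(0)
  for (k in seq_along(r$lengths))
    if (r$values[k] && r$lengths[k] >= minGap)
      breaks <- c(breaks, starts[k], ends[k])
  breaks <- c(breaks, n + 1)
  best <- 0
  for (k in seq(1, length(breaks) - 1, by = 2)) {
    i1 <- breaks[k] + 1; i2 <- breaks[k + 1] - 1
    if (i2 < i1) next
    act <- which(abs(seg[i1:i2]) >= iso)
    if (length(act)) best <- max(best, max(act) - min(act) + 1)
  }
  best
}

#' Per-electrode analysis table
#'
#' Runs the full processing chain over a list of electrograms and collects
#' DF, OI, morphology class and cycle-length statistics per electrode.
#'
#' @param egms list of \linkS4class{EGMTrace} (e.g. from
#'   \code{\link{computeEGMArray}})
#' @return data.frame with one row per electrode
#' @export
analyzeEGMs <- function(egms) {
  pos <- attr(egms, "positions")
  rows <- lapply(seq_along(egms), function(i) {
    eg <- egms[[i]]
    sp <- tryCatch(egmSpectrum(eg), error = function(e) NULL)
    cl <- tryCatch(cycleLengths(eg), error = function(e) NULL)
    mo <- classifyMorphology(eg)
    data.frame(
      electrode = i,
      x = if (!is.null(pos)) pos[i, 1] else eg@electrode@position[1],
      y = if (!is.null(pos)) pos[i, 2] else eg@electrode@position[2],
      df = if (!is.null(sp)) sp@df else NA_real_,
      oi = if (!is.null(sp)) sp@oi else NA_real_,
      morphology = mo@morphology,
      meanCL = if (!is.null(cl)) mean(cl$cl) else NA_real_,
      sdCL = if (!is.null(cl) && length(cl$cl) > 1) sd(cl$cl) else NA_real_)
  })
  do.call(rbind, rows)
}
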