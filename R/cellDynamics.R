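## Single-cell integration, pacing, APD measurement and restitution.

#' Advance a single cell by one or more fixed time steps
#'
#' Rush-Larsen update for the gating variables, forward Euler for membrane
#' potential and concentrations.  Intended for inspection and testing; use
#' \code{\link{paceCell}} for pacing protocols.
#'
#' @param state full cell state vector (see \code{\link{restingState}})
#' @param params a \linkS4class{CellParams}
#' @param iStim stimulus current, pA (positive depolarizes)
#' @param dt time step, ms (must not exceed 0.02 for tissue-consistent use)
#' @param n number of steps
#' @return named state vector after n steps, with attribute \code{dvdt}
#' @export
stepCell <- function(state, params, iStim = 0, dt = 0.02, n = 1L) {
  stopifnot(is(params, "CellParams"))
  if (dt > 0.02 + 1e-12)
    stop("dt = ", dt, " ms exceeds the 0.02 ms stability limit")
  if (any(!is.finite(state))) stop("state must be finite")
  out <- cpp_step_cell(.parVector(params), unname(state), iStim, dt, as.integer(n))
  if (out$diverged)
    stop("cell state diverged (non-finite Vm); dt too large or bad parameters")
  s <- out$state
  names(s) <- cpp_state_names()
  attr(s, "dvdt") <- out$dvdt
  s
}

#' Diastolic stimulus threshold of a cell variant
#'
#' Minimum amplitude of a 6 ms rectangular current pulse that elicits an
#' action potential from rest, found by bisection to 1% relative tolerance.
#' Cached per variant within the session.
#'
#' @param params a \linkS4class{CellParams}
#' @param stimDuration pulse duration, ms
#' @return threshold amplitude, pA
#' @export
diastolicThreshold <- function(params, stimDuration = 6) {
  key <- paste0("thr_", .paramsKey(params), "_", stimDuration)
  if (!is.null(.atriasim_cache[[key]])) return(.atriasim_cache[[key]])
  pv <- .parVector(params)
  captures <- function(amp) {
    r <- cpp_pace_cell(pv, 1L, 200, amp, stimDuration, 0.02, 0.5, NULL, FALSE, 0)
    max(r$vm) > -10
  }
  lo <- 50; hi <- 50
  while (!captures(hi)) {
    hi <- hi * 2
    if (hi > 2e5) stop("no capture even at ", hi / 2, " pA")
  }
  while ((hi - lo) / hi > 0.01) {
    mid <- (lo + hi) / 2
    if (captures(mid)) hi <- mid else lo <- mid
  }
  .atriasim_cache[[key]] <- hi
  hi
}

#' Pace a single cell with a train of rectangular stimuli
#'
#' Applies \code{nBeats} stimuli of \code{stimDuration} ms at basic cycle
#' length \code{bcl} and returns the full membrane-potential trace together
#' with per-beat upstroke times.  The default amplitude is twice the
#' diastolic threshold of the variant.  Loss of capture on any beat is an
#' error, not a silent truncation.
#'
#' @param params a \linkS4class{CellParams}
#' @param bcl basic cycle length, ms
#' @param nBeats number of stimuli (>= 1)
#' @param stimAmplitude stimulus amplitude, pA; NULL for 2x diastolic threshold
#' @param stimDuration stimulus duration, ms
#' @param dt integration step, ms
#' @param recordDt trace sampling interval, ms
#' @param state0 optional initial state (default: published resting state)
#' @param tailMs extra quiescent time appended after the last beat, ms
#' @return a \linkS4class{VmTrace}
#' @examples
#' tr <- paceCell(makeCellParams("AWM", "remodeled"), bcl = 1000, nBeats = 2)
#' measureAPD90(tr)
#' @export
paceCell <- function(params, bcl = 1000, nBeats = 10, stimAmplitude = NULL,
                     stimDuration = 6, dt = 0.02, recordDt = 0.2,
                     state0 = NULL, tailMs = 700) {
  stopifnot(is(params, "CellParams"))
  if (nBeats < 1) stop("nBeats must be >= 1")
  if (bcl <= stimDuration) stop("bcl must exceed the stimulus duration")
  if (is.null(stimAmplitude)) stimAmplitude <- 2 * diastolicThreshold(params, stimDuration)
  r <- cpp_pace_cell(.parVector(params), as.integer(nBeats), bcl, stimAmplitude,
                     stimDuration, dt, recordDt,
                     if (is.null(state0)) NULL else unname(state0), FALSE, tailMs)
  if (r$diverged) stop("integration diverged at t = ", r$t_diverged, " ms")
  ups <- numeric(nBeats)
  for (b in seq_len(nBeats)) {
    i <- which(r$t >= (b - 1) * bcl & r$t < (b - 1) * bcl + 100)
    if (max(r$vm[i]) < -10)
      stop("loss of capture on beat ", b, " (peak Vm ", round(max(r$vm[i]), 1),
           " mV); increase stimAmplitude")
    ups[b] <- r$t[i][which.max(r$dvdt[i])]
  }
  new("VmTrace", t = r$t, vm = r$vm, dvdt = r$dvdt, upstrokes = ups,
      params = params)
}

# internal: full state trajectory of the last paced beat (phase initiation)
.paceCellStates <- function(params, bcl, nBeats, stimAmplitude = NULL,
                            stimDuration = 6, dt = 0.02, recordDt = 1) {
  if (is.null(stimAmplitude)) stimAmplitude <- 2 * diastolicThreshold(params, stimDuration)
  r <- cpp_pace_cell(.parVector(params), as.integer(nBeats), bcl, stimAmplitude,
                     stimDuration, dt, recordDt, NULL, TRUE, 0)
  if (r$diverged) stop("integration diverged at t = ", r$t_diverged, " ms")
  keep <- r$t >= (nBeats - 1) * bcl
  list(t = r$t[keep] - (nBeats - 1) * bcl, states = r$states[, keep, drop = FALSE])
}

#' Measure action-potential duration at 90% repolarization
#'
#' APD90 is measured from the time of maximum upstroke velocity to recovery
#' to (diastolic + 10% of the AP amplitude), where the amplitude is the peak
#' minus the pre-stimulus diastolic potential of that beat.
#'
#' @param trace a \linkS4class{VmTrace}, or anything with \code{$t} and
#'   \code{$vm} components (ms, mV)
#' @param which "last" (default), "all", or a beat index
#' @param minUpstroke minimum dV/dt (mV/ms) for a deflection to count as an
#'   AP upstroke
#' @return APD90 in ms (vector for \code{which = "all"})
#' @export
measureAPD90 <- function(trace, which = "last", minUpstroke = 5) {
  if (is(trace, "VmTrace")) {
    t <- trace@t; v <- trace@vm
  } else {
    t <- trace$t; v <- trace$vm
  }
  if (length(t) < 3) stop("trace too short")
  dv <- diff(v) / diff(t)
  # upstroke candidates: local maxima of dV/dt above the threshold, separated
  # by at least 40 ms
  cand <- which(dv >= minUpstroke)
  if (!length(cand)) stop("no action potential detected in trace")
  grp <- cumsum(c(1, diff(t[cand]) > 40))
  ups <- vapply(split(cand, grp), function(ix) ix[which.max(dv[ix])],
                integer(1), USE.NAMES = FALSE)
  apd_one <- function(iu) {
    t_up <- t[iu]
    pre <- v[t >= t_up - 25 & t < t_up]
    dia <- if (length(pre)) min(pre) else v[1]
    seg <- which(t >= t_up)
    # AP support ends at the next upstroke if any
    nxt <- ups[ups > iu]
    if (length(nxt)) seg <- seg[t[seg] < t[nxt[1]]]
    peak <- max(v[seg])
    thr <- dia + 0.1 * (peak - dia)
    ipk <- seg[which.max(v[seg])]
    after <- seg[seg >= ipk]
    cross <- after[v[after] <= thr]
    if (!length(cross)) return(NA_real_)
    t[cross[1]] - t_up
  }
  res <- vapply(ups, apd_one, numeric(1))
  if (identical(which, "all")) return(res)
  if (identical(which, "last")) {
    res <- res[!is.na(res)]
    if (!length(res)) stop("no complete action potential in trace")
    return(res[length(res)])
  }
  res[which]
}

#' APD90 restitution curve by the S1-S2 protocol
#'
#' A conditioning train of \code{s1Beats} stimuli at \code{s1Bcl} is followed
#' by a single premature stimulus at each coupling interval (measured from
#' the upstroke of the last S1 beat); one S2 per run.  Non-captured coupling
#' intervals are flagged, not dropped silently.
#'
#' @param params a \linkS4class{CellParams}
#' @param ciList coupling intervals, ms
#' @param s1Bcl,s1Beats conditioning train settings
#' @param stimAmplitude stimulus amplitude, pA (NULL: 2x diastolic threshold)
#' @return data.frame with ci, apd90 and captured columns
#' @export
restitutionCurve <- function(params, ciList, s1Bcl = 1000, s1Beats = 10,
                             stimAmplitude = NULL) {
  stopifnot(is(params, "CellParams"))
  if (is.null(stimAmplitude)) stimAmplitude <- 2 * diastolicThreshold(params)
  pv <- .parVector(params)
  # conditioning train up to the beat before the last S1
  pre <- cpp_pace_cell(pv, as.integer(s1Beats - 1), s1Bcl, stimAmplitude, 6,
                       0.02, 1, NULL, FALSE, 0)
  # last S1 beat with full state recording so S2 can be launched at an exact
  # coupling interval from its upstroke
  maxci <- max(ciList)
  last <- cpp_pace_cell(pv, 1L, maxci + 60, stimAmplitude, 6, 0.02, 0.02,
                        pre$final_state, TRUE, 0)
  iu <- which.max(last$dvdt)
  t_up <- last$t[iu]
  out <- data.frame(ci = ciList, apd90 = NA_real_, captured = FALSE)
  for (k in seq_along(ciList)) {
    ci <- ciList[k]
    idx <- which.min(abs(last$t - (t_up + ci)))
    s2 <- cpp_pace_cell(pv, 1L, 900, stimAmplitude, 6, 0.02, 0.2,
                        last$states[, idx], FALSE, 0)
    if (max(s2$vm[s2$t < 100]) > -10) {
      out$captured[k] <- TRUE
      out$apd90[k] <- measureAPD90(list(t = s2$t, vm = s2$vm))
    }
  }
  out
}

#' Resting membrane currents of a cell state
#'
#' Instantaneous values of all membrane currents (pA) for a given state;
#' mainly a diagnostic for tests and teaching.
#' @param params a \linkS4class{CellParams}
#' @param state full cell state vector
#' @return named numeric vector of currents (pA) and the K reversal potential
#' @export
membraneCurrents <- function(params, state) {
  stopifnot(is(params, "CellParams"))
  cpp_currents(.parVector(params), unname(state))
}
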