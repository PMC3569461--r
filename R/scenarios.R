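## Desk-scale experiment drivers: the conduction-velocity table, a ring
## macroreentry (flutter analogue), a block-line tachycardia analogue on a
## sheet with an embedded crista-terminalis strip, and a focal-fibrillation
## analogue driven by a continuous high-rate focus.

#' Regional conduction-velocity table
#'
#' With the surface-to-volume ratio calibrated once on the control
#' working-myocardium cable, measures the longitudinal conduction velocity
#' of each conductivity region on a cable of its own cells (regions without
#' an ionic variant use working-myocardium cells).  Propagation failure in a
#' region is reported as a row-level failure, not an error.
#'
#' @param condition "control" or "remodeled"
#' @param Sv surface-to-volume ratio (NULL: calibrated default)
#' @param nNodes,dx cable geometry
#' @return data.frame with region, sigmaL, cellVariant, cv (cm/s), ok
#' @export
runCVTable <- function(condition = c("control", "remodeled"), Sv = NULL,
                       nNodes = 150, dx = 530) {
  condition <- match.arg(condition)
  if (is.null(Sv)) Sv <- defaultSv()
  regions <- c("CT", "BB", "PV", "ISTHMUS", "SAN", "AWM")
  rows <- lapply(regions, function(reg) {
    ct <- conductivityTable(reg)
    out <- data.frame(region = reg, sigmaL = ct$sigmaL,
                      cellVariant = unname(defaultVariantMap()[reg]),
                      cv = NA_real_, ok = FALSE)
    m <- monodomainModel(buildCable(nNodes, dx, reg), condition, Sv = Sv)
    cv <- tryCatch(cableCV(m), error = function(e) NA_real_)
    if (is.finite(cv)) { out$cv <- cv; out$ok <- TRUE }
    out
  })
  do.call(rbind, rows)
}

# phase-distributed initial condition: one full pre-excited lap around a ring
.ringPhaseInit <- function(model, cycleMs) {
  n <- model@grid@dims[1]
  variant <- model@variant[1]
  ps <- makeCellParams(variant, model@condition)
  tr <- .paceCellStates(ps, bcl = cycleMs, nBeats = 8, recordDt = 0.5)
  phase <- (seq_len(n) - 1) / n * cycleMs
  idx <- vapply(phase, function(p) which.min(abs(tr$t - p)), integer(1))
  tr$states[, idx, drop = FALSE]
}

#' Ring macroreentry (atrial-flutter analogue)
#'
#' A closed ring whose length is chosen as CV x target cycle length, so a
#' single circulating wavefront revisits each site at the flutter rate.
#' Circulation is started from a phase-distributed initial condition (one
#' full pre-excited lap) and run without further stimuli; electrograms are
#' computed on a regular lattice of electrodes and fed through the spectral
#' and morphology chain.
#'
#' @param condition "control" or "remodeled"
#' @param cycleMs target circulation cycle length, ms
#' @param tEnd simulated time, ms
#' @param nElectrodes electrodes around the ring
#' @param dx node spacing, um
#' @param Sv surface-to-volume ratio (NULL: calibrated default)
#' @return list with the simulation result, per-electrode analysis table,
#'   sustained flag and ring metadata
#' @export
runRingFlutter <- function(condition = "remodeled", cycleMs = 200,
                           tEnd = 5000, nElectrodes = 8, dx = 530,
                           Sv = NULL) {
  if (is.null(Sv)) Sv <- defaultSv()
  # measure the condition's cable CV, then size the ring to CV x CL
  mcv <- monodomainModel(buildCable(100, dx, "AWM"), condition, Sv = Sv)
  cv <- cableCV(mcv)                       # cm/s
  len_um <- cv * 1e4 * cycleMs / 1000      # um travelled in one cycle
  n <- max(10L, as.integer(round(len_um / dx)))
  ring <- buildRing(n, dx, "AWM")
  model <- monodomainModel(ring, condition, Sv = Sv)
  init <- .ringPhaseInit(model, cycleMs)
  empty <- stimulusProtocol(start = numeric(0), duration = numeric(0),
                            amplitude = numeric(0), nodes = list())
  sim <- runMonodomain(model, empty, tEnd = tEnd, initialStates = init,
                       checkCapture = FALSE)
  egms <- computeEGMArray(sim, spacing = n * dx / nElectrodes, offset = 200)
  # drop the filter warm-up and the initial-condition transient
  egms <- lapply(egms, function(e) {
    keep <- e@t >= 500
    new("EGMTrace", t = e@t[keep] - 500, phi = e@phi[keep],
        electrode = e@electrode)
  })
  tab <- analyzeEGMs(egms)
  lastAct <- max(unlist(lapply(sim@activations, function(a)
    if (length(a)) max(a) else -Inf)))
  list(result = sim, table = tab,
       sustained = lastAct > tEnd - 1.5 * cycleMs,
       ring = list(nNodes = n, circumference_cm = n * dx / 1e4,
                   cableCV = cv, cycleMs = cycleMs))
}

#' Block-line analogue: premature beat against a crista-terminalis strip
#'
#' A control sheet with an embedded CT strip whose longer action potential
#' makes it a functional obstacle for premature beats.  The strip leaves a
#' free conduction gap at one end.  After two fully recovered conditioning
#' beats, a premature stimulus just below the strip blocks across it (the
#' strip is still refractory where the bulk has recovered), detours through
#' the gap, and re-activates the far side and then the strip retrogradely.
#' Electrodes straddling the line of block therefore record two discrete
#' negative deflections per episode -- the near-side activation and the
#' delayed retrograde one -- i.e. double potentials, while electrodes away
#' from the line record single potentials.  The split interval at this
#' geometry is 40-90 ms, so the morphology analysis uses widened activation
#' windows (windowMs = 200, mergeMs = 100).
#'
#' @param condition "control" (default; the block needs the large
#'   control-state APD contrast between CT and working myocardium) or
#'   "remodeled"
#' @param nx,ny,dx sheet geometry
#' @param stripRows row range of the CT strip
#' @param gapCols columns left free of strip (the conduction gap)
#' @param s1Bcl conditioning cycle length, ms
#' @param s2Coupling premature coupling interval at the stimulus site, ms
#'   (scan with \code{\link{scanS2Window}}-style sweeps when changing the
#'   geometry)
#' @param Sv surface-to-volume ratio (NULL: calibrated default)
#' @return list with result, on/off-strip electrode tables, per-electrode
#'   double fraction and metadata
#' @export
runBlocklineTachycardia <- function(condition = "control", nx = 80, ny = 80,
                                    dx = 530, stripRows = 38:45,
                                    gapCols = 1:20, s1Bcl = 1000,
                                    s2Coupling = 178, Sv = NULL) {
  if (is.null(Sv)) Sv <- defaultSv()
  grid <- buildStripSheet(nx, ny, dx, "AWM", "CT", stripRows,
                          stripCols = setdiff(seq_len(nx), gapCols))
  model <- monodomainModel(grid, condition, Sv = Sv)
  edge <- edgeNodes(grid, "bottom", 2)
  ix <- rep(seq_len(nx), ny); iy <- rep(seq_len(ny), each = nx)
  # premature stimulus just below the strip, adjacent to the gap
  px <- max(gapCols) + 5:15
  s2nodes <- which(ix %in% px & iy %in% (min(stripRows) - 10):(min(stripRows) - 5))
  travel <- 45  # ms for the conditioning wave to reach the stimulus site
  t2 <- 5 + s1Bcl + travel + s2Coupling
  pr <- combineProtocols(
    stimulusProtocol(start = c(5, 5 + s1Bcl), duration = 6, amplitude = NA,
                     nodes = list(edge)),
    stimulusProtocol(start = t2, duration = 6, amplitude = NA,
                     nodes = list(s2nodes)))
  sim <- runMonodomain(model, pr, tEnd = t2 + 500, checkCapture = FALSE)

  # electrodes straddling the line of block (lower strip edge) and two
  # reference rows away from it
  onY <- (min(stripRows) - 1.5) * dx
  xs <- (max(gapCols) + c(3, 6, 9, 12, 15, 18)) * dx
  mkrow <- function(yy, xx = xs) lapply(xx, function(x) electrode(x, yy, 200))
  epoch <- function(e) {
    eg <- computeEGM(sim, e)
    keep <- eg@t >= t2 - 30
    new("EGMTrace", t = eg@t[keep] - (t2 - 30), phi = eg@phi[keep],
        electrode = e)
  }
  analyze <- function(els, ...) {
    egs <- lapply(els, epoch)
    tab <- analyzeEGMs(egs)
    tab$morphology <- vapply(egs, function(eg)
      classifyMorphology(eg, ...)@morphology, character(1))
    tab
  }
  onTab <- analyze(mkrow(onY), windowMs = 200, mergeMs = 100)
  offTab <- analyze(c(mkrow((min(stripRows) - 18) * dx),
                      mkrow((max(stripRows) + 16) * dx)),
                    windowMs = 200, mergeMs = 100)
  frac <- vapply(mkrow(onY), function(e) {
    mo <- classifyMorphology(epoch(e), windowMs = 200, mergeMs = 100)
    if (!nrow(mo@windows)) return(NA_real_)
    mean(mo@windows$class == "double")
  }, numeric(1))
  lastAct <- max(unlist(lapply(sim@activations, function(a)
    if (length(a)) max(a) else -Inf)))
  list(result = sim, onStrip = onTab, offStrip = offTab,
       onStripDoubleFraction = frac,
       meta = list(stripRows = stripRows, gapCols = gapCols,
                   s2Coupling = s2Coupling, condition = condition,
                   s2Time = t2, lastActivation = lastAct))
}

#' Focal-fibrillation analogue: continuous high-rate corner focus
#'
#' A continuous focus at cycle length 130 ms drives one corner of a large
#' remodeled sheet; near-focus electrodes follow the focus frequency with
#' high organization while remote tissue, unable to follow 1:1, shows lower
#' dominant frequency and organization.
#'
#' @param condition must allow fibrillatory conduction ("remodeled")
#' @param nx,ny,dx sheet geometry
#' @param focusCl focus cycle length, ms
#' @param tEnd simulated time, ms
#' @param Sv surface-to-volume ratio (NULL: calibrated default)
#' @return list with result, near/far electrode tables and metadata
#' @export
runFocalAF <- function(condition = "remodeled", nx = 150, ny = 150, dx = 530,
                       focusCl = 130, tEnd = 3000, Sv = NULL) {
  if (is.null(Sv)) Sv <- defaultSv()
  grid <- buildSheet(nx, ny, dx, "AWM")
  model <- monodomainModel(grid, condition, Sv = Sv)
  # focus patch just inside the corner: nodes on the sheet boundary are
  # electrotonically under-loaded and overdrive at threshold multiples
  ctr <- (8 - 1) * nx + 8
  focus <- patchNodes(grid, ctr, area_mm2 = 10)
  s1 <- stimulusProtocol(start = 5, duration = 6, amplitude = NA,
                         nodes = list(focus))
  s2 <- continuousS2(focus, cl = focusCl, start = 5 + 600, tEnd = tEnd)
  sim <- runMonodomain(model, combineProtocols(s1, s2), tEnd = tEnd,
                       checkCapture = FALSE)
  L <- (nx - 1) * dx
  near <- lapply(c(0.06, 0.1), function(f) electrode(L * f, L * f, 200))
  far <- lapply(c(0.75, 0.9), function(f) electrode(L * f, L * f, 200))
  cut <- function(els) {
    egs <- lapply(els, function(e) {
      eg <- computeEGM(sim, e)
      keep <- eg@t >= 5 + 600   # analyse the continuous-focus epoch
      new("EGMTrace", t = eg@t[keep] - (5 + 600), phi = eg@phi[keep],
          electrode = e)
    })
    analyzeEGMs(egs)
  }
  list(result = sim, near = cut(near), far = cut(far),
       meta = list(focusCl = focusCl, condition = condition))
}

#' Scan the S2 coupling-interval window for reentry induction
#'
#' Runs the cross-field S1-S2 protocol over a range of S2 delays and
#' reports, for each delay, whether activity outlived the last stimulus by
#' the requested margin (i.e. reentry was induced).
#'
#' @param model a sheet \linkS4class{MonodomainModel}
#' @param delays S2 delays to scan, ms
#' @param tEnd simulated time per trial, ms
#' @param marginMs activity must persist this long after S2 to count
#' @return data.frame with delay, induced, lastActivation
#' @export
scanS2Window <- function(model, delays, tEnd = 1000, marginMs = 300) {
  rows <- lapply(delays, function(d) {
    pr <- crossFieldProtocol(model@grid, s2Delay = d)
    sim <- tryCatch(
      runMonodomain(model, pr, tEnd = tEnd, recordVm = FALSE,
                    checkCapture = FALSE),
      error = function(e) NULL)
    if (is.null(sim))
      return(data.frame(delay = d, induced = NA, lastActivation = NA_real_))
    lastAct <- suppressWarnings(max(unlist(lapply(sim@activations, function(a)
      if (length(a)) max(a) else -Inf))))
    data.frame(delay = d, induced = lastAct > 5 + d + marginMs,
               lastActivation = lastAct)
  })
  do.call(rbind, rows)
}
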