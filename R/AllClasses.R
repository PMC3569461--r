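## Central S4 containers.  Constructors with validity live next to the class;
## user-facing builders are in the module files (geometry.R, monodomain.R, ...).

#' Regional cell parameter set
#'
#' Maximal conductances of the four regionally modified currents (nS, in the
#' cell model's native units) plus the three chronic-AF kinetic modifications:
#' a multiplier on the fast inactivation time constant of I_CaL and
#' depolarizing shifts of the I_t activation and I_Na inactivation curves.
#' All other cell-model parameters are fixed at their published values.
#'
#' @slot region one of CT, PM, APG, AVR, AWM
#' @slot condition "control" or "remodeled"
#' @slot gt,gCaL,gKr,gK1 maximal conductances, nS
#' @slot tauFCaLScale dimensionless multiplier on the fast I_CaL inactivation tau
#' @slot itActShift,iNaInactShift curve shifts, mV
#' @slot cm membrane capacitance, pF (fixed at 50)
#' @exportClass CellParams
setClass("CellParams", representation(
  region = "character", condition = "character",
  gt = "numeric", gCaL = "numeric", gKr = "numeric", gK1 = "numeric",
  tauFCaLScale = "numeric", itActShift = "numeric", iNaInactShift = "numeric",
  cm = "numeric"))

setValidity("CellParams", function(object) {
  msg <- character()
  if (!object@region %in% c("CT", "PM", "APG", "AVR", "AWM"))
    msg <- c(msg, "region must be one of CT, PM, APG, AVR, AWM")
  if (!object@condition %in% c("control", "remodeled"))
    msg <- c(msg, "condition must be 'control' or 'remodeled'")
  if (any(c(object@gt, object@gCaL, object@gKr, object@gK1) <= 0))
    msg <- c(msg, "all conductances must be positive")
  if (object@tauFCaLScale <= 0) msg <- c(msg, "tauFCaLScale must be positive")
  if (object@cm != 50) msg <- c(msg, "cm is fixed at 50 pF")
  if (length(msg)) msg else TRUE
})

#' Structured tissue geometry
#'
#' A 1D or 2D structured grid with per-node region label, fiber direction and
#' longitudinal/transverse conductivity.  Node positions are node-centered,
#' 0-based: physical position = index * dx (micrometres).
#'
#' @slot dims node counts per axis (length 1 for cable/ring, 2 for sheet)
#' @slot dx node spacing, micrometres (validated to the 300-700 um range)
#' @slot topology "cable", "sheet" or "ring"
#' @slot region per-node region label
#' @slot fiberAngle per-node fiber angle, degrees (sheet); along-axis otherwise
#' @slot sigmaL,sigmaT per-node conductivities, S/m
#' @exportClass TissueGrid
setClass("TissueGrid", representation(
  dims = "integer", dx = "numeric", topology = "character",
  region = "character", fiberAngle = "numeric",
  sigmaL = "numeric", sigmaT = "numeric"))

setValidity("TissueGrid", function(object) {
  msg <- character()
  n <- prod(object@dims)
  if (!object@topology %in% c("cable", "sheet", "ring"))
    msg <- c(msg, "topology must be cable, sheet or ring")
  if (object@dx < 300 || object@dx > 700)
    msg <- c(msg, "dx outside the validated 300-700 um resolution range")
  if (length(object@region) != n || length(object@fiberAngle) != n ||
      length(object@sigmaL) != n || length(object@sigmaT) != n)
    msg <- c(msg, "per-node fields must have length prod(dims)")
  if (!all(object@region %in% atrialRegions()))
    msg <- c(msg, "unknown region label")
  if (any(object@sigmaT <= 0) || any(object@sigmaL < object@sigmaT))
    msg <- c(msg, "need sigma_l >= sigma_t > 0 at every node")
  if (length(msg)) msg else TRUE
})

#' Timed stimulus events over node sets
#'
#' @slot events data.frame with columns start, duration (ms) and amplitude
#'   (pA per cell; NA means resolve automatically at run time)
#' @slot nodes list of integer vectors, one per event
#' @exportClass StimulusProtocol
setClass("StimulusProtocol", representation(
  events = "data.frame", nodes = "list"))

setValidity("StimulusProtocol", function(object) {
  ev <- object@events
  msg <- character()
  if (!all(c("start", "duration", "amplitude") %in% names(ev)))
    msg <- c(msg, "events needs columns start, duration, amplitude")
  if (nrow(ev) != length(object@nodes))
    msg <- c(msg, "one node set per event required")
  if (nrow(ev) && any(ev$duration <= 0)) msg <- c(msg, "durations must be positive")
  if (nrow(ev) && is.unsorted(ev$start)) msg <- c(msg, "events must be time-ordered")
  if (length(msg)) msg else TRUE
})

#' Monodomain tissue model
#'
#' Couples a \linkS4class{TissueGrid} to per-region cell variants under one
#' condition.  Sv is the surface-to-volume ratio (1/m) and cmArea the membrane
#' capacitance per unit area (uF/cm^2); together with the conductivities they
#' set the electrotonic diffusivity sigma / (Sv * cmArea).
#'
#' @slot grid the tissue geometry
#' @slot condition "control" or "remodeled"
#' @slot variant per-node cell-variant label (one of the five ionic variants)
#' @slot Sv surface-to-volume ratio, 1/m
#' @slot cmArea membrane capacitance per area, uF/cm^2
#' @slot dt integration step, ms (<= 0.02)
#' @exportClass MonodomainModel
setClass("MonodomainModel", representation(
  grid = "TissueGrid", condition = "character", variant = "character",
  Sv = "numeric", cmArea = "numeric", dt = "numeric"))

setValidity("MonodomainModel", function(object) {
  msg <- character()
  if (object@Sv <= 0) msg <- c(msg, "Sv must be positive")
  if (object@cmArea <= 0) msg <- c(msg, "cmArea must be positive")
  if (object@dt > 0.02 + 1e-12) msg <- c(msg, "dt must be <= 0.02 ms")
  if (length(object@variant) != prod(object@grid@dims))
    msg <- c(msg, "one cell variant per node required")
  if (!all(object@variant %in% c("CT", "PM", "APG", "AVR", "AWM")))
    msg <- c(msg, "cell variants must carry an ionic parameter set")
  if (length(msg)) msg else TRUE
})

#' Result of a monodomain simulation
#'
#' @slot times sample times, ms (1 ms cadence by default)
#' @slot vm Vm matrix, one row per sample time, one column per node (may be
#'   0 x 0 when recording was disabled)
#' @slot activations list of per-node activation times (time of maximum
#'   dV/dt within each suprathreshold excursion)
#' @slot finalStates full cell state per node at the end of the run
#' @slot grid,condition provenance
#' @slot diverged divergence flag with time/node diagnostics
#' @exportClass SimulationResult
setClass("SimulationResult", representation(
  times = "numeric", vm = "matrix", activations = "list",
  finalStates = "matrix", grid = "TissueGrid", condition = "character",
  diverged = "logical", diagnostics = "list"))

#' Paced single-cell membrane-potential trace
#'
#' @slot t time, ms
#' @slot vm membrane potential, mV
#' @slot dvdt time derivative, mV/ms
#' @slot upstrokes per-beat upstroke times (max dV/dt), ms
#' @slot params the CellParams that produced the trace
#' @exportClass VmTrace
setClass("VmTrace", representation(
  t = "numeric", vm = "numeric", dvdt = "numeric",
  upstrokes = "numeric", params = "CellParams"))

#' Extracellular recording electrode
#'
#' Position in micrometres; the z component is the normal offset from the
#' tissue plane and must be strictly positive (0.2 mm by convention).
#' @slot position numeric length-3 (x, y, z) in micrometres
#' @exportClass Electrode
setClass("Electrode", representation(position = "numeric"))

setValidity("Electrode", function(object) {
  if (length(object@position) != 3) return("position must be (x, y, z)")
  if (object@position[3] <= 0) return("electrode offset must be > 0")
  TRUE
})

#' Pseudo-unipolar electrogram trace
#'
#' Extracellular potential (arbitrary units, K = 1) at 1 ms sampling.
#' @slot t time, ms
#' @slot phi extracellular potential, arbitrary units
#' @slot electrode the recording electrode
#' @exportClass EGMTrace
setClass("EGMTrace", representation(
  t = "numeric", phi = "numeric", electrode = "Electrode"))

setValidity("EGMTrace", function(object) {
  if (length(object@t) != length(object@phi)) return("t and phi lengths differ")
  if (any(!is.finite(object@phi))) return("phi must be finite")
  TRUE
})

#' Power spectrum with dominant frequency and organization index
#'
#' @slot freqs frequency grid, Hz (resolution <= 0.12 Hz)
#' @slot power power spectrum over freqs
#' @slot df dominant frequency, Hz (NA when undefined)
#' @slot oi organization index in [0, 1] (NA when DF undefined)
#' @slot band analysis band used for the DF search and total power, Hz
#' @exportClass SpectralResult
setClass("SpectralResult", representation(
  freqs = "numeric", power = "numeric", df = "numeric", oi = "numeric",
  band = "numeric"))

#' Morphology classification of one electrogram
#'
#' Per-activation-window calls plus the trace-level summary class.
#' @slot morphology trace-level class: "single", "double", "cfae" or "no activity"
#' @slot windows per-window data.frame (start, end, class, nDeflections,
#'   nNegative, continuousMs)
#' @slot deflections data.frame of detected deflections (t, polarity, amplitude)
#' @exportClass MorphologyCall
setClass("MorphologyCall", representation(
  morphology = "character", windows = "data.frame", deflections = "data.frame"))
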