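## Stimulus protocols: generic constructor plus the named builders used in
## the experiments (sinus S1 train, ectopic S2 burst, continuous focus,
## cross-field S1-S2).

#' Construct a stimulus protocol
#'
#' @param start event start times, ms
#' @param duration event durations, ms (rectangular pulses; 6 ms by convention)
#' @param amplitude per-cell current, pA; NA resolves at run time to the
#'   patch-convention current or, if that fails to capture, twice the tissue
#'   diastolic threshold
#' @param nodes list of node index vectors, one per event (recycled if one)
#' @return a \linkS4class{StimulusProtocol}
#' @export
stimulusProtocol <- function(start, duration = 6, amplitude = NA,
                             nodes) {
  k <- length(start)
  ev <- data.frame(start = start,
                   duration = rep_len(duration, k),
                   amplitude = rep_len(amplitude, k))
  if (!is.list(nodes)) nodes <- list(nodes)
  if (length(nodes) == 1L) nodes <- rep(nodes, k)
  ord <- order(ev$start)
  new("StimulusProtocol", events = ev[ord, , drop = FALSE], nodes = nodes[ord])
}

#' Combine protocols
#' @param e1,e2 StimulusProtocol objects
#' @return merged, time-ordered protocol
#' @export
combineProtocols <- function(e1, e2) {
  ev <- rbind(e1@events, e2@events)
  nd <- c(e1@nodes, e2@nodes)
  ord <- order(ev$start)
  new("StimulusProtocol", events = ev[ord, , drop = FALSE], nodes = nd[ord])
}

#' Named protocol builders
#'
#' \code{sinusS1} is the conditioning train (10 beats at basic cycle length
#' 1000 ms by convention); \code{burstS2} the transient ectopic focus (six
#' beats at cycle length 130 ms); \code{continuousS2} a continuous focus at
#' cycle length 130 ms until \code{tEnd}.
#'
#' @param nodes stimulated node set (e.g. \code{\link{edgeNodes}} or
#'   \code{\link{cornerPatch}})
#' @param nBeats,bcl train length and basic cycle length, ms
#' @param start first stimulus onset, ms
#' @param duration,amplitude pulse shape (see \code{\link{stimulusProtocol}})
#' @return a \linkS4class{StimulusProtocol}
#' @export
sinusS1 <- function(nodes, nBeats = 10, bcl = 1000, start = 5, duration = 6,
                    amplitude = NA) {
  stimulusProtocol(start = start + bcl * (seq_len(nBeats) - 1),
                   duration = duration, amplitude = amplitude, nodes = nodes)
}

#' @rdname sinusS1
#' @param n number of burst beats
#' @param cl burst cycle length, ms
#' @export
burstS2 <- function(nodes, n = 6, cl = 130, start, duration = 6,
                    amplitude = NA) {
  stimulusProtocol(start = start + cl * (seq_len(n) - 1),
                   duration = duration, amplitude = amplitude, nodes = nodes)
}

#' @rdname sinusS1
#' @param tEnd protocol end time, ms
#' @export
continuousS2 <- function(nodes, cl = 130, start, tEnd, duration = 6,
                         amplitude = NA) {
  burstS2(nodes, n = max(1L, floor((tEnd - start) / cl) + 1L), cl = cl,
          start = start, duration = duration, amplitude = amplitude)
}

#' Cross-field S1-S2 protocol for spiral-wave initiation
#'
#' S1 is a plane wave from the left edge; S2 depolarizes the lower-left
#' quadrant at \code{s2Delay} ms after S1, timed into the repolarization tail
#' to launch a free spiral tip.
#'
#' @param grid a sheet \linkS4class{TissueGrid}
#' @param s1Start S1 onset, ms
#' @param s2Delay S2 onset relative to S1 onset, ms
#' @param amplitude per-cell current, pA (NA: resolved at run time)
#' @return a \linkS4class{StimulusProtocol}
#' @export
crossFieldProtocol <- function(grid, s1Start = 5, s2Delay, amplitude = NA) {
  stopifnot(grid@topology == "sheet")
  nx <- grid@dims[1]; ny <- grid@dims[2]
  s1 <- edgeNodes(grid, "left", depth = 2)
  id <- function(ix, iy) (iy - 1L) * nx + ix
  qx <- seq_len(floor(nx / 2)); qy <- seq_len(floor(ny / 2))
  s2 <- as.integer(outer(qx, qy, id))
  stimulusProtocol(start = c(s1Start, s1Start + s2Delay), duration = 6,
                   amplitude = amplitude, nodes = list(s1, s2))
}

#' Node-set helpers
#'
#' \code{edgeNodes} selects the nodes within \code{depth} of one sheet edge;
#' \code{cornerPatch} a square patch in a corner; \code{patchNodes} a disc of
#' given area around a centre node (approximating a stimulation electrode of
#' ~10 mm^2).
#'
#' @param grid a \linkS4class{TissueGrid}
#' @param side "left", "right", "bottom" or "top"
#' @param depth edge thickness in nodes
#' @return integer node indices
#' @export
edgeNodes <- function(grid, side = c("left", "right", "bottom", "top"),
                      depth = 2) {
  side <- match.arg(side)
  if (grid@topology != "sheet") return(switch(side, left = seq_len(depth),
    right = prod(grid@dims) - seq_len(depth) + 1L,
    stop("side not defined for 1D topologies")))
  nx <- grid@dims[1]; ny <- grid@dims[2]
  ix <- rep(seq_len(nx), ny); iy <- rep(seq_len(ny), each = nx)
  which(switch(side,
               left = ix <= depth, right = ix > nx - depth,
               bottom = iy <= depth, top = iy > ny - depth))
}

#' @rdname edgeNodes
#' @param corner "bottomleft", "bottomright", "topleft", "topright"
#' @param size patch edge length in nodes
#' @export
cornerPatch <- function(grid, corner = "bottomleft", size = 5) {
  stopifnot(grid@topology == "sheet")
  nx <- grid@dims[1]; ny <- grid@dims[2]
  ix <- rep(seq_len(nx), ny); iy <- rep(seq_len(ny), each = nx)
  xr <- if (grepl("left", corner)) ix <= size else ix > nx - size
  yr <- if (grepl("bottom", corner)) iy <= size else iy > ny - size
  which(xr & yr)
}

#' @rdname edgeNodes
#' @param center node index of the patch centre
#' @param area_mm2 target patch area, mm^2
#' @export
patchNodes <- function(grid, center, area_mm2 = 10) {
  pos <- nodePositions(grid)
  r <- sqrt(area_mm2 * 1e6 / pi)          # um
  d2 <- (pos[, 1] - pos[center, 1])^2 + (pos[, 2] - pos[center, 2])^2
  which(d2 <= r^2)
}
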