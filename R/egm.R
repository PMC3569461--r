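## Pseudo-unipolar electrograms by the large-volume-conductor approximation:
## phi_e(t) = K * sum_j [ -grad Vm_j . grad_j (1/r_j) ] dV_j, with K = 1
## (amplitudes in arbitrary units) and dV = dx^2 * h for the monolayer
## (h = dx).  The nodal sum collapses to one matrix-vector product per
## electrode: phi = Vm %*% u, with u assembling the finite-difference
## gradient and the 1/r^3 geometry weights.

#' Construct an electrode
#'
#' @param x,y in-plane position, micrometres
#' @param offset normal distance from the tissue plane, micrometres
#'   (0.2 mm = 200 um by convention; must be > 0)
#' @return an \linkS4class{Electrode}
#' @export
electrode <- function(x, y = 0, offset = 200) {
  new("Electrode", position = c(x, y, offset))
}

# geometry weight vectors w = (p_n - p_e) / r^3 * dV for each grid axis
.egmWeights <- function(grid, el) {
  pos <- nodePositions(grid)
  pe <- el@position
  dvec <- cbind(pos[, 1] - pe[1], pos[, 2] - pe[2], pos[, 3] - pe[3])
  r <- sqrt(rowSums(dvec^2))
  if (any(r < 1e-9)) stop("electrode coincides with a tissue node (r = 0)")
  dV <- grid@dx^3          # node area x monolayer thickness h = dx
  list(w = dvec / r^3 * dV, pos = pos)
}

# accumulate the per-electrode projection vector u such that phi = Vm %*% u
.egmVector <- function(grid, el) {
  gw <- .egmWeights(grid, el)
  n <- prod(grid@dims)
  dx <- grid@dx
  u <- numeric(n)
  scatter <- function(iup, idn, w) {
    # indexed assignment does not accumulate over duplicated indices
    for (k in seq_along(w)) {
      u[iup[k]] <- u[iup[k]] + w[k]
      u[idn[k]] <- u[idn[k]] - w[k]
    }
    u
  }
  if (grid@topology == "sheet") {
    nx <- grid@dims[1]; ny <- grid@dims[2]
    ix <- rep(seq_len(nx), ny); iy <- rep(seq_len(ny), each = nx)
    for (ax in 1:2) {
      ii <- if (ax == 1) ix else iy
      nmax <- if (ax == 1) nx else ny
      step <- if (ax == 1) 1L else nx
      up <- pmin(ii + 1L, nmax); dn <- pmax(ii - 1L, 1L)
      span <- (up - dn) * dx
      idx <- seq_len(n)
      iup <- idx + (up - ii) * step
      idn <- idx - (ii - dn) * step
      u <- scatter(iup, idn, gw$w[, ax] / span)
    }
  } else if (grid@topology == "ring") {
    nn <- grid@dims[1]
    th <- 2 * pi * (seq_len(nn) - 1) / nn
    tangent <- cbind(-sin(th), cos(th), 0)
    wt <- rowSums(gw$w * tangent) / (2 * dx)
    u <- scatter(c(2:nn, 1L), c(nn, 1:(nn - 1L)), wt)
  } else {
    nn <- grid@dims[1]
    idx <- seq_len(nn)
    up <- pmin(idx + 1L, nn); dn <- pmax(idx - 1L, 1L)
    span <- (up - dn) * dx
    u <- scatter(up, dn, gw$w[, 1] / span)
  }
  u
}

#' Compute a pseudo-unipolar electrogram
#'
#' Sums the projected transmembrane-potential gradient over all tissue
#' elements with 1/r^3 distance weighting (K = 1, arbitrary units), at the
#' Vm sampling cadence of the simulation (1 ms by default).
#'
#' @param result a \linkS4class{SimulationResult} with recorded Vm
#' @param el an \linkS4class{Electrode}
#' @return an \linkS4class{EGMTrace}
#' @examples
#' \dontrun{
#' eg <- computeEGM(sim, electrode(x = 2e4, y = 2e4))
#' }
#' @export
computeEGM <- function(result, el) {
  stopifnot(is(result, "SimulationResult"), is(el, "Electrode"))
  if (!nrow(result@vm)) stop("simulation was run without Vm recording")
  u <- .egmVector(result@grid, el)
  phi <- as.numeric(result@vm %*% u)
  new("EGMTrace", t = result@times, phi = phi, electrode = el)
}

#' Electrogram array over a regular lattice
#'
#' One electrode every \code{spacing} micrometres over the tissue footprint
#' (sheets) or every k-th node (cables and rings), all at the same normal
#' offset.
#'
#' @param result a \linkS4class{SimulationResult}
#' @param spacing lattice spacing, micrometres
#' @param offset electrode offset, micrometres
#' @param margin margin to the tissue border, micrometres
#' @return list of \linkS4class{EGMTrace} with a \code{positions} attribute
#' @export
computeEGMArray <- function(result, spacing, offset = 200, margin = 0) {
  stopifnot(is(result, "SimulationResult"))
  grid <- result@grid
  if (grid@topology == "sheet") {
    nx <- grid@dims[1]; ny <- grid@dims[2]; dx <- grid@dx
    xs <- seq(margin, (nx - 1) * dx - margin, by = spacing)
    ys <- seq(margin, (ny - 1) * dx - margin, by = spacing)
    pos <- cbind(x = rep(xs, length(ys)), y = rep(ys, each = length(xs)))
    els <- lapply(seq_len(nrow(pos)),
                  function(i) electrode(pos[i, 1], pos[i, 2], offset))
  } else {
    np <- nodePositions(grid)
    step <- max(1L, round(spacing / grid@dx))
    sel <- seq(1L, nrow(np), by = step)
    if (grid@topology == "ring") {
      # push electrodes radially outward from the ring plane centre
      R <- grid@dims[1] * grid@dx / (2 * pi)
      els <- lapply(sel, function(i) {
        new("Electrode", position = c(np[i, 1], np[i, 2], offset))
      })
    } else {
      els <- lapply(sel, function(i) electrode(np[i, 1], 0, offset))
    }
    pos <- cbind(x = vapply(els, function(e) e@position[1], 1),
                 y = vapply(els, function(e) e@position[2], 1))
  }
  out <- lapply(els, function(e) computeEGM(result, e))
  attr(out, "positions") <- pos
  out
}
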