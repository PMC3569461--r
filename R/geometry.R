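## Synthetic desk-scale geometries: cable, sheet, ring and a sheet with an
## embedded high-anisotropy strip.  Conductivities and anisotropy ratios are a
## pure lookup per region label.

.CONDUCTIVITY <- data.frame(
  region = c("CT", "BB", "PM", "FO_RIM", "PV", "ISTHMUS", "SAN", "AWM",
             "APG", "AVR"),
  sigmaL = c(0.7, 0.5, 0.5, 0.5, 0.15, 0.1, 0.05, 0.2, 0.2, 0.2),
  # transverse:longitudinal ratio -- 1:9 for CT, isotropic for SAN and the
  # isthmus, 1:2 everywhere else
  ratio = c(1 / 9, 1 / 2, 1 / 2, 1 / 2, 1 / 2, 1, 1, 1 / 2, 1 / 2, 1 / 2),
  stringsAsFactors = FALSE)

#' Atrial region labels
#' @return character vector of all region labels
#' @export
atrialRegions <- function() .CONDUCTIVITY$region

#' Regional conductivities and anisotropy ratios
#'
#' Longitudinal conductivity (S/m) and transverse:longitudinal ratio per
#' region.  APG and AVR carry the working-myocardium (AWM) conductivity: only
#' their ionic properties, not their coupling, are distinguished.
#' @param region optional label(s) to look up; default returns the full table
#' @return data.frame with region, sigmaL, sigmaT, ratio
#' @export
conductivityTable <- function(region = NULL) {
  tab <- .CONDUCTIVITY
  tab$sigmaT <- tab$sigmaL * tab$ratio
  tab <- tab[, c("region", "sigmaL", "sigmaT", "ratio")]
  if (is.null(region)) return(tab)
  bad <- setdiff(region, tab$region)
  if (length(bad)) stop("unknown region: ", paste(bad, collapse = ", "))
  tab[match(region, tab$region), ]
}

# default mapping from geometric region to ionic cell variant: regions
# without their own ionic variant use the working-myocardium cells
.DEFAULT_VARIANT <- c(CT = "CT", PM = "PM", APG = "APG", AVR = "AVR",
                      AWM = "AWM", BB = "AWM", FO_RIM = "AWM", PV = "AWM",
                      ISTHMUS = "AWM", SAN = "AWM")

#' Default cell variant assigned to each geometric region
#'
#' Regions without an ionic variant of their own (BB, FO rim, PV, isthmus,
#' SAN) default to the atrial-working-myocardium cells; override per model
#' via the \code{variantMap} argument of \code{\link{monodomainModel}}.
#' @return named character vector region -> cell variant
#' @export
defaultVariantMap <- function() .DEFAULT_VARIANT

.checkDx <- function(dx) {
  if (dx < 300 || dx > 700)
    stop("dx = ", dx, " um is outside the validated 300-700 um range")
  invisible(dx)
}

#' Build a 1D cable
#'
#' Fibers run along the cable axis; conductivities are the regional lookup.
#'
#' @param nNodes number of nodes (>= 3)
#' @param dx node spacing, micrometres (300-700)
#' @param region region label for the whole cable
#' @return a \linkS4class{TissueGrid}
#' @examples
#' g <- buildCable(150, 530, "AWM")   # 7.9 cm of working myocardium
#' @export
buildCable <- function(nNodes, dx = 530, region = "AWM") {
  if (nNodes < 3) stop("a cable needs at least 3 nodes for a Laplacian interior")
  .checkDx(dx)
  ct <- conductivityTable(region)
  new("TissueGrid", dims = as.integer(nNodes), dx = dx, topology = "cable",
      region = rep(region, nNodes), fiberAngle = rep(0, nNodes),
      sigmaL = rep(ct$sigmaL, nNodes), sigmaT = rep(ct$sigmaT, nNodes))
}

#' Build a 2D sheet with uniform fiber angle
#'
#' @param nx,ny node counts (>= 3 each)
#' @param dx node spacing, micrometres
#' @param region region label for the whole sheet
#' @param fiberAngle fiber direction, degrees from the x axis
#' @return a \linkS4class{TissueGrid}
#' @examples
#' g <- buildSheet(150, 150, 530, "AWM")  # the CV-calibration sheet
#' @export
buildSheet <- function(nx, ny, dx = 530, region = "AWM", fiberAngle = 0) {
  if (nx < 3 || ny < 3) stop("a sheet needs nx, ny >= 3")
  .checkDx(dx)
  n <- nx * ny
  ct <- conductivityTable(region)
  new("TissueGrid", dims = as.integer(c(nx, ny)), dx = dx, topology = "sheet",
      region = rep(region, n), fiberAngle = rep(fiberAngle, n),
      sigmaL = rep(ct$sigmaL, n), sigmaT = rep(ct$sigmaT, n))
}

#' Build a closed 1D ring
#'
#' A periodic cable: the minimal substrate for a macroreentrant circuit.
#' Fibers are tangential.
#'
#' @inheritParams buildCable
#' @return a \linkS4class{TissueGrid}
#' @examples
#' g <- buildRing(200, 530, "AWM")   # circumference 10.6 cm
#' @export
buildRing <- function(nNodes, dx = 530, region = "AWM") {
  if (nNodes < 3) stop("a ring needs at least 3 nodes")
  .checkDx(dx)
  ct <- conductivityTable(region)
  new("TissueGrid", dims = as.integer(nNodes), dx = dx, topology = "ring",
      region = rep(region, nNodes), fiberAngle = rep(0, nNodes),
      sigmaL = rep(ct$sigmaL, nNodes), sigmaT = rep(ct$sigmaT, nNodes))
}

#' Build a sheet with an embedded strip of another region
#'
#' The strip (e.g. crista terminalis in working myocardium) spans the given
#' row range, with fibers along the strip; used for block-line /
#' double-potential experiments.  By default the strip covers the full
#' width; restricting \code{stripCols} leaves a free conduction gap, the
#' substrate for pivoting/detour activation around the end of a block line.
#'
#' @inheritParams buildSheet
#' @param baseRegion region of the bulk sheet
#' @param stripRegion region of the strip
#' @param stripRows integer vector of row indices (1-based y indices)
#' @param stripCols integer vector of column indices (default: full width)
#' @return a \linkS4class{TissueGrid}
#' @export
buildStripSheet <- function(nx, ny, dx = 530, baseRegion = "AWM",
                            stripRegion = "CT", stripRows,
                            stripCols = seq_len(nx)) {
  if (missing(stripRows) || !length(stripRows)) stop("stripRows must be non-empty")
  stripRows <- as.integer(stripRows)
  stripCols <- as.integer(stripCols)
  if (any(stripRows < 1) || any(stripRows > ny))
    stop("stripRows outside 1..ny")
  if (!length(stripCols) || any(stripCols < 1) || any(stripCols > nx))
    stop("stripCols outside 1..nx")
  g <- buildSheet(nx, ny, dx, baseRegion, fiberAngle = 0)
  ct <- conductivityTable(stripRegion)
  ix <- rep(seq_len(nx), ny)
  iy <- rep(seq_len(ny), each = nx)
  sel <- iy %in% stripRows & ix %in% stripCols
  g@region[sel] <- stripRegion
  g@fiberAngle[sel] <- 0  # fibers run along the strip (x axis)
  g@sigmaL[sel] <- ct$sigmaL
  g@sigmaT[sel] <- ct$sigmaT
  validObject(g)
  g
}

#' Node positions of a grid
#'
#' Physical coordinates in micrometres (0-based node-centred); rings are
#' embedded as a circle of circumference nNodes * dx in the z = 0 plane.
#' @param grid a \linkS4class{TissueGrid}
#' @return matrix with columns x, y, z
#' @export
nodePositions <- function(grid) {
  stopifnot(is(grid, "TissueGrid"))
  dx <- grid@dx
  if (grid@topology == "sheet") {
    nx <- grid@dims[1]; ny <- grid@dims[2]
    cbind(x = rep((seq_len(nx) - 1) * dx, ny),
          y = rep((seq_len(ny) - 1) * dx, each = nx), z = 0)
  } else if (grid@topology == "ring") {
    n <- grid@dims[1]
    R <- n * dx / (2 * pi)
    th <- 2 * pi * (seq_len(n) - 1) / n
    cbind(x = R * cos(th), y = R * sin(th), z = 0)
  } else {
    n <- grid@dims[1]
    cbind(x = (seq_len(n) - 1) * dx, y = 0, z = 0)
  }
}

#' Per-node fiber unit vectors
#' @param grid a \linkS4class{TissueGrid}
#' @return matrix with columns fx, fy (unit norm)
#' @export
fiberVectors <- function(grid) {
  stopifnot(is(grid, "TissueGrid"))
  if (grid@topology == "ring") {
    n <- grid@dims[1]
    th <- 2 * pi * (seq_len(n) - 1) / n
    return(cbind(fx = -sin(th), fy = cos(th)))
  }
  a <- grid@fiberAngle * pi / 180
  cbind(fx = cos(a), fy = sin(a))
}

#' Serialize a grid as structured text
#'
#' A commented header (dims, dx, topology) followed by a columnar table of
#' region, fiber angle and conductivities; the inverse of
#' \code{readTissueGrid}.
#' @param grid a \linkS4class{TissueGrid}
#' @param file output path
#' @export
writeTissueGrid <- function(grid, file) {
  stopifnot(is(grid, "TissueGrid"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# atriasim TissueGrid v1",
               paste("# dims:", paste(grid@dims, collapse = " ")),
               paste("# dx_um:", grid@dx),
               paste("# topology:", grid@topology)), con)
  df <- data.frame(region = grid@region, fiberAngle = grid@fiberAngle,
                   sigmaL = grid@sigmaL, sigmaT = grid@sigmaT)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeTissueGrid
#' @export
readTissueGrid <- function(file) {
  hdr <- readLines(file, n = 4)
  if (!grepl("atriasim TissueGrid", hdr[1])) stop("not an atriasim grid file")
  dims <- as.integer(strsplit(sub("# dims: *", "", hdr[2]), " ")[[1]])
  dx <- as.numeric(sub("# dx_um: *", "", hdr[3]))
  topo <- sub("# topology: *", "", hdr[4])
  df <- read.table(file, sep = "\t", header = TRUE, skip = 4,
                   stringsAsFactors = FALSE)
  new("TissueGrid", dims = dims, dx = dx, topology = topo,
      region = df$region, fiberAngle = df$fiberAngle,
      sigmaL = df$sigmaL, sigmaT = df$sigmaT)
}
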