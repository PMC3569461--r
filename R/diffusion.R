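## Discrete anisotropic diffusion operator div(D grad .) on the structured
## grid, with D(x) = sigma_l f f' + sigma_t (I - f f').  Diagonal terms use a
## conservative flux form with face-averaged conductivity and zero-flux
## boundary faces; fiber rotation introduces cross-derivative terms
## discretized with centred differences and mirrored indices at boundaries.
## Entries carry sigma in S/m and dx in micrometres; the monodomain driver
## rescales by 1e9 / (Sv * cmArea) to obtain mV/ms.

#' Assemble the diffusion operator of a grid
#'
#' Returns the sparse matrix A approximating div(D grad u) with no-flux
#' boundaries (periodic on rings).  Rows sum to zero, so a spatially uniform
#' state generates no diffusion current, and A is invariant to flipping the
#' fiber sign (D depends on f only through f f').
#'
#' @param grid a \linkS4class{TissueGrid}
#' @return a \code{dgCMatrix} of dimension nNodes x nNodes
#' @export
assembleDiffusion <- function(grid) {
  stopifnot(is(grid, "TissueGrid"))
  fib <- fiberVectors(grid)
  sl <- grid@sigmaL; st <- grid@sigmaT
  Dxx <- sl * fib[, 1]^2 + st * fib[, 2]^2
  Dyy <- sl * fib[, 2]^2 + st * fib[, 1]^2
  Dxy <- (sl - st) * fib[, 1] * fib[, 2]
  if (any(Dxx <= 0) || any(Dyy <= 0) || any(Dxx * Dyy - Dxy^2 <= 0))
    stop("diffusion tensor not positive-definite")
  dx <- grid@dx
  if (grid@topology %in% c("cable", "ring"))
    .assemble1d(grid@dims[1], dx, sl, periodic = grid@topology == "ring")
  else
    .assemble2d(grid@dims[1], grid@dims[2], dx, Dxx, Dyy, Dxy)
}

.assemble1d <- function(n, dx, sig, periodic) {
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  idx <- seq_len(n)
  right <- if (periodic) c(idx[-1], 1L) else c(idx[-1], NA)
  for (k in idx) {
    r <- right[k]
    if (!is.na(r)) {
      c_face <- (sig[k] + sig[r]) / 2 / dx^2
      add(k, r, c_face); add(k, k, -c_face)
      add(r, k, c_face); add(r, r, -c_face)
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

.assemble2d <- function(nx, ny, dx, Dxx, Dyy, Dxy) {
  n <- nx * ny
  id <- function(ix, iy) (iy - 1L) * nx + ix
  IX <- rep(seq_len(nx), ny)
  IY <- rep(seq_len(ny), each = nx)
  refl <- function(i, nmax) ifelse(i < 1L, 2L - i, ifelse(i > nmax, 2L * nmax - i, i))

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    keep <- v != 0
    ii <<- c(ii, i[keep]); jj <<- c(jj, j[keep]); xx <<- c(xx, v[keep])
  }

  h2 <- dx^2
  # x-direction fluxes between (ix, iy) and (ix+1, iy)
  has <- IX < nx
  a <- id(IX[has], IY[has]); b <- id(IX[has] + 1L, IY[has])
  cf <- (Dxx[a] + Dxx[b]) / 2 / h2
  add(a, b, cf); add(a, a, -cf); add(b, a, cf); add(b, b, -cf)
  # y-direction fluxes
  has <- IY < ny
  a <- id(IX[has], IY[has]); b <- id(IX[has], IY[has] + 1L)
  cf <- (Dyy[a] + Dyy[b]) / 2 / h2
  add(a, b, cf); add(a, a, -cf); add(b, a, cf); add(b, b, -cf)

  if (any(Dxy != 0)) {
    # d/dx(Dxy du/dy) + d/dy(Dxy du/dx), centred with mirrored indices
    c4 <- 1 / (4 * h2)
    for (sx in c(-1L, 1L)) for (sy in c(-1L, 1L)) {
      # term d/dx(Dxy du/dy): contribution sx*sy * Dxy(ix+sx, iy) * u(ix+sx, iy+sy)
      nbx <- refl(IX + sx, nx); nby <- refl(IY + sy, ny)
      nb_mid_x <- id(nbx, IY)                 # (ix+sx, iy)
      nb_diag <- id(nbx, nby)                 # (ix+sx, iy+sy)
      w <- sx * sy * Dxy[nb_mid_x] * c4
      add(seq_len(n), nb_diag, w)
      # term d/dy(Dxy du/dx): contribution sx*sy * Dxy(ix, iy+sy) * u(ix+sx, iy+sy)
      nb_mid_y <- id(IX, nby)
      w2 <- sx * sy * Dxy[nb_mid_y] * c4
      add(seq_len(n), nb_diag, w2)
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}
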