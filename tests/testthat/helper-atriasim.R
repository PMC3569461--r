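# Shared fixtures; heavy objects are computed once per test run and reused.
# calibrateSv()/diastolicThreshold() cache internally, so repeated calls are
# cheap after the first.

.fixtures <- new.env(parent = emptyenv())

fix_get <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# quiescently settled cell state for a variant (20 s free run)
settled_state <- function(region = "AWM", condition = "control") {
  key <- paste0("settled_", region, "_", condition)
  fix_get(key, function() {
    p <- makeCellParams(region, condition)
    s <- restingState()
    for (i in 1:20) s <- stepCell(s, p, iStim = 0, dt = 0.02, n = 50000L)
    s
  })
}

# one-beat cable run used by several electrogram tests
cable_beat <- function() {
  fix_get("cable_beat", function() {
    g <- buildCable(60, 530, "AWM")
    m <- monodomainModel(g, "control", Sv = calibrateSv())
    pr <- stimulusProtocol(start = 2, duration = 6, amplitude = NA,
                           nodes = list(1:3))
    runMonodomain(m, pr, tEnd = 320)
  })
}

# a SimulationResult wrapper around an arbitrary Vm matrix (for EGM algebra)
fake_result <- function(vm, grid) {
  methods::new("SimulationResult", times = seq_len(nrow(vm)) - 1, vm = vm,
               activations = rep(list(numeric(0)), ncol(vm)),
               finalStates = matrix(0, 29, ncol(vm)), grid = grid,
               condition = "control", diverged = FALSE, diagnostics = list())
}

reference_apd <- function() {
  data.frame(
    region = rep(c("CT", "PM", "APG", "AVR", "AWM"), 2),
    condition = rep(c("control", "remodeled"), each = 5),
    apd90 = c(307, 237, 245, 180, 282, 92, 73, 78, 56, 80))
}

last_beat_apd <- function(region, condition) {
  key <- paste0("apd_", region, "_", condition)
  fix_get(key, function() {
    tr <- paceCell(makeCellParams(region, condition), bcl = 1000, nBeats = 10)
    measureAPD90(tr)
  })
}

# Independent dense oracle: apply the same physics (conservative fluxes with
# face-averaged D, centred cross-terms with mirrored indices) by direct
# looping, building the matrix column by column from unit vectors.
dense_oracle <- function(grid) {
  fib <- fiberVectors(grid)
  sl <- grid@sigmaL; st <- grid@sigmaT
  Dxx <- sl * fib[, 1]^2 + st * fib[, 2]^2
  Dyy <- sl * fib[, 2]^2 + st * fib[, 1]^2
  Dxy <- (sl - st) * fib[, 1] * fib[, 2]
  nx <- grid@dims[1]; ny <- grid@dims[2]; h <- grid@dx
  id <- function(ix, iy) (iy - 1) * nx + ix
  refl <- function(i, nmax) if (i < 1) 2 - i else if (i > nmax) 2 * nmax - i else i
  apply_op <- function(u) {
    out <- numeric(nx * ny)
    U <- matrix(u, nx, ny)
    for (ix in 1:nx) for (iy in 1:ny) {
      v <- 0
      # x fluxes (zero at boundary faces)
      if (ix < nx) v <- v + (Dxx[id(ix, iy)] + Dxx[id(ix + 1, iy)]) / 2 *
          (U[ix + 1, iy] - U[ix, iy]) / h^2
      if (ix > 1) v <- v - (Dxx[id(ix, iy)] + Dxx[id(ix - 1, iy)]) / 2 *
          (U[ix, iy] - U[ix - 1, iy]) / h^2
      if (iy < ny) v <- v + (Dyy[id(ix, iy)] + Dyy[id(ix, iy + 1)]) / 2 *
          (U[ix, iy + 1] - U[ix, iy]) / h^2
      if (iy > 1) v <- v - (Dyy[id(ix, iy)] + Dyy[id(ix, iy - 1)]) / 2 *
          (U[ix, iy] - U[ix, iy - 1]) / h^2
      # cross terms with mirrored indices
      for (sx in c(-1, 1)) for (sy in c(-1, 1)) {
        jx <- refl(ix + sx, nx); jy <- refl(iy + sy, ny)
        v <- v + sx * sy * Dxy[id(refl(ix + sx, nx), iy)] *
          U[jx, jy] / (4 * h^2)
        v <- v + sx * sy * Dxy[id(ix, refl(iy + sy, ny))] *
          U[jx, jy] / (4 * h^2)
      }
      out[id(ix, iy)] <- v
    }
    out
  }
  n <- nx * ny
  M <- matrix(0, n, n)
  for (j in 1:n) {
    e <- numeric(n); e[j] <- 1
    M[, j] <- apply_op(e)
  }
  M
}

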