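test_that("uniform potential fields produce a null electrogram", {
  g <- buildSheet(10, 10, 530, "AWM")
  vm <- matrix(42, nrow = 50, ncol = 100)
  r <- fake_result(vm, g)
  eg <- computeEGM(r, electrode(2000, 2000, 200))
  expect_true(all(abs(eg@phi) < 1e-9))
})

test_that("the forward model is linear in Vm", {
  g <- buildSheet(12, 12, 530, "AWM")
  set.seed(11)
  vm <- matrix(rnorm(30 * 144), nrow = 30)
  el <- electrode(3000, 2500, 200)
  p1 <- computeEGM(fake_result(vm, g), el)@phi
  p3 <- computeEGM(fake_result(3 * vm, g), el)@phi
  expect_equal(p3, 3 * p1, tolerance = 1e-12)
})

test_that("electrodes cannot sit in the tissue plane", {
  expect_error(electrode(0, 0, 0), "offset")
  expect_error(electrode(0, 0, -200), "offset")
})

test_that("a passing planar wave writes an RS complex", {
  r <- cable_beat()
  el <- electrode(30 * 530, 0, 200)  # above the cable midpoint
  eg <- computeEGM(r, el)
  ipos <- which.max(eg@phi); ineg <- which.min(eg@phi)
  expect_gt(max(eg@phi), 0)
  expect_lt(min(eg@phi), 0)
  expect_lt(eg@t[ipos], eg@t[ineg])   # positive phase leads (RS morphology)
  # biphasic with comparable lobes rather than monophasic
  expect_gt(min(abs(c(max(eg@phi), min(eg@phi)))) /
            max(abs(c(max(eg@phi), min(eg@phi)))), 0.2)
})

test_that("doubling the electrode offset strictly reduces the peak", {
  r <- cable_beat()
  a <- computeEGM(r, electrode(30 * 530, 0, 200))
  b <- computeEGM(r, electrode(30 * 530, 0, 400))
  expect_lt(max(abs(b@phi)), max(abs(a@phi)))
})

test_that("colliding wavefronts yield positive-dominant potentials", {
  g <- buildCable(60, 530, "AWM")
  m <- monodomainModel(g, "control", Sv = calibrateSv())
  pr <- stimulusProtocol(start = c(2, 2), duration = 6, amplitude = NA,
                         nodes = list(1:3, 58:60))
  r <- runMonodomain(m, pr, tEnd = 320)
  eg <- computeEGM(r, electrode(29.5 * 530, 0, 200))  # collision site
  expect_gt(max(eg@phi), abs(min(eg@phi)))
})

test_that("a wavefront emerging under the electrode and receding is negative-dominant", {
  sv <- calibrateSv()
  g <- buildSheet(31, 31, 530, "AWM")
  m <- monodomainModel(g, "control", Sv = sv)
  ctr <- which(rep(1:31, 31) == 16 & rep(1:31, each = 31) == 16)
  pr <- stimulusProtocol(start = 2, duration = 6, amplitude = NA,
                         nodes = list(patchNodes(g, ctr, area_mm2 = 2)))
  r <- runMonodomain(m, pr, tEnd = 300, checkCapture = FALSE)
  eg <- computeEGM(r, electrode(15 * 530, 15 * 530, 200))
  expect_gt(abs(min(eg@phi)), max(eg@phi))   # QS-like
})

test_that("electrode arrays cover the lattice and see time-shifted copies", {
  r <- cable_beat()
  egs <- computeEGMArray(r, spacing = 4 * 530, offset = 200)
  expect_equal(length(egs), 15)

  # electrodes on one isochrone line of a plane wave record time-shifted
  # copies of one waveform
  sh <- fix_get("sheet_beat", function() {
    g <- buildSheet(30, 24, 530, "AWM")
    m <- monodomainModel(g, "control", Sv = calibrateSv())
    pr <- stimulusProtocol(start = 2, duration = 6, amplitude = NA,
                           nodes = list(edgeNodes(g, "left", 2)))
    runMonodomain(m, pr, tEnd = 300)
  })
  iso <- lapply(c(8, 12, 16), function(iy)
    computeEGM(sh, electrode(15 * 530, iy * 530, 200)))
  xc <- function(a, b) {
    cc <- stats::ccf(a@phi, b@phi, lag.max = 100, plot = FALSE)
    max(cc$acf)
  }
  expect_gt(xc(iso[[1]], iso[[2]]), 0.99)
  expect_gt(xc(iso[[2]], iso[[3]]), 0.99)

  g <- buildSheet(20, 20, 530, "AWM")
  vm <- matrix(0, nrow = 10, ncol = 400)
  arr <- computeEGMArray(fake_result(vm, g), spacing = 1060)
  expect_equal(length(arr), 100)   # 10 x 10 lattice
})
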