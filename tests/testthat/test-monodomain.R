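test_that("unstimulated tissue stays quiescent", {
  g <- buildCable(20, 530, "AWM")
  m <- monodomainModel(g, "control", Sv = calibrateSv())
  init <- matrix(unname(settled_state("AWM", "control")), nrow = 29, ncol = 20)
  pr <- stimulusProtocol(start = numeric(0), duration = numeric(0),
                         amplitude = numeric(0), nodes = list())
  r <- runMonodomain(m, pr, tEnd = 500, initialStates = init,
                     checkCapture = FALSE)
  expect_lt(max(abs(sweep(r@vm, 2, r@vm[1, ]))), 1)
  expect_true(all(vapply(r@activations, length, 1L) == 0))
  expect_true(all(is.nan(activationMap(r))))
})

test_that("a single end stimulus yields one monotone wavefront", {
  r <- cable_beat()
  act <- activationMap(r)
  expect_true(all(is.finite(act)))
  # strictly increasing with distance beyond the stimulated region
  expect_true(all(diff(act[4:60]) > 0))
  expect_equal(vapply(r@activations, length, 1L), rep(1L, 60))
})

test_that("conduction velocity scales as the square root of conductivity", {
  # measured at the fine end of the resolution range so the upstroke is
  # spatially resolved for both conductivities
  sv <- calibrateSv()
  cv_for_sigma <- function(scale) {
    g <- buildCable(150, 300, "AWM")
    g@sigmaL <- g@sigmaL * scale
    g@sigmaT <- g@sigmaT * scale
    m <- monodomainModel(g, "control", Sv = sv)
    pr <- stimulusProtocol(start = 2, duration = 6, amplitude = NA,
                           nodes = list(1:3))
    measureCV(runMonodomain(m, pr, tEnd = 300, recordVm = FALSE))
  }
  cv1 <- cv_for_sigma(1)
  cv4 <- cv_for_sigma(4)
  expect_equal(cv4 / cv1, 2, tolerance = 0.05)
})

test_that("halving the time step changes CV by under 2 percent", {
  sv <- calibrateSv()
  cv_at_dt <- function(dt) {
    m <- monodomainModel(buildCable(80, 530, "AWM"), "control", Sv = sv,
                         dt = dt)
    pr <- stimulusProtocol(start = 2, duration = 6, amplitude = NA,
                           nodes = list(1:3))
    measureCV(runMonodomain(m, pr, tEnd = 200, recordVm = FALSE))
  }
  expect_equal(cv_at_dt(0.01) / cv_at_dt(0.02), 1, tolerance = 0.02)
})

test_that("simulations are deterministic and capture failures are explicit", {
  g <- buildCable(30, 530, "AWM")
  m <- monodomainModel(g, "control", Sv = calibrateSv())
  pr <- stimulusProtocol(start = 2, duration = 6, amplitude = NA,
                         nodes = list(1:3))
  a <- runMonodomain(m, pr, tEnd = 120)
  b <- runMonodomain(m, pr, tEnd = 120)
  expect_identical(a@vm, b@vm)

  weak <- stimulusProtocol(start = 2, duration = 6, amplitude = 10,
                           nodes = list(1:3))
  expect_error(runMonodomain(m, weak, tEnd = 120), "loss of capture")
})

test_that("isotropic and anisotropic point stimuli shape the isochrones", {
  sv <- calibrateSv()
  # isotropic region: circular isochrones
  g <- buildSheet(41, 41, 530, "ISTHMUS")
  m <- monodomainModel(g, "control", Sv = sv)
  ctr <- which(rep(1:41, 41) == 21 & rep(1:41, each = 41) == 21)
  pr <- stimulusProtocol(start = 2, duration = 6, amplitude = NA,
                         nodes = list(patchNodes(g, ctr, area_mm2 = 3)))
  r <- runMonodomain(m, pr, tEnd = 260, recordVm = FALSE)
  act <- activationMap(r)
  # compare arrival time at equal distances along x and y from the centre
  tx <- mean(c(act[21 + 15, 21], act[21 - 15, 21]))
  ty <- mean(c(act[21, 21 + 15], act[21, 21 - 15]))
  expect_equal(tx / ty, 1, tolerance = 0.05)

  # 1:2 anisotropy: elliptical isochrones with axis ratio ~ sqrt(2)
  g2 <- buildSheet(41, 41, 530, "AWM")
  m2 <- monodomainModel(g2, "control", Sv = sv)
  r2 <- runMonodomain(m2, stimulusProtocol(start = 2, duration = 6,
         amplitude = NA, nodes = list(patchNodes(g2, ctr, area_mm2 = 3))),
         tEnd = 260, recordVm = FALSE)
  act2 <- activationMap(r2)
  tx2 <- mean(c(act2[21 + 15, 21], act2[21 - 15, 21])) - 5
  ty2 <- mean(c(act2[21, 21 + 15], act2[21, 21 - 15])) - 5
  expect_equal(ty2 / tx2, sqrt(2), tolerance = 0.2)
})

test_that("waves circulate rings with preserved waveform", {
  sv <- calibrateSv()
  ring <- buildRing(60, 530, "AWM")
  m <- monodomainModel(ring, "control", Sv = sv)
  pr <- stimulusProtocol(start = 2, duration = 6, amplitude = NA,
                         nodes = list(1:3))
  r <- runMonodomain(m, pr, tEnd = 200, recordVm = TRUE,
                     checkCapture = FALSE)
  # symmetric split: the two wavefronts collide at the far side (the mirror
  # point of the three-node stimulus centre at node 2 is node 32)
  act <- activationMap(r)
  expect_true(all(is.finite(act)))
  expect_true(which.max(act) %in% 31:33)
  # waveform at mirror-image nodes is identical (periodicity/symmetry)
  expect_equal(r@vm[, 10], r@vm[, 54], tolerance = 1e-6)
})
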