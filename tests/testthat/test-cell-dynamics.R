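test_that("the settled resting state is quiescent", {
  p <- makeCellParams("AWM", "control")
  s <- settled_state("AWM", "control")
  # one further second without stimulus moves Vm by well under 1 mV
  s2 <- stepCell(s, p, iStim = 0, dt = 0.02, n = 50000L)
  expect_lt(abs(s2["Vm"] - s["Vm"]), 1)
  # from the published initial conditions the variant's higher I_K1 pulls the
  # cell toward its own rest; the excursion stays bounded
  r0 <- restingState()
  r1 <- stepCell(r0, p, iStim = 0, dt = 0.02, n = 50000L)
  expect_lt(abs(r1["Vm"] - r0["Vm"]), 8)
})

test_that("a suprathreshold pulse elicits a fast upstroke", {
  p <- makeCellParams("AWM", "control")
  tr <- paceCell(p, bcl = 1000, nBeats = 1, tailMs = 100)
  expect_gt(max(tr@dvdt), 100)            # V/s-scale atrial upstroke
  expect_gt(max(tr@vm), 0)
})

test_that("over-large time steps are rejected", {
  p <- makeCellParams("AWM", "control")
  expect_error(stepCell(restingState(), p, dt = 10), "stability limit")
  expect_error(stepCell(restingState(), p, dt = 0.5), "stability limit")
})

test_that("pacing is deterministic and loss of capture is an explicit error", {
  p <- makeCellParams("PM", "remodeled")
  a <- paceCell(p, bcl = 500, nBeats = 3, tailMs = 100)
  b <- paceCell(p, bcl = 500, nBeats = 3, tailMs = 100)
  expect_identical(a@vm, b@vm)
  expect_error(paceCell(p, bcl = 500, nBeats = 2, stimAmplitude = 5),
               "loss of capture")
  expect_error(paceCell(p, bcl = 500, nBeats = 0), "nBeats")
})

test_that("gates stay in [0,1] and concentrations positive under fast pacing", {
  gate_idx <- 2:13
  conc_idx <- 14:20
  for (cfg in list(c("AWM", "remodeled", 130), c("AWM", "control", 1000))) {
    p <- makeCellParams(cfg[1], cfg[2])
    bcl <- as.numeric(cfg[3])
    n <- max(3, round(3000 / bcl))
    st <- atriasim:::.paceCellStates(p, bcl = bcl, nBeats = n, recordDt = 5)
    expect_true(all(st$states[gate_idx, ] >= 0))
    expect_true(all(st$states[gate_idx, ] <= 1))
    expect_true(all(st$states[conc_idx, ] > 0))
    expect_true(all(is.finite(st$states)))
  }
})

test_that("APD90 is exact on an analytic square pulse", {
  tt <- 0:500
  vv <- ifelse(tt >= 100 & tt < 300, 100, 0)
  expect_equal(measureAPD90(list(t = tt, vm = vv)), 200, tolerance = 0.02)
})

test_that("remodeling shortens APD90 in every region and compresses dispersion", {
  tab <- expand.grid(region = cellVariantRegions(),
                     condition = c("control", "remodeled"),
                     stringsAsFactors = FALSE)
  tab$apd <- mapply(last_beat_apd, tab$region, tab$condition)
  ctrl <- tab$apd[tab$condition == "control"]
  remo <- tab$apd[tab$condition == "remodeled"]
  names(ctrl) <- names(remo) <- tab$region[tab$condition == "control"]
  expect_true(all(remo < ctrl))
  # CT longest and AVR shortest in both conditions
  expect_equal(names(which.max(ctrl)), "CT")
  expect_equal(names(which.min(ctrl)), "AVR")
  expect_equal(names(which.max(remo)), "CT")
  expect_equal(names(which.min(remo)), "AVR")
  # remodeling flattens the regional APD dispersion
  expect_lt(diff(range(remo)), diff(range(ctrl)))
})
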