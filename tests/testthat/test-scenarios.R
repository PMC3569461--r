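test_that("ring macroreentry circulates at the target rate with single potentials", {
  rf <- fix_get("ringflutter", function()
    runRingFlutter("remodeled", cycleMs = 200))
  expect_true(rf$sustained)
  tab <- rf$table
  # every electrode sees the circulation frequency, ~5 Hz
  expect_true(all(abs(tab$df - 1000 / 200) < 0.75))
  # cycle length nearly constant across the ring
  expect_true(all(tab$sdCL < 10, na.rm = TRUE))
  expect_lt(max(tab$meanCL) - min(tab$meanCL), 10)
})

test_that("the focal-fibrillation driver runs and captures near the focus", {
  ff <- runFocalAF("remodeled", nx = 40, ny = 40, tEnd = 5300, focusCl = 130)
  expect_true(is.data.frame(ff$near))
  # near-focus electrodes follow the focus frequency on this small sheet
  expect_true(all(is.finite(ff$near$df)))
})

test_that("the regional velocity ordering follows the conductivity ladder", {
  tab <- fix_get("cvtable_control", function() runCVTable("control"))
  expect_true(all(tab$ok))
  cv <- stats::setNames(tab$cv, tab$region)
  expect_true(cv["CT"] > cv["BB"] && cv["BB"] > cv["AWM"] &&
              cv["AWM"] > cv["PV"] && cv["PV"] > cv["ISTHMUS"] &&
              cv["ISTHMUS"] > cv["SAN"])
})
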