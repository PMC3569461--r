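test_that("regional conductance lookup returns the tabulated values", {
  awm <- makeCellParams("AWM", "control")
  expect_equal(unname(conductances(awm)), c(7.5, 6.7, 0.5, 4.2))
  expect_equal(awm@tauFCaLScale, 1)
  expect_equal(awm@itActShift, 0)

  awm_r <- makeCellParams("AWM", "remodeled")
  expect_equal(unname(conductances(awm_r)["gK1"]), 10.5)
  expect_equal(unname(conductances(awm_r)["gK1"]) /
               unname(conductances(awm)["gK1"]), 2.5)

  ct_r <- makeCellParams("CT", "remodeled")
  expect_equal(unname(conductances(ct_r)["gCaL"]), 2.7)
  # the stated 74% I_CaL reduction, realized as the tabulated value
  expect_equal(2.7 / 10.3, 0.26, tolerance = 0.01)

  # remodeling kinetic modifications
  expect_equal(ct_r@tauFCaLScale, 1.62)
  expect_equal(ct_r@itActShift, 16)
  expect_equal(ct_r@iNaInactShift, 1.6)
})

test_that("unknown regions and conditions are rejected", {
  expect_error(makeCellParams("SAN", "control"), "unknown cell variant")
  expect_error(makeCellParams("XX", "control"), "unknown cell variant")
  expect_error(makeCellParams("AWM", "weird"))
})

test_that("parameter sets round-trip through text export", {
  p <- makeCellParams("APG", "remodeled")
  f <- tempfile(fileext = ".tsv")
  exportCellParams(p, f)
  q <- importCellParams(f)
  expect_equal(conductances(q), conductances(p))
  expect_equal(q@tauFCaLScale, p@tauFCaLScale)
  expect_equal(q@region, "APG")
  unlink(f)
})
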