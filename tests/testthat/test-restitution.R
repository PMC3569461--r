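test_that("APD restitution is monotone and flattened by remodeling", {
  cis <- c(250, 500, 1000)
  ctrl <- restitutionCurve(makeCellParams("AWM", "control"), cis)
  remo <- restitutionCurve(makeCellParams("AWM", "remodeled"), cis)
  okc <- ctrl$captured; okr <- remo$captured
  expect_true(all(okc[cis >= 500]))
  expect_true(all(okr))

  # monotone non-decreasing with coupling interval
  expect_true(all(diff(ctrl$apd90[okc]) >= -2))
  expect_true(all(diff(remo$apd90[okr]) >= -2))

  # remodeled curve lies below control everywhere both captured
  both <- okc & okr
  expect_true(all(remo$apd90[both] < ctrl$apd90[both]))

  # and is flatter: less APD accommodation over the shared CI range
  slope <- function(d) {
    ok <- d$captured
    diff(range(d$apd90[ok])) / diff(range(d$ci[ok]))
  }
  expect_lt(slope(remo), slope(ctrl))

  # the CI = 1000 ms point agrees with steady 1 Hz pacing
  expect_equal(ctrl$apd90[ctrl$ci == 1000], last_beat_apd("AWM", "control"),
               tolerance = 0.06)
})
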