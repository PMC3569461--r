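test_that("cable construction matches the conductivity table", {
  g <- buildCable(150, 530, "AWM")
  expect_equal(prod(g@dims) * g@dx / 1e4, 7.95, tolerance = 0.01)  # ~7.9 cm
  expect_true(all(g@sigmaL == 0.2))
  expect_true(all(g@sigmaT == 0.1))

  san <- buildCable(3, 530, "SAN")
  expect_true(all(san@sigmaL == 0.05))
  expect_identical(san@sigmaL, san@sigmaT)   # isotropic node

  expect_error(buildCable(2, 530, "AWM"), "at least 3 nodes")
  expect_error(buildCable(10, 200, "AWM"), "300-700")
  expect_error(buildCable(10, 900, "AWM"), "300-700")
})

test_that("sheet and ring construction follow the regional policy", {
  ct <- buildSheet(10, 10, 530, "CT")
  expect_true(all(ct@sigmaL == 0.7))
  expect_equal(ct@sigmaT[1], 0.7 / 9)

  ring <- buildRing(200, 530, "AWM")
  expect_equal(200 * 530 / 1e4, 10.6)        # circumference, cm
  expect_equal(ring@topology, "ring")
  f <- fiberVectors(ring)
  expect_equal(sqrt(rowSums(f^2)), rep(1, 200), tolerance = 1e-12)
})

test_that("conductivity lookup round-trips the six tabulated rows exactly", {
  tab <- conductivityTable(c("CT", "BB", "PV", "ISTHMUS", "SAN", "AWM"))
  expect_equal(tab$sigmaL, c(0.7, 0.5, 0.15, 0.1, 0.05, 0.2))
  expect_equal(tab$ratio, c(1 / 9, 1 / 2, 1 / 2, 1, 1, 1 / 2))
  # inverse lookup: sigma pair identifies the row
  for (i in seq_len(nrow(tab))) {
    hit <- conductivityTable()$region[
      conductivityTable()$sigmaL == tab$sigmaL[i] &
      conductivityTable()$ratio == tab$ratio[i]]
    expect_true(tab$region[i] %in% hit)
  }
  expect_error(conductivityTable("LV"), "unknown region")
})

test_that("strip sheets embed the strip and degenerate to plain sheets", {
  g <- buildStripSheet(20, 20, 530, "AWM", "CT", stripRows = 9:11)
  iy <- rep(1:20, each = 20)
  expect_true(all(g@sigmaL[iy %in% 9:11] == 0.7))
  expect_true(all(g@sigmaL[!iy %in% 9:11] == 0.2))
  expect_equal(unique(g@sigmaT[iy %in% 9:11]), 0.7 / 9)

  same <- buildStripSheet(20, 20, 530, "AWM", "AWM", stripRows = 9:11)
  plain <- buildSheet(20, 20, 530, "AWM")
  expect_identical(same@sigmaL, plain@sigmaL)
  expect_identical(same@region, plain@region)

  expect_error(buildStripSheet(20, 20, 530, "AWM", "CT",
                               stripRows = integer(0)), "non-empty")
  expect_error(buildStripSheet(20, 20, 530, "AWM", "CT", stripRows = 19:22),
               "outside")
})

test_that("grids serialize to text and back", {
  g <- buildStripSheet(8, 8, 400, "AWM", "CT", stripRows = 4:5)
  f <- tempfile(fileext = ".txt")
  writeTissueGrid(g, f)
  h <- readTissueGrid(f)
  expect_identical(h@dims, g@dims)
  expect_equal(h@dx, g@dx)
  expect_identical(h@region, g@region)
  expect_equal(h@sigmaL, g@sigmaL)
  unlink(f)
})
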