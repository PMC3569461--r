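test_that("operator rows sum to zero and kill uniform fields", {
  for (g in list(buildCable(12, 530, "AWM"),
                 buildRing(12, 530, "AWM"),
                 buildSheet(6, 6, 530, "AWM", fiberAngle = 37),
                 buildStripSheet(8, 8, 530, "AWM", "CT", 4:5))) {
    A <- assembleDiffusion(g)
    expect_lt(max(abs(Matrix::rowSums(A))), 1e-12)
    u <- rep(13.7, prod(g@dims))
    expect_lt(max(abs(as.numeric(A %*% u))), 1e-10)
  }
})

test_that("sparse assembly matches the dense brute-force oracle on 5x5 sheets", {
  for (ang in c(0, 30, 90)) {
    g <- buildSheet(5, 5, 530, "CT", fiberAngle = ang)
    A <- as.matrix(assembleDiffusion(g))
    M <- dense_oracle(g)
    expect_lt(max(abs(A - M)), 1e-12)
  }
})

test_that("tensor assembly is invariant to fiber sign flips", {
  g1 <- buildSheet(6, 6, 530, "AWM", fiberAngle = 25)
  g2 <- buildSheet(6, 6, 530, "AWM", fiberAngle = 25 + 180)
  expect_equal(as.matrix(assembleDiffusion(g1)),
               as.matrix(assembleDiffusion(g2)), tolerance = 1e-14)
})

test_that("rotating fibers by 90 degrees transposes the grid axes", {
  n <- 7
  g0 <- buildSheet(n, n, 530, "AWM", fiberAngle = 0)
  g90 <- buildSheet(n, n, 530, "AWM", fiberAngle = 90)
  A0 <- assembleDiffusion(g0); A90 <- assembleDiffusion(g90)
  u <- matrix(stats::rnorm(n * n), n, n)
  r0 <- matrix(as.numeric(A0 %*% as.numeric(u)), n, n)
  r90 <- matrix(as.numeric(A90 %*% as.numeric(t(u))), n, n)
  expect_equal(r0, t(r90), tolerance = 1e-12)
})

test_that("non-positive tensors are rejected", {
  g <- buildCable(5, 530, "AWM")
  g@sigmaT[2] <- -0.1
  expect_error(validObject(g))
})
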