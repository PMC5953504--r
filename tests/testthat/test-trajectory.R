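test_that("degenerate trajectories: zero variance and pure drift", {
  p <- sampleTrajectory(0, c(0, 0), 10, 10, seed = 1)
  expect_equal(dim(p), c(10L, 2L))
  expect_true(all(p == 0))

  p <- sampleTrajectory(0, c(5, 0), 4, 10, seed = 1)
  expect_equal(p[, 1], c(0, 5, 10, 15))
  expect_equal(p[, 2], rep(0, 4))
})

test_that("per-step displacement variance matches 2*D*dt per axis", {
  D <- 7.3e-9; dt <- 10
  p <- sampleTrajectory(D, c(0, 0), 10001, dt, seed = 42)
  vx <- var(diff(p[, 1]))
  expected <- 2 * D * 1e14 * dt
  expect_lt(abs(vx - expected) / expected, 0.05)
})

test_that("confined walks stay within the confinement radius", {
  p <- sampleTrajectory(7.3e-9, c(0, 0), 500, 10, seed = 3,
                        confinementRadius = 75)
  expect_true(all(sqrt(rowSums(p^2)) <= 75 + 1e-9))
})

test_that("invalid parameters are rejected", {
  expect_error(sampleTrajectory(-1e-9, c(0, 0), 5, 10), "invalid")
  expect_error(sampleTrajectory(1e-9, c(0, 0), 5, -1), "invalid")
  expect_error(sampleTrajectory(1e-9, c(0, 0), 0, 10), "invalid")
})

test_that("trajectories are reproducible under a fixed seed", {
  a <- sampleTrajectory(2.1e-9, c(1, -1), 50, 10, seed = 7)
  b <- sampleTrajectory(2.1e-9, c(1, -1), 50, 10, seed = 7)
  expect_identical(a, b)
})

test_that("diffusion unit conversion is exact", {
  expect_identical(convertD(convertD(7.3e-9, "cm2", "nm2"), "nm2", "cm2"),
                   7.3e-9)
  expect_equal(convertD(1, "cm2", "nm2"), 1e14)
})
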