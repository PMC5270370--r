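test_that("readFixes parses, groups by animal and rejects bad timestamps", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = "a", ts = c(0, 3600, 7200),
                       x = c(0, 3, 3), y = c(0, 4, 9)), f, row.names = FALSE)
  cols <- c(id = "id", time = "ts", x = "x", y = "y")
  fx <- readFixes(f, columns = cols)
  expect_length(fx, 1)
  expect_length(fx[["a"]]$t, 3)

  write.csv(data.frame(id = c("a", "a", "b", "b"), ts = c(0, 3600, 0, 3600),
                       x = 0, y = 0), f, row.names = FALSE)
  expect_named(readFixes(f, columns = cols), c("a", "b"))

  write.csv(data.frame(id = "a", ts = c(0, 3600, 3600), x = 0, y = 0),
            f, row.names = FALSE)
  expect_error(readFixes(f, columns = cols), "duplicate timestamp")

  expect_error(readFixes(f, columns = c(id = "id", time = "when", x = "x", y = "y")),
               "not present")
  expect_error(readFixes(f, columns = c(id = "id", x = "x", y = "y")), "must map")
})

test_that("deriveSteps computes hand-checked geometry with destination hours", {
  fx <- fixSeries("a", c(0, 3600, 7200), x = c(0, 3, 3), y = c(0, 4, 9))
  tr <- deriveSteps(fx)
  expect_equal(tr$step_m, c(5, 5))
  expect_true(is.na(tr$turn_rad[1]))
  expect_equal(tr$turn_rad[2], atan2(5, 0) - atan2(4, 3), tolerance = 1e-12)
  expect_equal(tr$hour, c(1, 2))        # hour of the destination fix
  expect_equal(deriveSteps(fx, hourFrom = "start")$hour, c(0, 1))

  # collinear eastward: all defined turning angles are zero
  fx2 <- fixSeries("a", 3600 * (0:4), x = 0:4 * 10, y = rep(0, 5))
  expect_equal(deriveSteps(fx2)$turn_rad, c(NA, 0, 0, 0))
})

test_that("gaps exceeding the tolerance break segments and drop spanning steps", {
  fx <- fixSeries("a", 3600 * c(0, 1, 2, 5, 6), x = c(0:2, 10, 11), y = rep(0, 5))
  tr <- deriveSteps(fx)
  expect_equal(nrow(tr), 3)             # the 3 h gap step is excluded
  expect_equal(tr$segment, c(1L, 1L, 2L))
  expect_true(is.na(tr$turn_rad[3]))    # first step of the new segment
  # within tolerance (6 min) the segment is kept together
  fx2 <- fixSeries("a", c(0, 3600, 3600 * 2 + 300), x = 0:2, y = rep(0, 3))
  expect_equal(deriveSteps(fx2)$segment, c(1L, 1L))
  # single fix: warning + empty series
  expect_warning(tr0 <- deriveSteps(fixSeries("a", 0, 0, 0)), "fewer than 2")
  expect_equal(nrow(tr0), 0)
})

test_that("step lengths are rigid-motion invariant, turning angles rotation invariant", {
  set.seed(11)
  xy <- cbind(cumsum(rnorm(30, 0, 50)), cumsum(rnorm(30, 0, 50)))
  base <- deriveSteps(fixSeries("a", 3600 * (0:29), xy[, 1], xy[, 2]))
  for (phi in c(0.7, -2.1)) {
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
    rot <- xy %*% t(R)
    moved <- deriveSteps(fixSeries("a", 3600 * (0:29),
                                   rot[, 1] + 1234, rot[, 2] - 987))
    expect_equal(moved$step_m, base$step_m, tolerance = 1e-9)
    expect_equal(moved$turn_rad, base$turn_rad, tolerance = 1e-9)
  }
})

test_that("reconstructCoords followed by deriveSteps recovers the series", {
  set.seed(21)
  T <- 40
  turn <- periodicHMM:::.wrapAngle(runif(T, -pi, pi))
  turn[1] <- NA
  tr <- trajectory(rlnorm(T, 3, 1), turn, hour = seq_len(T) %% 24,
                   segment = rep(1L, T))
  coords <- reconstructCoords(tr, x0 = 5, y0 = -3, heading0 = 0.4)
  back <- deriveSteps(fixSeries("a", 3600 * (0:T), coords[, 1], coords[, 2]))
  expect_equal(back$step_m, tr$step_m, tolerance = 1e-9)
  expect_equal(back$turn_rad[-1], tr$turn_rad[-1], tolerance = 1e-9)
})

test_that("trajectory CSV round-trips including missing angles", {
  tr <- randomSeries(25, seed = 3, segments = 3)
  f <- tempfile(fileext = ".csv")
  writeTrajectory(tr, f)
  back <- readTrajectory(f)
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-12)
  expect_error(readTrajectory(tempfile()), "not found")
})

test_that("trajectory validator enforces the stated invariants", {
  expect_error(trajectory(-1, NA, 0, 1), "non-negative")
  expect_error(trajectory(1, 4, 0, 1), "-pi")
  expect_error(trajectory(c(1, 1), c(NA, 0), c(0, 25), c(1, 1)), "hour")
  expect_error(trajectory(c(1, 1), c(NA, 0), c(0, 1), c(2, 1)), "non-decreasing")
})
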