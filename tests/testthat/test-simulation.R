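test_that("simulation is seed-deterministic and respects the state model", {
  p <- pantherProfile("default")
  a <- simulateHMM(p$spec, p$theta, T = 500, seed = 14)
  b <- simulateHMM(p$spec, p$theta, T = 500, seed = 14)
  expect_identical(a$states, b$states)
  expect_identical(a$series, b$series)
  expect_true(all(a$states %in% 1:2))
  expect_true(is.na(a$series$turn_rad[1]))

  sp1 <- hmmSpec(1, "homogeneous")
  th1 <- hmmTheta(sp1, 1, periodicHMM:::.betaSkeleton(sp1),
                  emissionParams("lognormal", meanlog = 3, sdlog = 0.5))
  s1 <- simulateHMM(sp1, th1, T = 4000, seed = 3)
  expect_identical(unique(s1$states), 1L)
  expect_equal(mean(log(s1$series$step_m)), 3, tolerance = 3 * 0.5 / sqrt(4000))
})

test_that("dwell times under a homogeneous simulation are geometric", {
  sp <- hmmSpec(2, "homogeneous")
  b <- periodicHMM:::.betaSkeleton(sp)
  b[1, 1, 1] <- -log(9)   # pi_12 = 0.1 -> mean dwell 10
  b[2, 1, 1] <- log(9)    # pi_22 = 0.9
  th <- hmmTheta(sp, c(0.5, 0.5), b,
                 emissionParams("lognormal", meanlog = c(1, 4), sdlog = c(0.5, 0.5)))
  sim <- simulateHMM(sp, th, T = 30000, seed = 21)
  runs <- rle(sim$states)
  for (i in 1:2) {
    d <- runs$lengths[runs$values == i]
    d <- d[-c(1, length(d))]   # censored first/last runs
    se <- sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d) - 10), 3 * se)
  }
})

test_that("hourly occupancy cycles under sinusoidal truth and is flat without it", {
  het <- pantherProfile("default")
  sim <- simulateHMM(het$spec, het$theta, T = 24000, seed = 33)
  occ <- tapply(sim$states == 2, floor(sim$series$hour), mean)
  expect_gt(max(occ) - min(occ), 0.3)
  hom <- pantherProfile("homogeneous")
  sim2 <- simulateHMM(hom$spec, hom$theta, T = 24000, seed = 34)
  occ2 <- tapply(sim2$states == 2, floor(sim2$series$hour), mean)
  expect_lt(max(occ2) - min(occ2), 0.12)
})

test_that("coordinate reconstruction matches hand geometry", {
  tr <- trajectory(c(1, 1), c(NA, 0), hour = c(1, 2), segment = c(1L, 1L))
  expect_equal(unname(reconstructCoords(tr)),
               cbind(c(0, 1, 2), c(0, 0, 0)))
  tr2 <- trajectory(c(1, 1), c(NA, pi / 2), hour = c(1, 2), segment = c(1L, 1L))
  expect_equal(unname(reconstructCoords(tr2)),
               cbind(c(0, 1, 1), c(0, 0, 1)), tolerance = 1e-12)
  multi <- trajectory(c(1, 1), c(NA, NA), hour = c(1, 5), segment = c(1L, 2L))
  expect_error(reconstructCoords(multi), "single segment")
})

test_that("GPS noise: identity at sd 0 and Rayleigh inflation of zero steps", {
  coords <- cbind(runif(50), runif(50))
  expect_identical(addGpsNoise(coords, sd = 0), coords)
  # stationary animal: noisy step lengths have mean sd * sqrt(pi)
  still <- trajectory(rep(0, 40000), c(NA, rep(0, 39999)),
                      hour = seq_len(40000) %% 24, segment = rep(1L, 40000))
  noisy <- reobserveWithNoise(still, sd = 5, seed = 9)
  expect_equal(mean(noisy$step_m), 5 * sqrt(pi), tolerance = 0.05)
  expect_identical(noisy$hour, still$hour)
})

test_that("the panther-like fixture has a strong diurnal cycle; profiles validated", {
  fx <- pantherFixture(T = 6000, seed = 2)
  prof <- hourlyProfile(fx$series)
  expect_gt(max(prof$mean) / min(prof$mean), 2)
  expect_identical(pantherFixture(T = 200, seed = 5)$series,
                   pantherFixture(T = 200, seed = 5)$series)
  hom <- pantherFixture(T = 6000, seed = 2, profile = "homogeneous")
  ph <- hourlyProfile(hom$series)
  expect_lt(max(ph$mean) / min(ph$mean), 2)
  expect_error(pantherFixture(T = 100, seed = 1, profile = "nope"), "unknown")
})

test_that("small recovery experiments aggregate frequencies consistently", {
  res <- runRecoveryExperiment(truths = "heterogeneous", noise = FALSE,
                               classes = "sinusoidal", nReps = 2, T = 400,
                               nRange = 2:3, nStarts = 1, seed = 42)
  expect_equal(nrow(res$results), 2)
  expect_equal(sum(res$frequencies$count), 2)
  expect_true(all(res$results$n_selected %in% 2:3))
  expect_equal(recoveryRate(res, "heterogeneous", FALSE, "sinusoidal", 2),
               mean(res$results$n_selected == 2))
  one <- runRecoveryExperiment(truths = "homogeneous", noise = FALSE,
                               classes = "homogeneous", nReps = 1, T = 400,
                               nRange = 2:3, nStarts = 1, seed = 43)
  expect_equal(sum(one$frequencies$count), 1)       # one replicate in total
  expect_equal(sum(one$frequencies$count == 1), 1)  # one-hot
})
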