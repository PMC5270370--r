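test_that("hourly profiles summarise means, SEs and counts per hour", {
  tr <- trajectory(rep(100, 48), c(NA, rep(0, 47)),
                   hour = rep(0:23, 2), segment = rep(1L, 48))
  prof <- hourlyProfile(tr)
  expect_equal(prof$mean, rep(100, 24))
  expect_equal(prof$se, rep(0, 24))
  expect_equal(sum(prof$count), 48)

  # steps equal to their hour index
  tr2 <- trajectory(rep(0:23, 2), c(NA, rep(0, 47)),
                    hour = rep(0:23, 2), segment = rep(1L, 48))
  expect_equal(hourlyProfile(tr2)$mean, 0:23)

  # an empty hour is flagged
  tr3 <- trajectory(1:10, c(NA, rep(0, 9)), hour = rep(0:4, 2),
                    segment = rep(1L, 10))
  expect_warning(p3 <- hourlyProfile(tr3), "no steps")
  expect_true(all(is.na(p3$mean[p3$count == 0])))
  expect_equal(nrow(p3), 24)
})

test_that("step ACF is 1 at lag 0, bounded, white for iid steps, pooled over segments", {
  set.seed(55)
  tr <- trajectory(rlnorm(4000, 2, 0.8), c(NA, rep(0, 3999)),
                   hour = seq_len(4000) %% 24, segment = rep(1L, 4000))
  a <- stepAcf(tr, maxLag = 10)
  expect_identical(a$acf[1], 1)
  expect_true(all(abs(a$acf) <= 1))
  expect_true(all(abs(a$acf[-1]) < 3 / sqrt(4000)))

  # pooling is invariant to segment order
  tr2 <- randomSeries(300, seed = 9, segments = 3, angles = FALSE)
  a2 <- stepAcf(tr2, maxLag = 5)
  perm <- order(match(tr2$segment, c(2, 3, 1)))
  tr3 <- trajectory(tr2$step_m[perm], tr2$turn_rad[perm], tr2$hour[perm],
                    rep(1:3, times = table(tr2$segment)[c(2, 3, 1)]))
  expect_equal(stepAcf(tr3, maxLag = 5)$acf, a2$acf, tolerance = 1e-12)

  expect_warning(stepAcf(tr2, maxLag = 500), "truncating")
})

test_that("the diurnal fixture shows a 24 h autocorrelation peak", {
  fx <- pantherFixture(T = 6000, seed = 4)
  a <- stepAcf(fx$series, maxLag = 30)
  expect_gt(a$acf[24 + 1], a$acf[12 + 1])
  expect_gt(a$acf[24 + 1], a$acf[18 + 1])
  expect_gt(a$acf[24 + 1], 0)
})

test_that("simulated predictions are flat for homogeneous parameters and cyclic otherwise", {
  hom <- pantherProfile("homogeneous")
  fitH <- fakeFit(hom$spec, hom$theta)
  profH <- predictHourlyProfile(fitH, T = 2000, nReps = 200, seed = 6)
  expect_lt(max(profH$mean) - min(profH$mean), 3 * mean(profH$se))

  het <- pantherProfile("default")
  fitS <- fakeFit(het$spec, het$theta)
  profS <- predictHourlyProfile(fitS, T = 2000, nReps = 50, seed = 6)
  expect_gt(max(profS$mean) / min(profS$mean), 2)

  acfS <- predictStepAcf(fitS, T = 2000, nReps = 30, seed = 7, maxLag = 26)
  expect_gt(acfS$acf[25], acfS$acf[13])

  # a homogeneous finite mixture predicts no autocorrelation at all
  fmmSpec <- hmmSpec(2, "homogeneous", fmm = TRUE)
  bf <- periodicHMM:::.betaSkeleton(fmmSpec)
  bf[1, 1, 1] <- -0.5
  fmmTheta <- hmmTheta(fmmSpec, c(0.6, 0.4), bf, het$theta$emission)
  acfF <- predictStepAcf(fakeFit(fmmSpec, fmmTheta), T = 2000, nReps = 30,
                         seed = 8, maxLag = 10)
  expect_true(all(abs(acfF$acf[-1]) < 0.02))
})

test_that("Viterbi-conditional simulation conditions on the decoded states", {
  sp <- hmmSpec(2, "homogeneous")
  b <- periodicHMM:::.betaSkeleton(sp)
  b[1, 1, 1] <- -2; b[2, 1, 1] <- 2
  # near-degenerate emissions: conditional draws sit at the state means
  th <- hmmTheta(sp, c(0.5, 0.5), b,
                 emissionParams("lognormal", meanlog = c(1, 5),
                                sdlog = c(1e-3, 1e-3)))
  sim <- simulateHMM(sp, th, T = 300, seed = 10)
  out <- viterbiConditionalSim(fakeFit(sp, th), sim$series, seed = 11)
  expect_identical(out$states, sim$states)
  expect_equal(out$series$step_m, exp(c(1, 5))[sim$states], tolerance = 0.02)
  again <- viterbiConditionalSim(fakeFit(sp, th), sim$series, seed = 11)
  expect_identical(out$series, again$series)

  # within-sample predictions track the observed diurnal profile even for a
  # homogeneous model (the key caveat about Viterbi-based prediction)
  fx <- pantherFixture(T = 4000, seed = 12)
  fitHom <- fitHMM(fx$series, hmmSpec(2, "homogeneous"), nStarts = 2, seed = 13)
  cond <- viterbiConditionalSim(fitHom, fx$series, seed = 14)
  obs <- hourlyProfile(fx$series)
  prd <- hourlyProfile(cond$series)
  expect_gt(cor(obs$mean, prd$mean), 0.9)
})
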