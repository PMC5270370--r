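test_that("forward, Viterbi and posterior agree with brute-force enumeration", {
  cases <- expand.grid(n = 2:3, kind = c("homogeneous", "sinusoidal"),
                       segments = 1:2, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(cases))) {
    sp <- hmmSpec(cases$n[r], cases$kind[r], angles = TRUE)
    th <- randomTheta(sp, seed = 400 + r)
    tr <- randomSeries(5, seed = 500 + r, segments = cases$segments[r])
    oracle <- bruteHMM(sp, th, tr)
    expect_equal(forwardLoglik(sp, th, tr), oracle$loglik, tolerance = 1e-10)
    expect_identical(viterbiPath(sp, th, tr), oracle$viterbi)
    post <- posteriorProbs(sp, th, tr)
    expect_equal(post, oracle$post, tolerance = 1e-8)
    expect_equal(rowSums(post), rep(1, nrow(tr)), tolerance = 1e-12)
  }
})

test_that("single-state models degenerate to plain density sums", {
  sp <- hmmSpec(1, "homogeneous")
  th <- hmmTheta(sp, 1, periodicHMM:::.betaSkeleton(sp),
                 emissionParams("lognormal", meanlog = 2, sdlog = 0.6))
  tr <- randomSeries(50, seed = 2, segments = 3)
  expect_equal(forwardLoglik(sp, th, tr),
               sum(lognormalLogpdf(pmax(tr$step_m, 0.1), 2, 0.6)))
  expect_identical(viterbiPath(sp, th, tr), rep(1L, 50))
  expect_equal(posteriorProbs(sp, th, tr), matrix(1, 50, 1))
})

test_that("the likelihood is invariant to state relabelling", {
  for (kind in c("homogeneous", "sinusoidal")) {
    sp <- hmmSpec(3, kind)
    th <- randomTheta(sp, seed = 61)
    tr <- randomSeries(40, seed = 62, segments = 2, angles = FALSE)
    for (ord in list(c(2, 1, 3), c(3, 1, 2))) {
      th2 <- permuteTheta(sp, th, ord)
      expect_equal(forwardLoglik(sp, th2, tr), forwardLoglik(sp, th, tr),
                   tolerance = 1e-9)
    }
  }
})

test_that("segments are independent: loglik adds over segments", {
  sp <- hmmSpec(2, "sinusoidal")
  th <- randomTheta(sp, seed = 77)
  tr <- randomSeries(30, seed = 78, segments = 2, angles = FALSE)
  parts <- split(seq_len(30), tr$segment)
  ll <- vapply(parts, function(idx) {
    sub <- trajectory(tr$step_m[idx], tr$turn_rad[idx], tr$hour[idx],
                      tr$segment[idx])
    forwardLoglik(sp, th, sub)
  }, 0)
  expect_equal(forwardLoglik(sp, th, tr), sum(ll), tolerance = 1e-10)
})

test_that("non-finite emission parameters raise a located numerical error", {
  sp <- hmmSpec(2, "homogeneous")
  th <- randomTheta(sp, seed = 5)
  th$emission$step$meanlog[1] <- NaN
  tr <- randomSeries(10, seed = 6, angles = FALSE)
  expect_error(forwardLoglik(sp, th, tr), "time index")
})

test_that("fitting is deterministic and recovers a 2-state homogeneous truth", {
  gen <- pantherProfile("homogeneous")
  sim <- simulateHMM(gen$spec, gen$theta, T = 3000, seed = 99)
  fit <- fitHMM(sim$series, hmmSpec(2, "homogeneous"), nStarts = 2, seed = 17)
  fit2 <- fitHMM(sim$series, hmmSpec(2, "homogeneous"), nStarts = 2, seed = 17)
  expect_identical(fit$theta, fit2$theta)
  expect_identical(fit$loglik, fit2$loglik)
  expect_equal(fit$theta$emission$step$meanlog,
               gen$theta$emission$step$meanlog, tolerance = 0.1)
  # canonical ordering: state 1 is the shortest-step state
  expect_lt(fit$theta$emission$step$meanlog[1],
            fit$theta$emission$step$meanlog[2])
})

test_that("a single-state fit reproduces the closed-form log-Normal MLE", {
  tr <- randomSeries(400, seed = 123, angles = FALSE)
  fit <- fitHMM(tr, hmmSpec(1, "homogeneous"), nStarts = 1, seed = 1)
  ls <- log(pmax(tr$step_m, 0.1))
  expect_equal(fit$theta$emission$step$meanlog, mean(ls), tolerance = 1e-4)
  expect_equal(fit$theta$emission$step$sdlog,
               sqrt(mean((ls - mean(ls))^2)), tolerance = 1e-4)
})

test_that("more starts never lower the best log-likelihood (fixed seed stream)", {
  gen <- pantherProfile("default")
  sim <- simulateHMM(gen$spec, gen$theta, T = 800, seed = 31)
  f1 <- fitHMM(sim$series, hmmSpec(2, "sinusoidal"), nStarts = 1, seed = 4)
  f3 <- fitHMM(sim$series, hmmSpec(2, "sinusoidal"), nStarts = 3, seed = 4)
  expect_gte(f3$loglik, f1$loglik - 1e-8)
})

test_that("the homogeneous model is nested in the sinusoidal model", {
  gen <- pantherProfile("default")
  sim <- simulateHMM(gen$spec, gen$theta, T = 1500, seed = 8)
  fh <- fitHMM(sim$series, hmmSpec(2, "homogeneous"), nStarts = 3, seed = 2)
  fs <- fitHMM(sim$series, hmmSpec(2, "sinusoidal"), nStarts = 3, seed = 2)
  expect_gte(fs$loglik, fh$loglik - 0.05)
})

test_that("fitted models serialize to JSON and back", {
  gen <- pantherProfile("homogeneous")
  sim <- simulateHMM(gen$spec, gen$theta, T = 600, seed = 12)
  fit <- fitHMM(sim$series, hmmSpec(2, "homogeneous"), nStarts = 1, seed = 3)
  f <- tempfile(fileext = ".json")
  writeHMM(fit, f)
  back <- readHMM(f)
  expect_equal(back$theta$prior, fit$theta$prior, tolerance = 1e-12)
  expect_equal(back$theta$beta, fit$theta$beta, tolerance = 1e-12)
  expect_equal(back$theta$emission$step, fit$theta$emission$step,
               tolerance = 1e-12)
  expect_equal(back$loglik, fit$loglik, tolerance = 1e-12)
  expect_equal(forwardLoglik(back$spec, back$theta, sim$series), fit$loglik,
               tolerance = 1e-8)
})
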