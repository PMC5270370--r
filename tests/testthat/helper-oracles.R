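# Independent brute-force oracles and small fixture generators.
# The oracles enumerate all n^T hidden-state sequences directly from the
# model definition and never touch the recursive implementations.

logSumExp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# joint log-probability of one complete state path under the model
.pathLogProb <- function(theta, z, le, newseg, Pt) {
  ll <- 0
  for (t in seq_along(z)) {
    ll <- ll + if (newseg[t]) log(theta$prior[z[t]]) else
      log(Pt[[t]][z[t - 1], z[t]])
    ll <- ll + le[t, z[t]]
  }
  ll
}

# exhaustive-marginalisation oracle: loglik, posterior matrix, Viterbi path
bruteHMM <- function(spec, theta, series, stepFloor = 0.1) {
  T <- nrow(series)
  n <- spec$n
  le <- emissionLoglikMatrix(series, theta$emission,
                             includeAngles = spec$angles, stepFloor = stepFloor)
  newseg <- c(TRUE, series$segment[-1] != series$segment[-T])[seq_len(T)]
  Pt <- lapply(series$hour, function(h) transitionMatrix(spec, theta$beta, h))
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), T)))
  lp <- apply(paths, 1, function(z) .pathLogProb(theta, z, le, newseg, Pt))
  loglik <- logSumExp(lp)
  post <- vapply(seq_len(n), function(i)
    vapply(seq_len(T), function(t) exp(logSumExp(lp[paths[, t] == i]) - loglik), 0),
    numeric(T))
  list(loglik = loglik,
       post = matrix(post, nrow = T),
       viterbi = as.integer(paths[which.max(lp), ]))
}

randomTheta <- function(spec, seed) {
  set.seed(seed)
  n <- spec$n
  w <- rexp(n) + 0.2
  beta <- periodicHMM:::.betaSkeleton(spec)
  beta[] <- rnorm(length(beta), 0, 0.8)
  em <- emissionParams("lognormal",
                       meanlog = sort(rnorm(n, 1, 1.5)),
                       sdlog = runif(n, 0.4, 1),
                       mu = if (spec$angles) periodicHMM:::.wrapAngle(runif(n, -3, 3)),
                       kappa = if (spec$angles) runif(n, 0.2, 2))
  hmmTheta(spec, w / sum(w), beta, em)
}

randomSeries <- function(T, seed, segments = 1, angles = TRUE) {
  set.seed(seed)
  seg <- sort(rep_len(seq_len(segments), T))
  turn <- periodicHMM:::.wrapAngle(runif(T, -pi, pi))
  turn[c(TRUE, seg[-1] != seg[-T])] <- NA
  if (!angles) turn[] <- NA
  trajectory(rlnorm(T, 1.5, 1), turn,
             hour = (sample.int(24, 1) + seq_len(T)) %% 24, segment = seg)
}

# permute the states of a parameter set; transition coefficients transform
# exactly (the log-odds against the new baseline are differences of the old
# linear predictors, which share the hour basis)
permuteTheta <- function(spec, theta, ord) {
  n <- spec$n
  em <- theta$emission
  em$step <- lapply(em$step, function(v) v[ord])
  if (!is.null(em$angle)) em$angle <- lapply(em$angle, function(v) v[ord])
  kt <- specKt(spec)
  rows <- if (spec$fmm) 1L else n
  full <- array(0, dim = c(rows, n, kt))
  if (n > 1) full[, 2:n, ] <- theta$beta
  full <- full[if (spec$fmm) 1L else ord, ord, , drop = FALSE]
  beta <- periodicHMM:::.betaSkeleton(spec)
  for (j in seq_len(n - 1L)) beta[, j, ] <- full[, j + 1L, ] - full[, 1L, ]
  hmmTheta(spec, theta$prior[ord], beta, em)
}

# bare-bones fitted-model wrapper so diagnostics can be exercised on known
# parameter values without running the optimiser
fakeFit <- function(spec, theta, n_obs = 1000) {
  structure(list(spec = spec, theta = theta, loglik = NA_real_,
                 n_free = countFreeParams(spec), n_obs = n_obs,
                 convergence = data.frame(), converged = TRUE,
                 best_start = 1L, seed = 1L, stepFloor = 0.1),
            class = "hmm_fit")
}
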