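#' Model parameters
#'
#' A fitted or user-supplied parameter set `theta` is a plain list with
#' elements `prior` (initial-state probabilities, length `n`, summing to 1),
#' `beta` (transition coefficient array of dimension `(rows, n - 1, k_t)`,
#' see [linearPredictor()]) and `emission` (an [emissionParams]).
#' `hmmTheta()` validates the pieces against a specification.
#'
#' @param spec an [hmmSpec].
#' @param prior initial-state probabilities.
#' @param beta transition coefficient array.
#' @param emission an [emissionParams].
#' @return A validated list with class `hmm_theta`.
#' @export
hmmTheta <- function(spec, prior, beta, emission) {
  stopifnot(inherits(spec, "hmm_spec"), inherits(emission, "emission_params"))
  if (length(prior) != spec$n || abs(sum(prior) - 1) > 1e-8 || any(prior < 0))
    stop("prior must be a probability vector of length n")
  .checkBeta(spec, beta)
  if (emission$n != spec$n) stop("emission parameters must cover n states")
  if (spec$angles && is.null(emission$angle))
    stop("spec includes angles but emission parameters have none")
  structure(list(prior = as.numeric(prior), beta = beta, emission = emission),
            class = "hmm_theta")
}

# ---- packed parameter vector (order mirrored in src/hmm_core.cpp) ----------

.packLength <- function(spec) {
  rows <- if (spec$fmm) 1L else spec$n
  (spec$n - 1L) + rows * (spec$n - 1L) * specKt(spec) +
    spec$n * (2L + 2L * spec$angles)
}

.packTheta <- function(spec, theta) {
  em <- theta$emission
  pr <- if (spec$n > 1) log(theta$prior[-1] / theta$prior[1]) else numeric(0)
  tb <- as.vector(aperm(theta$beta, c(3, 2, 1)))  # covariate fastest, then target, row
  ep <- numeric(0)
  for (i in seq_len(spec$n)) {
    ep <- c(ep, if (em$family == "lognormal")
      c(em$step$meanlog[i], log(em$step$sdlog[i]))
    else
      c(log(em$step$shape[i]), log(em$step$scale[i])))
    if (spec$angles) ep <- c(ep, em$angle$mu[i], log(em$angle$kappa[i]))
  }
  c(pr, tb, ep)
}

.unpackTheta <- function(spec, par) {
  n <- spec$n
  kt <- specKt(spec)
  rows <- if (spec$fmm) 1L else n
  p <- 0L
  logits <- par[seq_len(n - 1L)]
  p <- n - 1L
  w <- exp(c(0, logits) - max(0, logits))
  prior <- w / sum(w)
  nb <- rows * (n - 1L) * kt
  beta <- aperm(array(par[p + seq_len(nb)], dim = c(kt, n - 1L, rows)), c(3, 2, 1))
  p <- p + nb
  ke <- 2L + 2L * spec$angles
  e <- matrix(par[p + seq_len(n * ke)], nrow = ke)
  if (spec$stepFamily == "lognormal") {
    em <- emissionParams("lognormal", meanlog = e[1, ], sdlog = exp(e[2, ]),
                         mu = if (spec$angles) .wrapAngle(e[3, ]),
                         kappa = if (spec$angles) exp(e[4, ]))
  } else {
    em <- emissionParams("weibull", shape = exp(e[1, ]), scale = exp(e[2, ]),
                         mu = if (spec$angles) .wrapAngle(e[3, ]),
                         kappa = if (spec$angles) exp(e[4, ]))
  }
  hmmTheta(spec, prior, beta, em)
}

# ---- shared data preparation ----------------------------------------------

.seriesHours <- function(series) {
  uh <- sort(unique(series$hour))
  list(hours = uh, idx0 = match(series$hour, uh) - 1L)
}

.makeAux <- function(spec, series, stepFloor = 0.1) {
  h <- .seriesHours(series)
  ang <- series$turn_rad
  hasAng <- !is.na(ang)
  ang[!hasAng] <- 0
  list(logs = log(pmax(series$step_m, stepFloor)),
       angle = ang, hasAngle = hasAng,
       basis = .hourBasis(spec, h$hours), hourIdx = h$idx0,
       newseg = .newSegment(series),
       n = spec$n, kt = specKt(spec), fmm = spec$fmm,
       family = if (spec$stepFamily == "lognormal") 0L else 1L,
       angles = spec$angles)
}

.emisOrStop <- function(spec, theta, series, stepFloor) {
  le <- emissionLoglikMatrix(series, theta$emission, includeAngles = spec$angles,
                             stepFloor = stepFloor)
  if (any(is.nan(le)) || any(is.na(le))) {
    bad <- which(apply(le, 1, function(r) any(is.nan(r) | is.na(r))))[1]
    stop("non-finite emission log-density at time index ", bad)
  }
  le
}

#' Marginal log-likelihood by the scaled forward recursion
#'
#' Computes `log P(Y | theta, X)` — the log-likelihood marginalised over all
#' hidden state sequences — using the numerically scaled forward algorithm.
#' Contiguous segments are treated as independent sequences, each restarting
#' from the initial-state distribution, and the transition into time `k` uses
#' the hour covariate of time `k`.
#'
#' @param spec an [hmmSpec].
#' @param theta a parameter list, see [hmmTheta()].
#' @param series a [trajectory].
#' @param stepFloor floor (metres) applied to zero steps before evaluating
#'   step densities.
#' @return Scalar log marginal likelihood.
#' @export
forwardLoglik <- function(spec, theta, series, stepFloor = 0.1) {
  stopifnot(inherits(spec, "hmm_spec"))
  le <- .emisOrStop(spec, theta, series, stepFloor)
  h <- .seriesHours(series)
  tpm <- .tpmArray(spec, theta$beta, h$hours)
  hmm_forward_cpp(le, theta$prior, tpm, h$idx0, .newSegment(series))
}

#' Most likely state sequence (Viterbi decoding)
#'
#' Dynamic-programming argmax of the joint probability of states and
#' observations, per segment; ties are broken toward the lower state index.
#'
#' @inheritParams forwardLoglik
#' @return Integer vector of decoded states in `1..n`.
#' @export
viterbiPath <- function(spec, theta, series, stepFloor = 0.1) {
  stopifnot(inherits(spec, "hmm_spec"))
  le <- .emisOrStop(spec, theta, series, stepFloor)
  h <- .seriesHours(series)
  tpm <- .tpmArray(spec, theta$beta, h$hours)
  hmm_viterbi_cpp(le, log(theta$prior), log(tpm), h$idx0, .newSegment(series))
}

#' Posterior state probabilities (forward-backward smoothing)
#'
#' @inheritParams forwardLoglik
#' @return A `T x n` matrix with rows summing to 1; entry `(t, i)` is
#'   `P(z_t = i | Y, theta, X)`.
#' @export
posteriorProbs <- function(spec, theta, series, stepFloor = 0.1) {
  stopifnot(inherits(spec, "hmm_spec"))
  le <- .emisOrStop(spec, theta, series, stepFloor)
  h <- .seriesHours(series)
  tpm <- .tpmArray(spec, theta$beta, h$hours)
  hmm_posterior_cpp(le, theta$prior, tpm, h$idx0, .newSegment(series))$gamma
}

# ---- canonical state ordering ---------------------------------------------

# reorder states by increasing mean step length.  The multinomial-logit
# coefficients transform exactly under a permutation sigma:
#   eta'_ij = eta_{sigma(i) sigma(j)} - eta_{sigma(i) sigma(1)}
# (with eta_{.1} = 0), which is linear in the shared hour basis, so the
# coefficient arrays transform the same way.
.canonicalOrder <- function(spec, theta) {
  n <- spec$n
  ord <- order(.meanStep(theta$emission))
  if (identical(ord, seq_len(n))) return(theta)
  em <- theta$emission
  em$step <- lapply(em$step, function(v) v[ord])
  if (!is.null(em$angle)) em$angle <- lapply(em$angle, function(v) v[ord])
  kt <- specKt(spec)
  rows <- if (spec$fmm) 1L else n
  # expand to full target set (baseline column of zeros), permute, re-baseline
  full <- array(0, dim = c(rows, n, kt))
  if (n > 1) full[, 2:n, ] <- theta$beta
  rowOrd <- if (spec$fmm) 1L else ord
  full <- full[rowOrd, ord, , drop = FALSE]
  newbeta <- .betaSkeleton(spec)
  for (j in seq_len(n - 1L))
    newbeta[, j, ] <- full[, j + 1L, ] - full[, 1L, ]
  hmmTheta(spec, theta$prior[ord], newbeta, em)
}

#' Fit a movement HMM by maximum likelihood
#'
#' Maximises the marginal log-likelihood over an unconstrained transformation
#' of all parameters (multinomial logits for the prior and transition rows,
#' log scales for positive emission parameters) with BFGS, from `nStarts`
#' jittered initialisations built by [initEmissionParams()] plus small random
#' transition coefficients biased toward state persistence.  The best start
#' is returned with states canonically reordered by increasing mean step
#' length, so state 1 is always the shortest-step state.
#'
#' @param series a [trajectory].
#' @param spec an [hmmSpec].
#' @param nStarts number of random restarts (default 10).
#' @param seed integer seed; the same seed and data give an identical fit.
#' @param maxIter BFGS iteration cap per start.
#' @param tol relative log-likelihood convergence tolerance.
#' @param stepFloor floor (metres) for zero steps.
#' @return An object of class `hmm_fit` with elements `spec`, `theta`,
#'   `loglik`, `n_free`, `n_obs`, `convergence` (per-start table),
#'   `best_start`, `seed`.
#' @export
fitHMM <- function(series, spec, nStarts = 10, seed = 1L, maxIter = 500,
                   tol = 1e-6, stepFloor = 0.1) {
  stopifnot(inherits(series, "trajectory"), inherits(spec, "hmm_spec"),
            nStarts >= 1)
  nfree <- countFreeParams(spec)
  if (nrow(series) < 3 * nfree)
    warning("series length (", nrow(series), ") is small relative to ",
            nfree, " free parameters")
  aux <- .makeAux(spec, series, stepFloor)
  fn <- function(p) hmm_nll_cpp(p, aux)
  set.seed(as.integer(seed))
  # drawn one at a time so the stream for nStarts = k is a prefix of the
  # stream for nStarts = k + 1 (multi-start monotonicity)
  startSeeds <- vapply(seq_len(nStarts), function(k)
    sample.int(.Machine$integer.max - 1L, 1L), 1L)
  starts <- vector("list", nStarts)
  diag <- data.frame(start = seq_len(nStarts), loglik = NA_real_,
                     convergence = NA_integer_, fevals = NA_integer_)
  for (k in seq_len(nStarts)) {
    par0 <- .initialPar(spec, series, startSeeds[k], stepFloor)
    tries <- 0L
    while (fn(par0) >= 1e9 && tries < 5L) {
      tries <- tries + 1L
      par0 <- .initialPar(spec, series, startSeeds[k] + tries * 7919L, stepFloor)
    }
    opt <- tryCatch(
      optim(par0, fn, method = "BFGS",
            control = list(maxit = maxIter, reltol = tol)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value) && opt$value < 1e9) {
      starts[[k]] <- opt
      diag$loglik[k] <- -opt$value
      diag$convergence[k] <- opt$convergence
      diag$fevals[k] <- opt$counts[["function"]]
    }
  }
  ok <- which(!vapply(starts, is.null, TRUE))
  if (!length(ok)) {
    stop("all ", nStarts, " optimisation starts failed; per-start diagnostics:\n",
         paste(capture.output(print(diag)), collapse = "\n"))
  }
  best <- ok[which.max(diag$loglik[ok])]
  if (diag$convergence[best] != 0)
    warning("best start did not meet the convergence tolerance ",
            "(optim code ", diag$convergence[best], ")")
  theta <- .canonicalOrder(spec, .unpackTheta(spec, starts[[best]]$par))
  structure(list(spec = spec, theta = theta, loglik = diag$loglik[best],
                 n_free = nfree, n_obs = nrow(series), convergence = diag,
                 converged = diag$convergence[best] == 0,
                 best_start = best, seed = as.integer(seed),
                 stepFloor = stepFloor),
            class = "hmm_fit")
}

# jittered starting vector for one optimisation start
.initialPar <- function(spec, series, startSeed, stepFloor) {
  startSeed <- as.integer(startSeed %% (.Machine$integer.max - 1))
  em0 <- initEmissionParams(series, spec$n, seed = startSeed,
                            family = spec$stepFamily, angles = spec$angles,
                            stepFloor = stepFloor)
  n <- spec$n
  beta0 <- .betaSkeleton(spec)
  beta0[] <- rnorm(length(beta0), 0, 0.3)
  if (!spec$fmm && n > 1) {
    # bias toward self-persistence: raise the predictor of the self target,
    # lower row 1's predictors (its self target is the baseline)
    for (i in seq_len(n)) for (j in seq_len(n - 1L)) {
      if (j + 1L == i) beta0[i, j, ] <- beta0[i, j, ] + 2
      if (i == 1L) beta0[i, j, ] <- beta0[i, j, ] - 2
    }
  }
  prior0 <- if (n > 1) {
    w <- exp(rnorm(n, 0, 0.3))
    w / sum(w)
  } else 1
  .packTheta(spec, hmmTheta(spec, prior0, beta0, em0))
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("Fitted", .specLabel(x$spec), "with", x$spec$n, "state(s)\n")
  cat(sprintf("  loglik %.2f | free parameters %d | observations %d\n",
              x$loglik, x$n_free, x$n_obs))
  ic <- informationCriteria(x)
  cat(sprintf("  BIC %.1f | AIC %.1f | best start %d/%d%s\n",
              ic[["BIC"]], ic[["AIC"]], x$best_start, nrow(x$convergence),
              if (x$converged) "" else " (not converged)"))
  cat("  states (by increasing mean step):\n")
  print(as.data.frame(c(x$theta$emission$step, x$theta$emission$angle)), ...)
  invisible(x)
}
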