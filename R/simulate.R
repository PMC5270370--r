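#' Simulate a movement series from a model
#'
#' Generates a hidden state sequence and emissions: the first state is drawn
#' from the prior, subsequent states from the transition matrix evaluated at
#' the hour of the step being entered, with hours advancing deterministically
#' by one (mod 24) from `hour0`.  Step lengths are drawn from the occupied
#' state's family; turning angles are drawn from the state's von Mises
#' distribution when the model includes one, otherwise isotropically (uniform
#' on `(-pi, pi]`), and the first angle is missing as in derived data.
#'
#' @param spec an [hmmSpec].
#' @param theta parameter list, see [hmmTheta()].
#' @param T number of steps to simulate, `>= 1`.
#' @param hour0 hour of day of the first step (default 0).
#' @param seed optional integer seed; the same seed reproduces the output
#'   bit for bit.
#' @return An object of class `sim_output`: list with `states` (integers),
#'   `series` (a single-segment [trajectory]), `spec`, `theta`, `seed`.
#' @export
simulateHMM <- function(spec, theta, T, hour0 = 0, seed = NULL) {
  stopifnot(inherits(spec, "hmm_spec"), T >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- spec$n
  hours <- (hour0 + seq_len(T) - 1) %% 24
  uh <- sort(unique(hours))
  tpm <- .tpmArray(spec, theta$beta, uh)
  hidx <- match(hours, uh)
  z <- integer(T)
  z[1] <- sample.int(n, 1, prob = theta$prior)
  if (T > 1) for (k in 2:T)
    z[k] <- sample.int(n, 1, prob = tpm[z[k - 1], , hidx[k]])
  em <- theta$emission
  s <- numeric(T)
  for (i in seq_len(n)) {
    idx <- which(z == i)
    if (!length(idx)) next
    s[idx] <- if (em$family == "lognormal")
      rlnorm(length(idx), em$step$meanlog[i], em$step$sdlog[i])
    else
      rweibull(length(idx), em$step$shape[i], em$step$scale[i])
  }
  turn <- numeric(T)
  if (!is.null(em$angle) && spec$angles) {
    for (i in seq_len(n)) {
      idx <- which(z == i)
      if (length(idx))
        turn[idx] <- rvonmises(length(idx), em$angle$mu[i], em$angle$kappa[i])
    }
  } else {
    turn <- .wrapAngle(runif(T, -pi, pi))
  }
  turn[1] <- NA_real_
  structure(list(states = z,
                 series = trajectory(s, turn, hours, rep(1L, T)),
                 spec = spec, theta = theta, seed = seed),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat("Simulated", .specLabel(x$spec), "series:", length(x$states), "steps,",
      x$spec$n, "state(s)\n")
  print(table(state = x$states))
  invisible(x)
}

#' Reconstruct planar coordinates from a step/turn series
#'
#' Inverts [deriveSteps()] on a single segment: an internal absolute heading
#' accumulates the turning angles (`h_k = h_{k-1} + turn_k`, starting from
#' `heading0` at the first step, whose turning angle is missing), and each
#' fix advances by `(s_k cos h_k, s_k sin h_k)`.  Running [deriveSteps()] on
#' the returned coordinates recovers the input step lengths and turning
#' angles to numerical tolerance.
#'
#' @param series a single-segment [trajectory].
#' @param x0,y0 coordinates of the first fix (metres).
#' @param heading0 absolute heading of the first step (radians).
#' @return A `(T + 1) x 2` matrix of fix coordinates.
#' @export
reconstructCoords <- function(series, x0 = 0, y0 = 0, heading0 = 0) {
  stopifnot(inherits(series, "trajectory"))
  if (length(unique(series$segment)) > 1)
    stop("reconstructCoords expects a single segment; reconstruct per segment")
  turns <- series$turn_rad
  turns[1] <- 0
  if (anyNA(turns)) stop("missing turning angle after the first step")
  h <- heading0 + cumsum(turns)
  cbind(x = c(x0, x0 + cumsum(series$step_m * cos(h))),
        y = c(y0, y0 + cumsum(series$step_m * sin(h))))
}

#' Add radially symmetric GPS noise to coordinates
#'
#' Perturbs each coordinate of each fix by independent Gaussian noise with
#' standard deviation `sd` metres (default 5).  `sd = 0` returns the input
#' unchanged.
#'
#' @param coords numeric matrix with columns x, y.
#' @param sd noise standard deviation per coordinate, metres.
#' @param seed optional integer seed.
#' @return Matrix of the same shape.
#' @export
addGpsNoise <- function(coords, sd = 5, seed = NULL) {
  stopifnot(is.matrix(coords), ncol(coords) == 2, sd >= 0)
  if (sd == 0) return(coords)
  if (!is.null(seed)) set.seed(as.integer(seed))
  coords + matrix(rnorm(length(coords), 0, sd), ncol = 2)
}

#' Re-observe a simulated series through GPS noise
#'
#' Implements the noise protocol used in the robustness simulations: the
#' true step/turn series is laid out as planar coordinates
#' ([reconstructCoords()]), independent Gaussian noise of standard deviation
#' `sd` metres is added to every coordinate ([addGpsNoise()]), and step
#' lengths and turning angles are recomputed from the noisy positions.
#' Noise is applied to positions, never to step lengths directly.  The hour
#' covariate and segment structure are unchanged.
#'
#' @param series a single-segment [trajectory] (or a `sim_output`, whose
#'   series is used).
#' @param sd per-coordinate noise standard deviation, metres (default 5).
#' @param seed optional integer seed.
#' @param x0,y0,heading0 layout of the true coordinates.
#' @return A [trajectory] of noisy observed steps.
#' @export
reobserveWithNoise <- function(series, sd = 5, seed = NULL,
                               x0 = 0, y0 = 0, heading0 = 0) {
  if (inherits(series, "sim_output")) series <- series$series
  coords <- reconstructCoords(series, x0, y0, heading0)
  noisy <- addGpsNoise(coords, sd = sd, seed = seed)
  dx <- diff(noisy[, 1])
  dy <- diff(noisy[, 2])
  s <- sqrt(dx^2 + dy^2)
  heading <- atan2(dy, dx)
  turn <- c(NA_real_, .wrapAngle(diff(heading)))
  trajectory(s, turn, series$hour, series$segment)
}

#' Panther-like generator profiles
#'
#' Named parameter profiles emulating long-term hourly carnivore GPS
#' trajectories: two latent movement states with log-Normal step lengths
#' around 15 m (resting/local, sdlog 0.8) and 500 m (traveling, sdlog 0.6).
#' The `"default"` profile uses sinusoidal transition predictors that bias
#' the long-move state toward night (predictors peak at hour 0); the
#' `"homogeneous"` profile shares the emissions but has constant transition
#' probabilities with the same day-night average persistence.
#'
#' @param profile profile name, `"default"` or `"homogeneous"`.
#' @return List with elements `spec` ([hmmSpec]) and `theta` ([hmmTheta]).
#' @export
pantherProfile <- function(profile = c("default", "homogeneous")) {
  if (!is.character(profile) || !profile[1] %in% c("default", "homogeneous"))
    stop("unknown generator profile: ", profile[1])
  profile <- match.arg(profile)
  em <- emissionParams("lognormal", meanlog = c(log(15), log(500)),
                       sdlog = c(0.8, 0.6))
  if (profile == "default") {
    spec <- hmmSpec(2, transition = "sinusoidal")
    beta <- .betaSkeleton(spec)
    # eta_i2(t) = b1 + b2 cos(2 pi t / 24): long-move propensity peaks at
    # midnight; row 1 = from short state, row 2 = from long state
    beta[1, 1, ] <- c(-2.0, 1.5, 0)
    beta[2, 1, ] <- c(1.0, 1.5, 0)
  } else {
    spec <- hmmSpec(2, transition = "homogeneous")
    beta <- .betaSkeleton(spec)
    beta[1, 1, 1] <- -2.0
    beta[2, 1, 1] <- 1.0
  }
  list(spec = spec, theta = hmmTheta(spec, c(0.7, 0.3), beta, em))
}

#' Simulate a panther-like fixture series
#'
#' Convenience wrapper around [pantherProfile()] and [simulateHMM()]
#' producing a synthetic stand-in for a long hourly movement data set: a
#' single contiguous segment of `T` hourly steps with a strong diurnal
#' activity cycle under the default profile.
#'
#' @param T series length (default 10000, echoing the scale of long GPS
#'   collar deployments).
#' @param seed integer seed.
#' @param profile generator profile name, see [pantherProfile()].
#' @return A `sim_output`.
#' @export
pantherFixture <- function(T = 10000, seed = 1L, profile = "default") {
  p <- pantherProfile(profile)
  simulateHMM(p$spec, p$theta, T = T, hour0 = 0, seed = seed)
}
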