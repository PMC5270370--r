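#' State-conditional emission distributions
#'
#' Movement states emit step lengths from a log-Normal or Weibull
#' distribution, optionally paired with a von Mises turning-angle
#' distribution.  `emissionParams()` bundles one parameter set per state.
#'
#' @param family step-length family, `"lognormal"` or `"weibull"`.
#' @param meanlog,sdlog log-Normal parameters, one per state (`sdlog > 0`).
#' @param shape,scale Weibull parameters, one per state (both `> 0`).
#' @param mu,kappa optional von Mises turning-angle parameters per state
#'   (`mu` in `(-pi, pi]`, `kappa >= 0`); supply both or neither.
#' @return An object of class `emission_params`.
#' @export
emissionParams <- function(family = c("lognormal", "weibull"),
                           meanlog = NULL, sdlog = NULL,
                           shape = NULL, scale = NULL,
                           mu = NULL, kappa = NULL) {
  family <- match.arg(family)
  if (family == "lognormal") {
    stopifnot(!is.null(meanlog), !is.null(sdlog),
              length(meanlog) == length(sdlog))
    if (any(sdlog <= 0)) stop("sdlog must be positive")
    n <- length(meanlog)
    step <- list(meanlog = as.numeric(meanlog), sdlog = as.numeric(sdlog))
  } else {
    stopifnot(!is.null(shape), !is.null(scale), length(shape) == length(scale))
    if (any(shape <= 0) || any(scale <= 0)) stop("shape and scale must be positive")
    n <- length(shape)
    step <- list(shape = as.numeric(shape), scale = as.numeric(scale))
  }
  angle <- NULL
  if (!is.null(mu) || !is.null(kappa)) {
    stopifnot(!is.null(mu), !is.null(kappa), length(mu) == n, length(kappa) == n)
    if (any(kappa < 0)) stop("kappa must be non-negative")
    if (any(mu <= -pi | mu > pi)) stop("mu must lie in (-pi, pi]")
    angle <- list(mu = as.numeric(mu), kappa = as.numeric(kappa))
  }
  structure(list(family = family, n = n, step = step, angle = angle),
            class = "emission_params")
}

#' @export
print.emission_params <- function(x, ...) {
  cat("Emission parameters (", x$family, " steps",
      if (!is.null(x$angle)) " + von Mises angles", "), ", x$n, " state(s)\n",
      sep = "")
  print(as.data.frame(c(x$step, x$angle)), ...)
  invisible(x)
}

#' Log-density of the log-Normal step-length distribution
#'
#' Thin validating wrapper around [stats::dlnorm()]; steps must be strictly
#' positive (zero steps are floored upstream, see [emissionLoglikMatrix()]).
#'
#' @param s step lengths, metres, `> 0`.
#' @param meanlog,sdlog log-Normal parameters, `sdlog > 0`.
#' @return Log-density values.
#' @export
lognormalLogpdf <- function(s, meanlog, sdlog) {
  if (any(s <= 0)) stop("step length must be positive for the log-Normal density")
  if (any(sdlog <= 0)) stop("sdlog must be positive")
  dlnorm(s, meanlog, sdlog, log = TRUE)
}

#' Log-density of the Weibull step-length distribution
#'
#' @param s step lengths, metres, `> 0`.
#' @param shape,scale Weibull parameters, both `> 0`.
#' @return Log-density values.
#' @export
weibullLogpdf <- function(s, shape, scale) {
  if (any(s <= 0)) stop("step length must be positive for the Weibull density")
  if (any(shape <= 0) || any(scale <= 0)) stop("shape and scale must be positive")
  dweibull(s, shape, scale, log = TRUE)
}

#' von Mises turning-angle density
#'
#' Density of the von Mises distribution on the circle with mean direction
#' `mu` and concentration `kappa`, normalised by `2 * pi * I0(kappa)`; the
#' Bessel normaliser uses the exponentially scaled [base::besselI()] so large
#' concentrations do not overflow.  `kappa = 0` gives the uniform circular
#' density `1 / (2 * pi)`.
#'
#' @param x angles in radians.
#' @param mu mean direction, radians.
#' @param kappa concentration, `>= 0`.
#' @param log return the log-density?
#' @return (Log-)density values.
#' @export
dvonmises <- function(x, mu = 0, kappa = 1, log = FALSE) {
  if (any(kappa < 0)) stop("kappa must be non-negative")
  ld <- kappa * cos(x - mu) - log(2 * pi) - (log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa)
  if (log) ld else exp(ld)
}

#' Sample from the von Mises distribution
#'
#' Best-Fisher rejection sampler; for `kappa` near zero draws are uniform on
#' `(-pi, pi]`.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration, `>= 0`.
#' @return Angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) return(.wrapAngle(runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- .wrapAngle(mu + sign(u[3] - 0.5) * acos(f))
      i <- i + 1L
    }
  }
  out
}

#' Per-observation emission log-likelihood matrix
#'
#' Entry `(t, i)` is the log-density of observation `t` under state `i`: the
#' step-length log-density plus, when a turning-angle family is present and
#' the angle is observed, the von Mises log-density.  Missing angles (the
#' first step of each segment) contribute a factor 1, so models with and
#' without angles are comparable on identical time points.  Step lengths are
#' floored at `stepFloor` metres before evaluation because both step families
#' have support on the positive half-line.
#'
#' @param series a [trajectory].
#' @param params an [emissionParams] object.
#' @param includeAngles evaluate the turning-angle density?  Defaults to
#'   `TRUE` when `params` carries angle parameters.
#' @param stepFloor floor, in metres, applied to zero/near-zero steps
#'   (default 0.1).
#' @return A `nrow(series) x n` matrix of log-densities.
#' @export
emissionLoglikMatrix <- function(series, params,
                                 includeAngles = !is.null(params$angle),
                                 stepFloor = 0.1) {
  stopifnot(inherits(series, "trajectory"), inherits(params, "emission_params"))
  if (nrow(series) == 0) stop("empty series")
  if (includeAngles && is.null(params$angle))
    stop("includeAngles = TRUE but `params` has no angle parameters")
  s <- pmax(series$step_m, stepFloor)
  n <- params$n
  out <- matrix(NA_real_, nrow(series), n)
  for (i in seq_len(n)) {
    out[, i] <- if (params$family == "lognormal")
      lognormalLogpdf(s, params$step$meanlog[i], params$step$sdlog[i])
    else
      weibullLogpdf(s, params$step$shape[i], params$step$scale[i])
    if (includeAngles) {
      ok <- !is.na(series$turn_rad)
      out[ok, i] <- out[ok, i] +
        dvonmises(series$turn_rad[ok], params$angle$mu[i], params$angle$kappa[i],
                  log = TRUE)
    }
  }
  out
}

#' Quantile-based starting values for emission parameters
#'
#' Splits the log step lengths at empirical quantiles into `n` bins and takes
#' per-bin moment estimates, jittered by seed-controlled Gaussian noise so
#' repeated calls give distinct multi-start initialisations.  Degenerate
#' series (all steps equal) fall back to a small fixed spread with a warning.
#'
#' @param series a [trajectory].
#' @param n number of states.
#' @param seed integer seed controlling the jitter; the same seed always
#'   yields the same initialisation.
#' @param family step-length family.
#' @param angles also initialise von Mises angle parameters?
#' @param jitter standard deviation of the multiplicative jitter on the
#'   location parameters (0 disables).
#' @param stepFloor floor applied to zero steps before taking logs.
#' @return An [emissionParams] object.
#' @export
initEmissionParams <- function(series, n, seed = 1L,
                               family = c("lognormal", "weibull"),
                               angles = FALSE, jitter = 0.15, stepFloor = 0.1) {
  stopifnot(inherits(series, "trajectory"), n >= 1)
  family <- match.arg(family)
  ls <- log(pmax(series$step_m, stepFloor))
  set.seed(as.integer(seed))
  qs <- quantile(ls, probs = seq(0, 1, length.out = n + 1), names = FALSE)
  degenerate <- length(unique(series$step_m)) < n || length(unique(qs)) < n + 1
  if (!degenerate)
    bin <- cut(ls, breaks = unique(qs), include.lowest = TRUE, labels = FALSE)
  if (degenerate) {
    warning("degenerate step distribution: falling back to fixed spread")
    ml <- mean(ls) + seq(-0.5, 0.5, length.out = n)
    sl <- rep(0.5, n)
  } else {
    ml <- vapply(seq_len(n), function(b) mean(ls[bin == b]), 0)
    sl <- vapply(seq_len(n), function(b) {
      v <- sd(ls[bin == b])
      if (!is.finite(v) || v < 0.05) 0.25 else v
    }, 0)
  }
  ml <- ml + rnorm(n, 0, jitter)
  sl <- sl * exp(rnorm(n, 0, jitter / 2))
  mu <- kap <- NULL
  if (angles) {
    mu <- rep(0, n)
    kap <- exp(rnorm(n, log(0.5), jitter))
  }
  if (family == "lognormal")
    emissionParams("lognormal", meanlog = ml, sdlog = sl, mu = mu, kappa = kap)
  else
    emissionParams("weibull", shape = 1 / sl, scale = exp(ml), mu = mu, kappa = kap)
}

# mean step length per state; used for canonical state ordering
.meanStep <- function(params) {
  if (params$family == "lognormal")
    exp(params$step$meanlog + params$step$sdlog^2 / 2)
  else
    params$step$scale * gamma(1 + 1 / params$step$shape)
}
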