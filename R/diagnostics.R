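#' Observed hourly step-length profile
#'
#' Groups steps by integer hour of day and reports the mean step length, the
#' standard error of the mean (`sd / sqrt(count)`), and the count per hour.
#' All 24 hours are always present; hours with no steps get an `NA` mean and
#' are flagged with a warning.
#'
#' @param series a [trajectory].
#' @return A data frame of class `hourly_profile` with columns `hour`,
#'   `mean`, `se`, `count`.
#' @export
hourlyProfile <- function(series) {
  stopifnot(inherits(series, "trajectory"))
  if (!nrow(series)) stop("empty series")
  h <- floor(series$hour) %% 24
  out <- data.frame(hour = 0:23, mean = NA_real_, se = NA_real_, count = 0L)
  for (hh in 0:23) {
    s <- series$step_m[h == hh]
    out$count[hh + 1] <- length(s)
    if (length(s)) {
      out$mean[hh + 1] <- mean(s)
      out$se[hh + 1] <- if (length(s) > 1) sd(s) / sqrt(length(s)) else 0
    }
  }
  if (any(out$count == 0))
    warning("hour(s) with no steps: ", paste(out$hour[out$count == 0], collapse = ", "))
  class(out) <- c("hourly_profile", "data.frame")
  out
}

#' Step-length autocorrelation function across segments
#'
#' Autocorrelation of the step lengths computed within contiguous segments
#' and pooled: lag products never span a gap, and all lags are normalised by
#' the overall (pooled) centred sum of squares, so `acf(0) = 1` exactly and
#' all values lie in `[-1, 1]`.
#'
#' @param series a [trajectory].
#' @param maxLag largest lag, in hours (steps); truncated with a warning if
#'   it reaches the longest segment.
#' @return A data frame of class `acf_curve` with columns `lag`, `acf`.
#' @export
stepAcf <- function(series, maxLag = 48) {
  stopifnot(inherits(series, "trajectory"), maxLag >= 0)
  segs <- split(series$step_m, series$segment)
  longest <- max(lengths(segs))
  if (maxLag >= longest) {
    warning("maxLag >= longest segment (", longest, "); truncating")
    maxLag <- longest - 1L
  }
  mu <- mean(series$step_m)
  denom <- sum((series$step_m - mu)^2)
  acf <- vapply(0:maxLag, function(k) {
    num <- 0
    for (s in segs) {
      m <- length(s)
      if (m > k) num <- num + sum((s[seq_len(m - k)] - mu) * (s[(k + 1):m] - mu))
    }
    num / denom
  }, 0)
  structure(data.frame(lag = 0:maxLag, acf = acf),
            class = c("acf_curve", "data.frame"))
}

# simulate nReps series of length T from a fitted model, seeded
.simReplicates <- function(fitted, T, nReps, seed) {
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, nReps)
  lapply(seq_len(nReps), function(r)
    simulateHMM(fitted$spec, fitted$theta, T = T, hour0 = 0,
                seed = seeds[r])$series)
}

#' Model-predicted hourly step-length profile
#'
#' Out-of-sample prediction of the hourly profile: simulates `nReps`
#' trajectories of length `T` from the fitted parameters and aggregates.  The
#' reported `mean` pools all simulated steps by hour; `se` is the Monte Carlo
#' standard error of that mean across replicates (standard deviation of the
#' per-replicate hourly means divided by `sqrt(nReps)`).
#'
#' @param fitted an `hmm_fit`.
#' @param T steps per simulated trajectory (use the length of the data the
#'   model was fitted to).
#' @param nReps number of replicate simulations (default 100).
#' @param seed integer seed.
#' @return An `hourly_profile` data frame.
#' @export
predictHourlyProfile <- function(fitted, T, nReps = 100, seed = 1L) {
  stopifnot(inherits(fitted, "hmm_fit"), T >= 24, nReps >= 2)
  sims <- .simReplicates(fitted, T, nReps, seed)
  perRep <- vapply(sims, function(s) {
    h <- floor(s$hour) %% 24
    vapply(0:23, function(hh) mean(s$step_m[h == hh]), 0)
  }, numeric(24))
  out <- data.frame(hour = 0:23,
                    mean = rowMeans(perRep),
                    se = apply(perRep, 1, sd) / sqrt(nReps),
                    count = as.integer(nReps * floor(T / 24)))
  class(out) <- c("hourly_profile", "data.frame")
  out
}

#' Model-predicted step-length autocorrelation function
#'
#' Simulates `nReps` trajectories from the fitted parameters, computes each
#' replicate's step ACF ([stepAcf()]) and averages across replicates.
#'
#' @inheritParams predictHourlyProfile
#' @param maxLag largest lag in hours.
#' @return An `acf_curve` data frame with columns `lag`, `acf`, `se`.
#' @export
predictStepAcf <- function(fitted, T, nReps = 100, seed = 1L, maxLag = 48) {
  stopifnot(inherits(fitted, "hmm_fit"), T > maxLag)
  sims <- .simReplicates(fitted, T, nReps, seed)
  curves <- vapply(sims, function(s) stepAcf(s, maxLag)$acf, numeric(maxLag + 1))
  structure(data.frame(lag = 0:maxLag, acf = rowMeans(curves),
                       se = apply(curves, 1, sd) / sqrt(nReps)),
            class = c("acf_curve", "data.frame"))
}

#' Viterbi-conditional within-sample simulation
#'
#' Decodes the most likely state sequence of the *observed* series with
#' [viterbiPath()], then draws a fresh step length (and turning angle, when
#' the model has an angle family) from each decoded state's emission
#' distribution.  Because the decoded states condition on the observed data,
#' this is a within-sample prediction: it can track observed temporal
#' patterns even for models that cannot reproduce them out of sample, and
#' must not be used as a goodness-of-fit comparison across model classes.
#'
#' @param fitted an `hmm_fit`.
#' @param series the observed [trajectory] the model was fitted to.
#' @param seed integer seed.
#' @return A list with `series` (a [trajectory] whose steps are the
#'   conditional draws) and `states` (the decoded sequence).
#' @export
viterbiConditionalSim <- function(fitted, series, seed = 1L) {
  stopifnot(inherits(fitted, "hmm_fit"), inherits(series, "trajectory"))
  z <- viterbiPath(fitted$spec, fitted$theta, series,
                   stepFloor = fitted$stepFloor)
  set.seed(as.integer(seed))
  em <- fitted$theta$emission
  s <- numeric(length(z))
  turn <- series$turn_rad
  for (i in seq_len(fitted$spec$n)) {
    idx <- which(z == i)
    if (!length(idx)) next
    s[idx] <- if (em$family == "lognormal")
      rlnorm(length(idx), em$step$meanlog[i], em$step$sdlog[i])
    else
      rweibull(length(idx), em$step$shape[i], em$step$scale[i])
    if (fitted$spec$angles) {
      ok <- idx[!is.na(turn[idx])]
      if (length(ok))
        turn[ok] <- rvonmises(length(ok), em$angle$mu[i], em$angle$kappa[i])
    }
  }
  list(series = trajectory(s, turn, series$hour, series$segment),
       states = z)
}

#' Plot an hourly profile or ACF curve
#'
#' Base-graphics displays: the hourly profile is drawn as a line with a
#' two-standard-error ribbon; the ACF as vertical lines per lag.
#'
#' @param x an `hourly_profile` or `acf_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hourly_profile <- function(x, ...) {
  ok <- !is.na(x$mean)
  graphics::plot(x$hour[ok], x$mean[ok], type = "l", xlab = "hour of day",
                 ylab = "mean step length (m)", ...)
  graphics::polygon(c(x$hour[ok], rev(x$hour[ok])),
                    c(x$mean[ok] - 2 * x$se[ok], rev(x$mean[ok] + 2 * x$se[ok])),
                    border = NA, col = grDevices::adjustcolor("grey", 0.5))
  graphics::lines(x$hour[ok], x$mean[ok])
  invisible(x)
}

#' @rdname plot.hourly_profile
#' @export
plot.acf_curve <- function(x, ...) {
  graphics::plot(x$lag, x$acf, type = "h", xlab = "lag (hours)",
                 ylab = "step-length ACF", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
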