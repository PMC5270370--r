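#' Model specification
#'
#' Defines the shape of a movement HMM: number of states, step-length family,
#' presence of a turning-angle family, transition structure, and whether the
#' model is a finite mixture (all transition-matrix rows identical, so state
#' occupancy is independent of the previous state).
#'
#' Transition structures (all via the multinomial-logit link with state 1 as
#' baseline, whose linear predictor is fixed at 0):
#' \describe{
#'   \item{homogeneous}{a single intercept per (row, target); constant in time.}
#'   \item{block}{piecewise-constant over `M` hour blocks (see
#'     [makeBlockMap()]); one coefficient per block.}
#'   \item{quadratic}{`b1 + b2 (t/24) + b3 (t/24)^2` in hour `t`; not
#'     diurnally continuous (nothing forces the predictor at hour 0 to equal
#'     its limit at hour 24).}
#'   \item{sinusoidal}{`b1 + b2 cos(2 pi t/24) + b3 sin(2 pi t/24)`; same
#'     complexity as quadratic but 24-hour periodic by construction.}
#'   \item{hourly}{a separate coefficient for each of the 24 hours (the block
#'     model with `M = 24`).}
#' }
#'
#' @param n number of movement states, `>= 1`.
#' @param transition transition structure, see Details.
#' @param stepFamily step-length emission family.
#' @param angles include a von Mises turning-angle emission?
#' @param fmm finite-mixture constraint: force all transition-matrix rows
#'   identical (state-independent entry probabilities).  Combines with any
#'   transition structure; `fmm = TRUE` with `transition = "sinusoidal"` gives
#'   the heterogeneous mixture whose occupancy prior varies sinusoidally.
#' @param blocks hour-to-block map from [makeBlockMap()]; only used when
#'   `transition = "block"`.
#' @return An object of class `hmm_spec`.
#' @export
hmmSpec <- function(n, transition = c("homogeneous", "block", "quadratic",
                                      "sinusoidal", "hourly"),
                    stepFamily = c("lognormal", "weibull"),
                    angles = FALSE, fmm = FALSE, blocks = makeBlockMap()) {
  stopifnot(n >= 1)
  transition <- match.arg(transition)
  stepFamily <- match.arg(stepFamily)
  if (transition == "block" && is.null(blocks))
    stop("block transition structure requires an hour-to-block map")
  structure(list(n = as.integer(n), transition = transition,
                 stepFamily = stepFamily, angles = isTRUE(angles),
                 fmm = isTRUE(fmm),
                 blocks = if (transition == "block") blocks else NULL),
            class = "hmm_spec")
}

#' @export
print.hmm_spec <- function(x, ...) {
  cat(if (x$fmm) "FMM" else "HMM", "specification:", x$n, "state(s),",
      x$transition, "transitions,", x$stepFamily, "steps",
      if (x$angles) "+ von Mises angles", "\n")
  cat("  covariate dimension k_t =", specKt(x),
      "| free parameters =", countFreeParams(x), "\n")
  invisible(x)
}

# short label used in grids and experiment tables
.specLabel <- function(spec)
  paste0(if (spec$fmm) "FMM-" else "HMM-", spec$transition)

#' Hour-to-block map for the block transition structure
#'
#' Partitions the 24 hours of the day into `M` blocks.  The default is the
#' three-block layout used for the panther analyses: block 1 = hours 21-23
#' and 0-6 (night), block 2 = hours 7-16 (day), block 3 = hours 17-20
#' (evening).
#'
#' @param groups list of integer vectors of hours (0-23) that must partition
#'   `0:23` exactly.
#' @return Integer vector of length 24 mapping hour `h` (via index `h + 1`)
#'   to its block, with attribute `M`.
#' @export
#' @examples
#' m <- makeBlockMap()
#' m[22 + 1]  # hour 22 -> block 1
makeBlockMap <- function(groups = list(c(21:23, 0:6), 7:16, 17:20)) {
  all_h <- sort(unlist(groups))
  if (!identical(all_h, 0:23))
    stop("hour groups must partition 0..23 exactly (overlap or gap found)")
  map <- integer(24)
  for (b in seq_along(groups)) map[groups[[b]] + 1L] <- b
  structure(map, M = length(groups))
}

#' Covariate dimension implied by a transition structure
#'
#' Returns the number of coefficients per (row, target) pair: 1 for
#' homogeneous, `M` for block, 3 for quadratic and sinusoidal, 24 for hourly.
#'
#' @param spec an [hmmSpec].
#' @return Integer covariate dimension `k_t`.
#' @export
specKt <- function(spec) {
  switch(spec$transition,
         homogeneous = 1L,
         block = as.integer(attr(spec$blocks, "M")),
         quadratic = 3L,
         sinusoidal = 3L,
         hourly = 24L)
}

# design row(s) of the linear predictor for given hour values; hours are
# reduced modulo 24 so periodic structures are exactly 24-periodic in
# floating point.
.hourBasis <- function(spec, hours) {
  t24 <- hours %% 24
  switch(spec$transition,
         homogeneous = matrix(1, length(hours), 1),
         block = {
           M <- attr(spec$blocks, "M")
           b <- spec$blocks[floor(t24) + 1L]
           out <- matrix(0, length(hours), M)
           out[cbind(seq_along(hours), b)] <- 1
           out
         },
         quadratic = cbind(1, t24 / 24, (t24 / 24)^2),
         sinusoidal = cbind(1, cos(2 * pi * t24 / 24), sin(2 * pi * t24 / 24)),
         hourly = {
           h <- floor(t24) + 1L
           out <- matrix(0, length(hours), 24)
           out[cbind(seq_along(hours), h)] <- 1
           out
         })
}

# empty coefficient array of the right shape: (rows) x (n-1 targets) x (kt)
.betaSkeleton <- function(spec) {
  array(0, dim = c(if (spec$fmm) 1L else spec$n, spec$n - 1L, specKt(spec)))
}

.checkBeta <- function(spec, beta) {
  want <- dim(.betaSkeleton(spec))
  if (!is.array(beta) || !identical(dim(beta), want))
    stop("transition coefficient array must have dim ",
         paste(want, collapse = " x "))
  if (!all(is.finite(beta))) stop("transition coefficients must be finite")
  invisible(beta)
}

#' Linear predictors of the transition link
#'
#' Evaluates the multinomial-logit linear predictors `eta_ij(t)` for targets
#' `j = 2..n` at one hour value; the baseline target `j = 1` carries no
#' coefficients and its predictor is identically 0.  Hours outside `[0, 24)`
#' are reduced modulo 24; fractional hours are allowed (block and hourly
#' structures use the integer hour).
#'
#' @param spec an [hmmSpec].
#' @param beta coefficient array of dimension `(rows, n - 1, k_t)` where
#'   `rows` is 1 for a finite mixture and `n` otherwise.
#' @param t hour of day (scalar).
#' @return An `n x (n - 1)` matrix of predictors (rows recycled when
#'   `fmm = TRUE`); `n = 1` yields a zero-column matrix.
#' @export
linearPredictor <- function(spec, beta, t) {
  stopifnot(inherits(spec, "hmm_spec"), length(t) == 1)
  .checkBeta(spec, beta)
  basis <- .hourBasis(spec, t)[1, ]
  nm1 <- spec$n - 1L
  rows <- dim(beta)[1]
  kt <- specKt(spec)
  eta <- matrix(0, rows, nm1)
  for (j in seq_len(nm1))
    eta[, j] <- matrix(beta[, j, ], nrow = rows, ncol = kt) %*% basis
  if (spec$fmm) eta <- matrix(eta, spec$n, nm1, byrow = TRUE)
  eta
}

#' Transition probability matrix at a given hour
#'
#' Maps the linear predictors through the multinomial-logit link: for targets
#' `j >= 2`, `pi_ij = exp(eta_ij) / (1 + sum_j exp(eta_ij))`, and the baseline
#' receives the complement `pi_i1 = 1 - sum_{j>=2} pi_ij`.  Overflow is
#' guarded by max-subtraction, so every entry lies in (0, 1) and each row sums
#' to 1 for any finite coefficients.  When `fmm = TRUE` all rows are
#' identical.
#'
#' @inheritParams linearPredictor
#' @return An `n x n` row-stochastic matrix.
#' @export
transitionMatrix <- function(spec, beta, t) {
  eta <- linearPredictor(spec, beta, t)
  n <- spec$n
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    e <- c(0, eta[i, ])
    m <- max(e)
    w <- exp(e - m)
    out[i, ] <- w / sum(w)
  }
  out
}

# n x n x H array over the distinct hour values `hours`
.tpmArray <- function(spec, beta, hours) {
  n <- spec$n
  out <- array(0, dim = c(n, n, length(hours)))
  for (h in seq_along(hours)) out[, , h] <- transitionMatrix(spec, beta, hours[h])
  out
}
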