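#' Free-parameter count of a movement HMM
#'
#' The number of free parameters is the sum over the three model components:
#' `k_i (n - 1)` for the initial-state distribution, `k_t n (n - 1)` for the
#' transition probabilities (reduced to `k_t (n - 1)` under the
#' finite-mixture constraint, which shares one row across states), and
#' `k_e n` for the emissions.  `k_i`, `k_t` and `k_e` are the per-component
#' covariate dimensions; a homogeneous component has `k = 1`.
#'
#' Can be called either with an [hmmSpec] (the `k`'s are then derived from
#' the specification: `k_i = 1`, `k_t` from the transition structure,
#' `k_e = 2` per step family plus 2 when angles are included) or with
#' explicit integers.
#'
#' @param spec an [hmmSpec], or an integer state count `n`.
#' @param k_i,k_t,k_e component covariate dimensions (ignored when `spec` is
#'   an `hmm_spec`).
#' @param fmm finite-mixture constraint (ignored when `spec` is an
#'   `hmm_spec`).
#' @return Integer free-parameter count.
#' @export
#' @examples
#' countFreeParams(3, k_i = 1, k_t = 1, k_e = 2)   # homogeneous log-Normal: 14
#' countFreeParams(5, k_i = 1, k_t = 3, k_e = 2)   # sinusoidal: 74
countFreeParams <- function(spec, k_i = 1L, k_t = 1L, k_e = 2L, fmm = FALSE) {
  if (inherits(spec, "hmm_spec")) {
    n <- spec$n
    k_i <- 1L
    k_t <- specKt(spec)
    k_e <- 2L + 2L * spec$angles
    fmm <- spec$fmm
  } else {
    n <- spec
  }
  stopifnot(n >= 1, k_i >= 1, k_t >= 1, k_e >= 1)
  trans <- if (fmm) k_t * (n - 1L) else k_t * n * (n - 1L)
  as.integer(k_i * (n - 1L) + trans + k_e * n)
}

#' Information criteria of a fitted model
#'
#' `BIC = -2 loglik + n_free log(n_obs)` and `AIC = -2 loglik + 2 n_free`,
#' where `n_obs` is the number of time points in the fitted series (not
#' doubled when turning angles are included; the penalty counts time points,
#' not scalar observations).
#'
#' @param fitted an `hmm_fit` from [fitHMM()].
#' @return Named numeric vector with elements `BIC` and `AIC`.
#' @export
informationCriteria <- function(fitted) {
  stopifnot(inherits(fitted, "hmm_fit"), fitted$n_obs > 0)
  c(BIC = -2 * fitted$loglik + fitted$n_free * log(fitted$n_obs),
    AIC = -2 * fitted$loglik + 2 * fitted$n_free)
}

#' Grid search over state counts and transition structures
#'
#' Fits every combination of state count and candidate structure, computes
#' BIC/AIC and delta-BIC (`BIC - min(BIC)` over converged fits), and selects
#' the minimum-BIC row.  Ties are broken toward the smaller state count, then
#' toward the earlier candidate.  Individual fit failures are recorded per
#' row and excluded from the minimum; they are never silently dropped.
#' Hourly-structure candidates are only fitted for `n <= 4` (with a message)
#' because of their very large parameter count.
#'
#' @param series a [trajectory].
#' @param nRange state counts to fit (default `2:6`).
#' @param transitions character vector of transition structures to try.
#' @param fmm logical vector of finite-mixture flags to cross with
#'   `transitions` (default `FALSE` only).
#' @param stepFamily,angles emission choices, see [hmmSpec()].
#' @param nStarts,seed,maxIter,tol,stepFloor passed to [fitHMM()]; every
#'   candidate uses the same start-seed stream, so identical candidates give
#'   identical fits.
#' @return An object of class `hmm_grid`: a data frame with one row per
#'   candidate (`label`, `n`, `n_free`, `loglik`, `BIC`, `AIC`, `dBIC`,
#'   `converged`, `selected`) and attributes `fits` (list of `hmm_fit`) and
#'   `selected` (row index).
#' @export
fitGrid <- function(series, nRange = 2:6,
                    transitions = c("homogeneous", "sinusoidal"),
                    fmm = FALSE, stepFamily = "lognormal", angles = FALSE,
                    nStarts = 10, seed = 1L, maxIter = 500, tol = 1e-6,
                    stepFloor = 0.1) {
  stopifnot(length(nRange) >= 1)
  cand <- expand.grid(transition = transitions, fmm = fmm, n = nRange,
                      stringsAsFactors = FALSE)
  drop <- cand$transition == "hourly" & cand$n > 4
  if (any(drop)) {
    message("dropping ", sum(drop), " hourly candidate(s) with n > 4")
    cand <- cand[!drop, , drop = FALSE]
  }
  fits <- vector("list", nrow(cand))
  res <- data.frame(label = character(nrow(cand)), n = cand$n,
                    n_free = NA_integer_, loglik = NA_real_, BIC = NA_real_,
                    AIC = NA_real_, dBIC = NA_real_, converged = FALSE,
                    error = NA_character_)
  for (r in seq_len(nrow(cand))) {
    spec <- hmmSpec(cand$n[r], transition = cand$transition[r],
                    stepFamily = stepFamily, angles = angles, fmm = cand$fmm[r])
    res$label[r] <- .specLabel(spec)
    res$n_free[r] <- countFreeParams(spec)
    fit <- tryCatch(
      withCallingHandlers(
        fitHMM(series, spec, nStarts = nStarts, seed = seed,
               maxIter = maxIter, tol = tol, stepFloor = stepFloor),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) e)
    if (inherits(fit, "error")) {
      res$error[r] <- conditionMessage(fit)
      next
    }
    fits[[r]] <- fit
    ic <- informationCriteria(fit)
    res$loglik[r] <- fit$loglik
    res$BIC[r] <- ic[["BIC"]]
    res$AIC[r] <- ic[["AIC"]]
    res$converged[r] <- fit$converged
  }
  usable <- which(!is.na(res$BIC))
  if (length(usable)) {
    res$dBIC[usable] <- res$BIC[usable] - min(res$BIC[usable])
    sel <- usable[order(res$BIC[usable], res$n[usable], usable)][1]
  } else {
    sel <- NA_integer_
  }
  res$selected <- seq_len(nrow(res)) == if (is.na(sel)) 0L else sel
  structure(res, fits = fits, selected = sel,
            class = c("hmm_grid", "data.frame"))
}

#' @export
print.hmm_grid <- function(x, ...) {
  cat("Model grid (", nrow(x), " candidates)\n", sep = "")
  df <- as.data.frame(x)
  df$loglik <- round(df$loglik, 1)
  df$BIC <- round(df$BIC, 1)
  df$AIC <- round(df$AIC, 1)
  df$dBIC <- round(df$dBIC, 1)
  print(df[, setdiff(names(df), "error")], row.names = FALSE)
  sel <- attr(x, "selected")
  if (!is.na(sel))
    cat("selected:", x$label[sel], "with n =", x$n[sel], "\n")
  invisible(x)
}

#' BIC-optimal state count of a grid
#'
#' @param grid an `hmm_grid` from [fitGrid()].
#' @return The state count of the minimum-BIC row (`NA` if nothing fitted).
#' @export
selectedStates <- function(grid) {
  sel <- attr(grid, "selected")
  if (is.na(sel)) NA_integer_ else grid$n[sel]
}
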