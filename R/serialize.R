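#' Serialize fitted models to JSON
#'
#' `writeHMM()` writes an `hmm_fit` (or a bare spec + theta pair wrapped the
#' same way) to a documented JSON schema: the specification, the estimated
#' parameters (prior, transition coefficient array with its dimensions,
#' emission parameters), the maximised log-likelihood, free-parameter count,
#' number of observations, seed and the per-start convergence log.
#' `readHMM()` restores the object.
#'
#' @param fit an `hmm_fit` from [fitHMM()].
#' @param path output (input) JSON path.
#' @return `writeHMM` returns `path` invisibly; `readHMM` returns an
#'   `hmm_fit`.
#' @export
writeHMM <- function(fit, path) {
  stopifnot(inherits(fit, "hmm_fit"))
  spec <- fit$spec
  obj <- list(
    schema = "periodicHMM-model-1",
    spec = list(n = spec$n, transition = spec$transition,
                stepFamily = spec$stepFamily, angles = spec$angles,
                fmm = spec$fmm,
                blocks = if (!is.null(spec$blocks)) as.integer(spec$blocks)),
    theta = list(prior = fit$theta$prior,
                 beta = as.vector(fit$theta$beta),
                 beta_dim = dim(fit$theta$beta),
                 emission = list(family = fit$theta$emission$family,
                                 step = fit$theta$emission$step,
                                 angle = fit$theta$emission$angle)),
    loglik = fit$loglik, n_free = fit$n_free, n_obs = fit$n_obs,
    converged = fit$converged, best_start = fit$best_start, seed = fit$seed,
    stepFloor = fit$stepFloor, convergence = fit$convergence,
    package_version = as.character(packageVersion("periodicHMM")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeHMM
#' @export
readHMM <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || obj$schema != "periodicHMM-model-1")
    stop("not a periodicHMM model file: ", path)
  s <- obj$spec
  blocks <- if (!is.null(s$blocks)) {
    groups <- split(0:23, s$blocks)
    makeBlockMap(groups[order(as.integer(names(groups)))])
  } else makeBlockMap()
  spec <- hmmSpec(s$n, transition = s$transition, stepFamily = s$stepFamily,
                  angles = s$angles, fmm = s$fmm, blocks = blocks)
  emj <- obj$theta$emission
  em <- if (emj$family == "lognormal")
    emissionParams("lognormal", meanlog = emj$step$meanlog,
                   sdlog = emj$step$sdlog, mu = emj$angle$mu,
                   kappa = emj$angle$kappa)
  else
    emissionParams("weibull", shape = emj$step$shape, scale = emj$step$scale,
                   mu = emj$angle$mu, kappa = emj$angle$kappa)
  beta <- array(obj$theta$beta, dim = obj$theta$beta_dim)
  theta <- hmmTheta(spec, obj$theta$prior, beta, em)
  structure(list(spec = spec, theta = theta, loglik = obj$loglik,
                 n_free = obj$n_free, n_obs = obj$n_obs,
                 convergence = as.data.frame(obj$convergence),
                 converged = obj$converged, best_start = obj$best_start,
                 seed = obj$seed, stepFloor = obj$stepFloor),
            class = "hmm_fit")
}
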