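#' State-count recovery experiment
#'
#' Runs the simulation experiment quantifying how model misspecification
#' inflates the BIC-selected number of movement states.  Replicate series are
#' simulated from a 2-state truth that is either temporally heterogeneous
#' (sinusoidal transition predictors) or homogeneous, optionally re-observed
#' through radially symmetric GPS noise ([reobserveWithNoise()]); each
#' replicate is then fitted with each *fitting class* (a transition
#' structure, e.g. homogeneous vs sinusoidal) over a range of state counts,
#' and the BIC-optimal state count is recorded.
#'
#' Every source of randomness descends deterministically from `seed`:
#' per-replicate simulation, noise and fitting seeds are drawn once from the
#' root seed, so the experiment is reproducible and replicates are
#' independent.
#'
#' @param truths character subset of `c("heterogeneous", "homogeneous")`
#'   naming the generating profiles (see [pantherProfile()]; heterogeneous is
#'   the `"default"` profile).
#' @param noise logical vector: re-observe through GPS noise or not; crossed
#'   with `truths` to form the experiment cases.
#' @param classes transition structures used as fitting classes.
#' @param nReps replicates per case (the full-scale experiment uses 100).
#' @param T simulated series length per replicate.
#' @param nRange state counts fitted (default `2:4`).
#' @param noiseSd GPS noise standard deviation, metres per coordinate.
#' @param nStarts random restarts per fit (kept small in replicate
#'   experiments; see the package vignette).
#' @param seed root seed.
#' @return An object of class `recovery_result`: list with `results`
#'   (per-replicate data frame: `truth`, `noise`, `class`, `rep`,
#'   `n_selected`), `frequencies` (aggregated counts of the selected state
#'   count per case and class), `failures` (replicate fits that errored) and
#'   `config`.
#' @export
runRecoveryExperiment <- function(truths = c("heterogeneous", "homogeneous"),
                                  noise = c(FALSE, TRUE),
                                  classes = c("homogeneous", "sinusoidal"),
                                  nReps = 100, T = 2000, nRange = 2:4,
                                  noiseSd = 5, nStarts = 3, seed = 1L) {
  stopifnot(all(truths %in% c("heterogeneous", "homogeneous")),
            nReps >= 1, T >= 10)
  set.seed(as.integer(seed))
  maxint <- .Machine$integer.max - 1L
  rows <- list()
  fails <- list()
  for (truth in truths) {
    profile <- if (truth == "heterogeneous") "default" else "homogeneous"
    gen <- pantherProfile(profile)
    # one seed per replicate, shared across noise settings, so the same true
    # series is observed with and without noise (paired comparison)
    repSeeds <- sample.int(maxint, nReps)
    for (withNoise in noise) {
      for (r in seq_len(nReps)) {
        sim <- simulateHMM(gen$spec, gen$theta, T = T, hour0 = 0,
                           seed = repSeeds[r])
        series <- if (withNoise)
          reobserveWithNoise(sim, sd = noiseSd, seed = repSeeds[r] %% maxint + 1L)
        else sim$series
        for (cls in classes) {
          grid <- tryCatch(
            fitGrid(series, nRange = nRange, transitions = cls,
                    nStarts = nStarts, seed = repSeeds[r]),
            error = function(e) e)
          if (inherits(grid, "error")) {
            fails[[length(fails) + 1L]] <- data.frame(
              truth = truth, noise = withNoise, class = cls, rep = r,
              message = conditionMessage(grid))
            next
          }
          rows[[length(rows) + 1L]] <- data.frame(
            truth = truth, noise = withNoise, class = cls, rep = r,
            n_selected = selectedStates(grid))
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  freq <- as.data.frame(table(truth = results$truth, noise = results$noise,
                              class = results$class, n_selected = results$n_selected),
                        stringsAsFactors = FALSE)
  names(freq)[names(freq) == "Freq"] <- "count"
  freq$n_selected <- as.integer(freq$n_selected)
  freq$noise <- as.logical(freq$noise)
  # keep only case x class combinations that were actually run
  run <- unique(results[, c("truth", "noise", "class")])
  freq <- merge(run, freq, by = c("truth", "noise", "class"))
  structure(list(results = results, frequencies = freq,
                 failures = if (length(fails)) do.call(rbind, fails) else NULL,
                 config = list(truths = truths, noise = noise,
                               classes = classes, nReps = nReps, T = T,
                               nRange = nRange, noiseSd = noiseSd,
                               nStarts = nStarts, seed = seed)),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cfg <- x$config
  cat("State-count recovery experiment:", cfg$nReps, "replicate(s) of length",
      cfg$T, "\n")
  f <- x$frequencies[x$frequencies$count > 0, ]
  f <- f[order(f$truth, f$noise, f$class, f$n_selected), ]
  print(f, row.names = FALSE)
  if (!is.null(x$failures))
    cat(nrow(x$failures), "replicate fit(s) failed and were excluded\n")
  invisible(x)
}

#' Fraction of replicates selecting a given state count
#'
#' @param result a `recovery_result`.
#' @param truth,noise,class case selectors.
#' @param n state count of interest.
#' @return Proportion in `[0, 1]` of that case's replicates whose BIC-optimal
#'   state count equals `n`.
#' @export
recoveryRate <- function(result, truth, noise, class, n) {
  r <- result$results
  sub <- r[r$truth == truth & r$noise == noise & r$class == class, ]
  if (!nrow(sub)) stop("no replicates for the requested case")
  mean(sub$n_selected == n)
}
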