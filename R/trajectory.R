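#' GPS fix series
#'
#' Container for the raw GPS fixes of one animal: strictly increasing
#' timestamps and projected planar coordinates in metres.  Timestamps may be
#' `POSIXct` or numeric seconds; no geodesy is performed, coordinates are
#' assumed already projected.
#'
#' @param id animal identifier (any scalar label).
#' @param t timestamps, `POSIXct` or numeric seconds; strictly increasing.
#' @param x,y projected coordinates in metres; finite.
#' @return An object of class `fix_series`.
#' @export
fixSeries <- function(id, t, x, y) {
  if (length(t) != length(x) || length(t) != length(y))
    stop("t, x and y must have equal length")
  tn <- as.numeric(t)
  if (anyNA(tn)) stop("unparseable timestamps in fix series '", id, "'")
  d <- diff(tn)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1] + 1
    stop("timestamps for animal '", id, "' not strictly increasing at row ", bad)
  }
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite coordinates in fix series '", id, "'")
  structure(list(id = id, t = t, x = as.numeric(x), y = as.numeric(y)),
            class = "fix_series")
}

#' @export
print.fix_series <- function(x, ...) {
  cat("GPS fix series: animal", format(x$id), "-", length(x$t), "fixes\n")
  invisible(x)
}

#' Read GPS fix tables from delimited text
#'
#' Reads a CSV/TSV table of GPS fixes and returns one [fixSeries] per animal,
#' sorted by time.  Duplicate timestamps within an animal are rejected.
#'
#' @param path path to a delimited text file.
#' @param columns named character vector mapping the roles `id`, `time`, `x`,
#'   `y` to column names in the file.
#' @param sep field separator, default comma.
#' @return Named list of `fix_series`, one element per animal id.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(id = "a", t = c(0, 3600, 7200), x = c(0, 3, 3),
#'                      y = c(0, 4, 9)), f, row.names = FALSE)
#' fixes <- readFixes(f)
#' length(fixes[["a"]]$t)
readFixes <- function(path, columns = c(id = "id", time = "t", x = "x", y = "y"),
                      sep = ",") {
  if (!file.exists(path)) stop("fix file not found: ", path)
  need <- c("id", "time", "x", "y")
  if (!all(need %in% names(columns)))
    stop("`columns` must map all of: ", paste(need, collapse = ", "))
  dat <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  missing <- setdiff(unname(columns[need]), names(dat))
  if (length(missing))
    stop("mapped column(s) not present in file: ", paste(missing, collapse = ", "))
  tsraw <- dat[[columns[["time"]]]]
  ts <- if (is.numeric(tsraw)) tsraw else {
    parsed <- as.POSIXct(tsraw, tz = "UTC",
                         tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                        "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d"))
    if (anyNA(parsed)) stop("unparseable timestamp at row ", which(is.na(parsed))[1])
    parsed
  }
  ids <- dat[[columns[["id"]]]]
  out <- lapply(split(seq_len(nrow(dat)), ids), function(rows) {
    o <- rows[order(ts[rows])]
    tt <- ts[o]
    dup <- which(diff(as.numeric(tt)) == 0)
    if (length(dup))
      stop("duplicate timestamp for animal '", ids[o[1]], "' at input row ",
           o[dup[1] + 1])
    fixSeries(ids[o[1]], tt, dat[[columns[["x"]]]][o], dat[[columns[["y"]]]][o])
  })
  out
}

#' Step-length / turning-angle trajectory series
#'
#' Constructor and validator for derived movement series: step lengths in
#' metres, turning angles in radians in (-pi, pi] (missing at the first step
#' of each contiguous segment), the hour-of-day covariate of each step, and an
#' integer segment label marking maximal runs of consecutive hourly steps.
#'
#' @param step_m numeric step lengths, metres, `>= 0`.
#' @param turn_rad turning angles in radians in `(-pi, pi]`; `NA` allowed.
#' @param hour hour-of-day covariate in `[0, 24)`; fractional values allowed.
#' @param segment non-decreasing integer segment labels.
#' @param animal optional animal id carried as an attribute.
#' @return A `data.frame` of class `trajectory` with columns `segment`,
#'   `hour`, `step_m`, `turn_rad`.
#' @export
trajectory <- function(step_m, turn_rad, hour, segment, animal = NULL) {
  n <- length(step_m)
  stopifnot(length(turn_rad) == n, length(hour) == n, length(segment) == n)
  if (n > 0) {
    if (!all(is.finite(step_m)) || any(step_m < 0))
      stop("step lengths must be finite and non-negative")
    ok <- is.na(turn_rad) | (turn_rad > -pi & turn_rad <= pi + 1e-12)
    if (!all(ok)) stop("turning angles must lie in (-pi, pi] or be missing")
    if (any(hour < 0 | hour >= 24)) stop("hour covariate must lie in [0, 24)")
    if (any(diff(segment) < 0)) stop("segment labels must be non-decreasing")
  }
  out <- data.frame(segment = as.integer(segment), hour = as.numeric(hour),
                    step_m = as.numeric(step_m), turn_rad = as.numeric(turn_rad))
  class(out) <- c("trajectory", "data.frame")
  attr(out, "animal") <- animal
  out
}

#' Derive step lengths and turning angles from GPS fixes
#'
#' Decomposes a fix series into successive step lengths (Euclidean distance
#' between consecutive fixes, metres) and turning angles (change in heading
#' between consecutive steps, wrapped to (-pi, pi]).  A new contiguous segment
#' starts whenever the inter-fix gap differs from the nominal interval by more
#' than `tolerance`; steps spanning larger gaps are dropped, and the turning
#' angle is missing at the first step of every segment.
#'
#' The hour-of-day covariate of a step is, by default, the hour of its
#' destination fix, so that the covariate indexes the transition *into* the
#' state emitting the step.  Set `hourFrom = "start"` for the alternative
#' convention.
#'
#' @param fixes a [fixSeries].
#' @param interval nominal inter-fix interval in seconds (default 3600, one
#'   hour).
#' @param tolerance allowed deviation from `interval` in seconds before a gap
#'   breaks the series into segments (default 360, six minutes).
#' @param hourFrom `"end"` (default) or `"start"`: which fix of a step
#'   provides its hour covariate.
#' @return A [trajectory]; empty (with a warning) when fewer than two fixes
#'   are available.
#' @export
#' @examples
#' fx <- fixSeries("a", c(0, 3600, 7200), x = c(0, 3, 3), y = c(0, 4, 9))
#' deriveSteps(fx)
deriveSteps <- function(fixes, interval = 3600, tolerance = 360,
                        hourFrom = c("end", "start")) {
  stopifnot(inherits(fixes, "fix_series"), interval > 0)
  hourFrom <- match.arg(hourFrom)
  tn <- as.numeric(fixes$t)
  N <- length(tn)
  if (N < 2) {
    warning("fewer than 2 fixes: returning an empty trajectory")
    return(trajectory(numeric(0), numeric(0), numeric(0), integer(0),
                      animal = fixes$id))
  }
  dt <- diff(tn)
  keep <- abs(dt - interval) <= tolerance   # usable steps (fix k -> k+1)
  dx <- diff(fixes$x)
  dy <- diff(fixes$y)
  s <- sqrt(dx^2 + dy^2)
  heading <- atan2(dy, dx)
  hourOf <- function(sec) (sec %% 86400) / 3600
  hour <- if (hourFrom == "end") hourOf(tn[-1]) else hourOf(tn[-N])

  idx <- which(keep)
  if (!length(idx)) {
    warning("no inter-fix gaps within tolerance of the nominal interval")
    return(trajectory(numeric(0), numeric(0), numeric(0), integer(0),
                      animal = fixes$id))
  }
  # consecutive kept steps share a segment
  segment <- cumsum(c(1L, as.integer(diff(idx) != 1L)))
  turn <- rep(NA_real_, length(idx))
  consec <- which(diff(idx) == 1L) + 1L
  turn[consec] <- .wrapAngle(heading[idx[consec]] - heading[idx[consec] - 1L])
  trajectory(s[idx], turn, hour[idx], segment, animal = fixes$id)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Movement trajectory:", nrow(x), "steps in",
      if (nrow(x)) length(unique(x$segment)) else 0L, "segment(s)\n")
  if (nrow(x)) {
    cat(sprintf("  step length: median %.1f m, range [%.1f, %.1f] m\n",
                stats::median(x$step_m), min(x$step_m), max(x$step_m)))
    cat(sprintf("  turning angle missing at %d step(s)\n", sum(is.na(x$turn_rad))))
  }
  NextMethod()
}

#' Write / read derived trajectory series
#'
#' Derived series round-trip through plain CSV with columns `segment`,
#' `hour`, `step_m`, `turn_rad` (blank when the angle is missing).
#'
#' @param series a [trajectory].
#' @param path output (input) CSV path.
#' @return `writeTrajectory` returns `path` invisibly; `readTrajectory`
#'   returns a [trajectory].
#' @export
writeTrajectory <- function(series, path) {
  stopifnot(inherits(series, "trajectory"))
  write.csv(as.data.frame(series), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  dat <- read.csv(path)
  need <- c("segment", "hour", "step_m", "turn_rad")
  missing <- setdiff(need, names(dat))
  if (length(missing))
    stop("trajectory file lacks column(s): ", paste(missing, collapse = ", "))
  trajectory(dat$step_m, dat$turn_rad, dat$hour, dat$segment)
}

# first-observation-of-segment indicator used by all recursions
.newSegment <- function(series) {
  n <- nrow(series)
  if (n == 0) return(logical(0))
  c(TRUE, series$segment[-1] != series$segment[-n])
}
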