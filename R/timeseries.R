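#' Construct a labeled time series
#'
#' Plain carrier for per-frame scalar traces (RMSD, distances, hydrogen-bond
#' indicators). Times must be strictly increasing and match the value vector
#' in length.
#'
#' @param times_ns numeric vector of times in nanoseconds.
#' @param values numeric vector, same length as `times_ns`.
#' @param label trace label.
#' @param units unit string for `values` (e.g. `"A"`).
#' @return An object of class `trj_timeseries`.
#' @export
time_series <- function(times_ns, values, label = "", units = "") {
  if (length(times_ns) != length(values)) {
    stop("times_ns and values must have equal length")
  }
  if (length(times_ns) == 0) stop("empty time series")
  if (any(diff(times_ns) <= 0)) stop("times must be strictly increasing")
  structure(list(label = as.character(label), times_ns = as.numeric(times_ns),
                 values = as.numeric(values), units = as.character(units)),
            class = "trj_timeseries")
}

#' @export
as.data.frame.trj_timeseries <- function(x, ...) {
  data.frame(time_ns = x$times_ns, value = x$values)
}

#' @export
print.trj_timeseries <- function(x, ...) {
  cat(sprintf("<trj_timeseries> '%s': %d points, %g..%g ns, units %s\n",
              x$label, length(x$values), min(x$times_ns), max(x$times_ns),
              if (nzchar(x$units)) x$units else "(none)"))
  invisible(x)
}

#' Drop the burn-in segment of a time series
#'
#' Removes every point with time strictly less than `burn_in_ns`. Equilibrium
#' statistics (e.g. distance-population fits) conventionally exclude an
#' initial segment to avoid bias from the starting configuration; apply this
#' per trajectory, before pooling.
#'
#' @param ts a `trj_timeseries`.
#' @param burn_in_ns burn-in length in nanoseconds (>= 0).
#' @return A `trj_timeseries` with the early points removed.
#' @export
apply_burn_in <- function(ts, burn_in_ns) {
  stopifnot(inherits(ts, "trj_timeseries"))
  if (!is.numeric(burn_in_ns) || length(burn_in_ns) != 1 || burn_in_ns < 0) {
    stop("burn_in_ns must be a single non-negative number")
  }
  keep <- ts$times_ns >= burn_in_ns
  if (!any(keep)) {
    stop(sprintf("burn-in of %g ns removes all %d frames", burn_in_ns, length(keep)))
  }
  time_series(ts$times_ns[keep], ts$values[keep], label = ts$label, units = ts$units)
}
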