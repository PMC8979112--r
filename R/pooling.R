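#' Sampling schedule
#'
#' An ordered set of blood-collection times anchoring both the pooling
#' weights and the truncation point of every AUC in the package. The first
#' time is the pre-dose sample (usually 0 h); schedules starting later than
#' 0 h are allowed, and all downstream spans use `t_n - t_0`, not `t_n`.
#'
#' @param times Numeric vector of collection times in hours. At least two
#'   values, strictly increasing, finite and non-negative.
#' @return A numeric vector of class `"sampling_schedule"`.
#' @examples
#' sampling_schedule(c(0, 0.25, 0.5, 1, 2, 3, 4, 6, 8, 10, 12, 24))
#' @seealso [hamilton_weights()], [pooling_volumes()]
#' @export
sampling_schedule <- function(times) {
  times <- as.numeric(times)
  if (length(times) < 2L)
    stop("a sampling schedule needs at least 2 collection times", call. = FALSE)
  if (anyNA(times) || any(!is.finite(times)))
    stop("collection times must be finite", call. = FALSE)
  if (any(times < 0))
    stop("collection times must be >= 0", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("collection times must be strictly increasing", call. = FALSE)
  structure(times, class = "sampling_schedule")
}

as_schedule <- function(x) {
  if (inherits(x, "sampling_schedule")) x else sampling_schedule(x)
}

#' @export
print.sampling_schedule <- function(x, ...) {
  cat("Sampling schedule:", length(x), "time points,",
      sprintf("%g-%g h (span %g h)\n", x[1], x[length(x)], x[length(x)] - x[1]))
  print(unclass(x), ...)
  invisible(x)
}

#' Half-interval (Hamilton) pooling weights
#'
#' Weights `w_k` such that the volume-weighted mean of per-time-point
#' concentrations, multiplied by the schedule span, equals the linear
#' trapezoidal AUC of the serial profile:
#' `w_0 = (t_1 - t_0)/2`, `w_k = (t_{k+1} - t_{k-1})/2` for interior points,
#' `w_n = (t_n - t_{n-1})/2`. They sum to `t_n - t_0` by telescoping. The
#' pre-dose point carries weight `(t_1 - t_0)/2`, i.e. it is part of the pool.
#'
#' @param schedule A [sampling_schedule()] (or a plain numeric time vector).
#' @return Numeric vector of weights (hours), one per collection time.
#' @examples
#' hamilton_weights(sampling_schedule(c(0, 1, 2, 4)))  # 0.5 1 1.5 1
#' @export
hamilton_weights <- function(schedule) {
  t <- as_schedule(schedule)
  n <- length(t)
  w <- numeric(n)
  h <- diff(t)
  w[1] <- h[1] / 2
  w[n] <- h[n - 1] / 2
  if (n > 2L)
    w[2:(n - 1)] <- (t[3:n] - t[1:(n - 2)]) / 2
  w
}

#' Per-time-point plasma pooling volumes
#'
#' Allocates a total pooled plasma volume across the schedule in proportion
#' to the half-interval weights, optionally rounding each aliquot to a
#' pipettable increment. The resulting single mixed sample encodes the
#' trapezoidal AUC: its concentration times the schedule span reproduces the
#' serial-sampling AUC exactly when the exact (unrounded) volumes are used.
#'
#' @param schedule A [sampling_schedule()] or numeric time vector (hours).
#' @param total_volume Total pooled volume in microliters; must be > 0.
#' @param rounding_increment Rounding step in microliters for each aliquot;
#'   0 keeps exact volumes. Default 0.1 (a pipettable increment).
#' @return An object of class `"pooling_design"`: a list with elements
#'   `schedule`, `volumes` (uL), `total_volume`, `rounding_increment` and
#'   `diagnostics` (character, possibly empty). If any rounded volume
#'   deviates more than 1% from its exact value a warning is raised and
#'   recorded in `diagnostics`.
#' @examples
#' sched <- sampling_schedule(c(0, 0.25, 0.5, 1, 2, 3, 4, 6, 8, 10, 12, 24))
#' pooling_volumes(sched, total_volume = 480)
#' @export
pooling_volumes <- function(schedule, total_volume, rounding_increment = 0.1) {
  sched <- as_schedule(schedule)
  if (!is.numeric(total_volume) || length(total_volume) != 1L ||
      !is.finite(total_volume) || total_volume <= 0)
    stop("'total_volume' must be a single positive number (uL)", call. = FALSE)
  if (!is.numeric(rounding_increment) || length(rounding_increment) != 1L ||
      !is.finite(rounding_increment) || rounding_increment < 0)
    stop("'rounding_increment' must be a single number >= 0 (uL)", call. = FALSE)

  w <- hamilton_weights(sched)
  exact <- total_volume * w / sum(w)
  diagnostics <- character()
  if (rounding_increment > 0) {
    v <- round(exact / rounding_increment) * rounding_increment
    if (any(v <= 0))
      stop("rounding increment ", rounding_increment,
           " uL drives a pooling volume to zero; use a finer increment",
           call. = FALSE)
    rel <- abs(v - exact) / exact
    if (any(rel > 0.01)) {
      bad <- which(rel > 0.01)
      diagnostics <- sprintf(
        "volume at t=%g h rounded %.4g -> %.4g uL (%.2f%% deviation)",
        sched[bad], exact[bad], v[bad], 100 * rel[bad])
      warning("rounded pooling volumes deviate >1% from exact at ",
              length(bad), " time point(s)", call. = FALSE)
    }
  } else {
    v <- exact
  }
  structure(
    list(schedule = sched, volumes = v, total_volume = total_volume,
         rounding_increment = rounding_increment, diagnostics = diagnostics),
    class = "pooling_design")
}

#' @export
print.pooling_design <- function(x, ...) {
  cat("Pooling design:", length(x$volumes), "aliquots,",
      sprintf("total %g uL (increment %g uL)\n",
              x$total_volume, x$rounding_increment))
  print(as.data.frame(x), row.names = FALSE, ...)
  if (length(x$diagnostics))
    cat("Diagnostics:\n ", paste(x$diagnostics, collapse = "\n  "), "\n")
  invisible(x)
}

#' @export
as.data.frame.pooling_design <- function(x, ...) {
  data.frame(time_h = as.numeric(x$schedule), volume_uL = x$volumes)
}

#' Write / read a pooling design as delimited text
#'
#' Two-column CSV with header `time_h, volume_uL`.
#'
#' @param design A [pooling_volumes()] result.
#' @param path File path.
#' @return `write_design` returns `path` invisibly; `read_design_config`
#'   returns the parsed key-value document as a list.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "pooling_design"))
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' Read a schedule/pooling configuration document
#'
#' YAML key-value document with keys `times_h` (list of hours),
#' `total_volume_uL`, and optional `rounding_increment_uL`.
#'
#' @param path Path to the YAML document.
#' @return A list with `schedule` ([sampling_schedule()]), `total_volume`
#'   and `rounding_increment`.
#' @export
read_design_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in c("times_h", "total_volume_uL"))
    if (is.null(cfg[[key]]))
      stop("design config is missing required key '", key, "'", call. = FALSE)
  list(schedule = sampling_schedule(unlist(cfg$times_h)),
       total_volume = as.numeric(cfg$total_volume_uL),
       rounding_increment =
         if (is.null(cfg$rounding_increment_uL)) 0.1
         else as.numeric(cfg$rounding_increment_uL))
}
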