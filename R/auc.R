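#' Concentration (or peak-area) profile
#'
#' A per-compound value-versus-time series. Values may be calibrated
#' concentrations or semi-quantitative peak areas; the unit is carried as an
#' opaque label and never converted. Points flagged below the lower limit of
#' quantification (LLOQ) are treated as zero by every AUC and pooling
#' computation; the flags propagate to outputs.
#'
#' @param times Numeric, strictly increasing times in hours.
#' @param values Numeric, non-negative measurements, same length as `times`.
#' @param compound_id Compound identifier.
#' @param unit_label Unit of `values` (e.g. `"mg/L"` or `"area"`).
#' @param below_lloq Logical vector, same length as `values`; defaults to
#'   all `FALSE`.
#' @return An object of class `"concentration_profile"`.
#' @examples
#' concentration_profile(c(0, 1, 2), c(0, 10, 0), compound_id = "demo")
#' @export
concentration_profile <- function(times, values, compound_id = "compound",
                                  unit_label = "conc",
                                  below_lloq = rep(FALSE, length(values))) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("'times' and 'values' must have the same length", call. = FALSE)
  if (length(below_lloq) != length(values))
    stop("'below_lloq' must match 'values' in length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (anyNA(values) || any(values < 0))
    stop("'values' must be non-negative and non-missing", call. = FALSE)
  structure(
    list(compound_id = as.character(compound_id), times = times,
         values = values, unit_label = as.character(unit_label),
         below_lloq = as.logical(below_lloq)),
    class = "concentration_profile")
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf("Concentration profile '%s': %d points, %g-%g h [%s]",
              x$compound_id, length(x$times), x$times[1],
              x$times[length(x$times)], x$unit_label))
  if (any(x$below_lloq)) cat(",", sum(x$below_lloq), "below LLOQ")
  cat("\n")
  print(data.frame(time_h = x$times, value = x$values,
                   below_lloq = x$below_lloq), row.names = FALSE, ...)
  invisible(x)
}

#' @export
plot.concentration_profile <- function(x, ...) {
  graphics::plot(x$times, effective_values(x), type = "b",
                 xlab = "time (h)", ylab = x$unit_label,
                 main = x$compound_id, ...)
  invisible(x)
}

# LLOQ-censored values used by all integrations
effective_values <- function(profile) {
  v <- profile$values
  v[profile$below_lloq] <- 0
  v
}

new_auc_estimate <- function(compound_id, value, method, t_start, t_end,
                             unit_label = "conc") {
  stopifnot(t_end > t_start, value >= 0)
  structure(
    list(compound_id = compound_id, value = value, method = method,
         t_start = t_start, t_end = t_end, unit_label = unit_label),
    class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC[%g-%g h] of '%s' (%s method): %g %s*h\n",
              x$t_start, x$t_end, x$compound_id, x$method, x$value,
              x$unit_label))
  invisible(x)
}

#' Serial-sampling trapezoidal AUC
#'
#' Linear trapezoidal rule over the full profile,
#' `AUC = sum (C_i + C_{i+1})/2 * (t_{i+1} - t_i)` — the "traditional method"
#' against which the pooled estimate is validated. Only the linear rule is
#' provided: the pooling identity is exact for it and for no log-linear
#' variant.
#'
#' @param profile A [concentration_profile()].
#' @return An `auc_estimate` with `method = "trapezoid"`.
#' @examples
#' trapezoid_auc(concentration_profile(c(0, 1, 2), c(0, 10, 0)))  # value 10
#' @export
trapezoid_auc <- function(profile) {
  stopifnot(inherits(profile, "concentration_profile"))
  v <- effective_values(profile)
  t <- profile$times
  n <- length(t)
  value <- sum((v[-n] + v[-1]) / 2 * diff(t))
  new_auc_estimate(profile$compound_id, value, "trapezoid", t[1], t[n],
                   profile$unit_label)
}

#' Pool a serial profile in silico
#'
#' Volume-weighted mean `sum(v_i C_i) / sum(v_i)` — the concentration of the
#' single mixed sample obtained by combining the design's aliquots. The
#' result always lies between the smallest and largest (LLOQ-censored)
#' profile values.
#'
#' @param profile A [concentration_profile()] sampled at the design's times.
#' @param design A [pooling_volumes()] design whose schedule matches the
#'   profile's times.
#' @return The pooled value (same unit as the profile).
#' @export
pool_concentration <- function(profile, design) {
  stopifnot(inherits(profile, "concentration_profile"),
            inherits(design, "pooling_design"))
  if (length(profile$times) != length(design$schedule) ||
      !isTRUE(all.equal(profile$times, as.numeric(design$schedule))))
    stop("profile times do not match the pooling design schedule",
         call. = FALSE)
  v <- effective_values(profile)
  sum(design$volumes * v) / sum(design$volumes)
}

#' AUC from a single pooled measurement
#'
#' The pooled-sample concentration multiplied by the schedule span
#' `t_n - t_0` estimates the truncated AUC: with exact pooling volumes the
#' identity `pooled_auc == trapezoid_auc` holds to floating tolerance for
#' every profile.
#'
#' @param pooled_value Measured concentration/area of the pooled sample
#'   (non-negative).
#' @param schedule The [sampling_schedule()] the pool was designed for.
#' @param compound_id Compound identifier for the estimate.
#' @param unit_label Unit of `pooled_value`.
#' @return An `auc_estimate` with `method = "pooled"`.
#' @examples
#' sched <- sampling_schedule(c(0, 1, 2, 4))
#' pooled_auc(4, sched)  # 4 * 4 h = 16
#' @export
pooled_auc <- function(pooled_value, schedule, compound_id = "compound",
                       unit_label = "conc") {
  sched <- as_schedule(schedule)
  if (!is.numeric(pooled_value) || length(pooled_value) != 1L ||
      is.na(pooled_value) || pooled_value < 0)
    stop("'pooled_value' must be a single non-negative number", call. = FALSE)
  span_t <- range(sched)
  new_auc_estimate(compound_id, pooled_value * (span_t[2] - span_t[1]),
                   "pooled", span_t[1], span_t[2], unit_label)
}

auc_value <- function(x) {
  if (inherits(x, "auc_estimate")) x$value else as.numeric(x)
}

#' Unsigned percent difference between two AUC estimates
#'
#' `|pooled - traditional| / traditional * 100`, with the serial trapezoidal
#' estimate as the reference denominator.
#'
#' @param auc_traditional Serial-sampling estimate (an `auc_estimate` or a
#'   number); must be > 0.
#' @param auc_pooled Pooled-sample estimate (an `auc_estimate` or a number).
#' @return Percent difference (non-negative, unrounded).
#' @examples
#' percent_difference(72517.5, 81786.81)  # 12.78 (to 2 decimals)
#' percent_difference(57651, 57984.4)     # 0.58
#' @export
percent_difference <- function(auc_traditional, auc_pooled) {
  trad <- auc_value(auc_traditional)
  pooled <- auc_value(auc_pooled)
  if (!is.finite(trad) || trad <= 0)
    stop("the traditional (reference) AUC must be > 0", call. = FALSE)
  abs(pooled - trad) / trad * 100
}

#' Mean and standard deviation across replicate AUC estimates
#'
#' Replicate pooled samples are routinely measured in triplicate; this
#' summarises one compound/method set as mean +/- sample SD (n-1
#' denominator; SD is 0 when n = 1).
#'
#' @param estimates A list of `auc_estimate` objects for a single compound
#'   and method, or a plain numeric vector.
#' @return A list with `compound_id`, `method`, `mean`, `sd`, `n`.
#' @export
replicate_summary <- function(estimates) {
  if (is.numeric(estimates)) {
    values <- estimates
    compound_id <- NA_character_; method <- NA_character_
  } else {
    stopifnot(length(estimates) >= 1L,
              all(vapply(estimates, inherits, TRUE, "auc_estimate")))
    compound_id <- unique(vapply(estimates, `[[`, "", "compound_id"))
    method <- unique(vapply(estimates, `[[`, "", "method"))
    if (length(compound_id) != 1L || length(method) != 1L)
      stop("replicate estimates must share one compound and one method",
           call. = FALSE)
    values <- vapply(estimates, `[[`, 0, "value")
  }
  if (length(values) < 1L) stop("need at least one estimate", call. = FALSE)
  list(compound_id = compound_id, method = method,
       mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else 0,
       n = length(values))
}

#' Compare the pooled and serial AUC estimates for one profile
#'
#' Pools the serial profile with the given design, forms both estimates and
#' the unsigned percent difference.
#'
#' @param profile A [concentration_profile()].
#' @param design A [pooling_volumes()] design on the profile's times.
#' @return A `method_comparison` object: `compound_id`, both `auc_estimate`s
#'   and `percent_difference`.
#' @export
compare_methods <- function(profile, design) {
  trad <- trapezoid_auc(profile)
  pooled <- pooled_auc(pool_concentration(profile, design), design$schedule,
                       profile$compound_id, profile$unit_label)
  structure(
    list(compound_id = profile$compound_id, auc_traditional = trad,
         auc_pooled = pooled,
         percent_difference = percent_difference(trad, pooled)),
    class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf(
    "'%s': traditional %g, pooled %g (difference %.2f%%)\n",
    x$compound_id, x$auc_traditional$value, x$auc_pooled$value,
    x$percent_difference))
  invisible(x)
}
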