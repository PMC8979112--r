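# Shared fixtures: the 12-point 0-24 h study schedule and random generators
# used by the property-style suites.

study_times <- c(0, 0.25, 0.5, 1, 2, 3, 4, 6, 8, 10, 12, 24)
study_schedule <- sampling_schedule(study_times)
study_volumes <- c(2.5, 5, 7.5, 15, 20, 20, 30, 40, 40, 40, 140, 120)

random_schedule <- function(n_points = sample(3:15, 1), t_max = 48) {
  sampling_schedule(sort(c(0, runif(n_points - 1, 0.01, t_max))))
}

random_profile <- function(schedule, scale = 100) {
  concentration_profile(as.numeric(schedule),
                        runif(length(schedule), 0, scale))
}

# Definitional Pearson r via raw sums — independent oracle for cor-based code
pearson_oracle <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# Dense-grid trapezoid of a function, oracle for closed-form AUCs
dense_auc <- function(f, upper, step = 0.01) {
  t <- seq(0, upper, by = step)
  y <- f(t)
  sum((y[-length(y)] + y[-1]) / 2 * diff(t))
}
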