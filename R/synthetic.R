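#' Ground-truth organ kinetic model
#'
#' A noise-free sum-of-exponentials concentration model used by the
#' synthetic-data generator. Signed amplitudes are allowed so uptake phases
#' can be modelled as `A - B exp(-k t)`; the predicted mean must stay
#' non-negative over the first 30 days.
#'
#' @param organ tissue label.
#' @param amplitude signed amplitudes, %IA/g.
#' @param rate_h rates, 1/hour (non-negative; a zero rate is a plateau).
#' @param noise_cv lognormal inter-animal coefficient of variation.
#' @return object of class `organ_model`.
#' @export
organ_model <- function(organ, amplitude, rate_h, noise_cv = 0.15) {
  if (length(amplitude) != length(rate_h) || length(amplitude) == 0L) {
    stop_validation("amplitude and rate_h must be non-empty, equal length")
  }
  if (noise_cv < 0) stop_validation("noise_cv must be >= 0")
  if (any(rate_h < 0)) stop_validation("rates must be >= 0 (", organ, ")")
  m <- structure(list(organ = organ, amplitude = amplitude, rate_h = rate_h,
                      noise_cv = noise_cv),
                 class = "organ_model")
  chk <- organ_model_mean(m, seq(0, 720, by = 1))
  if (any(chk < 0)) {
    stop_validation("model predicts negative concentration within 30 days (",
                    organ, ")")
  }
  m
}

organ_model_mean <- function(model, time_h) {
  exp_value(model$amplitude, model$rate_h, time_h)
}

#' Default ground-truth organ library
#'
#' Thirteen tissues qualitatively emulating a mouse antibody
#' biodistribution: bi-phasic blood clearance (63% with a 6 h half-life plus
#' 37% with a 19 h half-life), slow hepatic and splenic accumulation,
#' moderate kidney retention, and low muscle background. These are
#' validation fixtures with known parameters, not measured data.
#'
#' @param blood_c0 blood concentration at t = 0, %IA/g.
#' @param noise_cv shared inter-animal CV.
#' @return named list of [organ_model()] objects.
#' @export
default_organ_library <- function(blood_c0 = 30, noise_cv = 0.15) {
  lam <- function(t12) log(2) / t12
  lst <- list(
    organ_model("blood", blood_c0 * c(0.63, 0.37), c(lam(6), lam(19)), noise_cv),
    organ_model("heart", c(8, -4), c(lam(60), lam(3)), noise_cv),
    organ_model("lungs", c(10, -4), c(lam(70), lam(3)), noise_cv),
    organ_model("liver", c(22, -14), c(lam(900), lam(12)), noise_cv),
    organ_model("spleen", c(40, -25), c(lam(700), lam(10)), noise_cv),
    organ_model("kidneys", c(9, -4), c(lam(150), lam(5)), noise_cv),
    organ_model("stomach", c(3, -1.5), c(lam(80), lam(4)), noise_cv),
    organ_model("intestine", c(4, -2), c(lam(90), lam(5)), noise_cv),
    organ_model("bone", c(5, -2.5), c(lam(200), lam(8)), noise_cv),
    organ_model("thymus", c(18, -16), c(lam(400), lam(9)), noise_cv),
    organ_model("muscle", c(1.5, -0.8), c(lam(120), lam(6)), noise_cv),
    organ_model("tumor", c(12, -11), c(lam(300), lam(10)), noise_cv),
    organ_model("bat", c(6, -3), c(lam(100), lam(6)), noise_cv))
  stats::setNames(lst, vapply(lst, `[[`, "", "organ"))
}

#' Generate a synthetic biodistribution cohort
#'
#' For each organ and sampling time, draws `n_per_time` animal values with
#' mean-preserving lognormal noise (CV = the model's `noise_cv`) around the
#' ground-truth mean, then records the per-time sample mean, SD and n —
#' mirroring a sacrifice-design biodistribution study. The default schedule
#' is 1, 6, 24, 72 and 144 h.
#'
#' @param models list of [organ_model()] objects.
#' @param schedule sampling times, hours, strictly increasing.
#' @param n_per_time animals per time point (>= 1).
#' @param seed RNG seed; fixing it fixes every generated value.
#' @return object of class `biodist`: `curves` (list of [tac()]) plus the
#'   generation settings.
#' @export
simulate_biodistribution <- function(models,
                                     schedule = c(1, 6, 24, 72, 144),
                                     n_per_time = 5, seed = NULL) {
  if (any(diff(schedule) <= 0) || length(schedule) < 1L) {
    stop_validation("schedule must be strictly increasing and non-empty")
  }
  if (n_per_time < 1L) stop_validation("n_per_time must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  curves <- lapply(models, function(m) {
    mu <- organ_model_mean(m, schedule)
    if (any(mu < 0)) {
      stop_validation("model predicts negative mean at a schedule time (",
                      m$organ, ")")
    }
    if (m$noise_cv == 0) {
      return(tac(m$organ, schedule, mu,
                 sd = rep(0, length(mu)),
                 n = rep(n_per_time, length(mu))))
    }
    sdlog <- sqrt(log(1 + m$noise_cv^2))
    mean_s <- sd_s <- numeric(length(schedule))
    for (i in seq_along(schedule)) {
      draws <- mu[i] * stats::rlnorm(n_per_time,
                                     meanlog = -sdlog^2 / 2, sdlog = sdlog)
      mean_s[i] <- mean(draws)
      sd_s[i] <- if (n_per_time > 1L) stats::sd(draws) else 0
    }
    tac(m$organ, schedule, mean_s, sd = sd_s,
        n = rep(n_per_time, length(schedule)))
  })
  structure(list(curves = stats::setNames(curves,
                                          vapply(curves, `[[`, "", "organ")),
                 schedule = schedule, n_per_time = n_per_time, seed = seed),
            class = "biodist")
}

#' @export
print.biodist <- function(x, ...) {
  cat(sprintf("Biodistribution dataset: %d organs x %d times (n = %d/time)\n",
              length(x$curves), length(x$schedule), x$n_per_time))
  cat("organs:", paste(names(x$curves), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a kidney well-counter decay series
#'
#' Simulates 1-min-interval gamma-counter measurements of an excised kidney
#' containing free Bi-213 (fast component, 45.6 min half-life) and
#' parent-bound Ac-225 (slow component, 10 d half-life). Expected counts per
#' interval are the efficiency-weighted integral of the two-component
#' activity over the interval; realised counts are Poisson.
#'
#' @param free_bq_g free Bi-213 activity concentration at t = 0, Bq/g.
#' @param supported_bq_g parent-supported activity concentration, Bq/g.
#' @param mass_g sample mass, grams.
#' @param efficiency counts per decay, in (0, 1].
#' @param duration_h counting duration, hours (default 4.5).
#' @param interval_min interval length, minutes (default 1).
#' @param background_cpm constant background count rate (default 0).
#' @param seed RNG seed.
#' @return object of class `well_counter`: `t_start_min`, `interval_min`,
#'   `counts`, plus `efficiency` and `mass_g`.
#' @export
simulate_well_counter <- function(free_bq_g, supported_bq_g, mass_g,
                                  efficiency, duration_h = 4.5,
                                  interval_min = 1, background_cpm = 0,
                                  seed = NULL) {
  if (free_bq_g < 0 || supported_bq_g < 0) {
    stop_validation("activities must be >= 0")
  }
  if (efficiency <= 0 || efficiency > 1) {
    stop_validation("efficiency must be in (0, 1]")
  }
  if (interval_min <= 0 || duration_h <= 0) {
    stop_validation("duration and interval must be positive")
  }
  if (!is.null(seed)) set.seed(seed)
  t0 <- seq(0, duration_h * 60 - interval_min, by = interval_min)
  mu <- expected_counts(free_bq_g * mass_g, supported_bq_g * mass_g,
                        efficiency, t0, interval_min) +
    background_cpm * interval_min
  counts <- stats::rpois(length(mu), mu)
  structure(list(t_start_min = t0, interval_min = interval_min,
                 counts = counts, efficiency = efficiency, mass_g = mass_g),
            class = "well_counter")
}

# Expected counts in [t0, t0 + dt] (minutes) for amplitudes in Bq:
# eff * A0/lambda_s * (exp(-l t0) - exp(-l t1)) with lambda per second.
expected_counts <- function(free_bq, supported_bq, efficiency,
                            t_start_min, interval_min,
                            half_life_fast_h = BI213_HALF_LIFE_H,
                            half_life_slow_h = 240) {
  piece <- function(A0, t12_h) {
    if (A0 == 0) return(0 * t_start_min)
    l_s <- log(2) / (t12_h * 3600)
    t0 <- t_start_min * 60
    t1 <- (t_start_min + interval_min) * 60
    A0 / l_s * (exp(-l_s * t0) - exp(-l_s * t1))
  }
  efficiency * (piece(free_bq, half_life_fast_h) +
                piece(supported_bq, half_life_slow_h))
}

#' @export
print.well_counter <- function(x, ...) {
  cat(sprintf("Well-counter series: %d x %g-min intervals, %.3g g, eff %.2f\n",
              length(x$counts), x$interval_min, x$mass_g, x$efficiency))
  cat(sprintf("total counts: %d\n", sum(x$counts)))
  invisible(x)
}
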