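# Shared fixtures: published blood kinetic parameter sets and oracles.

# Blood phase tables (percent, half-life h) for the three protein doses of
# the In-111 surrogate and the Ac-225 conjugate.
blood_params <- list(
  in111_1mgkg = list(percent = c(93, 7), t12 = c(7, 32)),
  in111_3mgkg = list(percent = c(95, 5), t12 = c(14, 46)),
  in111_10mgkg = list(percent = c(100), t12 = c(21)),
  ac225_3mgkg = list(percent = c(63, 37), t12 = c(6, 19)))

blood_model <- function(params, c0 = 30, organ = "blood") {
  exp_model(c0 * params$percent / 100, log(2) / params$t12, organ)
}

study_schedule <- c(1, 6, 24, 72, 144)

noise_free_tac <- function(model, times = study_schedule) {
  tac(model$organ, times, predict(model, times))
}

# Independent quadrature oracle for TIA / AUC of c(t) * exp(-lambda t);
# integrates to 30 half-lives of the slowest effective rate.
quad_tia <- function(model, lambda_phys = 0) {
  f <- function(t) predict(model, t) * exp(-lambda_phys * t)
  upper <- 30 * log(2) / min(model$terms$rate_h + lambda_phys)
  stats::integrate(f, 0, upper, rel.tol = 1e-10,
                   subdivisions = 2000L)$value
}

# random stable (all-positive) 2-term models for property loops
random_stable_model <- function() {
  t12 <- sort(stats::runif(2, 1, 120))
  exp_model(stats::runif(2, 1, 40), log(2) / t12, "random")
}

new_tia_for_test <- function(value, organ = "kidneys") {
  alphadose:::new_tia(organ, value, "fit")
}
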