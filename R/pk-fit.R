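#' Sum-of-exponentials clearance model from known parameters
#'
#' Builds an `expfit` model directly from amplitudes and rates, e.g. from a
#' published table of blood kinetic parameters, bypassing fitting. The value
#' at t = 0 is the sum of the amplitudes.
#'
#' @param amplitude term amplitudes, %IA/g (same units as the data).
#' @param rate_h term clearance rates, 1/hour, all > 0 for cleared phases.
#' @param organ label carried through to results.
#' @return object of class `expfit`.
#' @examples
#' # blood, 63% with 6 h half-life + 37% with 19 h half-life, C0 = 30 %IA/g
#' m <- exp_model(30 * c(0.63, 0.37), log(2) / c(6, 19), organ = "blood")
#' auc(m)
#' @export
exp_model <- function(amplitude, rate_h, organ = "organ") {
  if (length(amplitude) != length(rate_h) || length(amplitude) == 0L) {
    stop_validation("amplitude and rate_h must be non-empty and equal length")
  }
  if (any(!is.finite(amplitude)) || any(!is.finite(rate_h))) {
    stop_validation("non-finite model parameters")
  }
  o <- order(rate_h, decreasing = TRUE)
  amplitude <- amplitude[o]; rate_h <- rate_h[o]
  terms <- data.frame(amplitude = amplitude, rate_h = rate_h,
                      half_life_h = log(2) / rate_h,
                      fraction = amplitude / sum(amplitude))
  structure(list(organ = organ, terms = terms, data = NULL,
                 rss = NA_real_, converged = NA, fallback = FALSE),
            class = "expfit")
}

exp_value <- function(amplitude, rate_h, time_h) {
  drop(exp(-outer(time_h, rate_h)) %*% amplitude)
}

# Curve-peeling start: log-linear tail from the last two points, subtract,
# log-linear fit of the positive remainder.
peel_start <- function(t, y, n_terms) {
  k <- length(t)
  span <- t[k] - t[1]
  lam2 <- if (y[k] > 0 && y[k - 1] > y[k]) {
    log(y[k - 1] / y[k]) / (t[k] - t[k - 1])
  } else {
    log(2) / (2 * span)
  }
  A2 <- y[k] * exp(lam2 * t[k])
  if (!is.finite(A2) || A2 <= 0) A2 <- max(y[k], 1e-6 * max(y))
  if (n_terms == 1L) {
    pos <- y > 0
    if (sum(pos) >= 2) {
      f <- stats::lm.fit(cbind(1, t[pos]), log(y[pos]))
      lam <- -f$coefficients[2]
      A <- exp(f$coefficients[1])
      if (is.finite(lam) && lam > 0 && is.finite(A) && A > 0) {
        return(list(A = A, lam = lam))
      }
    }
    return(list(A = A2, lam = max(lam2, log(2) / (10 * span))))
  }
  r <- y - A2 * exp(-lam2 * t)
  head_idx <- seq_len(max(2L, ceiling(k / 2)))
  pos <- head_idx[r[head_idx] > 0]
  lam1 <- 4 * lam2
  A1 <- max(y[1] - A2, 0.1 * y[1])
  if (length(pos) >= 2) {
    f <- stats::lm.fit(cbind(1, t[pos]), log(r[pos]))
    cand_lam <- -f$coefficients[2]
    cand_A <- exp(f$coefficients[1])
    if (is.finite(cand_lam) && cand_lam > lam2 && is.finite(cand_A) &&
        cand_A > 0) {
      lam1 <- cand_lam; A1 <- cand_A
    }
  }
  list(A = c(A1, A2), lam = c(lam1, lam2))
}

#' Fit a mono- or bi-exponential clearance model
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt) on a positive
#' sum-of-exponentials, with curve-peeling initialisation and a
#' deterministic multi-start over rate scalings so convergence does not
#' depend on a single starting point. With `n_terms = 2` and
#' `fallback = TRUE`, a degenerate two-phase fit (rate ratio < 1.2 or a
#' phase fraction < 1%) is automatically replaced by the single-phase fit,
#' mirroring the usual single-exponential fallback for blood curves that do
#' not support two phases.
#'
#' @param curve a [tac()].
#' @param n_terms 1 or 2 exponential terms.
#' @param weighting `"auto"` uses inverse-variance weights (1/SE^2) when the
#'   curve carries per-time SDs, `"inverse-variance"` requires them,
#'   `"none"` fits unweighted.
#' @param fallback drop to 1 term when the 2-term fit is degenerate.
#' @return object of class `expfit`: `terms` (amplitude, rate_h,
#'   half_life_h, fraction; fastest phase first), the input `data`, weighted
#'   `rss`, approximate standard errors of log-parameters (`se_log`), and a
#'   `fallback` flag.
#' @export
fit_clearance <- function(curve, n_terms = 2,
                          weighting = c("auto", "inverse-variance", "none"),
                          fallback = TRUE) {
  stopifnot(inherits(curve, "tac"))
  weighting <- match.arg(weighting)
  n_terms <- as.integer(n_terms)
  if (!n_terms %in% c(1L, 2L)) stop_validation("n_terms must be 1 or 2")
  t <- curve$time_h; y <- curve$conc
  k <- length(t)
  if (k < 2L * n_terms) {
    stop_validation("need at least ", 2L * n_terms, " time points for ",
                    n_terms, "-term fit (", curve$organ, "); got ", k)
  }
  # a positive sum of decaying exponentials is monotone decreasing; a curve
  # peaking after the first sample has an uptake phase this model cannot fit
  if (which.max(y) != 1L) {
    stop_numerical("concentration peaks after the first time point: ",
                   "uptake phase, clearance model not applicable (",
                   curve$organ, ")")
  }
  se <- rep(1, k)
  have_sd <- !is.null(curve$sd) && all(is.finite(curve$sd)) && all(curve$sd > 0)
  if (weighting == "inverse-variance" && !have_sd) {
    stop_validation("inverse-variance weighting requires positive SDs (",
                    curve$organ, ")")
  }
  if (weighting != "none" && have_sd) {
    nn <- if (is.null(curve$n)) rep(1L, k) else curve$n
    se <- curve$sd / sqrt(pmax(nn, 1L))
  }

  start <- peel_start(t, y, n_terms)
  scales <- if (n_terms == 1L) {
    lapply(c(1, 0.5, 2, 0.25, 4, 0.1, 10, 0.05, 20), function(s) s)
  } else {
    list(c(1, 1), c(0.5, 1), c(2, 1), c(1, 0.5), c(1, 2), c(2, 0.5),
         c(0.5, 2), c(4, 1), c(1, 4))
  }
  resid_fun <- function(p) {
    A <- exp(p[seq_len(n_terms)])
    lam <- exp(p[n_terms + seq_len(n_terms)])
    (y - exp_value(A, lam, t)) / se
  }
  best <- NULL
  for (s in scales) {
    p0 <- c(log(start$A), log(start$lam * s))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ok <- fit$info %in% 1:4
    if (is.null(best) || (ok && !best$ok) ||
        (ok == best$ok && fit$deviance < best$fit$deviance)) {
      best <- list(fit = fit, ok = ok)
    }
  }
  if (is.null(best)) {
    stop_numerical("all multi-start fits failed (", curve$organ, ")")
  }
  if (!best$ok) {
    stop_numerical("fit did not converge after multi-start (", curve$organ,
                   "): ", best$fit$message, data = best$fit)
  }
  p <- best$fit$par
  A <- exp(p[seq_len(n_terms)])
  lam <- exp(p[n_terms + seq_len(n_terms)])

  span <- t[k] - t[1]
  if (any(lam * span < 0.01)) {
    stop_numerical("rate at the zero boundary: curve is not clearing over ",
                   "the sampled span (", curve$organ, ")")
  }
  if (n_terms == 2L && fallback) {
    ratio <- max(lam) / min(lam)
    fr <- A / sum(A)
    if (ratio < 1.2 || any(fr < 0.01)) {
      out <- fit_clearance(curve, n_terms = 1L, weighting = weighting)
      out$fallback <- TRUE
      return(out)
    }
  }

  se_log <- tryCatch({
    h <- best$fit$hessian
    s2 <- best$fit$deviance / max(k - 2 * n_terms, 1L)
    sqrt(diag(solve(h)) * 2 * s2)
  }, error = function(e) rep(NA_real_, 2 * n_terms))

  o <- order(lam, decreasing = TRUE)
  m <- exp_model(A[o], lam[o], organ = curve$organ)
  m$data <- curve
  m$weights <- 1 / se^2
  m$rss <- best$fit$deviance
  m$se_log <- se_log
  m$converged <- TRUE
  m$fallback <- FALSE
  m
}

#' @export
print.expfit <- function(x, ...) {
  nt <- nrow(x$terms)
  cat(sprintf("%d-exponential clearance model: %s%s\n", nt, x$organ,
              if (isTRUE(x$fallback)) " (fallback to single phase)" else ""))
  tt <- x$terms
  tt$percent <- 100 * tt$fraction
  print(format(tt[c("amplitude", "half_life_h", "percent")], digits = 4),
        row.names = FALSE)
  if (is.finite(x$rss)) cat(sprintf("weighted RSS: %.4g\n", x$rss))
  invisible(x)
}

#' @export
coef.expfit <- function(object, ...) {
  with(object$terms,
       stats::setNames(c(amplitude, rate_h),
                       c(paste0("A", seq_along(amplitude)),
                         paste0("lambda", seq_along(rate_h)))))
}

#' @export
predict.expfit <- function(object, time_h = NULL, ...) {
  if (is.null(time_h)) {
    if (is.null(object$data)) stop_validation("no data; supply time_h")
    time_h <- object$data$time_h
  }
  exp_value(object$terms$amplitude, object$terms$rate_h, time_h)
}

#' @export
fitted.expfit <- function(object, ...) predict(object)

#' @export
residuals.expfit <- function(object, ...) {
  if (is.null(object$data)) stop_validation("model was not fitted to data")
  object$data$conc - predict(object)
}

#' @export
summary.expfit <- function(object, ...) {
  out <- list(organ = object$organ,
              phases = blood_pk_summary(object),
              auc = auc(object),
              rss = object$rss,
              fallback = object$fallback)
  class(out) <- "summary.expfit"
  out
}

#' @export
print.summary.expfit <- function(x, ...) {
  cat("Clearance summary:", x$organ, "\n")
  print(format(x$phases, digits = 3), row.names = FALSE)
  cat(sprintf("AUC (0-Inf): %.4g %%IA.h/g\n", x$auc))
  if (isTRUE(x$fallback)) cat("note: fell back to single-phase fit\n")
  invisible(x)
}

#' @export
plot.expfit <- function(x, ..., n_grid = 200) {
  if (is.null(x$data)) stop_validation("model was not fitted to data")
  t <- x$data$time_h
  grid <- seq(0, max(t), length.out = n_grid)
  graphics::plot(t, x$data$conc, log = "y", xlab = "time (h)",
                 ylab = "%IA/g", main = x$organ, pch = 19, ...)
  if (!is.null(x$data$sd)) {
    graphics::arrows(t, pmax(x$data$conc - x$data$sd, 1e-12),
                     t, x$data$conc + x$data$sd,
                     angle = 90, code = 3, length = 0.03)
  }
  graphics::lines(grid, predict(x, grid))
  invisible(x)
}

#' Simulate datasets from a fitted clearance model
#'
#' Parametric resampling: lognormal multiplicative noise with coefficient of
#' variation `cv` around the model mean at the fitted design times.
#'
#' @param object an `expfit` fitted to data.
#' @param nsim number of replicate curves.
#' @param seed RNG seed.
#' @param cv noise coefficient of variation.
#' @param n_per_time animals per time point.
#' @return list of [tac()] objects.
#' @export
simulate.expfit <- function(object, nsim = 1, seed = NULL, cv = 0.15,
                            n_per_time = 5, ...) {
  if (is.null(object$data)) stop_validation("model was not fitted to data")
  if (!is.null(seed)) set.seed(seed)
  mdl <- organ_model(object$organ, object$terms$amplitude,
                     object$terms$rate_h, noise_cv = cv)
  lapply(seq_len(nsim), function(i) {
    ds <- simulate_biodistribution(list(mdl), schedule = object$data$time_h,
                                   n_per_time = n_per_time)
    ds$curves[[1]]
  })
}

#' Blood pharmacokinetic summary of a clearance model
#'
#' Phase table in the conventional reporting form: percent of the t = 0
#' value clearing in each phase and the phase half-life, fastest phase
#' first. Percents sum to 100. A model with a negative amplitude (an uptake
#' phase) is not a clearance summary and is rejected.
#'
#' @param model an `expfit`.
#' @return data.frame with `percent` and `half_life_h`.
#' @examples
#' blood_pk_summary(exp_model(c(6.3, 3.7), log(2) / c(6, 19)))
#' @export
blood_pk_summary <- function(model) {
  stopifnot(inherits(model, "expfit"))
  if (any(model$terms$amplitude < 0)) {
    stop_validation("negative amplitude: uptake-phase model has no ",
                    "clearance-phase summary")
  }
  tt <- model$terms[order(model$terms$rate_h, decreasing = TRUE), ]
  data.frame(percent = 100 * tt$amplitude / sum(tt$amplitude),
             half_life_h = log(2) / tt$rate_h)
}

#' Area under the concentration-time curve, zero to infinity
#'
#' Closed form for a sum of decaying exponentials: `sum(A_i / rate_i)`.
#'
#' @param x an `expfit`.
#' @param ... unused.
#' @return AUC in %IA.h/g.
#' @export
auc <- function(x, ...) UseMethod("auc")

#' @export
auc.expfit <- function(x, ...) {
  if (any(x$terms$rate_h <= 0)) {
    stop_validation("non-positive rate: AUC diverges (", x$organ, ")")
  }
  sum(x$terms$amplitude / x$terms$rate_h)
}
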