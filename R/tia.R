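new_tia <- function(organ, tia, method, tail_fraction = NA_real_,
                    nuclide = "none", flag = "ok") {
  if (!is.finite(tia) || tia < 0) {
    stop_numerical("time-integrated activity is not finite and >= 0 (",
                   organ, ")")
  }
  structure(list(organ = organ, tia = tia, method = method,
                 tail_fraction = tail_fraction, nuclide = nuclide,
                 flag = flag),
            class = "tia")
}

#' @export
print.tia <- function(x, ...) {
  cat(sprintf("TIA [%s]: %.4g %%IA.h/g (method %s, tail %.1f%%, nuclide %s%s)\n",
              x$organ, x$tia, x$method,
              100 * x$tail_fraction, x$nuclide,
              if (x$flag != "ok") paste0(", flag: ", x$flag) else ""))
  invisible(x)
}

#' @export
as.data.frame.tia <- function(x, ...) {
  data.frame(organ = x$organ, tia_pia_h_g = x$tia, method = x$method,
             tail_fraction = x$tail_fraction, nuclide = x$nuclide,
             flag = x$flag)
}

#' Time-integrated activity from a fitted clearance model
#'
#' Closed-form integral of the model from zero to infinity, optionally
#' under additional physical decay `lambda_phys`:
#' `sum(A_i / (rate_i + lambda_phys))`. The `tail_fraction` is the share of
#' the integral beyond the last observation time.
#'
#' @param model an `expfit` with all rates > 0 (or rates + `lambda_phys` > 0).
#' @param lambda_phys physical decay constant, 1/hour (0 = biological TIA).
#' @param last_time end of the measured period, hours; defaults to the last
#'   fitted data time when the model carries data.
#' @param nuclide label recorded on the result.
#' @return a `tia` object (%IA.h/g), method `"fit"`.
#' @export
tia_fit <- function(model, lambda_phys = 0, last_time = NULL,
                    nuclide = "none") {
  stopifnot(inherits(model, "expfit"))
  if (lambda_phys < 0) stop_validation("lambda_phys must be >= 0")
  r <- model$terms$rate_h + lambda_phys
  if (any(r <= 0)) {
    stop_validation("divergent model: rate + lambda_phys must be > 0 (",
                    model$organ, ")")
  }
  A <- model$terms$amplitude
  total <- sum(A / r)
  if (is.null(last_time) && !is.null(model$data)) {
    last_time <- max(model$data$time_h)
  }
  tail_fraction <- if (is.null(last_time)) NA_real_ else {
    sum(A * exp(-r * last_time) / r) / total
  }
  new_tia(model$organ, total, "fit", tail_fraction, nuclide)
}

#' Hybrid time-integrated activity: trapezoid plus exponential tail
#'
#' For curves that resist model fitting: numerical (trapezoid) integration
#' over the measured period plus an analytically integrated exponential tail
#' whose rate is the log-linear slope of the last two time points. The
#' leading edge (t = 0 to the first sample) is back-extrapolated at the
#' first-segment log-linear slope, floored at the first measured value, so
#' early blood activity is neither discarded nor turned into an invented
#' peak. A non-decreasing tail has no defined log-linear clearance rate; the
#' biological tail is then held constant and only physical decay
#' (`lambda_phys > 0`) terminates the integral — the result is flagged
#' `"constant_tail"` and upper-bounds the true integral.
#'
#' @param curve a [tac()] of decay-corrected concentrations.
#' @param lambda_phys physical decay constant, 1/hour, applied as
#'   `c(t) * exp(-lambda_phys t)` across the whole integral.
#' @param log_trapezoid use log-linear (geometric) interpolation between
#'   samples instead of the linear trapezoid.
#' @param nuclide label recorded on the result.
#' @return a `tia` object, method `"hybrid"`; `tail_fraction` is the share
#'   contributed by the extrapolated tail.
#' @export
tia_hybrid <- function(curve, lambda_phys = 0, log_trapezoid = FALSE,
                       nuclide = "none") {
  stopifnot(inherits(curve, "tac"))
  if (lambda_phys < 0) stop_validation("lambda_phys must be >= 0")
  t <- curve$time_h; y <- curve$conc
  k <- length(t)
  if (k < 2L) stop_validation("hybrid TIA needs >= 2 time points (",
                              curve$organ, ")")
  ye <- y * exp(-lambda_phys * t)

  # measured span
  measured <- if (log_trapezoid) {
    sum(vapply(seq_len(k - 1L), function(i) {
      dt <- t[i + 1L] - t[i]
      a <- ye[i]; b <- ye[i + 1L]
      if (a > 0 && b > 0 && abs(log(a / b)) > 1e-12) {
        dt * (a - b) / log(a / b)
      } else dt * (a + b) / 2
    }, 0))
  } else {
    sum(diff(t) * (ye[-k] + ye[-1L]) / 2)
  }

  # leading edge 0..t[1]: back-extrapolate at the first-segment clearance
  # rate when the curve starts by clearing; otherwise hold at y[1].
  lam_lead <- if (y[1] > 0 && y[2] > 0) log(y[1] / y[2]) / (t[2] - t[1]) else 0
  leading <- if (lam_lead > 0) {
    r <- lam_lead + lambda_phys
    y[1] * exp(lam_lead * t[1]) * (1 - exp(-r * t[1])) / r
  } else if (lambda_phys > 0) {
    y[1] * (1 - exp(-lambda_phys * t[1])) / lambda_phys
  } else {
    y[1] * t[1]
  }

  # tail beyond t[k]
  flag <- "ok"
  if (y[k] <= 0) {
    tail_area <- 0
    flag <- "zero_tail"
  } else {
    lam_tail <- if (y[k - 1L] > 0) log(y[k - 1L] / y[k]) / (t[k] - t[k - 1L]) else -1
    if (lam_tail <= 0) {
      if (lambda_phys <= 0) {
        stop_numerical("non-decreasing tail with no physical decay: ",
                       "integral diverges (", curve$organ, ")")
      }
      lam_tail <- 0
      flag <- "constant_tail"
    }
    tail_area <- ye[k] / (lam_tail + lambda_phys)
  }

  total <- measured + leading + tail_area
  new_tia(curve$organ, total, "hybrid", tail_area / total, nuclide, flag)
}

#' Time-integrated activity under substituted physical decay
#'
#' Recomputes TIA for a candidate radionuclide by imposing its physical
#' decay on the biological (decay-corrected) kinetics: the integrand becomes
#' `c(t) exp(-lambda_phys t)`. For a fitted model this is the closed form
#' `sum(A_i / (rate_i + lambda_phys))`; for a raw curve the hybrid rule is
#' applied. TIA is monotonically non-increasing in `lambda_phys`, so
#' shorter-lived nuclides never gain TIA.
#'
#' @param x an `expfit` or a [tac()].
#' @param nuclide a [radionuclide()] (e.g. `radionuclide("Ac-225")`).
#' @param ... passed to [tia_fit()] or [tia_hybrid()].
#' @return a `tia` object labelled with the nuclide.
#' @export
substitute_radionuclide <- function(x, nuclide, ...) {
  UseMethod("substitute_radionuclide")
}

#' @export
substitute_radionuclide.expfit <- function(x, nuclide, ...) {
  stopifnot(inherits(nuclide, "radionuclide"))
  tia_fit(x, lambda_phys = nuclide$lambda_h, nuclide = nuclide$label, ...)
}

#' @export
substitute_radionuclide.tac <- function(x, nuclide, ...) {
  stopifnot(inherits(nuclide, "radionuclide"))
  tia_hybrid(x, lambda_phys = nuclide$lambda_h, nuclide = nuclide$label, ...)
}

#' Per-organ TIA with automatic route selection
#'
#' The primary route fits a clearance model ([fit_clearance()]) and
#' integrates it in closed form; when the data cannot be fitted — uptake
#' organs, non-clearing tails, degenerate fits — the hybrid
#' trapezoid-plus-tail rule takes over. The route actually used is recorded
#' in the result's `method` field so every report states, per organ, how
#' its integral was obtained.
#'
#' @param curve a [tac()].
#' @param nuclide optional [radionuclide()] whose physical decay is imposed
#'   on the biological kinetics.
#' @param method `"auto"` (fit, falling back to hybrid), `"fit"` (closed
#'   form only; numerical failures propagate) or `"hybrid"`.
#' @param n_terms exponential terms for the fit route.
#' @return a `tia` object.
#' @export
organ_tia <- function(curve, nuclide = NULL,
                      method = c("auto", "fit", "hybrid"), n_terms = 2) {
  method <- match.arg(method)
  lambda <- if (is.null(nuclide)) 0 else nuclide$lambda_h
  label <- if (is.null(nuclide)) "none" else nuclide$label
  fit_route <- function() {
    tia_fit(fit_clearance(curve, n_terms = n_terms), lambda_phys = lambda,
            last_time = max(curve$time_h), nuclide = label)
  }
  hybrid_route <- function() {
    tia_hybrid(curve, lambda_phys = lambda, nuclide = label)
  }
  switch(method,
         fit = fit_route(),
         hybrid = hybrid_route(),
         auto = tryCatch(fit_route(),
                         alphadose_numerical_error = function(e) {
                           hybrid_route()
                         }))
}

#' Table of TIA ratios relative to a reference tissue
#'
#' Dimensionless tumor-to-organ (or any numerator-to-denominator) TIA
#' ratios, computed within each group of extra columns (e.g. nuclide,
#' protein dose).
#'
#' @param results a data.frame with columns `organ` and `tia_pia_h_g`
#'   (optionally `nuclide` and other grouping columns), or a list of `tia`
#'   objects.
#' @param numerator organ used as the ratio numerator.
#' @param denominators organs used as denominators.
#' @return data.frame with grouping columns, `denominator` and `ratio`.
#' @export
tia_ratio_table <- function(results, numerator, denominators) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- do.call(rbind, lapply(results, as.data.frame))
  }
  if (!all(c("organ", "tia_pia_h_g") %in% names(results))) {
    stop_validation("results must have columns organ and tia_pia_h_g")
  }
  group_cols <- setdiff(names(results),
                        c("organ", "tia_pia_h_g", "method",
                          "tail_fraction", "flag"))
  key <- if (length(group_cols)) {
    interaction(results[group_cols], drop = TRUE)
  } else factor(rep("all", nrow(results)))
  out <- do.call(rbind, lapply(split(results, key), function(g) {
    num <- g$tia_pia_h_g[g$organ == numerator]
    if (length(num) != 1L) {
      stop_validation("numerator organ '", numerator,
                      "' not found exactly once in a group")
    }
    do.call(rbind, lapply(denominators, function(d) {
      den <- g$tia_pia_h_g[g$organ == d]
      if (length(den) != 1L) {
        stop_validation("denominator organ '", d, "' not found exactly once")
      }
      if (den == 0) stop_validation("zero TIA for denominator organ '", d, "'")
      cbind(g[1L, group_cols, drop = FALSE],
            data.frame(numerator = numerator, denominator = d,
                       ratio = num / den))
    }))
  }))
  rownames(out) <- NULL
  out
}
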