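#' Time-activity curve
#'
#' One tissue's sampled activity concentration over time: the atomic input of
#' the pipeline. Concentrations are percent injected activity per gram
#' (%IA/g) and are taken as decay-corrected (biological) values; physical
#' decay is applied explicitly and exactly once, in
#' [substitute_radionuclide()] or the constant-tail fallback of
#' [tia_hybrid()].
#'
#' @param organ tissue label.
#' @param time_h sampling times in hours, strictly increasing.
#' @param conc mean activity concentration, %IA/g, non-negative.
#' @param sd per-time standard deviation of `conc` (optional).
#' @param n per-time animal count (optional).
#' @param mass_g organ mass in grams (optional; carried for reporting).
#' @return object of class `tac`.
#' @export
tac <- function(organ, time_h, conc, sd = NULL, n = NULL, mass_g = NA_real_) {
  time_h <- as.numeric(time_h)
  conc <- as.numeric(conc)
  if (length(time_h) != length(conc)) {
    stop_validation("time_h and conc must have the same length")
  }
  if (length(time_h) == 0L) stop_validation("empty time-activity curve")
  if (any(!is.finite(time_h)) || any(diff(time_h) <= 0)) {
    stop_validation("times must be finite and strictly increasing (", organ, ")")
  }
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop_validation("concentrations must be finite and >= 0 (", organ, ")")
  }
  for (nm in c("sd", "n")) {
    v <- get(nm)
    if (!is.null(v) && length(v) != length(time_h)) {
      stop_validation(nm, " must match the number of time points (", organ, ")")
    }
  }
  structure(
    list(organ = organ, time_h = time_h, conc = conc,
         sd = if (is.null(sd)) NULL else as.numeric(sd),
         n = if (is.null(n)) NULL else as.integer(n),
         mass_g = mass_g),
    class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat("Time-activity curve:", x$organ, "\n")
  df <- data.frame(time_h = x$time_h, conc_pia_g = x$conc)
  if (!is.null(x$sd)) df$sd <- x$sd
  if (!is.null(x$n)) df$n <- x$n
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.tac <- function(x, ...) {
  data.frame(organ = x$organ, time_h = x$time_h,
             mean_pia_g = x$conc,
             sd_pia_g = if (is.null(x$sd)) NA_real_ else x$sd,
             n = if (is.null(x$n)) NA_integer_ else x$n)
}

#' Terminal clearance half-time from the last two time points
#'
#' The log-linear half-time of the final observed segment:
#' `ln2 * (t_k - t_{k-1}) / ln(c_{k-1} / c_k)`. When the curve is not
#' clearing over the last segment (flat or rising tail) no half-time exists
#' and the result is flagged instead.
#'
#' @param curve a [tac()].
#' @return list with `half_life_h` (NA when non-clearing) and logical
#'   `non_clearing`.
#' @examples
#' terminal_half_life(tac("blood", c(72, 144), c(10, 5)))  # 72 h
#' @export
terminal_half_life <- function(curve) {
  stopifnot(inherits(curve, "tac"))
  k <- length(curve$time_h)
  if (k < 2L) stop_validation("need at least two time points (", curve$organ, ")")
  c1 <- curve$conc[k - 1L]; c2 <- curve$conc[k]
  if (c2 <= 0 || c1 <= 0) {
    stop_validation("terminal concentrations must be positive (", curve$organ, ")")
  }
  if (c2 >= c1) {
    return(list(half_life_h = NA_real_, non_clearing = TRUE))
  }
  dt <- curve$time_h[k] - curve$time_h[k - 1L]
  list(half_life_h = log(2) * dt / log(c1 / c2), non_clearing = FALSE)
}
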