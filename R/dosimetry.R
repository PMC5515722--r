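# Unit conversion, derived symbolically once and verified by a
# dimensional-analysis test: dose coefficient [mGy/kBq] =
#   TIA [%IA.h/g]  x (1/100)      [fraction per %]
#                  x 1000         [Bq administered per kBq]
#                  x 3600         [s per h]        -> Bq.s/g per kBq
#                  x Delta        [J/(Bq.s)]       -> J/g per kBq
#                  x 1000         [g per kg]       -> Gy per kBq
#                  x 1000         [mGy per Gy]
PCT_TIA_TO_MGY_PER_KBQ <- (1 / 100) * 1000 * 3600 * 1000 * 1000
# same, for TIA already in Bq.h/g per kBq administered
BQ_TIA_TO_MGY_PER_KBQ <- 3600 * 1000 * 1000

new_dose_coeff <- function(organ, coefficient, nuclide = NA_character_,
                           components = NULL) {
  if (!is.finite(coefficient) || coefficient < 0) {
    stop_validation("dose coefficient must be finite and >= 0 (", organ, ")")
  }
  if (!is.null(components) &&
      abs(sum(components) - coefficient) > 1e-8 * max(coefficient, 1)) {
    stop_validation("components must sum to the total coefficient (",
                    organ, ")")
  }
  structure(list(organ = organ, coefficient = coefficient,
                 nuclide = nuclide, components = components),
            class = "dose_coeff")
}

#' @export
print.dose_coeff <- function(x, ...) {
  cat(sprintf("%s: %s mGy/kBq", x$organ, signif(x$coefficient, 3)))
  if (!is.null(x$components)) {
    cat(" (", paste(sprintf("%s %s", names(x$components),
                            signif(x$components, 3)), collapse = " + "), ")")
  }
  cat("\n")
  invisible(x)
}

#' Absorbed-dose coefficient from time-integrated activity
#'
#' Mean absorbed dose per unit administered activity via the mean
#' absorbed-dose equation `D = A_tilde * Delta * phi / m`, specialised to
#' activity concentration (per-gram TIA), alpha emissions only, and full
#' local energy deposition (`phi = 1` by default). The result is linear in
#' TIA, Delta and phi.
#'
#' @param tia a `tia` object or a bare TIA value.
#' @param nuclide a [radionuclide()] supplying the alpha Delta of its chain.
#' @param phi absorbed fraction, in (0, 1].
#' @param tia_units `"pct_ia_h_per_g"` (%IA.h/g, the biodistribution
#'   convention) or `"bq_h_per_g_per_kbq"` (used for the free-Bi-213 series).
#' @param organ label when `tia` is a bare number.
#' @return a `dose_coeff` in mGy per kBq administered.
#' @examples
#' nuc <- radionuclide("Ac-225")
#' dose_coefficient(4660, nuc, organ = "liver")  # ~738 mGy/kBq
#' @export
dose_coefficient <- function(tia, nuclide, phi = 1,
                             tia_units = c("pct_ia_h_per_g",
                                           "bq_h_per_g_per_kbq"),
                             organ = NULL) {
  tia_units <- match.arg(tia_units)
  stopifnot(inherits(nuclide, "radionuclide"))
  if (phi <= 0 || phi > 1) stop_validation("phi must be in (0, 1]")
  if (inherits(tia, "tia")) {
    organ <- tia$organ
    tia <- tia$tia
  }
  if (is.null(organ)) organ <- "organ"
  if (!is.finite(tia) || tia < 0) stop_validation("TIA must be >= 0")
  f <- if (tia_units == "pct_ia_h_per_g") PCT_TIA_TO_MGY_PER_KBQ else
    BQ_TIA_TO_MGY_PER_KBQ
  new_dose_coeff(organ, tia * f * nuclide$delta_alpha * phi,
                 nuclide = nuclide$label)
}

# Exact 2-variable non-negative least squares: unconstrained solve, then
# clamp-and-refit on the active set.
nnls2 <- function(X, y) {
  xtx <- crossprod(X); xty <- crossprod(X, y)
  b <- tryCatch(drop(solve(xtx, xty)), error = function(e) c(0, 0))
  if (all(b >= 0)) return(b)
  b1 <- max(sum(X[, 1] * y) / sum(X[, 1]^2), 0)
  b2 <- max(sum(X[, 2] * y) / sum(X[, 2]^2), 0)
  r1 <- sum((y - X[, 1] * b1)^2)
  r2 <- sum((y - X[, 2] * b2)^2)
  if (r1 <= r2) c(b1, 0) else c(0, b2)
}

#' Strip a kidney well-counter series into free Bi-213 and parent activity
#'
#' Curve stripping with known decay constants: expected counts per interval
#' are the interval-integrated sum of a fast component (free Bi-213,
#' 45.6 min half-life) and a slow component (parent-bound Ac-225, 10 d
#' half-life); the two t = 0 amplitudes are estimated by non-negative least
#' squares. The free Bi-213 activity concentration is the fast-component
#' time-zero intercept divided by efficiency and mass.
#'
#' @param series a `well_counter` object (or list with `t_start_min`,
#'   `interval_min`, `counts`).
#' @param efficiency counts per decay; defaults to the value carried by the
#'   series.
#' @param mass_g sample mass in grams; defaults likewise.
#' @param half_life_fast_h fast-component half-life, hours.
#' @param half_life_slow_h slow-component half-life, hours.
#' @return object of class `kidney_decomp`: `free_bi_conc` and
#'   `supported_conc` (Bq/g at the time of counting), `fit_rss`, `flag`.
#' @export
decompose_kidney_counts <- function(series,
                                    efficiency = series$efficiency,
                                    mass_g = series$mass_g,
                                    half_life_fast_h = BI213_HALF_LIFE_H,
                                    half_life_slow_h = 240) {
  t0 <- series$t_start_min
  dt <- series$interval_min
  counts <- series$counts
  if (is.null(t0) || is.null(counts) || length(t0) != length(counts)) {
    stop_validation("series must carry matching t_start_min and counts")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_validation("counts must be non-negative integers")
  }
  if (is.null(efficiency) || efficiency <= 0 || efficiency > 1) {
    stop_validation("efficiency must be in (0, 1]")
  }
  if (is.null(mass_g) || mass_g <= 0) stop_validation("mass_g must be > 0")
  span_min <- max(t0) + dt - min(t0)
  if (span_min < half_life_fast_h * 60) {
    stop_numerical("series shorter than one fast half-life: components ",
                   "are not identifiable")
  }
  if (all(counts == 0)) {
    return(structure(list(free_bi_conc = 0, supported_conc = 0,
                          fit_rss = 0, flag = "all_zero"),
                     class = "kidney_decomp"))
  }
  X <- cbind(
    fast = expected_counts(1, 0, efficiency, t0, dt,
                           half_life_fast_h, half_life_slow_h),
    slow = expected_counts(0, 1, efficiency, t0, dt,
                           half_life_fast_h, half_life_slow_h))
  b <- unname(nnls2(X, counts))
  structure(list(free_bi_conc = b[1] / mass_g,
                 supported_conc = b[2] / mass_g,
                 fit_rss = sum((counts - drop(X %*% b))^2),
                 flag = "ok"),
            class = "kidney_decomp")
}

#' @export
print.kidney_decomp <- function(x, ...) {
  cat(sprintf("Kidney decomposition: free Bi-213 %.4g Bq/g, parent %.4g Bq/g",
              x$free_bi_conc, x$supported_conc))
  if (x$flag != "ok") cat(" [", x$flag, "]")
  cat("\n")
  invisible(x)
}

#' Kidney dose coefficient including the free Bi-213 contribution
#'
#' Free Bi-213 released by the Ac-225 chain concentrates in the kidneys, so
#' the kidney absorbed dose is the parent-chain coefficient (full-chain
#' Delta) plus a free-Bi-213 coefficient computed from the time course of
#' free Bi-213 activity concentration (hybrid TIA rule) with the Bi-213
#' sub-chain Delta. Both components are recorded and sum exactly to the
#' total.
#'
#' @param kidney_tia kidney `tia` (%IA.h/g) for the parent-bound antibody.
#' @param free_bi_curve [tac()] of free Bi-213 activity concentration, Bq/g
#'   per kBq administered, at the sacrifice times.
#' @param ac parent [radionuclide()] (default Ac-225).
#' @param bi daughter [radionuclide()] (default Bi-213 sub-chain).
#' @param phi absorbed fraction.
#' @return a `dose_coeff` with components `parent` and `free_bi`.
#' @export
kidney_dose_with_free_bi <- function(kidney_tia, free_bi_curve,
                                     ac = radionuclide("Ac-225"),
                                     bi = radionuclide("Bi-213"),
                                     phi = 1) {
  parent <- dose_coefficient(kidney_tia, ac, phi)
  free_tia <- tryCatch(
    tia_hybrid(free_bi_curve, lambda_phys = 0),
    alphadose_numerical_error = function(e) {
      # non-decreasing free-Bi tail: terminate with Bi-213 physical decay
      tia_hybrid(free_bi_curve, lambda_phys = bi$lambda_h)
    })
  free <- dose_coefficient(free_tia, bi, phi,
                           tia_units = "bq_h_per_g_per_kbq")
  new_dose_coeff(parent$organ, parent$coefficient + free$coefficient,
                 nuclide = ac$label,
                 components = c(parent = parent$coefficient,
                                free_bi = free$coefficient))
}

#' Red-marrow dose coefficient from the blood coefficient
#'
#' For intact antibody, under rapid equilibration and volume-of-distribution
#' assumptions, the red-marrow absorbed dose is taken as a fixed fraction
#' (default 36%) of the blood absorbed dose.
#'
#' @param blood_coeff blood `dose_coeff` (or bare mGy/kBq value).
#' @param factor marrow-to-blood dose ratio, in (0, 1].
#' @return a `dose_coeff` for `"red marrow"`.
#' @examples
#' marrow_from_blood(80.4)  # ~29 mGy/kBq
#' @export
marrow_from_blood <- function(blood_coeff, factor = 0.36) {
  if (factor <= 0 || factor > 1) stop_validation("factor must be in (0, 1]")
  v <- if (inherits(blood_coeff, "dose_coeff")) blood_coeff$coefficient
       else blood_coeff
  new_dose_coeff("red marrow", v * factor,
                 nuclide = if (inherits(blood_coeff, "dose_coeff"))
                   blood_coeff$nuclide else NA_character_)
}

#' Prescribe administered activity under organ dose limits
#'
#' The administrable activity is the largest activity keeping every limited
#' organ at or below its absorbed-dose limit:
#' `min over organs of limit / coefficient`. All organ doses at that
#' activity are reported, including unlimited organs (tumor, marrow).
#'
#' @param coeffs list of `dose_coeff` objects, or a named numeric vector of
#'   coefficients in mGy/kBq.
#' @param limits named numeric vector of organ dose limits in Gy.
#' @return object of class `prescription`: `limiting_organ`, `limit_gy`,
#'   `activity_kbq` (unrounded; the print method reports 2 significant
#'   figures), and `organ_doses_gy` for every organ with a coefficient.
#' @examples
#' pres <- prescribe_activity(c(liver = 738, tumor = 141), c(liver = 28))
#' print(pres)
#' @export
prescribe_activity <- function(coeffs, limits) {
  if (length(limits) == 0L || is.null(names(limits))) {
    stop_validation("limits must be a non-empty named vector of Gy")
  }
  if (is.list(coeffs)) {
    cv <- vapply(coeffs, function(x) x$coefficient, 0)
    names(cv) <- vapply(coeffs, function(x) x$organ, "")
  } else cv <- coeffs
  missing <- setdiff(names(limits), names(cv))
  if (length(missing)) {
    stop_validation("no dose coefficient for limited organ(s): ",
                    paste(missing, collapse = ", "))
  }
  lim_coeff <- cv[names(limits)]
  if (any(lim_coeff <= 0)) {
    stop_validation("limited organs must have positive coefficients")
  }
  act <- limits * 1000 / lim_coeff   # Gy -> mGy, per (mGy/kBq) -> kBq
  i <- which.min(act)
  structure(list(limiting_organ = names(limits)[i],
                 limit_gy = unname(limits[i]),
                 activity_kbq = unname(act[i]),
                 organ_doses_gy = cv * unname(act[i]) / 1000,
                 limits_gy = limits),
            class = "prescription")
}

#' @export
print.prescription <- function(x, ...) {
  cat(sprintf("Prescribed activity: %s kBq (limiting organ: %s at %g Gy)\n",
              signif(x$activity_kbq, 2), x$limiting_organ, x$limit_gy))
  d <- x$organ_doses_gy
  cat("organ doses at prescription (Gy):\n")
  print(stats::setNames(signif(d, 2), names(d)))
  invisible(x)
}
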