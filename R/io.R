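#' Write a biodistribution dataset to CSV
#'
#' Long format, one row per organ and time:
#' `organ,time_h,mean_pia_g,sd_pia_g,n`. Values are written with full
#' (15-digit) precision so read/write round trips are lossless.
#'
#' @param dataset a `biodist` (or list with `curves`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_biodistribution <- function(dataset, path) {
  df <- do.call(rbind, lapply(dataset$curves, as.data.frame))
  write_csv15(df, path)
}

#' Read a biodistribution dataset from CSV
#'
#' Expects the schema written by [write_biodistribution()]. Rows are
#' validated: concentrations must be non-negative and (organ, time) pairs
#' unique; offending row numbers are named in errors.
#'
#' @param path CSV file with columns `organ,time_h,mean_pia_g,sd_pia_g,n`.
#' @return a `biodist` object.
#' @export
read_biodistribution <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("organ", "time_h", "mean_pia_g", "sd_pia_g", "n")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_validation("missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(!is.finite(df$mean_pia_g) | df$mean_pia_g < 0)
  if (length(bad)) {
    stop_validation("negative or non-finite concentration at row(s) ",
                    paste(bad, collapse = ", "))
  }
  dup <- which(duplicated(df[c("organ", "time_h")]))
  if (length(dup)) {
    stop_validation("duplicate (organ, time) at row(s) ",
                    paste(dup, collapse = ", "))
  }
  curves <- lapply(split(df, factor(df$organ, levels = unique(df$organ))),
                   function(g) {
    g <- g[order(g$time_h), ]
    tac(g$organ[1], g$time_h, g$mean_pia_g,
        sd = if (all(is.na(g$sd_pia_g))) NULL else g$sd_pia_g,
        n = if (all(is.na(g$n))) NULL else g$n)
  })
  structure(list(curves = curves,
                 schedule = sort(unique(df$time_h)),
                 n_per_time = if (all(is.na(df$n))) NA_integer_
                              else max(df$n, na.rm = TRUE),
                 seed = NULL),
            class = "biodist")
}

#' Write / read a well-counter series
#'
#' CSV columns `t_start_min,interval_min,counts`; efficiency and mass ride
#' along as commented header metadata so a file is self-describing.
#'
#' @param series a `well_counter`.
#' @param path file path.
#' @return `path` (write) or a `well_counter` (read).
#' @export
write_well_counter <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# efficiency=%.15g mass_g=%.15g",
                     series$efficiency, series$mass_g), con)
  utils::write.csv(data.frame(t_start_min = series$t_start_min,
                              interval_min = series$interval_min,
                              counts = series$counts),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_well_counter
#' @export
read_well_counter <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  header <- readLines(path, n = 1L)
  eff <- mass <- NULL
  if (startsWith(header, "#")) {
    m <- regmatches(header, regexec("efficiency=([0-9.eE+-]+) mass_g=([0-9.eE+-]+)",
                                    header))[[1]]
    if (length(m) == 3L) {
      eff <- as.numeric(m[2]); mass <- as.numeric(m[3])
    }
  }
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("t_start_min", "interval_min", "counts")
  if (!all(need %in% names(df))) {
    stop_validation("well-counter CSV must have columns ",
                    paste(need, collapse = ", "))
  }
  if (any(df$counts < 0) || any(df$counts != round(df$counts))) {
    stop_validation("counts must be non-negative integers")
  }
  structure(list(t_start_min = df$t_start_min,
                 interval_min = df$interval_min[1],
                 counts = as.integer(df$counts),
                 efficiency = eff, mass_g = mass),
            class = "well_counter")
}

# full-precision CSV writer shared by the tabular outputs
write_csv15 <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA, sprintf("%.15g", x))
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write the dose report: coefficient table plus prescription
#'
#' Emits a CSV of dose coefficients (with component breakdown columns for
#' organs that carry one, e.g. the kidney free-Bi-213 share) and, when a
#' prescription is given, a JSON file with the limiting organ, administered
#' activity and per-organ doses. Output is deterministic for fixed input.
#'
#' @param coeffs list of `dose_coeff` objects.
#' @param path output CSV path.
#' @param prescription optional `prescription`; written to
#'   `sub("\\\\.csv$", ".json", path)` unless `json_path` is given.
#' @param json_path optional explicit JSON path.
#' @return `path`, invisibly.
#' @export
write_dose_report <- function(coeffs, path, prescription = NULL,
                              json_path = NULL) {
  rows <- lapply(coeffs, function(x) {
    data.frame(organ = x$organ,
               dose_mgy_per_kbq = x$coefficient,
               nuclide = if (is.na(x$nuclide)) "" else x$nuclide,
               component_parent = if (is.null(x$components)) NA_real_
                                  else x$components[["parent"]],
               component_free_bi = if (is.null(x$components)) NA_real_
                                   else x$components[["free_bi"]])
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(organ = character(), dose_mgy_per_kbq = numeric(),
               nuclide = character(), component_parent = numeric(),
               component_free_bi = numeric())
  write_csv15(df, path)
  if (!is.null(prescription)) {
    if (is.null(json_path)) json_path <- sub("\\.csv$", ".json", path)
    jsonlite::write_json(
      list(limiting_organ = prescription$limiting_organ,
           limit_gy = prescription$limit_gy,
           activity_kbq = prescription$activity_kbq,
           activity_kbq_2sf = signif(prescription$activity_kbq, 2),
           organ_doses_gy = as.list(prescription$organ_doses_gy)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a dose-coefficient CSV back into `dose_coeff` objects
#'
#' @param path CSV written by [write_dose_report()].
#' @return list of `dose_coeff`.
#' @export
read_dose_report <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("organ", "dose_mgy_per_kbq") %in% names(df))) {
    stop_validation("dose CSV must have columns organ, dose_mgy_per_kbq")
  }
  lapply(seq_len(nrow(df)), function(i) {
    comp <- NULL
    if (!is.null(df$component_parent) && !is.na(df$component_parent[i])) {
      comp <- c(parent = df$component_parent[i],
                free_bi = df$component_free_bi[i])
    }
    new_dose_coeff(df$organ[i], df$dose_mgy_per_kbq[i],
                   nuclide = if (is.null(df$nuclide)) NA_character_
                             else df$nuclide[i],
                   components = comp)
  })
}

#' Read and validate a run configuration (YAML)
#'
#' Recognised keys: `seed`, `noise_cv`, `schedule`, `n_per_time`,
#' `nuclide`, `method`, `limits_gy` (map organ to Gy). Unknown keys are
#' rejected so typos fail loudly.
#'
#' @param path YAML file.
#' @return validated named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_validation("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  allowed <- c("seed", "noise_cv", "schedule", "n_per_time", "nuclide",
               "method", "limits_gy")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop_validation("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(cfg$noise_cv) && cfg$noise_cv < 0) {
    stop_validation("noise_cv must be >= 0")
  }
  if (!is.null(cfg$schedule) && any(diff(as.numeric(cfg$schedule)) <= 0)) {
    stop_validation("schedule must be strictly increasing")
  }
  if (!is.null(cfg$nuclide) &&
      !cfg$nuclide %in% c("Ac-225", "Pb-212", "At-211", "Bi-213", "none")) {
    stop_validation("unknown nuclide: ", cfg$nuclide)
  }
  if (!is.null(cfg$limits_gy) &&
      (is.null(names(cfg$limits_gy)) || any(unlist(cfg$limits_gy) <= 0))) {
    stop_validation("limits_gy must map organ names to positive Gy")
  }
  cfg
}
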