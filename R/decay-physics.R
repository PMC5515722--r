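#' @keywords internal
"_PACKAGE"

# 1 MeV in joule (CODATA); energies are carried in MeV internally and
# converted exactly once, here.
MEV_TO_J <- 1.602176634e-13

# Bi-213 physical half-life, hours (45.61 min); used wherever free Bi-213
# kinetics enter (well-counter stripping, kidney dose).
BI213_HALF_LIFE_H <- 45.61 / 60

#' Decay constant from half-life
#'
#' @param half_life_h physical half-life in hours.
#' @return decay constant in 1/hour (`ln 2 / half_life_h`).
#' @examples
#' decay_constant(240)   # Ac-225, 10 d
#' decay_constant(7.2)   # At-211
#' @export
decay_constant <- function(half_life_h) {
  if (!is.numeric(half_life_h) || any(!is.finite(half_life_h)) ||
      any(half_life_h <= 0)) {
    stop_validation("half_life_h must be a positive finite number")
  }
  log(2) / half_life_h
}

#' Load the embedded alpha decay-chain table
#'
#' Returns the packaged table of chain members with intensity-weighted mean
#' alpha energies (MeV), alpha yields per parent decay, and member
#' half-lives. An alternative table with the same columns can be supplied to
#' audit or update the decay data.
#'
#' @param path optional path to a replacement CSV with columns
#'   `nuclide,member,mean_energy_MeV,yield,half_life_h`.
#' @return data.frame of chain members.
#' @export
alpha_chain_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "alpha_chains.csv", package = "alphadose",
                        mustWork = TRUE)
  }
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("nuclide", "member", "mean_energy_MeV", "yield", "half_life_h")
  if (!all(need %in% names(tab))) {
    stop_validation("decay-data table must have columns ",
                    paste(need, collapse = ", "))
  }
  bad <- tab$yield > 0 & (tab$mean_energy_MeV <= 0 | tab$yield > 1)
  if (any(bad)) {
    stop_validation("invalid emission rows in decay-data table: ",
                    paste(tab$member[bad], collapse = ", "))
  }
  tab
}

#' Decay chain for an alpha-therapy radionuclide
#'
#' Assembles the local decay chain of `nuclide` from the embedded decay data:
#' the parent half-life plus every alpha emission of the chain, each with an
#' intensity-weighted mean energy and a yield per parent decay. Secular
#' equilibrium is assumed, so chain energy can be booked per parent decay.
#'
#' @param nuclide parent label, one of `"Ac-225"`, `"Bi-213"`, `"Pb-212"`,
#'   `"At-211"` (or any parent present in a replacement table).
#' @param table decay-data table as returned by [alpha_chain_table()].
#' @return an object of class `decay_chain` with elements `parent`,
#'   `half_life_h`, and `emissions` (data.frame `member`, `mean_energy_MeV`,
#'   `yield`).
#' @seealso [delta_alpha()], [radionuclide()]
#' @export
alpha_chain <- function(nuclide, table = alpha_chain_table()) {
  rows <- table[table$nuclide == nuclide, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop_validation("no decay data for nuclide '", nuclide, "'")
  }
  parent <- rows[rows$member == nuclide, , drop = FALSE]
  if (nrow(parent) != 1L) {
    stop_validation("decay-data table must have exactly one parent row for '",
                    nuclide, "'")
  }
  emissions <- rows[rows$yield > 0,
                    c("member", "mean_energy_MeV", "yield"), drop = FALSE]
  structure(
    list(parent = nuclide,
         half_life_h = parent$half_life_h,
         emissions = emissions),
    class = "decay_chain")
}

#' Mean alpha energy per nuclear transition
#'
#' Yield-weighted sum of the mean alpha energies over all chain members, the
#' Delta constant of MIRD-style dosimetry restricted to alpha particles:
#' energy emitted per parent decay, in J/(Bq s). Independent of half-life and
#' additive over chain members.
#'
#' @param chain a `decay_chain`.
#' @return mean alpha energy per transition in J/(Bq s).
#' @examples
#' delta_alpha(alpha_chain("Ac-225"))  # ~4.40e-12 J/(Bq s)
#' delta_alpha(alpha_chain("Bi-213"))  # ~1.33e-12 J/(Bq s)
#' @export
delta_alpha <- function(chain) {
  stopifnot(inherits(chain, "decay_chain"))
  em <- chain$emissions
  if (nrow(em) == 0L) {
    stop_validation("decay chain '", chain$parent,
                    "' has no alpha emissions; Delta is undefined")
  }
  sum(em$yield * em$mean_energy_MeV) * MEV_TO_J
}

#' Radionuclide physical constants
#'
#' Bundles the physical half-life, decay constant and alpha Delta of a
#' nuclide's local chain for use by the TIA and dosimetry routines.
#'
#' @param label parent nuclide label (see [alpha_chain()]).
#' @param table decay-data table.
#' @return object of class `radionuclide` with `label`, `half_life_h`,
#'   `lambda_h` (1/hour) and `delta_alpha` (J/(Bq s)).
#' @export
radionuclide <- function(label, table = alpha_chain_table()) {
  chain <- alpha_chain(label, table)
  structure(
    list(label = label,
         half_life_h = chain$half_life_h,
         lambda_h = decay_constant(chain$half_life_h),
         delta_alpha = delta_alpha(chain)),
    class = "radionuclide")
}

#' @export
print.decay_chain <- function(x, ...) {
  cat("Decay chain:", x$parent,
      sprintf("(T1/2 = %g h)\n", x$half_life_h))
  print(x$emissions, row.names = FALSE)
  cat(sprintf("Delta (alpha) = %.3e J/(Bq s)\n", delta_alpha(x)))
  invisible(x)
}

#' @export
print.radionuclide <- function(x, ...) {
  cat(sprintf("%s: T1/2 = %g h, lambda = %.4g 1/h, Delta = %.3e J/(Bq s)\n",
              x$label, x$half_life_h, x$lambda_h, x$delta_alpha))
  invisible(x)
}
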