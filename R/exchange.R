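# Metabolite uptake/release rates from spent vs. control medium.
#
# Sign convention: release positive, uptake negative (as in the uptake/release
# flux figures). Rates are normalized to µmol per gram tissue per day using
# the medium volume, tissue mass and collection window.

new_exchange_measurement <- function(metabolite, rate, sd, method,
                                     window = 22, volume = 1.3, mass = NA) {
  stopifnot(window > 0, volume > 0)
  structure(list(metabolite = metabolite, rate = rate, sd = sd,
                 method = method, window = window, volume = volume,
                 mass = mass), class = "exchange_measurement")
}

# Concentration change (µmol/ml, release-positive) to µmol/g/day.
normalize_rate <- function(delta_c_release, window, volume, mass) {
  delta_c_release * volume / (mass * window) * 24
}

#' Uptake/release rate from a peak-area fold change
#'
#' For metabolites present in fresh medium at known concentration `c`, the
#' concentration change over the culture window is estimated from the
#' spent/control peak-area ratio `f`. Under the release-positive convention
#' the change is `c * (f - 1)`.
#'
#' @param c Known fresh-medium concentration (mM = µmol/ml).
#' @param f Spent/control peak-area fold change; `NA` yields a missing value
#'   with a warning (zero control area upstream).
#' @param metabolite Metabolite id.
#' @param sd_f Standard deviation of the fold change (propagated linearly);
#'   default 0 gives `sd = 0`.
#' @param window Collection window in hours (default 22 h, after the 2-h
#'   medium change).
#' @param volume Medium volume in ml (default 1.3).
#' @param mass Tissue mass in g.
#' @return An `exchange_measurement` (rate in µmol per g per day), or `NULL`
#'   when `f` is missing.
#' @export
rate_from_foldchange <- function(c, f, metabolite = NA_character_, sd_f = 0,
                                 window = 22, volume = 1.3, mass = 0.01) {
  stopifnot(c >= 0)
  if (is.na(f)) {
    warning("fold change undefined for '", metabolite,
            "' (zero control area); returning NULL")
    return(NULL)
  }
  stopifnot(f >= 0)
  rate <- normalize_rate(c * (f - 1), window, volume, mass)
  sdv <- normalize_rate(c * sd_f, window, volume, mass)
  new_exchange_measurement(metabolite, rate, sdv, "fold_change",
                           window, volume, mass)
}

#' Absolute concentration by isotope dilution
#'
#' A spent-medium sample with unknown concentration `c` and measured MID `x`
#' is mixed 1:1 with fresh 12C medium of known concentration `c0` and
#' natural-abundance MID `x0 = Bin(n, p_nat)`. Mass balance per isotopomer
#' gives `(c + c0) * x_mix = c * x + c0 * x0`, which is linear in `c`; it is
#' solved by least squares over all MI indices.
#'
#' @param x_mix Measured MID of the 1:1 mixture.
#' @param x Measured MID of the spent medium.
#' @param c0 Known fresh-medium concentration (> 0).
#' @param n Carbon count.
#' @param p_nat Natural 13C abundance for the fresh-medium MID.
#' @return List with `c` (>= 0, clipped with a warning if the least-squares
#'   solution is negative) and `residual` (root-mean-square misfit of the
#'   mixture equation).
#' @export
concentration_by_isotope_dilution <- function(x_mix, x, c0, n = length(x) - 1L,
                                              p_nat = 0.0107) {
  stopifnot(c0 > 0, length(x_mix) == length(x))
  check_mid(x, tol = 1e-6, what = "spent-medium MID")
  check_mid(x_mix, tol = 1e-6, what = "mixture MID")
  x0 <- natural_mid(n, p_nat)
  a <- x_mix - x      # coefficient of c
  b <- c0 * (x0 - x_mix)
  if (sqrt(sum((x - x0)^2)) < 1e-6)
    stop("spent-medium labeling indistinguishable from fresh medium; ",
         "concentration unidentifiable by isotope dilution")
  cc <- sum(a * b) / sum(a * a)
  if (cc < 0) {
    warning("negative concentration solution clipped to 0")
    cc <- 0
  }
  resid <- sqrt(mean(((cc + c0) * x_mix - (cc * x + c0 * x0))^2))
  list(c = cc, residual = resid)
}

#' Uptake/release rates from direct concentration assays
#'
#' For metabolites quantified by accredited assays in fresh and spent medium
#' (e.g. glucose, lactate, triglycerides), the rate follows directly from the
#' concentration difference, with the same normalization as
#' [rate_from_foldchange()].
#'
#' @param assay Data frame with columns `metabolite`, `fresh`, `spent`
#'   (concentrations, µmol/ml), optional `sd` (concentration-difference sd),
#'   optional `mass` (g).
#' @param window,volume,mass Defaults as in [rate_from_foldchange()].
#' @return List of `exchange_measurement`; rows with missing concentrations
#'   are skipped with a warning.
#' @export
ingest_direct_assay <- function(assay, window = 22, volume = 1.3,
                                mass = 0.01) {
  stopifnot(all(c("metabolite", "fresh", "spent") %in% names(assay)))
  out <- list()
  for (i in seq_len(nrow(assay))) {
    if (is.na(assay$fresh[i]) || is.na(assay$spent[i])) {
      warning("skipping '", assay$metabolite[i],
              "': missing fresh or spent concentration")
      next
    }
    m <- if ("mass" %in% names(assay) && !is.na(assay$mass[i]))
      assay$mass[i] else mass
    rate <- normalize_rate(assay$spent[i] - assay$fresh[i], window, volume, m)
    sdv <- if ("sd" %in% names(assay) && !is.na(assay$sd[i]))
      normalize_rate(assay$sd[i], window, volume, m) else 0
    out[[length(out) + 1L]] <- new_exchange_measurement(
      assay$metabolite[i], rate, sdv, "direct_assay", window, volume, m)
  }
  out
}

#' Collect exchange measurements into a data frame
#'
#' @param measurements List of `exchange_measurement`.
#' @return Data frame with columns `metabolite`, `rate`, `sd`, `method`.
#' @export
exchange_table <- function(measurements) {
  do.call(rbind, lapply(measurements, function(m)
    data.frame(metabolite = m$metabolite, rate = m$rate, sd = m$sd,
               method = m$method, stringsAsFactors = FALSE)))
}
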