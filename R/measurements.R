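# Measurement assembly: MI fractions, uptake/release fluxes and literature
# constraints in one weighted-least-squares target table.

#' Declare a measured quantity
#'
#' A measured quantity is what one LC-MS MID refers to: either a single
#' network metabolite, or a linear mixture of pools (compartment mixture, or
#' the pseudo-steady-state spent-medium mixture of fresh medium and released
#' intracellular metabolite). Mixture components are metabolite ids, or
#' `"fresh:<substrate>"` to reference the fixed fresh-medium labeling of a
#' substrate.
#'
#' @param id Quantity id (how measurement rows refer to it).
#' @param met Single metabolite (shorthand for a one-component mixture).
#' @param components Character vector of component ids.
#' @param weights Fixed numeric convex weights, or `NULL` when `weight_param`
#'   is used.
#' @param weight_param Name of a free mixture coefficient, fitted with the
#'   fluxes. Only two-component mixtures may have a free weight: the
#'   coefficient is the weight of the first component.
#' @return A `measured_quantity` object.
#' @export
measured_quantity <- function(id, met = NULL, components = NULL,
                              weights = NULL, weight_param = NULL) {
  if (!is.null(met)) {
    components <- met
    weights <- 1
  }
  stopifnot(length(components) >= 1)
  if (!is.null(weight_param)) {
    if (length(components) != 2L)
      stop("free mixture weights are supported for 2 components")
    weights <- NULL
  } else if (is.null(weights)) {
    stop("either weights or weight_param required")
  }
  structure(list(id = id, components = components, weights = weights,
                 weight_param = weight_param), class = "measured_quantity")
}

# Parse "R1 - R2", "2*R1 + 0.5*R2", "-R1" into a named coefficient vector.
parse_flux_combo <- function(s) {
  s <- gsub("-", "+-", gsub("[[:space:]]", "", s))
  terms <- strsplit(s, "+", fixed = TRUE)[[1]]
  terms <- terms[nzchar(terms)]
  coefs <- numeric(0)
  prev <- function(nm) if (nm %in% names(coefs)) coefs[[nm]] else 0
  for (t in terms) {
    sign <- 1
    if (startsWith(t, "-")) { sign <- -1; t <- substring(t, 2) }
    if (grepl("*", t, fixed = TRUE)) {
      p <- strsplit(t, "*", fixed = TRUE)[[1]]
      coefs[p[2]] <- sign * as.numeric(p[1]) + prev(p[2])
    } else {
      coefs[t] <- sign + prev(t)
    }
  }
  coefs
}

#' Assemble the fitting target table
#'
#' Combines corrected MI-fraction summaries, uptake/release flux measurements
#' and literature constraints into one table, applying the MID standard
#' deviation floor. Replicate sds below the floor underestimate the true
#' measurement error (systematic effects are invisible in replicates), so MI
#' rows are floored; flux rows keep their stated sd.
#'
#' @param net An `mfa_network`.
#' @param quantities List of [measured_quantity()] declarations.
#' @param mi_rows Data frame with columns `quantity`, `mi`, `mean`, `sd`
#'   (corrected space), or `NULL`.
#' @param flux_rows Data frame with columns `target` (a reaction id or linear
#'   combination such as `"GLC_rel - GLC_up"`, in the release-positive
#'   orientation of the model), `mean`, `sd`, or `NULL`.
#' @param literature_rows Same schema as `flux_rows`, or `NULL`.
#' @param sd_floor MID sd floor (default 0.03).
#' @return A `measurement_table` data frame with columns `kind`, `target`,
#'   `mi`, `mean`, `sd`, `sd_floored`, `source`; attribute `n` holds the row
#'   count.
#' @export
assemble_measurements <- function(net, quantities = list(), mi_rows = NULL,
                                  flux_rows = NULL, literature_rows = NULL,
                                  sd_floor = 0.03) {
  qids <- vapply(quantities, `[[`, character(1), "id")
  rows <- list()
  if (!is.null(mi_rows) && nrow(mi_rows) > 0) {
    bad <- setdiff(unique(mi_rows$quantity), qids)
    if (length(bad) > 0)
      stop("MI rows reference undeclared quantities: ",
           paste(bad, collapse = ", "))
    sdv <- mi_rows$sd
    sdv[is.na(sdv)] <- 0
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "MI_fraction", target = mi_rows$quantity, mi = mi_rows$mi,
      mean = mi_rows$mean, sd = mi_rows$sd,
      sd_floored = pmax(sdv, sd_floor),
      source = mi_rows$source %||% "MID", stringsAsFactors = FALSE)
  }
  check_combo <- function(targets, what) {
    ids <- reaction_ids(net)
    for (t in unique(targets)) {
      bad <- setdiff(names(parse_flux_combo(t)), ids)
      if (length(bad) > 0)
        stop(what, " row '", t, "' references unknown reaction(s): ",
             paste(bad, collapse = ", "))
    }
  }
  add_flux_rows <- function(df, kind, src) {
    check_combo(df$target, kind)
    if (any(is.na(df$sd) | df$sd <= 0))
      stop(kind, " rows need a positive sd")
    data.frame(kind = kind, target = df$target, mi = NA_integer_,
               mean = df$mean, sd = df$sd, sd_floored = df$sd,
               source = df$source %||% src, stringsAsFactors = FALSE)
  }
  if (!is.null(flux_rows) && nrow(flux_rows) > 0)
    rows[[length(rows) + 1L]] <- add_flux_rows(flux_rows, "exchange_flux",
                                               "exchange")
  if (!is.null(literature_rows) && nrow(literature_rows) > 0)
    rows[[length(rows) + 1L]] <- add_flux_rows(literature_rows,
                                               "literature_constraint",
                                               "literature")
  if (length(rows) == 0) stop("no measurements supplied")
  tab <- do.call(rbind, rows)
  # every MI row must index within its quantity's carbon range
  if (any(tab$kind == "MI_fraction")) {
    ncarb <- stats::setNames(net$mets$carbons, net$mets$met)
    for (q in quantities) {
      comp <- sub("^fresh:", "", q$components[1])
      nq <- ncarb[[comp]]
      sel <- tab$kind == "MI_fraction" & tab$target == q$id
      if (any(sel) && any(tab$mi[sel] < 0 | tab$mi[sel] > nq))
        stop("MI index out of range for quantity '", q$id, "'")
    }
  }
  attr(tab, "n") <- nrow(tab)
  class(tab) <- c("measurement_table", class(tab))
  tab
}

#' Chi-square acceptance threshold for a flux fit
#'
#' One-sided rejection threshold for the weighted SSR: the stated quantile of
#' the chi-square distribution with `n - p` degrees of freedom. Degrees of
#' freedom count every included MI fraction and flux row (no reduction for
#' MID normalization).
#'
#' @param n_measurements Number of independent measurement rows.
#' @param p_parameters Number of free model parameters (free fluxes, exchange
#'   fluxes, mixture coefficients).
#' @param quantile Acceptance quantile (default 0.90).
#' @return The threshold value.
#' @export
chi2_threshold <- function(n_measurements, p_parameters, quantile = 0.90) {
  dof <- n_measurements - p_parameters
  if (dof <= 0) stop("no degrees of freedom (n <= p)")
  stats::qchisq(quantile, df = dof)
}
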