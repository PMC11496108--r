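# Substrate labeling specifications.
#
# A labeling is a mixture of positional components: each component has a
# weight and a per-atom 13C probability vector (atoms independent within a
# component). This covers the designs used in practice: uniformly labeled
# tracers with a stated purity, positional tracers (e.g. 3-13C-lactate), and
# unlabeled substrates. All labeling lives in natural-abundance-corrected
# space: an unlabeled substrate has per-atom probability 0, not 0.0107.

#' Positional substrate labeling
#'
#' @param p Per-atom probability of 13C (length = carbon count).
#' @return A `substrate_mid` object.
#' @export
labeling_positional <- function(p) {
  stopifnot(all(p >= 0 & p <= 1), length(p) >= 1)
  structure(list(components = list(list(weight = 1, p = as.numeric(p))),
                 n = length(p)), class = "substrate_mid")
}

#' Uniformly 13C-labeled substrate at a given isotopic purity
#'
#' @param n Carbon count.
#' @param purity Per-atom 13C enrichment of the tracer (default 0.99).
#' @return A `substrate_mid` object.
#' @export
labeling_pure <- function(n, purity = 0.99) labeling_positional(rep(purity, n))

#' Unlabeled substrate (corrected space: zero 13C)
#'
#' @param n Carbon count.
#' @return A `substrate_mid` object.
#' @export
labeling_unlabeled <- function(n) labeling_positional(rep(0, n))

#' Mixture of labeling components
#'
#' @param components List of `substrate_mid` objects with equal carbon count.
#' @param weights Convex weights.
#' @return A `substrate_mid` object.
#' @export
labeling_mixture <- function(components, weights) {
  stopifnot(length(components) == length(weights),
            abs(sum(weights) - 1) < 1e-9, all(weights >= 0))
  ns <- vapply(components, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1) stop("components differ in carbon count")
  comps <- list()
  for (i in seq_along(components)) {
    for (cmp in components[[i]]$components) {
      cmp$weight <- cmp$weight * weights[i]
      comps[[length(comps) + 1L]] <- cmp
    }
  }
  structure(list(components = comps, n = ns[1]), class = "substrate_mid")
}

#' Substrate labeling for a network
#'
#' @param net An `mfa_network`.
#' @param spec Named list mapping every network substrate to a
#'   `substrate_mid`; substrates omitted from `spec` default to unlabeled.
#' @return A `substrate_labeling` object (named list of `substrate_mid`).
#' @export
substrate_labeling <- function(net, spec = list()) {
  subs <- network_substrates(net)
  out <- list()
  for (s in subs) {
    n <- net$mets$carbons[net$mets$met == s]
    if (!is.null(spec[[s]])) {
      sm <- spec[[s]]
      if (sm$n != n) stop("labeling for '", s, "' has ", sm$n,
                          " carbons; network says ", n)
      out[[s]] <- sm
    } else {
      out[[s]] <- labeling_unlabeled(max(n, 1L))
    }
  }
  extra <- setdiff(names(spec), subs)
  if (length(extra) > 0)
    stop("labeling given for non-substrate species: ",
         paste(extra, collapse = ", "))
  structure(out, class = "substrate_labeling")
}

# MID of an atom subset of a labeled substrate (Poisson-binomial per
# component, mixed by component weights).
substrate_emu_mid <- function(labeling, met, atoms) {
  sm <- labeling[[met]]
  if (is.null(sm)) stop("no labeling for substrate '", met, "'")
  out <- numeric(length(atoms) + 1L)
  for (cmp in sm$components) {
    mid <- 1
    for (q in cmp$p[atoms]) mid <- mid_convolve(mid, c(1 - q, q))
    out <- out + cmp$weight * mid
  }
  out
}

# Full-molecule MID of a substrate.
substrate_full_mid <- function(labeling, met) {
  sm <- labeling[[met]]
  if (is.null(sm)) stop("no labeling for substrate '", met, "'")
  substrate_emu_mid(labeling, met, seq_len(sm$n))
}
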