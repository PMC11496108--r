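# Carbon-flow decomposition: how much carbon each substrate contributes to
# each released product. For each substrate i, MIDs are re-simulated at the
# optimal flux vector with substrate i fully labelled and all others
# unlabelled; the enrichment e_ij of the released metabolite j times the
# release rate r_j (in carbon units) is the substrate-to-product carbon flow.

# Base compound name of an external species id (strip the dot suffix).
ext_base <- function(id) sub("\\..*$", "", id)

#' Substrate-to-product carbon flow matrix
#'
#' @param net An `mfa_network`.
#' @param fit An `mfa_fit` (or any `flux_state`-like list with `net_flux` and
#'   `exchange_flux`).
#' @param discount_exchange When `TRUE` (the default and the published rule),
#'   a released metabolite whose compound is also taken up from the medium
#'   gets `e_ij = 0` for all substrates, discounting exchange fluxes.
#' @return A `carbon_flow` list: `flow` matrix (substrates x release
#'   reactions, carbon-µmol per g per day), `enrichment` matrix `e_ij`,
#'   `release_rates` `r_j` (µmol/g/day), `release_carbons`, and `shares`
#'   (fraction of total released carbon per product).
#' @export
carbon_flow <- function(net, fit, discount_exchange = TRUE) {
  state <- if (inherits(fit, "mfa_fit")) fit$flux_state else fit
  subs <- network_substrates(net)
  rel_rxns <- Filter(function(r) r$kind == "release", net$reactions)
  if (length(rel_rxns) == 0) stop("network has no release reactions")
  rel_ids <- vapply(rel_rxns, `[[`, character(1), "id")
  src_mets <- vapply(rel_rxns, function(r) r$lhs$met[1], character(1))
  ncarb <- stats::setNames(net$mets$carbons, net$mets$met)
  rel_n <- ncarb[src_mets]
  r_j <- pmax(vapply(rel_ids, function(id) state$net_flux[[id]], numeric(1)),
              0)

  # compound also taken up? compare base names of external species
  uptake_bases <- ext_base(network_substrates(net))
  rel_ext <- vapply(rel_rxns, function(r)
    if (nrow(r$rhs) > 0) r$rhs$met[1] else r$lhs$met[1], character(1))
  exchanged <- ext_base(rel_ext) %in% uptake_bases

  decomp <- emu_decompose(net, as.list(unique(src_mets)))
  E <- matrix(0, length(subs), length(rel_ids),
              dimnames = list(subs, rel_ids))
  for (s in subs) {
    spec <- stats::setNames(list(labeling_pure(max(ncarb[[s]], 1L),
                                               purity = 1)), s)
    lab_s <- substrate_labeling(net, spec)
    sims <- simulate_mids(net, state, lab_s, decomp = decomp)
    for (j in seq_along(rel_ids)) {
      E[s, j] <- enrichment(sims[[src_mets[j]]], rel_n[j])
    }
  }
  if (discount_exchange) E[, exchanged] <- 0
  flow <- sweep(E, 2, r_j * rel_n, `*`)
  total <- sum(flow)
  shares <- if (total > 0) colSums(flow) / total else colSums(flow)
  structure(list(flow = flow, enrichment = E, release_rates = r_j,
                 release_carbons = rel_n, release_metabolites = src_mets,
                 discounted = rel_ids[exchanged & discount_exchange],
                 shares = shares, substrates = subs),
            class = "carbon_flow")
}

#' Total carbon uptake per substrate
#'
#' Carbon influx through each uptake reaction at a flux state, in carbon-µmol
#' per g per day; useful for checking carbon-flow conservation.
#'
#' @param net An `mfa_network`.
#' @param state A `flux_state`.
#' @return Named vector over substrates.
#' @export
substrate_carbon_uptake <- function(net, state) {
  ncarb <- stats::setNames(net$mets$carbons, net$mets$met)
  out <- stats::setNames(numeric(length(network_substrates(net))),
                         network_substrates(net))
  for (r in net$reactions) {
    if (r$kind != "uptake") next
    s <- r$lhs$met[1]
    out[s] <- out[s] + state$net_flux[[r$id]] * ncarb[[s]]
  }
  out
}
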