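# Synthetic ground-truth experiments. The bundled toy model is an original
# liver-like network (glycolysis/gluconeogenesis with a futile glucose cycle,
# glycogenolysis, a lumped TCA cycle, alanine exchange, protein synthesis and
# degradation, CO2 release) small enough for the brute-force isotopomer
# oracle, with a deep-labeling tracer design (glucose and alanine fully 13C;
# glycogen and tissue protein unlabeled, emulating 12C dilution from protein
# turnover).

#' Small atom-mapped toy networks for oracle testing
#'
#' A named list of tiny networks (<= 6 carbons, <= 10 reactions) exercising
#' pass-through chains, condensation, cleavage, reversibility and cycles.
#' Each entry has `net`, a default `labeling`, and `targets`.
#'
#' @return Named list of toy network bundles.
#' @export
toy_networks <- function() {
  mk <- function(rows) {
    parse_openflux(data.frame(rxnID = vapply(rows, `[[`, "", 1),
                              rxnEQ = vapply(rows, `[[`, "", 2),
                              rxnCTrans = vapply(rows, `[[`, "", 3),
                              rxnType = vapply(rows, `[[`, "", 4),
                              stringsAsFactors = FALSE))
  }
  out <- list()

  net <- mk(list(c("up", "Ax = A", "ab = ab", "S"),
                 c("r1", "A = B", "ab = ab", "F"),
                 c("out", "B = Bx", "ab = ab", "B")))
  out$chain <- list(
    net = net,
    labeling = substrate_labeling(net, list(Ax = labeling_positional(c(1, 0)))),
    targets = list("A", "B"))

  net <- mk(list(c("upA", "Ax = A", "a = a", "S"),
                 c("upB", "Bx = B", "a = a", "S"),
                 c("cond", "A + B = C", "a + b = ab", "F"),
                 c("out", "C = Cx", "ab = ab", "B")))
  out$condense <- list(
    net = net,
    labeling = substrate_labeling(net, list(Ax = labeling_positional(1))),
    targets = list("C"))

  net <- mk(list(c("up", "Sx = S6", "abcdef = abcdef", "S"),
                 c("cleave", "S6 = T3 + U3", "abcdef = cba + def", "FR"),
                 c("iso", "T3 = U3", "abc = abc", "FR"),
                 c("outU", "U3 = Ux", "abc = abc", "B")))
  out$cleave_rev <- list(
    net = net,
    labeling = substrate_labeling(
      net, list(Sx = labeling_positional(c(1, 0, 0, 0, 0, 1)))),
    targets = list("S6", "T3", "U3"))

  net <- mk(list(c("upA", "Ax = A2", "ab = ab", "S"),
                 c("upO", "Ox = O4", "abcd = abcd", "S"),
                 c("cs", "A2 + O4 = C6", "ab + cdef = abcdef", "F"),
                 c("dc1", "C6 = K5 + CO2", "abcdef = abcde + f", "F"),
                 c("dc2", "K5 = O4 + CO2", "abcde = bcde + a", "F"),
                 c("oout", "O4 = Oy", "abcd = abcd", "B"),
                 c("cout", "CO2 = COx", "a = a", "B")))
  out$cycle <- list(
    net = net,
    labeling = substrate_labeling(net, list(Ax = labeling_pure(2, 1))),
    targets = list("C6", "K5", "O4", "CO2"))

  net <- mk(list(c("up", "Ax = A", "abc = abc", "S"),
                 c("split1", "A = B", "abc = abc", "F"),
                 c("split2", "A = C", "abc = abc", "F"),
                 c("merge", "B = D", "abc = abc", "F"),
                 c("merge2", "C = D", "abc = cba", "F"),
                 c("rev", "D = E", "abc = abc", "FR"),
                 c("out", "E = Ex", "abc = abc", "B")))
  out$scramble <- list(
    net = net,
    labeling = substrate_labeling(net,
                                  list(Ax = labeling_positional(c(1, 0, 0)))),
    targets = list("D", "E"))

  out
}

#' Liver-like toy model with ground truth
#'
#' Builds the bundled toy model of fasted-state liver slice metabolism:
#' glucose uptake and release with a glucokinase/glucose-6-phosphatase futile
#' cycle, glycogenolysis feeding G6P with unlabeled carbon, glycolysis to
#' pyruvate and lactate release, alanine uptake with transamination, protein
#' degradation diluting the alanine pool with 12C and protein synthesis
#' draining it, a lumped TCA cycle with pyruvate carboxylase and PEPCK, and
#' CO2 release. Fluxes are in µmol per gram liver per day; glycogenolysis is
#' set to 300 (in the published 200-400 range) and glucose release dominates
#' glucose uptake, as in fasted liver.
#'
#' @return A list with `net`, `truth` (a balanced `flux_state` incl. exchange
#'   fluxes and the spent-medium mixture coefficient), `labeling` (the
#'   deep-labeling design), `quantities` (measured MID targets incl. the
#'   spent-medium glucose mixture), `flux_rows` and `literature_rows`
#'   (noise-free measured values with realistic sds), `mid_quantities`
#'   (ids of MID-measured quantities).
#' @export
toy_liver_model <- function() {
  rows <- list(
    c("GLC_up",   "GLC.ext = GLC",        "abcdef = abcdef", "S"),
    c("GLYC_in",  "GLYCOGEN.ext = G6P",   "abcdef = abcdef", "S"),
    c("ALA_up",   "ALA.ext = ALA",        "abc = abc",       "S"),
    c("PROT_deg", "PROT.ext = ALA",       "abc = abc",       "S"),
    c("GK",       "GLC = G6P",            "abcdef = abcdef", "F"),
    c("G6PASE",   "G6P = GLC",            "abcdef = abcdef", "F"),
    c("ALD",      "G6P = GAP + GAP",      "abcdef = cba + def", "FR"),
    c("GAPD",     "GAP = PYR",            "abc = abc",       "FR"),
    c("LDH",      "PYR = LAC",            "abc = abc",       "FR"),
    c("ALT",      "ALA = PYR",            "abc = abc",       "FR"),
    c("PDH",      "PYR = ACA + CO2",      "abc = bc + a",    "F"),
    c("PC",       "PYR + CO2 = OAA",      "abc + d = abcd",  "F"),
    c("CS",       "ACA + OAA = CIT",      "ab + cdef = abcdef", "F"),
    c("CITDH",    "CIT = AKG + CO2",      "abcdef = abcde + f", "F"),
    c("AKGDH",    "AKG = OAA + CO2",      "abcde = bcde + a", "F"),
    c("PEPCK",    "OAA = GAP + CO2",      "abcd = abc + d",  "F"),
    c("PROT_syn", "ALA = PROT.snk",       "abc = abc",       "B"),
    c("GLC_rel",  "GLC = GLC.med",        "abcdef = abcdef", "B"),
    c("LAC_rel",  "LAC = LAC.med",        "abc = abc",       "B"),
    c("CO2_rel",  "CO2 = CO2.med",        "a = a",           "B"))
  net <- parse_openflux(data.frame(
    rxnID = vapply(rows, `[[`, "", 1), rxnEQ = vapply(rows, `[[`, "", 2),
    rxnCTrans = vapply(rows, `[[`, "", 3),
    rxnType = vapply(rows, `[[`, "", 4), stringsAsFactors = FALSE))

  v <- c(GLC_up = 100, GLYC_in = 300, ALA_up = 150, PROT_deg = 100,
         GK = 150, G6PASE = 400, ALD = 50, GAPD = 160, LDH = 120,
         ALT = 200, PDH = 180, PC = 60, CS = 180, CITDH = 180, AKGDH = 180,
         PEPCK = 60, PROT_syn = 50, GLC_rel = 350, LAC_rel = 120,
         CO2_rel = 540)
  xch <- c(ALD = 20, GAPD = 40, LDH = 60, ALT = 30)
  alpha_true <- 0.6
  truth <- flux_state(net, v, xch,
                      mixture_coefficients = list(alpha_GLCmed =
                                                    c(alpha_true,
                                                      1 - alpha_true)))

  labeling <- substrate_labeling(net, list(
    GLC.ext = labeling_pure(6, 0.99),
    ALA.ext = labeling_pure(3, 0.99)))
  # GLYCOGEN.ext and PROT.ext default to unlabeled: 12C dilution sources

  quantities <- list(
    measured_quantity("GLC.tis", met = "GLC"),
    measured_quantity("G6P.tis", met = "G6P"),
    measured_quantity("LAC.tis", met = "LAC"),
    measured_quantity("ALA.tis", met = "ALA"),
    measured_quantity("CIT.tis", met = "CIT"),
    measured_quantity("AKG.tis", met = "AKG"),
    measured_quantity("GLC.med",
                      components = c("fresh:GLC.ext", "GLC"),
                      weight_param = "alpha_GLCmed"))

  flux_rows <- data.frame(
    target = c("GLC_rel - GLC_up", "LAC_rel", "-1*ALA_up"),
    mean = c(250, 120, -150),
    sd = c(15, 8, 10), stringsAsFactors = FALSE)
  literature_rows <- data.frame(
    target = c("CO2_rel", "PROT_syn", "PROT_deg"),
    mean = c(540, 50, 100),
    sd = c(50, 10, 20), stringsAsFactors = FALSE)

  list(net = net, truth = truth, labeling = labeling,
       quantities = quantities, flux_rows = flux_rows,
       literature_rows = literature_rows,
       mid_quantities = vapply(quantities, `[[`, character(1), "id"),
       alpha_true = alpha_true)
}

#' Sample a feasible steady-state flux vector
#'
#' Rejection-samples free fluxes uniformly within bounds until all sign
#' constraints on dependent irreversible fluxes hold.
#'
#' @param net An `mfa_network`.
#' @param flux_ub Upper bound for sampled fluxes.
#' @param seed Integer seed.
#' @param max_tries Attempt cap.
#' @return A named net-flux vector satisfying steady state.
#' @export
sample_flux_state <- function(net, flux_ub = 10, seed = 1, max_tries = 5000) {
  basis <- free_flux_basis(net)
  rev_ids <- reaction_ids_reversible(net)
  irrev <- setdiff(reaction_ids(net), rev_ids)
  lower <- ifelse(basis$free_ids %in% rev_ids, -flux_ub, 0)
  rng <- new_rng(seed)
  for (i in seq_len(max_tries)) {
    w <- lower + rng$unif(basis$n_free) * (flux_ub - lower)
    v <- basis$flux(w)
    if (all(v[irrev] >= 0)) return(v)
  }
  stop("no feasible flux vector found in ", max_tries,
       " attempts; revise bounds")
}

#' Generate a synthetic deep-labeling dataset
#'
#' Simulates true MIDs and exchange rates for the toy experiment, then adds
#' independent Gaussian noise per replicate (MID vectors clipped at zero and
#' renormalized) and aggregates replicate means and sds, producing a
#' measurement table directly consumable by [fit_fluxes()] together with the
#' hidden truth for recovery scoring.
#'
#' @param model A [toy_liver_model()]-style bundle (or compatible list).
#' @param n_replicates Number of tissue-slice replicates (default 3).
#' @param noise_sd MID noise sd per replicate (default 0.03). Flux
#'   measurements use the sds declared in the bundle's rows.
#' @param seed Integer seed; the generator is bit-reproducible given the seed.
#' @param sd_floor Floor applied when assembling the table (default 0.03).
#' @return List with `table` (a `measurement_table`), `truth`, `mi_rows`,
#'   and `sim_mids` (the noise-free simulated quantity MIDs).
#' @export
generate_dataset <- function(model, n_replicates = 3, noise_sd = 0.03,
                             seed = 1, sd_floor = 0.03) {
  net <- model$net
  truth <- model$truth
  rng <- new_rng(seed)
  decomp <- emu_decompose(net, as.list(unique(setdiff(
    sub("^fresh:", "", unlist(lapply(model$quantities, `[[`, "components"))),
    character(0)))))
  sims <- simulate_mids(net, truth, model$labeling, decomp = decomp)
  qmids <- list()
  for (q in model$quantities) {
    comps <- lapply(q$components, function(cmp) {
      if (startsWith(cmp, "fresh:"))
        substrate_full_mid(model$labeling, sub("^fresh:", "", cmp))
      else sims[[cmp]]
    })
    wts <- if (!is.null(q$weight_param))
      truth$mixture_coefficients[[q$weight_param]] else q$weights
    qmids[[q$id]] <- mix_mids(comps, wts)
  }

  mi_rows <- list()
  for (qid in names(qmids)) {
    mu <- qmids[[qid]]
    n <- length(mu) - 1L
    reps <- matrix(0, n_replicates, n + 1L)
    for (r in seq_len(n_replicates)) {
      noisy <- mu + if (noise_sd > 0) rng$norm(n + 1L) * noise_sd else 0
      reps[r, ] <- mid_clip(noisy)
    }
    mi_rows[[qid]] <- data.frame(
      quantity = qid, mi = 0:n,
      mean = colMeans(reps),
      sd = if (n_replicates > 1) apply(reps, 2, stats::sd) else 0,
      stringsAsFactors = FALSE)
  }
  mi_rows <- do.call(rbind, mi_rows)

  # flux rows: noisy means around the true values of the target combinations
  flux_rows <- model$flux_rows
  true_of <- function(tgt) {
    cf <- parse_flux_combo(tgt)
    sum(cf * truth$net_flux[names(cf)])
  }
  for (i in seq_len(nrow(flux_rows))) {
    tv <- true_of(flux_rows$target[i])
    flux_rows$mean[i] <- tv + if (noise_sd > 0)
      rng$norm(1) * flux_rows$sd[i] else 0
  }
  literature_rows <- model$literature_rows
  for (i in seq_len(nrow(literature_rows))) {
    tv <- true_of(literature_rows$target[i])
    literature_rows$mean[i] <- tv + if (noise_sd > 0)
      rng$norm(1) * literature_rows$sd[i] else 0
  }

  table <- assemble_measurements(net, model$quantities, mi_rows = mi_rows,
                                 flux_rows = flux_rows,
                                 literature_rows = literature_rows,
                                 sd_floor = sd_floor)
  list(table = table, truth = truth, mi_rows = mi_rows,
       flux_rows = flux_rows, literature_rows = literature_rows,
       sim_mids = qmids, seed = seed, n_replicates = n_replicates,
       noise_sd = noise_sd)
}

#' Recovery and coverage report against hidden truth
#'
#' @param truth The true `flux_state`.
#' @param fit An `mfa_fit` on the same network.
#' @param cis Optional list of `flux_ci` (or a [profile_ci_table()] data
#'   frame) for coverage scoring.
#' @return List with `fluxes` (per-reaction truth, estimate, abs/rel error,
#'   and CI coverage when available) and `coverage` (aggregate rate, `NA`
#'   without CIs).
#' @export
recovery_report <- function(truth, fit, cis = NULL) {
  est <- fit$flux_state$net_flux
  ids <- names(est)
  tv <- truth$net_flux[ids]
  df <- data.frame(reaction = ids, truth = as.numeric(tv),
                   estimate = as.numeric(est),
                   abs_error = abs(est - tv),
                   rel_error = abs(est - tv) / pmax(abs(tv), 1e-12),
                   stringsAsFactors = FALSE)
  cover <- NA
  if (!is.null(cis)) {
    if (!is.data.frame(cis))
      cis <- do.call(rbind, lapply(cis, function(ci)
        data.frame(reaction = ci$reaction, lower = ci$lower,
                   upper = ci$upper, stringsAsFactors = FALSE)))
    df <- merge(df, cis[, c("reaction", "lower", "upper")], by = "reaction",
                all.x = TRUE, sort = FALSE)
    df$covered <- !is.na(df$lower) & df$lower - 1e-9 <= df$truth &
      df$truth <= df$upper + 1e-9
    cover <- mean(df$covered[!is.na(df$lower)])
  }
  list(fluxes = df, coverage = cover, ssr = fit$ssr,
       accepted = fit$accepted)
}
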