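# EMU (elementary metabolite unit) simulation of steady-state mass-isotopomer
# distributions. An EMU is a subset of a metabolite's carbon atoms; at
# isotopic steady state the MIDs of all EMUs of one size satisfy a linear
# balance system given the MIDs of smaller EMUs and substrate labeling, so the
# full system decomposes into a cascade of small linear solves.

emu_key <- function(met, atoms) paste0(met, "|", paste(atoms, collapse = ","))

# Expand reactions into unidirectional atom-transfer entries. Static with
# respect to flux values; reversible reactions contribute a forward and a
# backward entry whose magnitudes are assigned at simulation time.
expand_unidirectional <- function(net) {
  uni <- list()
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    carbon_l <- nzchar(r$trans_lhs); carbon_r <- nzchar(r$trans_rhs)
    if (any(r$lhs$coef[carbon_l] != 1) || any(r$rhs$coef[carbon_r] != 1))
      stop("reaction '", r$id, "': carbon-carrying species must have unit ",
           "stoichiometry (write repeated occurrences explicitly)")
    fwd <- list(rxn = j, dir = 1L,
                subs = r$lhs[carbon_l, , drop = FALSE],
                subs_tr = r$trans_lhs[carbon_l],
                prods = r$rhs[carbon_r, , drop = FALSE],
                prods_tr = r$trans_rhs[carbon_r])
    uni[[length(uni) + 1L]] <- fwd
    if (r$reversible) {
      uni[[length(uni) + 1L]] <- list(rxn = j, dir = -1L,
                                      subs = fwd$prods, subs_tr = fwd$prods_tr,
                                      prods = fwd$subs, prods_tr = fwd$subs_tr)
    }
  }
  uni
}

# Precompute the substrate EMU MIDs a decomposition will need (they depend
# only on the labeling design, not the flux state). Ordered to match
# decomp$sub_keys, as required by the compiled solver.
substrate_mid_cache <- function(decomp, labeling) {
  cache <- lapply(decomp$sub_keys, function(k) {
    info <- decomp$sub_src_info[[k]]
    substrate_emu_mid(labeling, info$met, info$atoms)
  })
  names(cache) <- decomp$sub_keys
  cache
}

# Unidirectional flux magnitudes for a flux state (vectorized against the
# integer plumbing stored in the decomposition).
unidirectional_fluxes <- function(decomp, flux) {
  v <- as.numeric(flux$net_flux[decomp$rxn_ids])
  if (anyNA(v)) stop("net_flux missing reactions")
  xch_full <- numeric(length(decomp$rxn_ids))
  xch <- flux$exchange_flux
  if (!is.null(xch) && length(xch) > 0)
    xch_full[match(names(xch), decomp$rxn_ids)] <- as.numeric(xch)
  vk <- v[decomp$uni_rxn]
  xv <- xch_full[decomp$uni_rxn]
  fwd <- decomp$uni_dir == 1L
  w <- numeric(length(vk))
  w[fwd] <- pmax(vk[fwd], 0) + ifelse(decomp$uni_rev[fwd], xv[fwd], 0)
  w[!fwd] <- pmax(-vk[!fwd], 0) + xv[!fwd]
  if (any(w < -1e-9)) stop("negative effective unidirectional flux")
  pmax(w, 0)
}

#' Decompose a network into the EMU system needed for given targets
#'
#' Traces each target EMU back through the atom maps to substrate EMUs,
#' collecting all intermediate EMUs and their production terms (including
#' convolutions of smaller EMUs for condensation reactions), grouped into
#' levels by EMU size.
#'
#' @param net An `mfa_network`.
#' @param targets List of targets; each either a metabolite id (string, all
#'   carbons) or `list(met =, atoms =)`.
#' @return An `emu_decomposition` object, reusable across flux states.
#' @export
emu_decompose <- function(net, targets) {
  uni <- expand_unidirectional(net)
  roles <- stats::setNames(net$mets$role, net$mets$met)
  ncarb <- stats::setNames(net$mets$carbons, net$mets$met)

  norm_target <- function(t) {
    if (is.character(t)) t <- list(met = t, atoms = seq_len(ncarb[[t]]))
    stopifnot(!is.null(t$met), !is.null(t$atoms))
    if (is.null(roles[[t$met]])) stop("unknown target metabolite '", t$met, "'")
    if (any(t$atoms < 1 | t$atoms > ncarb[[t$met]]) ||
        anyDuplicated(t$atoms))
      stop("invalid atom set for target '", t$met, "'")
    t$atoms <- sort(as.integer(t$atoms))
    t
  }
  targets <- lapply(targets, norm_target)

  # producer occurrences per metabolite: list of (uni index, prod occurrence)
  producers <- list()
  for (k in seq_along(uni)) {
    for (o in seq_len(nrow(uni[[k]]$prods))) {
      m <- uni[[k]]$prods$met[o]
      producers[[m]] <- c(producers[[m]], list(c(k, o)))
    }
  }

  emus <- list()      # key -> list(met, atoms, size)
  terms <- list()     # key -> list of production terms
  queue <- list()
  push <- function(met, atoms) {
    key <- emu_key(met, atoms)
    if (is.null(emus[[key]])) {
      emus[[key]] <<- list(met = met, atoms = atoms, size = length(atoms))
      queue[[length(queue) + 1L]] <<- key
    }
    key
  }
  for (t in targets) {
    if (roles[[t$met]] == "balanced") push(t$met, t$atoms)
    else if (roles[[t$met]] == "sink")
      stop("target '", t$met, "' is a sink species; simulate its source ",
           "metabolite instead")
  }

  while (length(queue) > 0) {
    key <- queue[[1]]; queue[[1]] <- NULL
    e <- emus[[key]]
    prods <- producers[[e$met]]
    if (is.null(prods))
      stop("EMU '", key, "' is unreachable: metabolite '", e$met,
           "' has no producing reaction")
    tlist <- list()
    for (p in prods) {
      k <- p[1]; o <- p[2]
      u <- uni[[k]]
      letters_p <- strsplit(u$prods_tr[o], "")[[1]]
      want <- letters_p[e$atoms]
      # locate each wanted letter on the substrate side
      frags <- list()
      for (s in seq_len(nrow(u$subs))) {
        letters_s <- strsplit(u$subs_tr[s], "")[[1]]
        pos <- which(letters_s %in% want)
        if (length(pos) > 0)
          frags[[length(frags) + 1L]] <-
            list(met = u$subs$met[s], atoms = sort(pos))
      }
      got <- sum(vapply(frags, function(f) length(f$atoms), integer(1)))
      if (got != length(want))
        stop("reaction '", net$reactions[[u$rxn]]$id,
             "': atoms of EMU '", key, "' not traceable")
      srcs <- lapply(frags, function(f) {
        if (roles[[f$met]] == "balanced") {
          list(type = "emu", key = push(f$met, f$atoms),
               size = length(f$atoms))
        } else {
          list(type = "sub", met = f$met, atoms = f$atoms,
               size = length(f$atoms), key = emu_key(f$met, f$atoms))
        }
      })
      tlist[[length(tlist) + 1L]] <- list(uni = k, sources = srcs)
    }
    terms[[key]] <- tlist
  }

  gid <- stats::setNames(seq_along(emus), names(emus))
  sizes <- sort(unique(vapply(emus, `[[`, integer(1), "size")))
  levels <- lapply(sizes, function(s) {
    keys <- names(emus)[vapply(emus, `[[`, integer(1), "size") == s]
    idx <- stats::setNames(seq_along(keys), keys)
    coupling <- list()  # (i, j, uni)
    known <- list()     # (i, uni, sources with integer ids)
    for (key in keys) {
      i <- idx[[key]]
      for (tm in terms[[key]]) {
        one_emu_same <- length(tm$sources) == 1L &&
          tm$sources[[1]]$type == "emu" && tm$sources[[1]]$size == s
        if (one_emu_same) {
          coupling[[length(coupling) + 1L]] <-
            list(i = i, j = idx[[tm$sources[[1]]$key]], uni = tm$uni)
        } else {
          srcs <- lapply(tm$sources, function(src) {
            src$gid <- if (src$type == "emu") gid[[src$key]] else NA_integer_
            src
          })
          known[[length(known) + 1L]] <-
            list(i = i, uni = tm$uni, sources = srcs)
        }
      }
    }
    list(size = s, keys = keys, gids = unname(gid[keys]),
         mets = vapply(keys, function(k) emus[[k]]$met, character(1)),
         coupling = coupling, known = known)
  })

  # total consumption occurrences per balanced metabolite: (uni index, count)
  cons <- list()
  for (k in seq_along(uni)) {
    tab <- table(uni[[k]]$subs$met)
    for (m in names(tab)) {
      if (roles[[m]] == "balanced")
        cons[[m]] <- rbind(cons[[m]], c(k, as.integer(tab[[m]])))
    }
  }
  cons_mets <- net$mets$met[net$mets$role == "balanced"]
  cons_flat <- NULL
  for (m in names(cons))
    cons_flat <- rbind(cons_flat, cbind(match(m, cons_mets), cons[[m]]))
  if (is.null(cons_flat)) cons_flat <- matrix(numeric(), 0, 3)

  # flatten the level plans into integer tables for the compiled solver
  sub_keys <- character(0)
  sub_src_info <- list()
  note_sub <- function(key, met, atoms) {
    pos <- match(key, sub_keys)
    if (is.na(pos)) {
      sub_keys <<- c(sub_keys, key)
      sub_src_info[[key]] <<- list(met = met, atoms = atoms)
      pos <- length(sub_keys)
    }
    pos
  }
  levels <- lapply(levels, function(lv) {
    cp <- if (length(lv$coupling))
      t(vapply(lv$coupling, function(x) c(x$i, x$j, x$uni), integer(3)))
    else matrix(integer(), 0, 3)
    term_i <- integer(0); term_uni <- integer(0)
    src_term <- integer(0); src_type <- integer(0); src_idx <- integer(0)
    for (t in seq_along(lv$known)) {
      kn <- lv$known[[t]]
      term_i <- c(term_i, kn$i)
      term_uni <- c(term_uni, kn$uni)
      for (src in kn$sources) {
        src_term <- c(src_term, t)
        if (src$type == "sub") {
          src_type <- c(src_type, 0L)
          src_idx <- c(src_idx, note_sub(src$key, src$met, src$atoms))
        } else {
          src_type <- c(src_type, 1L)
          src_idx <- c(src_idx, src$gid)
        }
      }
    }
    lv$met_idx <- match(lv$mets, cons_mets)
    lv$coupling_mat <- cp
    lv$term_i <- term_i; lv$term_uni <- term_uni
    lv$src_term <- src_term; lv$src_type <- src_type; lv$src_idx <- src_idx
    lv
  })

  # integer plumbing for fast flux evaluation
  rxn_ids <- vapply(net$reactions, `[[`, character(1), "id")
  uni_rxn <- vapply(uni, `[[`, integer(1), "rxn")
  uni_dir <- vapply(uni, `[[`, integer(1), "dir")
  uni_rev <- vapply(uni, function(u) net$reactions[[u$rxn]]$reversible,
                    logical(1))
  for (t in seq_along(targets)) {
    key <- emu_key(targets[[t]]$met, targets[[t]]$atoms)
    targets[[t]]$key <- key
    if (roles[[targets[[t]]$met]] == "substrate")
      note_sub(key, targets[[t]]$met, targets[[t]]$atoms)
    targets[[t]]$gid <- if (!is.null(emus[[key]]) &&
                            roles[[targets[[t]]$met]] == "balanced")
      gid[[key]] else NA_integer_
  }

  structure(list(uni = uni, emus = emus, levels = levels, cons = cons,
                 cons_mets = cons_mets, cons_flat = cons_flat,
                 sub_keys = sub_keys, sub_src_info = sub_src_info,
                 targets = targets, roles = roles, ncarb = ncarb,
                 n_emus = length(emus), rxn_ids = rxn_ids,
                 uni_rxn = uni_rxn, uni_dir = uni_dir, uni_rev = uni_rev),
            class = "emu_decomposition")
}

#' Simulate steady-state MIDs via the EMU cascade
#'
#' Solves, for each EMU size in increasing order, the linear balance system
#' for all unknown EMU MIDs given substrate labeling and previously solved
#' smaller EMUs, and returns the MIDs of the requested targets.
#'
#' @param net An `mfa_network`.
#' @param flux A `flux_state` (or a list with `net_flux` and optionally
#'   `exchange_flux`).
#' @param labeling A `substrate_labeling`.
#' @param targets As in [emu_decompose()]; ignored when `decomp` is given.
#' @param decomp Optional precomputed [emu_decompose()] result (reuse across
#'   many flux states for speed).
#' @param prune_tol Pools with total throughput below this are pruned from
#'   the system (with a warning) unless they feed a target, in which case an
#'   error is raised.
#' @return Named list of MID vectors (index `0..size`), one per target, in
#'   target order; names are `met` or `met|atoms` keys.
#' @export
simulate_mids <- function(net, flux, labeling, targets = NULL, decomp = NULL,
                          prune_tol = 1e-12, sub_mids = NULL) {
  if (is.null(decomp)) decomp <- emu_decompose(net, targets)
  if (is.null(sub_mids)) sub_mids <- substrate_mid_cache(decomp, labeling)
  w <- unidirectional_fluxes(decomp, flux)

  cons_val <- numeric(length(decomp$cons_mets))
  cf <- decomp$cons_flat
  if (nrow(cf) > 0) {
    agg <- rowsum(w[cf[, 2]] * cf[, 3], cf[, 1])
    cons_val[as.integer(rownames(agg))] <- agg[, 1]
  }
  dead <- decomp$cons_mets[cons_val < prune_tol]
  if (length(dead) > 0) {
    tmets <- vapply(decomp$targets, `[[`, character(1), "met")
    hit <- intersect(dead, tmets)
    if (length(hit) > 0)
      stop("zero-throughput pool feeds a simulation target: ",
           paste(hit, collapse = ", "))
  }

  # pruned pools get a placeholder unlabeled MID inside the solver; they are
  # only ever referenced through fluxes below prune_tol
  solved <- .emu_solve_cpp(decomp$levels, w, cons_val,
                           unname(sub_mids), decomp$n_emus, prune_tol)

  out <- list()
  for (t in decomp$targets) {
    mid <- if (decomp$roles[[t$met]] == "substrate")
      sub_mids[[t$key]] %||% substrate_emu_mid(labeling, t$met, t$atoms)
    else solved[[t$gid]]
    nm <- if (length(t$atoms) == decomp$ncarb[[t$met]]) t$met else t$key
    out[[nm]] <- mid
  }
  out
}

#' Convex mixture of MIDs
#'
#' Used for metabolites present in multiple cellular compartments (cytosol,
#' mitochondria, lysosomes, endoplasmic reticulum), which are observed as a
#' linear mixture of the pool MIDs.
#'
#' @param components List of MID vectors with equal carbon count.
#' @param weights Convex weights (non-negative, sum 1).
#' @return The mixed MID vector.
#' @export
mix_mids <- function(components, weights) {
  lens <- vapply(components, length, integer(1))
  if (length(unique(lens)) != 1) stop("mismatched carbon counts in mixture")
  if (any(weights < -1e-9) || abs(sum(weights) - 1) > 1e-9)
    stop("mixture weights must be convex")
  out <- numeric(lens[1])
  for (i in seq_along(components)) out <- out + weights[i] * components[[i]]
  out
}

#' Pseudo-steady-state spent-medium MID
#'
#' Spent culture medium is modelled as a linear mixture of fresh medium and
#' intracellular metabolite released into the medium over the culture window.
#'
#' @param fresh MID of the metabolite in fresh medium.
#' @param intracellular MID of the released intracellular pool.
#' @param alpha Fresh-medium weight in `[0, 1]`.
#' @return `alpha * fresh + (1 - alpha) * intracellular`.
#' @export
spent_medium_mid <- function(fresh, intracellular, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  mix_mids(list(fresh, intracellular), c(alpha, 1 - alpha))
}
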