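# Atom-mapped metabolic network models in the OpenFLUX sheet dialect.
#
# A model sheet has one row per reaction with columns (at least)
#   rxnID     unique reaction identifier
#   rxnEQ     chemical equation, e.g. "A + B = C"
#   rxnCTrans carbon transitions, one letter group per metabolite occurrence,
#             e.g. "ab + c = abc"; the token "X" marks a carbon-free species
#   rxnType   F  irreversible internal reaction
#             FR reversible internal reaction (single row)
#             R  reverse direction of a previously declared FR row (merged)
#             S  substrate uptake (left-hand species are external substrates
#                with fixed labeling)
#             B  sink / release (right-hand species, if any, are external;
#                carbon may exit the balanced set here)
# Extra columns (e.g. a rates/basis column) are ignored.
#
# External species ids conventionally carry a dot suffix (GLC.ext, LAC.med);
# the prefix before the first dot identifies the compound, which is how
# "taken up AND released" metabolites are recognized in carbon-flow analysis.

#' Parse an OpenFLUX-dialect model sheet
#'
#' Reads an atom-mapped metabolic network from a data frame or a delimited
#' text file (comma- or tab-separated, auto-detected). Carbon counts per
#' metabolite are inferred from the transition strings and checked for
#' consistency; every internal (`F`/`FR`) and uptake (`S`) reaction must
#' balance its carbon-letter multiset, while sink (`B`) reactions may retire
#' letters.
#'
#' @param sheet A data frame with columns `rxnID`, `rxnEQ`, `rxnCTrans`,
#'   `rxnType` (case-insensitive), or a path to a delimited file with these
#'   columns.
#' @return A validated `mfa_network` object: a list with `reactions` (each a
#'   list with `id`, `lhs`/`rhs` data frames of (`met`, `coef`), transition
#'   strings, `reversible` flag and `kind`), and `mets`, a data frame of
#'   metabolite, carbon count and role (`balanced`, `substrate`, `sink`).
#' @export
parse_openflux <- function(sheet) {
  if (is.character(sheet) && length(sheet) == 1L) {
    first <- readLines(sheet, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    sheet <- utils::read.table(sheet, sep = sep, header = TRUE,
                               stringsAsFactors = FALSE, strip.white = TRUE,
                               comment.char = "#", quote = "\"")
  }
  stopifnot(is.data.frame(sheet))
  names(sheet) <- tolower(names(sheet))
  need <- c("rxnid", "rxneq", "rxnctrans", "rxntype")
  missing_cols <- setdiff(need, names(sheet))
  if (length(missing_cols) > 0)
    stop("model sheet lacks column(s): ", paste(missing_cols, collapse = ", "))

  reactions <- list()
  for (k in seq_len(nrow(sheet))) {
    id <- trimws(as.character(sheet$rxnid[k]))
    eq <- as.character(sheet$rxneq[k])
    tr <- as.character(sheet$rxnctrans[k])
    ty <- toupper(trimws(as.character(sheet$rxntype[k])))
    if (!ty %in% c("F", "FR", "R", "S", "B"))
      stop("reaction '", id, "': unknown reaction type '", ty, "'")
    sides <- parse_equation(eq, id)
    trs <- parse_transitions(tr, sides, id)

    if (ty == "R") {
      # reverse row of a reversible pair: merge into the forward reaction
      base <- sub("(_b|_r|_rev)$", "", id)
      j <- which(vapply(reactions, function(r) r$id == base, logical(1)))
      if (length(j) != 1L)
        stop("reaction '", id, "': reverse row has no matching forward row '",
             base, "'")
      reactions[[j]]$reversible <- TRUE
      next
    }

    rxn <- list(
      id = id,
      lhs = sides$lhs, rhs = sides$rhs,
      trans_lhs = trs$lhs, trans_rhs = trs$rhs,
      reversible = (ty == "FR"),
      kind = switch(ty, F = "internal", FR = "internal",
                    S = "uptake", B = "release")
    )
    if (any(vapply(reactions, function(r) r$id == id, logical(1))))
      stop("duplicate reaction id '", id, "'")
    reactions[[length(reactions) + 1L]] <- rxn
  }

  net <- structure(list(reactions = reactions), class = "mfa_network")
  net$mets <- infer_metabolites(net)
  validate_network(net)
  net
}

# Split "A + 2 B = C" into lhs/rhs data frames of (met, coef).
parse_equation <- function(eq, id) {
  parts <- strsplit(eq, "=|->", fixed = FALSE)[[1]]
  if (length(parts) > 2L)
    stop("reaction '", id, "': equation has more than one '='")
  if (length(parts) == 1L) parts <- c(parts, "")
  parse_side <- function(s) {
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    terms <- terms[nzchar(terms)]
    if (length(terms) == 0)
      return(data.frame(met = character(), coef = numeric(),
                        stringsAsFactors = FALSE))
    met <- character(length(terms)); coef <- numeric(length(terms))
    for (i in seq_along(terms)) {
      tok <- strsplit(terms[i], "[ ]+")[[1]]
      if (length(tok) == 2L && !is.na(suppressWarnings(as.numeric(tok[1])))) {
        coef[i] <- as.numeric(tok[1]); met[i] <- tok[2]
      } else {
        coef[i] <- 1; met[i] <- paste(tok, collapse = " ")
      }
    }
    data.frame(met = met, coef = coef, stringsAsFactors = FALSE)
  }
  list(lhs = parse_side(parts[1]), rhs = parse_side(parts[2]))
}

# Split "ab + c = abc" into per-occurrence letter strings aligned with the
# equation sides. "X" (or an entirely empty field) marks carbon-free species.
parse_transitions <- function(tr, sides, id) {
  tr <- trimws(tr)
  if (!nzchar(tr) || toupper(tr) == "X") {
    return(list(lhs = rep("", nrow(sides$lhs)),
                rhs = rep("", nrow(sides$rhs))))
  }
  parts <- strsplit(tr, "=|->", fixed = FALSE)[[1]]
  if (length(parts) == 1L) parts <- c(parts, "")
  split_side <- function(s, side) {
    toks <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    toks <- toks[nzchar(toks)]
    n <- nrow(sides[[side]])
    if (length(toks) != n)
      stop("reaction '", id, "': ", length(toks), " transition group(s) for ",
           n, " metabolite(s) on the ", side)
    ifelse(toupper(toks) == "X", "", toks)
  }
  lhs <- split_side(parts[1], "lhs")
  rhs <- split_side(parts[2], "rhs")
  for (side in list(lhs, rhs)) {
    letters_used <- unlist(strsplit(paste0(side, collapse = ""), ""))
    if (anyDuplicated(letters_used))
      stop("reaction '", id, "': duplicate carbon letter within one side")
  }
  list(lhs = lhs, rhs = rhs)
}

# Infer metabolite roles and carbon counts from the reaction list.
infer_metabolites <- function(net) {
  carbons <- list(); role <- list()
  note_carbons <- function(met, n, id) {
    if (!is.null(carbons[[met]]) && carbons[[met]] != n)
      stop("metabolite '", met, "': inconsistent carbon count (",
           carbons[[met]], " vs ", n, " in reaction '", id, "')")
    carbons[[met]] <<- n
  }
  subs <- character(); snks <- character()
  for (r in net$reactions) {
    for (i in seq_len(nrow(r$lhs)))
      note_carbons(r$lhs$met[i], nchar(r$trans_lhs[i]), r$id)
    for (i in seq_len(nrow(r$rhs)))
      note_carbons(r$rhs$met[i], nchar(r$trans_rhs[i]), r$id)
    if (r$kind == "uptake") subs <- c(subs, r$lhs$met)
    if (r$kind == "release") snks <- c(snks, r$rhs$met)
  }
  mets <- names(carbons)
  role <- ifelse(mets %in% subs, "substrate",
                 ifelse(mets %in% snks, "sink", "balanced"))
  both <- intersect(subs, snks)
  if (length(both) > 0)
    stop("species cannot be both uptake substrate and release sink: ",
         paste(both, collapse = ", "),
         " (use distinct external ids, e.g. GLC.ext / GLC.med)")
  data.frame(met = mets, carbons = unlist(carbons, use.names = FALSE),
             role = role, stringsAsFactors = FALSE)
}

#' Validate an mfa_network
#'
#' Checks carbon-letter conservation reaction by reaction, carbon-count
#' consistency, and that balanced metabolites are both produced and consumed
#' somewhere.
#'
#' @param net An `mfa_network`.
#' @return `net`, invisibly; stops with an informative error on violation.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "mfa_network"))
  for (r in net$reactions) {
    lset <- sort(unlist(strsplit(paste0(r$trans_lhs, collapse = ""), "")))
    rset <- sort(unlist(strsplit(paste0(r$trans_rhs, collapse = ""), "")))
    if (r$kind == "release") {
      if (!all(rset %in% lset))
        stop("reaction '", r$id, "': sink side introduces carbon letters")
    } else if (!identical(lset, rset)) {
      stop("reaction '", r$id, "': carbon letters unbalanced (",
           paste(lset, collapse = ""), " vs ", paste(rset, collapse = ""), ")")
    }
  }
  invisible(net)
}

#' @export
print.mfa_network <- function(x, ...) {
  nb <- sum(x$mets$role == "balanced")
  cat("mfa_network:", length(x$reactions), "reactions,",
      nb, "balanced metabolites,",
      sum(x$mets$role == "substrate"), "substrates,",
      sum(x$mets$role == "sink"), "sinks\n")
  invisible(x)
}

#' Balanced metabolites of a network
#' @param net An `mfa_network`.
#' @return Character vector of balanced metabolite ids.
#' @export
balanced_metabolites <- function(net) net$mets$met[net$mets$role == "balanced"]

#' Substrate (fixed-labeling) species of a network
#' @param net An `mfa_network`.
#' @return Character vector of external substrate ids.
#' @export
network_substrates <- function(net) net$mets$met[net$mets$role == "substrate"]

#' Reaction ids of a network
#' @param net An `mfa_network`.
#' @param kind Optional filter: `internal`, `uptake` or `release`.
#' @return Character vector of reaction ids.
#' @export
reaction_ids <- function(net, kind = NULL) {
  ids <- vapply(net$reactions, `[[`, character(1), "id")
  if (!is.null(kind)) {
    kk <- vapply(net$reactions, `[[`, character(1), "kind")
    ids <- ids[kk %in% kind]
  }
  ids
}

#' Stoichiometric matrix over balanced metabolites
#'
#' @param net An `mfa_network`.
#' @return Numeric matrix, rows = balanced metabolites, columns = reactions
#'   (one signed net-flux column per reaction, reversible or not).
#' @export
stoichiometric_matrix <- function(net) {
  bal <- balanced_metabolites(net)
  ids <- reaction_ids(net)
  S <- matrix(0, nrow = length(bal), ncol = length(ids),
              dimnames = list(bal, ids))
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    for (i in seq_len(nrow(r$lhs))) {
      m <- r$lhs$met[i]
      if (m %in% bal) S[m, j] <- S[m, j] - r$lhs$coef[i]
    }
    for (i in seq_len(nrow(r$rhs))) {
      m <- r$rhs$met[i]
      if (m %in% bal) S[m, j] <- S[m, j] + r$rhs$coef[i]
    }
  }
  S
}

#' Free-flux parameterization of the steady-state flux space
#'
#' Computes a basis of the steady-state null space `S v = 0` and selects a set
#' of reactions whose fluxes act as free coordinates: any assignment of the
#' free fluxes determines the full balanced net-flux vector. Optionally, some
#' reactions may be pinned to fixed values, reducing the number of free
#' coordinates.
#'
#' @param net An `mfa_network`.
#' @param fixed Named numeric vector of reaction fluxes to pin (may be empty).
#' @return An object of class `flux_basis` with elements `free_ids` (the free
#'   reactions), `n_free`, and `flux(w)`, a function mapping a vector of free
#'   flux values (in `free_ids` order) to the full named net-flux vector.
#' @export
free_flux_basis <- function(net, fixed = numeric()) {
  S <- stoichiometric_matrix(net)
  ids <- colnames(S)
  # null space of S via QR of t(S)
  qr_t <- qr(t(S))
  rank_s <- qr_t$rank
  d <- ncol(S) - rank_s
  if (d <= 0) stop("network has no flux degrees of freedom")
  N <- qr.Q(qr_t, complete = TRUE)[, seq(rank_s + 1L, ncol(S)), drop = FALSE]
  rownames(N) <- ids

  u0 <- rep(0, ncol(N))
  if (length(fixed) > 0) {
    bad <- setdiff(names(fixed), ids)
    if (length(bad) > 0) stop("unknown fixed reaction(s): ",
                              paste(bad, collapse = ", "))
    C <- N[names(fixed), , drop = FALSE]
    qc <- qr(t(C))
    if (qc$rank < length(fixed))
      stop("fixed fluxes are linearly dependent given steady state: ",
           paste(names(fixed), collapse = ", "))
    u0 <- as.numeric(t(C) %*% solve(C %*% t(C), as.numeric(fixed)))
    if (qc$rank < ncol(N)) {
      Z <- qr.Q(qc, complete = TRUE)[, seq(qc$rank + 1L, ncol(N)),
                                     drop = FALSE]
    } else {
      Z <- matrix(0, ncol(N), 0)
    }
  } else {
    Z <- diag(d)
  }
  nfree <- ncol(Z)
  NZ <- N %*% Z
  v_base <- as.numeric(N %*% u0)
  names(v_base) <- ids

  free_ids <- character(0)
  if (nfree > 0) {
    # pick reporting reactions whose rows of NZ are independent
    # (column-pivoted QR so pinned/zero rows are never selected)
    qrows <- qr(t(NZ), LAPACK = TRUE)
    dR <- abs(diag(qr.R(qrows)))
    rnk <- sum(dR > max(dR, 0) * 1e-10)
    if (rnk < nfree)
      stop("could not select ", nfree, " independent free fluxes")
    free_ids <- ids[qrows$pivot[seq_len(nfree)]]
    Mfree <- NZ[free_ids, , drop = FALSE]
    Minv <- solve(Mfree)
  }

  flux_fun <- function(w) {
    if (length(w) != nfree)
      stop("expected ", nfree, " free flux value(s)")
    if (nfree == 0) return(v_base)
    v <- v_base + as.numeric(NZ %*% (Minv %*% (w - v_base[free_ids])))
    names(v) <- ids
    v
  }

  structure(list(free_ids = free_ids, n_free = nfree, flux = flux_fun,
                 fixed = fixed, reaction_ids = ids, null_dim = d),
            class = "flux_basis")
}

#' Construct and validate a flux state
#'
#' @param net An `mfa_network`.
#' @param net_flux Named numeric vector of net fluxes, one per reaction
#'   (µmol per gram tissue per day).
#' @param exchange_flux Named non-negative exchange fluxes for reversible
#'   reactions (missing ids default to 0).
#' @param mixture_coefficients Named list of convex weight vectors.
#' @param tol Relative steady-state tolerance.
#' @return A `flux_state` list.
#' @export
flux_state <- function(net, net_flux, exchange_flux = numeric(),
                       mixture_coefficients = list(), tol = 1e-6) {
  ids <- reaction_ids(net)
  if (!all(ids %in% names(net_flux)))
    stop("net_flux missing reactions: ",
         paste(setdiff(ids, names(net_flux)), collapse = ", "))
  v <- net_flux[ids]
  rev_ids <- reaction_ids_reversible(net)
  irrev <- setdiff(ids, rev_ids)
  if (any(v[irrev] < -1e-9))
    stop("negative net flux on irreversible reaction(s): ",
         paste(irrev[v[irrev] < -1e-9], collapse = ", "))
  if (length(exchange_flux) > 0 && any(exchange_flux < -1e-12))
    stop("exchange fluxes must be non-negative")
  S <- stoichiometric_matrix(net)
  resid <- as.numeric(S %*% v)
  scale <- max(1, max(abs(v)))
  if (max(abs(resid)) > tol * scale)
    stop("net_flux violates steady state (max |S v| = ",
         format(max(abs(resid))), ")")
  for (nm in names(mixture_coefficients)) {
    wts <- mixture_coefficients[[nm]]
    if (any(wts < -1e-9) || abs(sum(wts) - 1) > 1e-9)
      stop("mixture '", nm, "': weights must be convex")
  }
  structure(list(net_flux = v, exchange_flux = exchange_flux,
                 mixture_coefficients = mixture_coefficients),
            class = "flux_state")
}

reaction_ids_reversible <- function(net) {
  ids <- vapply(net$reactions, `[[`, character(1), "id")
  rev <- vapply(net$reactions, `[[`, logical(1), "reversible")
  ids[rev]
}

#' Serialize a network back to the OpenFLUX sheet dialect
#'
#' @param net An `mfa_network`.
#' @param path Optional output file (comma-separated); if `NULL`, the sheet
#'   data frame is returned.
#' @return The sheet data frame, invisibly when written to file.
#' @export
write_openflux <- function(net, path = NULL) {
  fmt_side <- function(df) {
    if (nrow(df) == 0) return("")
    paste(ifelse(df$coef == 1, df$met, paste(df$coef, df$met)),
          collapse = " + ")
  }
  fmt_trans <- function(tr) {
    if (length(tr) == 0) return("")
    paste(ifelse(nzchar(tr), tr, "X"), collapse = " + ")
  }
  rows <- lapply(net$reactions, function(r) {
    has_c <- any(nzchar(c(r$trans_lhs, r$trans_rhs)))
    data.frame(
      rxnID = r$id,
      rxnEQ = paste(fmt_side(r$lhs), "=", fmt_side(r$rhs)),
      rxnCTrans = if (has_c)
        paste(fmt_trans(r$trans_lhs), "=", fmt_trans(r$trans_rhs)) else "",
      rxnType = switch(r$kind,
                       internal = if (r$reversible) "FR" else "F",
                       uptake = "S", release = "B"),
      stringsAsFactors = FALSE)
  })
  sheet <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(sheet, path, row.names = FALSE, quote = TRUE)
    return(invisible(sheet))
  }
  sheet
}

#' Summarize a network as a JSON-ready report
#'
#' @param net An `mfa_network`.
#' @param path Optional path to write a JSON report.
#' @return A list with reaction, metabolite and free-flux counts.
#' @export
network_summary <- function(net, path = NULL) {
  basis <- free_flux_basis(net)
  out <- list(
    n_reactions = length(net$reactions),
    n_net_fluxes = length(net$reactions),
    n_internal = sum(reaction_ids(net) %in% reaction_ids(net, "internal")),
    n_balanced_metabolites = length(balanced_metabolites(net)),
    n_substrates = length(network_substrates(net)),
    n_free_fluxes = basis$n_free,
    n_reversible = length(reaction_ids_reversible(net)),
    validation = "ok")
  if (!is.null(path))
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  out
}
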