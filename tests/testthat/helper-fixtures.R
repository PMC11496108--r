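# Shared fixtures and small independent oracles.

sheet_of <- function(...) {
  rows <- list(...)
  data.frame(rxnID = vapply(rows, `[[`, "", 1),
             rxnEQ = vapply(rows, `[[`, "", 2),
             rxnCTrans = vapply(rows, `[[`, "", 3),
             rxnType = vapply(rows, `[[`, "", 4),
             stringsAsFactors = FALSE)
}

# independent matrix rank by Gaussian elimination with partial pivoting
rank_oracle <- function(M, tol = 1e-10) {
  M <- as.matrix(M)
  r <- 0
  for (j in seq_len(ncol(M))) {
    if (r == nrow(M)) break
    piv <- which.max(abs(M[(r + 1):nrow(M), j]))
    if (abs(M[r + piv, j]) < tol) next
    tmp <- M[r + 1, ]; M[r + 1, ] <- M[r + piv, ]; M[r + piv, ] <- tmp
    r <- r + 1
    for (i in seq_len(nrow(M))) {
      if (i != r && abs(M[i, j]) > 0)
        M[i, ] <- M[i, ] - M[i, j] / M[r, j] * M[r, ]
    }
  }
  r
}

# independent count of EMUs required for given targets: breadth-first
# predecessor closure over the atom maps, written directly against the
# parsed reaction structures
emu_closure_oracle <- function(net, targets) {
  roles <- stats::setNames(net$mets$role, net$mets$met)
  ncarb <- stats::setNames(net$mets$carbons, net$mets$met)
  key <- function(m, a) paste0(m, "[", paste(sort(a), collapse = ","), "]")
  seen <- character(0)
  queue <- lapply(targets, function(t) {
    if (is.character(t)) list(met = t, atoms = seq_len(ncarb[[t]])) else t
  })
  queue <- Filter(function(t) roles[[t$met]] == "balanced", queue)
  while (length(queue) > 0) {
    t <- queue[[1]]; queue[[1]] <- NULL
    k <- key(t$met, t$atoms)
    if (k %in% seen) next
    seen <- c(seen, k)
    for (r in net$reactions) {
      sides <- list(list(prods = r$rhs, ptr = r$trans_rhs,
                         subs = r$lhs, str = r$trans_lhs))
      if (r$reversible)
        sides <- c(sides, list(list(prods = r$lhs, ptr = r$trans_lhs,
                                    subs = r$rhs, str = r$trans_rhs)))
      for (sd in sides) {
        for (o in seq_len(nrow(sd$prods))) {
          if (sd$prods$met[o] != t$met || !nzchar(sd$ptr[o])) next
          want <- strsplit(sd$ptr[o], "")[[1]][t$atoms]
          for (s in seq_len(nrow(sd$subs))) {
            if (!nzchar(sd$str[s])) next
            pos <- which(strsplit(sd$str[s], "")[[1]] %in% want)
            if (length(pos) > 0 && roles[[sd$subs$met[s]]] == "balanced")
              queue[[length(queue) + 1L]] <- list(met = sd$subs$met[s],
                                                  atoms = pos)
          }
        }
      }
    }
  }
  length(seen)
}

liver_fit_cached <- local({
  cache <- new.env(parent = emptyenv())
  function(noise_sd = 0, seed = 1, n_starts = 2) {
    key <- paste(noise_sd, seed, n_starts, sep = "_")
    if (is.null(cache[[key]])) {
      m <- toy_liver_model()
      ds <- generate_dataset(m, noise_sd = noise_sd, seed = seed)
      fit <- fit_fluxes(m$net, ds$table, m$labeling, m$quantities,
                        n_starts = n_starts, seed = seed + 500,
                        bounds = list(flux_ub = 2000))
      cache[[key]] <- list(model = m, ds = ds, fit = fit)
    }
    cache[[key]]
  }
})
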