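# Independent brute-force oracle: enumerate all 2^n isotopomers per balanced
# metabolite and solve the species balances by damped Gauss-Seidel fixed-point
# iteration. Deliberately shares no simulation code with the EMU engine.

# isotopomer distribution (length 2^n, bit i-1 = atom i) of a substrate
oracle_substrate_iso <- function(labeling, met) {
  sm <- labeling[[met]]
  n <- sm$n
  out <- numeric(2^n)
  for (cmp in sm$components) {
    pr <- rep(1, 2^n)
    for (i in seq_len(n)) {
      bit <- bitwAnd(0:(2^n - 1), 2^(i - 1)) > 0
      pr <- pr * ifelse(bit, cmp$p[i], 1 - cmp$p[i])
    }
    out <- out + cmp$weight * pr
  }
  out
}

oracle_simulate <- function(net, flux, labeling, targets, tol = 1e-13,
                            maxit = 200000) {
  ncarb <- stats::setNames(net$mets$carbons, net$mets$met)
  roles <- stats::setNames(net$mets$role, net$mets$met)
  bal <- net$mets$met[net$mets$role == "balanced"]

  # unidirectional reactions with flux magnitudes
  uni <- list()
  for (r in net$reactions) {
    vk <- flux$net_flux[[r$id]]
    xk <- if (!is.null(flux$exchange_flux) &&
              r$id %in% names(flux$exchange_flux))
      flux$exchange_flux[[r$id]] else 0
    keep <- nzchar(r$trans_lhs)
    fw <- list(w = max(vk, 0) + if (r$reversible) xk else 0,
               smet = r$lhs$met[keep], str = r$trans_lhs[keep],
               pmet = r$rhs$met[nzchar(r$trans_rhs)],
               ptr = r$trans_rhs[nzchar(r$trans_rhs)])
    uni[[length(uni) + 1L]] <- fw
    if (r$reversible)
      uni[[length(uni) + 1L]] <- list(w = max(-vk, 0) + xk,
                                      smet = fw$pmet, str = fw$ptr,
                                      pmet = fw$smet, ptr = fw$str)
  }
  uni <- Filter(function(u) u$w > 0, uni)

  # per product occurrence: index map from joint substrate isotopomer index
  # (mixed radix over substrate occurrences) to product isotopomer index
  plans <- list()
  for (k in seq_along(uni)) {
    u <- uni[[k]]
    ns <- ncarb[u$smet]
    sizes <- 2^ns
    grid <- as.matrix(expand.grid(lapply(sizes, function(s) 0:(s - 1))))
    for (o in seq_along(u$pmet)) {
      pm <- u$pmet[o]
      if (roles[[pm]] != "balanced") next
      letters_p <- strsplit(u$ptr[o], "")[[1]]
      pidx <- rep(0L, nrow(grid))
      for (a in seq_along(letters_p)) {
        found <- FALSE
        for (s in seq_along(u$smet)) {
          pos <- regexpr(letters_p[a], u$str[s], fixed = TRUE)
          if (pos > 0) {
            bit <- bitwAnd(grid[, s], 2^(pos - 1)) > 0
            pidx <- pidx + as.integer(bit) * 2^(a - 1)
            found <- TRUE
            break
          }
        }
        stopifnot(found)
      }
      plans[[length(plans) + 1L]] <- list(k = k, pm = pm, pidx = pidx,
                                          smet = u$smet, w = u$w)
    }
  }

  cons <- stats::setNames(numeric(length(bal)), bal)
  for (u in uni) for (m in u$smet) if (m %in% bal)
    cons[m] <- cons[m] + u$w

  y <- lapply(stats::setNames(ncarb[bal], bal), function(n) {
    v <- numeric(2^n); v[1] <- 1; v
  })
  subiso <- lapply(stats::setNames(nm = names(labeling)), function(s)
    oracle_substrate_iso(labeling, s))

  getdist <- function(m) if (m %in% bal) y[[m]] else subiso[[m]]

  for (it in seq_len(maxit)) {
    delta <- 0
    for (m in bal) {
      acc <- numeric(length(y[[m]]))
      for (pl in plans) {
        if (pl$pm != m) next
        joint <- 1
        for (s in pl$smet) joint <- as.numeric(outer(joint, getdist(s)))
        contrib <- rowsum(joint, pl$pidx)
        acc[as.integer(rownames(contrib)) + 1L] <-
          acc[as.integer(rownames(contrib)) + 1L] + pl$w * contrib[, 1]
      }
      newy <- acc / cons[m]
      delta <- max(delta, max(abs(newy - y[[m]])))
      y[[m]] <- newy
    }
    if (delta < tol) break
  }
  if (delta >= tol) stop("oracle fixed point did not converge")

  out <- list()
  for (t in targets) {
    m <- if (is.character(t)) t else t$met
    dist <- getdist(m)
    n <- ncarb[[m]]
    pop <- vapply(0:(2^n - 1), function(b) sum(bitwAnd(b, 2^(0:(n - 1))) > 0),
                  numeric(1))
    out[[m]] <- as.numeric(rowsum(dist, pop))
  }
  out
}

# joint outer order: outer(joint, dist) flattens with earlier occurrences
# varying fastest, matching expand.grid's mixed-radix order used for pidx
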