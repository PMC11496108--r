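# Weighted least-squares flux fitting. The objective simulates MIDs inside
# the residual evaluation (nested mode): parameters are the free net fluxes,
# exchange fluxes of reversible reactions and free mixture coefficients;
# dependent fluxes follow from steady state. Sign constraints on dependent
# irreversible fluxes are enforced by a quadratic penalty; a solve only
# counts as converged when the violation is below tolerance.

# Construct the optimization problem. `fixed` pins reaction net fluxes (used
# by profile-likelihood CIs). Returns the objective and the parameter layout.
build_fit_problem <- function(net, table, labeling, quantities,
                              bounds = list(), fixed = numeric(),
                              decomp = NULL, penalty_weight = NULL) {
  basis <- free_flux_basis(net, fixed = fixed)
  ids <- reaction_ids(net)
  rev_ids <- reaction_ids_reversible(net)
  irrev <- setdiff(ids, rev_ids)

  flux_means <- table$mean[table$kind != "MI_fraction"]
  flux_scale <- max(abs(flux_means), 1)
  flux_ub <- bounds$flux_ub %||% (10 * flux_scale)
  xch_ub <- bounds$xch_ub %||% flux_ub

  nf <- basis$n_free
  free_ids <- basis$free_ids
  wp_names <- unique(unlist(lapply(quantities, `[[`, "weight_param")))
  wp_names <- wp_names[!is.null(wp_names)]
  par_names <- c(free_ids, if (length(rev_ids)) paste0("xch.", rev_ids),
                 wp_names)
  idx_w <- seq_len(nf)
  idx_x <- if (length(rev_ids)) nf + seq_along(rev_ids) else integer(0)
  idx_a <- if (length(wp_names)) nf + length(rev_ids) + seq_along(wp_names)
           else integer(0)

  lower <- c(ifelse(free_ids %in% rev_ids, -flux_ub, 0),
             rep(0, length(rev_ids)), rep(0, length(wp_names)))
  upper <- c(rep(flux_ub, nf), rep(xch_ub, length(rev_ids)),
             rep(1, length(wp_names)))

  mi_sel <- table$kind == "MI_fraction"
  mi_rows <- table[mi_sel, ]
  fl_rows <- table[!mi_sel, ]
  combos <- lapply(fl_rows$target, parse_flux_combo)

  qmap <- stats::setNames(quantities, vapply(quantities, `[[`, character(1),
                                             "id"))
  # EMU targets: every balanced metabolite appearing in a measured quantity
  if (is.null(decomp) && nrow(mi_rows) > 0) {
    bal <- balanced_metabolites(net)
    comp_mets <- unique(unlist(lapply(qmap[unique(mi_rows$target)],
                                      `[[`, "components")))
    comp_mets <- setdiff(sub("^fresh:", "", comp_mets), "")
    tmets <- union(intersect(comp_mets, bal),
                   intersect(comp_mets, network_substrates(net)))
    decomp <- emu_decompose(net, as.list(tmets))
  }

  sub_cache <- if (!is.null(decomp)) substrate_mid_cache(decomp, labeling)
  fresh_mids <- list()
  for (q in qmap) {
    for (cmp in q$components) {
      if (startsWith(cmp, "fresh:") && is.null(fresh_mids[[cmp]]))
        fresh_mids[[cmp]] <- substrate_full_mid(labeling,
                                                sub("^fresh:", "", cmp))
    }
  }
  used_q <- if (nrow(mi_rows) > 0) unique(mi_rows$target) else character(0)
  row_q <- match(mi_rows$target, used_q)
  row_mi <- mi_rows$mi + 1L

  quantity_mid <- function(q, sims, theta) {
    mids <- lapply(q$components, function(cmp) {
      if (startsWith(cmp, "fresh:")) fresh_mids[[cmp]] else sims[[cmp]]
    })
    wts <- if (!is.null(q$weight_param)) {
      a <- theta[idx_a[match(q$weight_param, wp_names)]]
      c(a, 1 - a)
    } else q$weights
    mix_mids(mids, wts)
  }

  pw <- penalty_weight %||% (1e7 / flux_scale^2)
  viol_fun <- function(v) sum(pmin(v[irrev], 0)^2)

  sim_values <- function(theta) {
    v <- basis$flux(theta[idx_w])
    viol <- viol_fun(v)
    xch <- stats::setNames(theta[idx_x], rev_ids)
    vs <- v; vs[irrev] <- pmax(vs[irrev], 0)
    sim_mi <- numeric(0)
    if (nrow(mi_rows) > 0) {
      sims <- simulate_mids(net, list(net_flux = vs, exchange_flux = xch),
                            labeling, decomp = decomp, sub_mids = sub_cache)
      qmids <- lapply(qmap[used_q], quantity_mid, sims = sims, theta = theta)
      sim_mi <- vapply(seq_along(row_q), function(i)
        qmids[[row_q[i]]][row_mi[i]], numeric(1))
    }
    sim_fl <- vapply(combos, function(cf) sum(cf * v[names(cf)]), numeric(1))
    list(v = v, sim = c(sim_mi, sim_fl), viol = viol)
  }

  residuals_fun <- function(theta) {
    sv <- sim_values(theta)
    res <- (sv$sim - c(mi_rows$mean, fl_rows$mean)) /
      c(mi_rows$sd_floored, fl_rows$sd_floored)
    list(res = res, viol = sv$viol, v = sv$v)
  }

  objective <- function(theta) {
    out <- tryCatch({
      r <- residuals_fun(theta)
      sum(r$res^2) + pw * r$viol
    }, error = function(e) {
      # simulation failed (dead pool / singular balance at this point);
      # fall back to a large but violation-guided value so the optimizer
      # can still move toward the feasible region
      v <- basis$flux(theta[idx_w])
      1e8 + pw * viol_fun(v)
    })
    if (!is.finite(out)) 1e12 else out
  }

  table_ord <- rbind(mi_rows, fl_rows)

  list(objective = objective, residuals = residuals_fun,
       sim_values = sim_values,
       lower = lower, upper = upper, par_names = par_names,
       n_par = length(par_names), basis = basis, decomp = decomp,
       idx_w = idx_w, idx_x = idx_x, idx_a = idx_a,
       free_ids = free_ids, rev_ids = rev_ids, wp_names = wp_names,
       irrev = irrev, flux_scale = flux_scale, flux_ub = flux_ub,
       penalty_weight = pw, table = table_ord, net = net,
       labeling = labeling, quantities = quantities, bounds = bounds)
}

# Draw a random feasible-ish start for the parameter vector.
random_start <- function(prob, rng_unif) {
  best <- NULL; best_viol <- Inf
  for (try in 1:50) {
    theta <- prob$lower + rng_unif(prob$n_par) * (prob$upper - prob$lower)
    if (length(prob$idx_x))
      theta[prob$idx_x] <- theta[prob$idx_x] * 0.1  # modest exchange starts
    v <- prob$basis$flux(theta[prob$idx_w])
    viol <- sum(pmin(v[prob$irrev], 0)^2)
    if (viol < best_viol) { best <- theta; best_viol <- viol }
    if (viol == 0) break
  }
  best
}

#' Fit a metabolic network model to measurements
#'
#' Minimizes the weighted sum of squared residuals between simulated and
#' measured MI fractions and fluxes over free net fluxes, exchange fluxes and
#' mixture coefficients, subject to steady state and bounds. The best of
#' `n_starts` local optimizations from seeded random starts is returned.
#'
#' @param net An `mfa_network`.
#' @param table A [assemble_measurements()] table.
#' @param labeling A `substrate_labeling`.
#' @param quantities List of [measured_quantity()].
#' @param n_starts Number of random multi-starts (default 10).
#' @param seed Integer seed for reproducible starts.
#' @param bounds List with optional `flux_ub`, `xch_ub`.
#' @param level Chi-square acceptance quantile (default 0.90).
#' @param control Passed to [stats::nlminb()] (defaults set internally).
#' @param theta0 Optional explicit start for the first local solve.
#' @return An `mfa_fit` object: optimal `flux_state`, `ssr`, per-row
#'   `residuals`, `dof`, `threshold`, `accepted`, `start_index`, per-start
#'   diagnostics, and the problem definition for downstream analyses.
#' @export
fit_fluxes <- function(net, table, labeling, quantities = list(),
                       n_starts = 10, seed = 1, bounds = list(),
                       level = 0.90, control = list(), theta0 = NULL) {
  prob <- build_fit_problem(net, table, labeling, quantities, bounds)
  ctl <- utils::modifyList(list(iter.max = 500, eval.max = 2000,
                                rel.tol = 1e-10), control)
  rng <- new_rng(seed)
  starts <- list()
  for (s in seq_len(n_starts)) {
    th0 <- if (s == 1 && !is.null(theta0)) theta0 else
      random_start(prob, rng$unif)
    opt <- stats::nlminb(th0, prob$objective, lower = prob$lower,
                         upper = prob$upper, control = ctl)
    r <- tryCatch(prob$residuals(opt$par), error = function(e) NULL)
    starts[[s]] <- list(theta = opt$par, objective = opt$objective,
                        ssr = if (is.null(r)) Inf else sum(r$res^2),
                        viol = if (is.null(r)) Inf else r$viol,
                        convergence = opt$convergence)
  }
  viols <- vapply(starts, `[[`, numeric(1), "viol")
  objs <- vapply(starts, `[[`, numeric(1), "objective")
  feasible <- viols < (1e-9 * prob$flux_scale^2)
  if (!any(feasible) || all(!is.finite(objs)))
    stop("no optimization start converged to a feasible solution; ",
         "violations: ", paste(signif(viols, 3), collapse = ", "))
  objs[!feasible] <- Inf
  best <- which.min(objs)
  theta <- starts[[best]]$theta
  r <- prob$residuals(theta)

  v <- r$v
  v[prob$irrev] <- pmax(v[prob$irrev], 0)
  xch <- stats::setNames(theta[prob$idx_x], prob$rev_ids)
  alphas <- stats::setNames(theta[prob$idx_a], prob$wp_names)
  mixc <- lapply(alphas, function(a) c(a, 1 - a))
  state <- list(net_flux = v, exchange_flux = xch,
                mixture_coefficients = mixc)
  class(state) <- "flux_state"

  n <- nrow(prob$table)
  p <- prob$n_par
  dof <- n - p
  ssr <- sum(r$res^2)
  threshold <- if (dof > 0) stats::qchisq(level, dof) else NA_real_
  resid_tab <- cbind(prob$table,
                     data.frame(simulated = r$res * prob$table$sd_floored +
                                  prob$table$mean,
                                residual = r$res^2))

  structure(list(flux_state = state, theta = theta, ssr = ssr,
                 residuals = resid_tab, n = n, p = p, dof = dof,
                 level = level, threshold = threshold,
                 accepted = is.finite(threshold) && ssr <= threshold,
                 start_index = best, starts = starts, problem = prob,
                 seed = seed),
            class = "mfa_fit")
}

#' @export
print.mfa_fit <- function(x, ...) {
  cat(sprintf("mfa_fit: SSR (chi2) = %.4g on %d measurements, %d parameters\n",
              x$ssr, x$n, x$p))
  cat(sprintf("  dof = %d, %.0f%% threshold = %.4g -> %s (start %d of %d)\n",
              x$dof, 100 * x$level, x$threshold,
              if (x$accepted) "ACCEPT" else "REJECT",
              x$start_index, length(x$starts)))
  invisible(x)
}

#' Rank measurements by their chi-square residual
#'
#' @param fit An `mfa_fit`.
#' @return The residual table sorted by decreasing squared weighted residual;
#'   the `residual` column sums to the fit SSR.
#' @export
residual_influence <- function(fit) {
  tab <- fit$residuals
  tab[order(tab$residual, decreasing = TRUE), ]
}

# Small counter-based uniform RNG wrapper so every consumer of randomness in
# the package draws from one seeded stream without touching .Random.seed.
new_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- as.integer(seed)
  unif <- function(n) {
    out <- withr_seed(env, function() stats::runif(n))
    out
  }
  norm <- function(n) withr_seed(env, function() stats::rnorm(n))
  list(unif = unif, norm = norm)
}

# Run fn under a private RNG state stored in env, advancing it.
withr_seed <- function(env, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  if (is.null(env$rs)) {
    set.seed(env$state)
    env$rs <- get(".Random.seed", globalenv())
  }
  assign(".Random.seed", env$rs, globalenv())
  out <- fn()
  env$rs <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  out
}
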