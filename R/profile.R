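# Profile-likelihood confidence intervals: push one net flux away from its
# optimum, re-optimize all remaining parameters under the pinned value (an
# exact linear constraint absorbed into the free-flux basis), and find where
# the chi-square objective rises by the 1-dof quantile.

profile_ssr <- function(fit, reaction, t, warm, ctl) {
  prob0 <- fit$problem
  prob <- build_fit_problem(prob0$net, prob0$table, prob0$labeling,
                            prob0$quantities, bounds = prob0$bounds,
                            fixed = stats::setNames(t, reaction),
                            decomp = prob0$decomp,
                            penalty_weight = prob0$penalty_weight)
  # warm start: map the previous full flux vector onto the new free set
  th0 <- c(warm$v[prob$free_ids],
           warm$theta[c(prob0$idx_x, prob0$idx_a)])
  th0 <- pmin(pmax(th0, prob$lower), prob$upper)
  if (length(th0) == 0) {
    r <- prob$residuals(numeric(0))
    return(list(ssr = sum(r$res^2), viol = r$viol,
                warm = warm, feasible = r$viol < 1e-9 * prob$flux_scale^2))
  }
  opt <- stats::nlminb(th0, prob$objective, lower = prob$lower,
                       upper = prob$upper, control = ctl)
  r <- prob$residuals(opt$par)
  list(ssr = sum(r$res^2), viol = r$viol,
       warm = list(v = r$v, theta = c(rep(0, length(prob0$idx_w)),
                                      opt$par[-seq_along(prob$idx_w)])),
       feasible = r$viol < 1e-9 * prob$flux_scale^2)
}

#' Profile-likelihood confidence interval for a net flux
#'
#' @param fit An `mfa_fit` from [fit_fluxes()].
#' @param reaction Reaction id to profile.
#' @param level Confidence level (default 0.90; the objective increase is the
#'   chi-square 1-dof quantile, 2.706 at 0.90).
#' @param step_frac Initial step as a fraction of the flux scale.
#' @param rel_tol Bisection tolerance relative to the flux scale.
#' @param maxit Iteration cap per re-optimization.
#' @return A `flux_ci` list: `reaction`, `estimate`, `lower`, `upper`,
#'   `level`, and `open_lower`/`open_upper` flags set when the profile ran
#'   into the configured flux bounds without crossing the threshold
#'   (structural non-identifiability).
#' @export
profile_ci <- function(fit, reaction, level = 0.90, step_frac = 0.05,
                       rel_tol = 0.005, maxit = 200) {
  prob <- fit$problem
  if (!reaction %in% reaction_ids(prob$net))
    stop("unknown reaction '", reaction, "'")
  delta <- stats::qchisq(level, df = 1)
  limit <- fit$ssr + delta
  vhat <- fit$flux_state$net_flux[[reaction]]
  scale <- max(abs(vhat), prob$flux_scale * 0.1)
  ctl <- list(iter.max = maxit, eval.max = 4 * maxit, rel.tol = 1e-9)
  lb <- if (reaction %in% prob$irrev) 0 else -prob$flux_ub
  ub <- prob$flux_ub

  one_side <- function(dir) {
    bound <- if (dir > 0) ub else lb
    h <- step_frac * scale
    t_in <- vhat
    warm <- list(v = fit$flux_state$net_flux, theta = fit$theta)
    ssr_in <- fit$ssr
    open <- FALSE
    t_out <- NULL
    repeat {
      t_try <- vhat + dir * h
      hit_bound <- (dir > 0 && t_try >= bound) || (dir < 0 && t_try <= bound)
      if (hit_bound) t_try <- bound
      pr <- profile_ssr(fit, reaction, t_try, warm, ctl)
      if (pr$feasible && pr$ssr <= limit) {
        t_in <- t_try; warm <- pr$warm; ssr_in <- pr$ssr
        if (hit_bound) { open <- TRUE; break }
        h <- h * 2
      } else {
        t_out <- t_try
        break
      }
    }
    if (open) return(list(value = bound, open = TRUE))
    # bisect between t_in (inside) and t_out (outside)
    while (abs(t_out - t_in) > rel_tol * scale) {
      t_mid <- (t_in + t_out) / 2
      pr <- profile_ssr(fit, reaction, t_mid, warm, ctl)
      if (pr$feasible && pr$ssr <= limit) {
        t_in <- t_mid; warm <- pr$warm
      } else t_out <- t_mid
    }
    list(value = (t_in + t_out) / 2, open = FALSE)
  }

  up <- one_side(+1)
  dn <- one_side(-1)
  structure(list(reaction = reaction, estimate = vhat,
                 lower = dn$value, upper = up$value, level = level,
                 open_lower = dn$open, open_upper = up$open),
            class = "flux_ci")
}

#' @export
print.flux_ci <- function(x, ...) {
  cat(sprintf("%s: %.4g [%s%.4g, %.4g%s] (%.0f%% profile likelihood)\n",
              x$reaction, x$estimate,
              if (x$open_lower) "<=" else "", x$lower, x$upper,
              if (x$open_upper) ">=" else "", 100 * x$level))
  invisible(x)
}

#' Profile-likelihood CIs for several reactions
#'
#' @param fit An `mfa_fit`.
#' @param reactions Character vector of reaction ids (default: all).
#' @param ... Passed to [profile_ci()].
#' @return Data frame with estimate, lower, upper and open-end flags.
#' @export
profile_ci_table <- function(fit, reactions = NULL, ...) {
  reactions <- reactions %||% reaction_ids(fit$problem$net)
  cis <- lapply(reactions, function(r) profile_ci(fit, r, ...))
  do.call(rbind, lapply(cis, function(ci)
    data.frame(reaction = ci$reaction, estimate = ci$estimate,
               lower = ci$lower, upper = ci$upper,
               open_lower = ci$open_lower, open_upper = ci$open_upper,
               level = ci$level, stringsAsFactors = FALSE)))
}
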