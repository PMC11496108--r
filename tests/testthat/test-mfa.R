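test_that("assemble_measurements counts rows and floors sds", {
  m <- toy_liver_model()
  mi <- data.frame(quantity = "GLC.tis", mi = 0:6,
                   mean = c(0.4, rep(0.1, 6)), sd = 0.001)
  fl <- data.frame(target = "LAC_rel", mean = 120, sd = 8)
  lit <- data.frame(target = "CO2_rel", mean = 540, sd = 50)
  tab <- assemble_measurements(m$net, m$quantities, mi_rows = mi,
                               flux_rows = fl, literature_rows = lit)
  expect_equal(attr(tab, "n"), 9)
  expect_equal(tab$sd_floored[tab$kind == "MI_fraction"], rep(0.03, 7))
  expect_equal(tab$sd_floored[tab$kind != "MI_fraction"], c(8, 50))

  # empty MID input: table of flux rows only
  tab2 <- assemble_measurements(m$net, m$quantities, flux_rows = fl)
  expect_equal(nrow(tab2), 1)

  expect_error(assemble_measurements(m$net, m$quantities,
                                     mi_rows = data.frame(quantity = "nope",
                                                          mi = 0, mean = 1,
                                                          sd = 0.1)),
               "undeclared quantities")
  expect_error(assemble_measurements(m$net, m$quantities,
                                     flux_rows = data.frame(target = "GLX",
                                                            mean = 1,
                                                            sd = 1)),
               "unknown reaction")
})

test_that("chi2_threshold reproduces standard quantiles", {
  expect_equal(round(chi2_threshold(149, 69, 0.90), 1), 96.6)
  expect_equal(chi2_threshold(2, 1, 0.90), 2.706, tolerance = 1e-3)
  expect_error(chi2_threshold(10, 10), "degrees of freedom")
})

test_that("noise-free fit recovers the ground truth", {
  fx <- liver_fit_cached(noise_sd = 0, seed = 1)
  fit <- fx$fit
  expect_lt(fit$ssr, 1e-6)
  rep <- recovery_report(fx$ds$truth, fit)
  expect_lt(max(rep$fluxes$rel_error), 1e-3)
  expect_equal(fit$flux_state$mixture_coefficients$alpha_GLCmed[1],
               fx$model$alpha_true, tolerance = 1e-3)
  # best-of-n contract
  cand <- vapply(fit$starts, `[[`, numeric(1), "ssr")
  expect_true(all(fit$ssr <= cand + 1e-9))
  # residuals sum to SSR
  expect_equal(sum(fit$residuals$residual), fit$ssr, tolerance = 1e-9)
  expect_true(fit$accepted)
})

test_that("a 10-sd perturbation raises the objective by ~100", {
  fx <- liver_fit_cached(noise_sd = 0, seed = 1)
  fit <- fx$fit
  tab <- fx$ds$table
  i <- which(tab$kind == "MI_fraction")[5]
  tab$mean[i] <- tab$mean[i] + 10 * tab$sd_floored[i]
  prob <- sliceMFA:::build_fit_problem(fx$model$net, tab, fx$model$labeling,
                                       fx$model$quantities,
                                       bounds = list(flux_ub = 2000))
  # at the old optimum the perturbed residual contributes exactly 10^2
  expect_equal(prob$objective(fit$theta), fit$ssr + 100, tolerance = 1e-6)
  # refitting can only reduce it, and the perturbed row dominates residuals
  fit2 <- fit_fluxes(fx$model$net, tab, fx$model$labeling,
                     fx$model$quantities, n_starts = 1, seed = 1,
                     bounds = list(flux_ub = 2000), theta0 = fit$theta)
  expect_lte(fit2$ssr, 100 + 1e-6)
  top <- residual_influence(fit2)[1, ]
  expect_equal(top$target, tab$target[i])
  expect_equal(top$mi, tab$mi[i])
  expect_equal(sum(residual_influence(fit2)$residual), fit2$ssr,
               tolerance = 1e-9)
})

test_that("residual influence of a perfect fit is zero everywhere", {
  fx <- liver_fit_cached(noise_sd = 0, seed = 1)
  expect_lt(max(residual_influence(fx$fit)$residual), 1e-7)
})

test_that("profile CI matches the linear-Gaussian closed form", {
  net <- parse_openflux(sheet_of(
    c("up", "Ax = A", "ab = ab", "S"),
    c("out", "A = Ay", "ab = ab", "B")))
  fl <- data.frame(target = "out", mean = 10, sd = 2)
  tab <- assemble_measurements(net, list(), flux_rows = fl)
  lab <- substrate_labeling(net)
  fit <- fit_fluxes(net, tab, lab, list(), n_starts = 2, seed = 1,
                    bounds = list(flux_ub = 100))
  expect_equal(unname(fit$flux_state$net_flux["out"]), 10, tolerance = 1e-5)
  ci <- profile_ci(fit, "out", rel_tol = 0.002)
  expect_equal(ci$lower, 10 - 1.645 * 2, tolerance = 0.05)
  expect_equal(ci$upper, 10 + 1.645 * 2, tolerance = 0.05)
  expect_true(ci$lower <= ci$estimate && ci$estimate <= ci$upper)
})

test_that("structurally unidentifiable routes give open-ended CIs", {
  net <- parse_openflux(sheet_of(
    c("up", "Ax = A", "a = a", "S"),
    c("r1", "A = B", "a = a", "F"),
    c("r2", "A = B", "a = a", "F"),
    c("out", "B = Bx", "a = a", "B")))
  fl <- data.frame(target = "up", mean = 10, sd = 1)
  tab <- assemble_measurements(net, list(), flux_rows = fl)
  fit <- fit_fluxes(net, tab, substrate_labeling(net), list(),
                    n_starts = 2, seed = 3, bounds = list(flux_ub = 50))
  # r1 and r2 split the measured uptake with no data to separate them: the
  # lower end runs to the configured bound at 0 and is flagged open
  ci <- profile_ci(fit, "r1")
  expect_true(ci$open_lower)
  expect_equal(ci$lower, 0, tolerance = 1e-6)

  # a futile cycle is unbounded above without labeling
  cyc <- parse_openflux(sheet_of(
    c("up", "Ax = A", "a = a", "S"),
    c("f", "A = B", "a = a", "F"),
    c("b", "B = A", "a = a", "F"),
    c("out", "B = Bx", "a = a", "B")))
  tab2 <- assemble_measurements(cyc, list(), flux_rows = fl)
  fit2 <- fit_fluxes(cyc, tab2, substrate_labeling(cyc), list(),
                     n_starts = 2, seed = 3, bounds = list(flux_ub = 50))
  ci2 <- profile_ci(fit2, "f")
  expect_true(ci2$open_upper)
  expect_equal(ci2$upper, 50, tolerance = 1e-6)
})

test_that("carbon flow conserves carbon and discounts exchanged species", {
  m <- toy_liver_model()
  cf <- carbon_flow(m$net, m$truth, discount_exchange = FALSE)
  total_in <- sum(substrate_carbon_uptake(m$net, m$truth))
  expect_equal(sum(cf$flow), total_in, tolerance = 1e-6 * total_in)
  # per-substrate conservation is stronger and also holds
  per_sub <- rowSums(cf$flow)
  up <- substrate_carbon_uptake(m$net, m$truth)
  expect_equal(per_sub[names(up)], up, tolerance = 1e-6)

  # glucose is taken up and released: its column is discounted to zero
  cf2 <- carbon_flow(m$net, m$truth, discount_exchange = TRUE)
  expect_true(all(cf2$enrichment[, "GLC_rel"] == 0))
  expect_true(all(cf2$flow >= 0))
  expect_true(all(cf2$enrichment >= 0 & cf2$enrichment <= 1))
})

test_that("carbon flow splits a shared product by substrate influx", {
  net <- parse_openflux(sheet_of(
    c("upA", "Ax = A", "a = a", "S"),
    c("upB", "Bx = B", "a = a", "S"),
    c("ra", "A = C", "a = a", "F"),
    c("rb", "B = C", "a = a", "F"),
    c("out", "C = Cx", "a = a", "B")))
  fs <- list(net_flux = c(upA = 3, upB = 1, ra = 3, rb = 1, out = 4),
             exchange_flux = numeric())
  cf <- carbon_flow(net, fs)
  expect_equal(unname(cf$enrichment["Ax", "out"]), 0.75, tolerance = 1e-12)
  expect_equal(unname(cf$enrichment["Bx", "out"]), 0.25, tolerance = 1e-12)
  expect_equal(unname(cf$flow["Ax", "out"]), 3, tolerance = 1e-12)
})

test_that("label-free FVA pins determined chains and frees cycles", {
  chain <- parse_openflux(sheet_of(
    c("up", "Ax = A", "a = a", "S"),
    c("mid", "A = B", "a = a", "F"),
    c("out", "B = Bx", "a = a", "B")))
  fl <- data.frame(target = "up", mean = 10, sd = 1e-6)
  fva <- label_free_fva(chain, fl, bounds = list(flux_ub = 100))
  r <- fva[fva$reaction == "mid", ]
  expect_equal(r$min, 10, tolerance = 1e-3)
  expect_equal(r$max, 10, tolerance = 1e-3)
  expect_true(r$bounded)

  cyc <- parse_openflux(sheet_of(
    c("up", "Ax = A", "a = a", "S"),
    c("f", "A = B", "a = a", "F"),
    c("b", "B = A", "a = a", "F"),
    c("out", "B = Bx", "a = a", "B")))
  fva2 <- label_free_fva(cyc, fl, bounds = list(flux_ub = 100))
  rf <- fva2[fva2$reaction == "f", ]
  expect_true(rf$at_upper_bound)  # internal cycle: unbounded without labeling
  expect_false(rf$bounded)
})
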