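test_that("parse_openflux handles identity, condensation and type rows", {
  net <- parse_openflux(sheet_of(
    c("up", "Ax = A", "ab = ab", "S"),
    c("v1", "A = B", "ab = ab", "F"),
    c("out", "B = Bx", "ab = ab", "B")))
  expect_s3_class(net, "mfa_network")
  expect_length(net$reactions, 3)
  expect_false(net$reactions[[2]]$reversible)
  expect_equal(net$mets$carbons[net$mets$met == "A"], 2)
  expect_equal(net$mets$carbons[net$mets$met == "B"], 2)

  net2 <- parse_openflux(sheet_of(
    c("upA", "Ax = A", "a = a", "S"),
    c("upB", "Bx = B", "b = b", "S"),
    c("v2", "A + B = C", "a + b = ab", "F"),
    c("out", "C = Cx", "ab = ab", "B")))
  expect_equal(net2$mets$carbons[net2$mets$met == "C"], 2)
})

test_that("parse_openflux rejects malformed models", {
  expect_error(parse_openflux(sheet_of(c("bad", "A = B", "ab = abc", "F"))),
               "carbon letters unbalanced")
  expect_error(parse_openflux(sheet_of(
    c("v1", "A = B", "ab = ab", "F"),
    c("v2", "B = A", "abc = abc", "F"))),
    "inconsistent carbon count")
  expect_error(parse_openflux(sheet_of(c("v1", "A = B", "ab = ab", "Q"))),
               "unknown reaction type")
  expect_error(parse_openflux(sheet_of(c("v1", "A = B", "aa = aa", "F"))),
               "duplicate carbon letter")
})

test_that("reverse rows merge into reversible reactions", {
  net <- parse_openflux(sheet_of(
    c("v1", "A = B", "ab = ab", "FR"),
    c("v1_b", "B = A", "ab = ab", "R")))
  expect_length(net$reactions, 1)
  expect_true(net$reactions[[1]]$reversible)
  expect_error(parse_openflux(sheet_of(c("v9_b", "B = A", "ab = ab", "R"))),
               "no matching forward row")
})

test_that("file parsing auto-detects delimiter and round-trips", {
  net <- toy_liver_model()$net
  path <- withr::local_tempfile(fileext = ".csv")
  write_openflux(net, path)
  net2 <- parse_openflux(path)
  expect_equal(write_openflux(net), write_openflux(net2))
  expect_equal(balanced_metabolites(net), balanced_metabolites(net2))
  expect_equal(stoichiometric_matrix(net), stoichiometric_matrix(net2))
  # tab-delimited variant
  tsv <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(write_openflux(net), tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_equal(write_openflux(parse_openflux(tsv)), write_openflux(net))
})

test_that("stoichiometric_matrix has signed entries and the right null space", {
  net <- parse_openflux(sheet_of(
    c("up", "Ax = A", "a = a", "S"),
    c("v1", "A = B", "a = a", "F"),
    c("out", "B = Bx", "a = a", "B")))
  S <- stoichiometric_matrix(net)
  expect_equal(S["A", "v1"], -1)
  expect_equal(S["B", "v1"], 1)
  # cyclic A->B->A: rows sum to zero at equal fluxes
  net2 <- parse_openflux(sheet_of(
    c("f", "A = B", "a = a", "F"),
    c("b", "B = A", "a = a", "F"),
    c("up", "Ax = A", "a = a", "S"),
    c("out", "A = Ay", "a = a", "B")))
  S2 <- stoichiometric_matrix(net2)
  expect_equal(as.numeric(S2 %*% c(3, 3, 5, 5)), c(0, 0))
  # null-space dimension equals reactions - rank (independent rank oracle)
  for (net_i in list(net, net2, toy_liver_model()$net)) {
    S_i <- stoichiometric_matrix(net_i)
    expect_equal(free_flux_basis(net_i)$null_dim,
                 ncol(S_i) - rank_oracle(S_i))
  }
})

test_that("free_flux_basis parameterizes steady-state flux space", {
  chain <- parse_openflux(sheet_of(
    c("r1", "A = B", "a = a", "F"),
    c("r2", "B = C", "a = a", "F"),
    c("up", "Ax = A", "a = a", "S"),
    c("outC", "C = Cx", "a = a", "B")))
  b <- free_flux_basis(chain)
  expect_equal(b$n_free, 1)
  v <- b$flux(5)
  expect_equal(unname(v[c("r1", "r2")]), c(5, 5))
  b0 <- free_flux_basis(chain, fixed = c(up = 5))
  expect_equal(b0$n_free, 0)
  expect_equal(unname(b0$flux(numeric(0))[c("r1", "r2")]), c(5, 5))

  div <- parse_openflux(sheet_of(
    c("up", "Ax = A", "a = a", "S"),
    c("vb", "A = B", "a = a", "F"),
    c("vc", "A = C", "a = a", "F"),
    c("outB", "B = Bx", "a = a", "B"),
    c("outC", "C = Cx", "a = a", "B")))
  b2 <- free_flux_basis(div, fixed = c(up = 10))
  expect_equal(b2$n_free, 1)
  v2 <- b2$flux(4)
  expect_equal(unname(v2["up"]), 10)
  expect_equal(unname(v2["vb"] + v2["vc"]), 10)

  expect_error(free_flux_basis(chain, fixed = c(r1 = 1, r2 = 2)),
               "linearly dependent")
})

test_that("free_flux_basis fluxes are steady-state balanced (property)", {
  net <- toy_liver_model()$net
  S <- stoichiometric_matrix(net)
  b <- free_flux_basis(net)
  rng_vals <- withr::with_seed(
    99, matrix(stats::runif(b$n_free * 20, -50, 400), ncol = b$n_free))
  for (i in seq_len(nrow(rng_vals))) {
    v <- b$flux(rng_vals[i, ])
    expect_lt(max(abs(S %*% v)), 1e-6 * max(1, max(abs(v))))
    # the reported free fluxes are reproduced exactly
    expect_equal(unname(v[b$free_ids]), unname(rng_vals[i, ]))
  }
})

test_that("flux_state validates balance, signs and mixtures", {
  m <- toy_liver_model()
  expect_s3_class(m$truth, "flux_state")
  bad <- m$truth$net_flux
  bad["GK"] <- bad["GK"] + 50
  expect_error(flux_state(m$net, bad), "steady state")
  bad2 <- m$truth$net_flux
  bad2["GK"] <- -1  # also violates balance, but sign is checked first
  expect_error(flux_state(m$net, bad2), "negative net flux")
  expect_error(flux_state(m$net, m$truth$net_flux,
                          mixture_coefficients = list(a = c(0.6, 0.6))),
               "convex")
})

test_that("network_summary reports counts and free fluxes", {
  net <- toy_liver_model()$net
  s <- network_summary(net)
  expect_equal(s$n_reactions, 20)
  expect_equal(s$n_balanced_metabolites, 11)
  expect_equal(s$n_free_fluxes, 9)
})
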