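test_that("emu_decompose traces chains, convolutions and closures", {
  chain <- parse_openflux(sheet_of(
    c("up", "Ax = A", "ab = ab", "S"),
    c("r1", "A = B", "ab = ab", "F"),
    c("out", "B = Bx", "ab = ab", "B")))
  d <- emu_decompose(chain, list(list(met = "B", atoms = 1:2)))
  expect_setequal(names(d$emus), c("B|1,2", "A|1,2"))

  cond <- parse_openflux(sheet_of(
    c("upA", "Ax = A", "a = a", "S"),
    c("upB", "Bx = B", "b = b", "S"),
    c("v", "A + B = C", "a + b = ab", "F"),
    c("out", "C = Cx", "ab = ab", "B")))
  d2 <- emu_decompose(cond, list(list(met = "C", atoms = 1:2)))
  # C{1,2} is formed by convolution of the one-carbon EMUs A{1} and B{1}
  expect_setequal(names(d2$emus), c("C|1,2", "A|1", "B|1"))
  lv2 <- d2$levels[[which(vapply(d2$levels, `[[`, 0L, "size") == 2)]]
  expect_length(lv2$known, 1)
  expect_equal(length(lv2$known[[1]]$sources), 2)
  expect_setequal(vapply(lv2$known[[1]]$sources, `[[`, "", "key"),
                  c("A|1", "B|1"))

  # EMU counts match the independent predecessor-closure oracle on all toys
  for (b in toy_networks()) {
    d_i <- emu_decompose(b$net, b$targets)
    expect_equal(length(d_i$emus), emu_closure_oracle(b$net, b$targets))
  }

  orphan <- parse_openflux(sheet_of(
    c("out", "B = Bx", "ab = ab", "B"),
    c("up", "Ax = A", "ab = ab", "S"),
    c("r1", "A = C", "ab = ab", "F"),
    c("outC", "C = Cy", "ab = ab", "B")))
  expect_error(emu_decompose(orphan, list("B")), "unreachable")
})

test_that("simulate_mids reproduces degenerate cases exactly", {
  m <- toy_liver_model()
  unlab <- substrate_labeling(m$net)  # everything unlabeled
  sims <- simulate_mids(m$net, m$truth, unlab,
                        targets = list("GLC", "CIT", "CO2"))
  for (s in sims) {
    expect_equal(s[1], 1, tolerance = 1e-12)
    expect_equal(sum(s), 1, tolerance = 1e-12)
  }

  chain <- parse_openflux(sheet_of(
    c("up", "Ax = A", "abc = abc", "S"),
    c("r1", "A = B", "abc = abc", "F"),
    c("out", "B = Bx", "abc = abc", "B")))
  mu <- c(0.2, 0.3, 0.4, 0.1)
  lab <- substrate_labeling(chain, list(
    Ax = labeling_mixture(list(labeling_positional(c(1, 1, 1)),
                               labeling_positional(c(1, 1, 0)),
                               labeling_positional(c(1, 0, 0)),
                               labeling_unlabeled(3)),
                          weights = c(0.1, 0.4, 0.3, 0.2))))
  sims2 <- simulate_mids(chain, list(net_flux = c(up = 2, r1 = 2, out = 2)),
                         lab, targets = list("B"))
  expect_equal(sims2$B, c(0.2, 0.3, 0.4, 0.1), tolerance = 1e-12)

  cond <- parse_openflux(sheet_of(
    c("upA", "Ax = A", "a = a", "S"),
    c("upB", "Bx = B", "b = b", "S"),
    c("v", "A + B = C", "a + b = ab", "F"),
    c("out", "C = Cx", "ab = ab", "B")))
  lab3 <- substrate_labeling(cond, list(Ax = labeling_positional(1)))
  s3 <- simulate_mids(cond, list(net_flux = c(upA = 1, upB = 1, v = 1,
                                              out = 1)),
                      lab3, targets = list("C"))
  expect_equal(s3$C, c(0, 1, 0), tolerance = 1e-12)
})

test_that("simulate_mids agrees with the brute-force isotopomer oracle", {
  for (nm in names(toy_networks())) {
    b <- toy_networks()[[nm]]
    rev_ids <- names(which(vapply(b$net$reactions, function(r) r$reversible,
                                  logical(1))))
    for (s in 1:5) {
      v <- sample_flux_state(b$net, flux_ub = 10, seed = s)
      rng <- sliceMFA:::new_rng(s * 13 + 7)
      xch <- stats::setNames(rng$unif(length(rev_ids)) * 3, rev_ids)
      fs <- list(net_flux = v, exchange_flux = xch)
      emu <- simulate_mids(b$net, fs, b$labeling, targets = b$targets)
      orc <- oracle_simulate(b$net, fs, b$labeling, targets = b$targets)
      for (t in names(emu)) {
        expect_lt(max(abs(emu[[t]] - orc[[t]])), 1e-10)
        expect_gt(min(emu[[t]]), -1e-9)
        expect_equal(sum(emu[[t]]), 1, tolerance = 1e-9)
      }
    }
  }
})

test_that("simulation is linear in single-substrate labeling", {
  # holds for networks without condensation reactions (no convolutions);
  # the scramble toy is purely unimolecular
  b <- toy_networks()$scramble
  net <- b$net
  fs <- list(net_flux = sample_flux_state(net, flux_ub = 8, seed = 3),
             exchange_flux = c(rev = 1.1))
  mu1 <- labeling_positional(c(1, 0, 1))
  mu2 <- labeling_positional(c(0, 1, 0))
  lam <- 0.3
  mix <- labeling_mixture(list(mu1, mu2), c(lam, 1 - lam))
  r1 <- simulate_mids(net, fs, substrate_labeling(net, list(Ax = mu1)),
                      targets = b$targets)
  r2 <- simulate_mids(net, fs, substrate_labeling(net, list(Ax = mu2)),
                      targets = b$targets)
  rm_ <- simulate_mids(net, fs, substrate_labeling(net, list(Ax = mix)),
                       targets = b$targets)
  for (t in names(rm_))
    expect_equal(rm_[[t]], lam * r1[[t]] + (1 - lam) * r2[[t]],
                 tolerance = 1e-10)
})

test_that("condensation product enrichment is the carbon-weighted mean", {
  x <- c(0.1, 0.5, 0.4)         # 2 carbons
  y <- c(0.3, 0.2, 0.2, 0.3)    # 3 carbons
  z <- sliceMFA:::mid_convolve(x, y)
  expect_equal(enrichment(z, 5),
               (2 * enrichment(x, 2) + 3 * enrichment(y, 3)) / 5,
               tolerance = 1e-12)
})

test_that("mix_mids and spent_medium_mid implement convex mixtures", {
  a <- c(1, 0, 0); b <- c(0, 0, 1)
  expect_equal(mix_mids(list(a, b), c(1, 0)), a)
  expect_equal(mix_mids(list(c(1, 0), c(0, 1)), c(0.5, 0.5)), c(0.5, 0.5))
  expect_equal(mix_mids(list(a, b, c(0, 1, 0)), rep(1 / 3, 3)),
               c(1, 1, 1) / 3)
  expect_error(mix_mids(list(c(1, 0), c(1, 0, 0)), c(0.5, 0.5)),
               "mismatched carbon")
  expect_error(mix_mids(list(a, b), c(0.7, 0.7)), "convex")

  fresh <- c(0, 0, 1); intra <- c(0.4, 0.4, 0.2)
  expect_equal(spent_medium_mid(fresh, intra, 1), fresh)
  expect_equal(spent_medium_mid(fresh, intra, 0), intra)
  expect_equal(spent_medium_mid(fresh, intra, 0.5), (fresh + intra) / 2)
})

test_that("zero-throughput pools prune or error appropriately", {
  net <- parse_openflux(sheet_of(
    c("up", "Ax = A", "a = a", "S"),
    c("r1", "A = B", "a = a", "F"),
    c("side", "A = C", "a = a", "F"),
    c("r2", "C = B", "a = a", "F"),
    c("out", "B = Bx", "a = a", "B")))
  lab <- substrate_labeling(net, list(Ax = labeling_positional(1)))
  # dead side branch: prune silently, main chain unaffected
  fs <- list(net_flux = c(up = 2, r1 = 2, side = 0, r2 = 0, out = 2))
  s <- simulate_mids(net, fs, lab, targets = list("B"))
  expect_equal(s$B, c(0, 1), tolerance = 1e-12)
  # dead pool feeding a target: error naming the pool
  expect_error(simulate_mids(net, fs, lab, targets = list("C")),
               "zero-throughput")
})
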