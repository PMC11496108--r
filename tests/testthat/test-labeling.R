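test_that("areas_to_mid normalizes and flags missing", {
  expect_equal(areas_to_mid(c(100, 0, 0), n = 2), c(1, 0, 0))
  expect_equal(areas_to_mid(c(50, 50), n = 1), c(0.5, 0.5))
  expect_null(areas_to_mid(c(0, 0), n = 1))
  expect_equal(areas_to_mid(c(30, 10), n = 3), c(0.75, 0.25, 0, 0))
})

test_that("collision_filter removes only excessive MI >= 1 peaks", {
  # n = 6: expected natural M1 fraction is 6 * 0.0107 * 0.9893^5 = 0.0608
  unl <- natural_mid(6)
  unl[2] <- 0.12; unl[1] <- unl[1] - (0.12 - natural_mid(6)[2])
  keep <- collision_filter(unl, 6)
  expect_false(keep[2])   # excess 0.059 > 0.05
  unl2 <- natural_mid(6)
  unl2[2] <- 0.08; unl2[1] <- unl2[1] - (0.08 - natural_mid(6)[2])
  expect_true(collision_filter(unl2, 6)[2])  # excess 0.019 <= 0.05
  # M0 always kept even though an unlabeled compound exceeds binomial M0
  pure_m0 <- c(1, rep(0, 6))
  expect_true(collision_filter(pure_m0, 6)[1])
  expect_warning(k <- collision_filter(NULL, 4), "no unlabeled control")
  expect_true(all(k))
})

test_that("binomial_correct inverts the natural-abundance transform", {
  expect_equal(binomial_correct(natural_mid(2)), c(1, 0, 0),
               tolerance = 1e-9)
  for (n in c(1, 3, 6, 9)) {
    expect_equal(binomial_correct(natural_mid(n)),
                 c(1, rep(0, n)), tolerance = 1e-9)
  }
  x <- c(0.2, 0.3, 0.5)
  expect_equal(binomial_correct(x, p_nat = 0), x)
  expect_equal(binomial_correct(c(0, 0, 0, 1)), c(0, 0, 0, 1))
  # round trip at several abundances (property)
  rng <- sliceMFA:::new_rng(17)
  for (i in 1:25) {
    n <- 1 + (i %% 6)
    x <- rng$unif(n + 1); x <- x / sum(x)
    p <- rng$unif(1) * 0.02
    expect_equal(binomial_correct(binomial_convolve(x, p), p), x,
                 tolerance = 1e-9)
  }
})

test_that("enrichment matches the mean-label formula", {
  expect_equal(enrichment(c(1, 0, 0, 0)), 0)
  expect_equal(enrichment(c(0, 0, 0, 1)), 1)
  for (n in 1:8) expect_equal(enrichment(natural_mid(n)), 0.0107,
                              tolerance = 1e-9)
  expect_error(enrichment(c(1), n = 0), "undefined")
  # scale invariance of the area normalization upstream
  a <- c(30, 20, 10)
  expect_equal(enrichment(areas_to_mid(a)), enrichment(areas_to_mid(a * 7)))
})

test_that("process_peak_areas runs filter, correction and aggregation", {
  # build records: metabolite X (n = 2), 3 labeled replicates + 2 controls;
  # true tracer MID (0.25, 0.25, 0.5), measured space convolved with p_nat,
  # plus a colliding peak at M1 in the controls
  true_mid <- c(0.25, 0.25, 0.5)
  meas <- binomial_convolve(true_mid)
  rows <- list()
  for (smp in c("s1", "s2", "s3")) {
    rows[[length(rows) + 1]] <- data.frame(
      metabolite = "X", n = 2, sample = smp, group = "g24", mi = 0:2,
      area = meas * 1e6, labeled = TRUE)
  }
  ctl <- natural_mid(2)
  for (smp in c("c1", "c2")) {
    rows[[length(rows) + 1]] <- data.frame(
      metabolite = "X", n = 2, sample = smp, group = "ctl", mi = 0:2,
      area = ctl * 2e5, labeled = FALSE)
  }
  # second metabolite with a collision at M1 in the unlabeled control
  bad_ctl <- c(0.80, 0.19, 0.01)
  for (smp in c("c1", "c2")) {
    rows[[length(rows) + 1]] <- data.frame(
      metabolite = "Y", n = 2, sample = smp, group = "ctl", mi = 0:2,
      area = bad_ctl * 1e5, labeled = FALSE)
  }
  rows[[length(rows) + 1]] <- data.frame(
    metabolite = "Y", n = 2, sample = "s1", group = "g24", mi = 0:2,
    area = c(50, 30, 20) * 1e3, labeled = TRUE)
  rec <- do.call(rbind, rows)

  out <- process_peak_areas(rec)
  expect_equal(out$mids[["X::s1"]], true_mid, tolerance = 1e-9)
  sx <- out$summary[out$summary$metabolite == "X", ]
  expect_equal(sx$mean[sx$group == "g24"], true_mid, tolerance = 1e-9)
  expect_equal(sx$sd[sx$group == "g24"], rep(0, 3), tolerance = 1e-12)
  # collision on Y at M1 removed for the labeled sample, renormalized
  sy <- out$summary[out$summary$metabolite == "Y" & out$summary$group ==
                      "g24", ]
  expect_false(sy$kept[sy$mi == 1])
  expect_equal(out$mids[["Y::s1"]][2], 0)
  expect_equal(sum(out$mids[["Y::s1"]]), 1, tolerance = 1e-9)
  # enrichment table present and in [0, 1]
  expect_true(all(out$enrichment$e >= 0 & out$enrichment$e <= 1))
  expect_equal(out$enrichment$e[out$enrichment$metabolite == "X" &
                                  out$enrichment$sample == "s1"],
               enrichment(true_mid), tolerance = 1e-9)
})

test_that("collision decisions depend only on the control group", {
  ctl <- natural_mid(3)
  keep1 <- collision_filter(ctl, 3)
  expect_true(all(keep1))
  # changing labeled data cannot change the filter (it never sees it):
  # assert the function signature takes only control information
  expect_named(formals(collision_filter),
               c("unlabeled_mid", "n", "threshold", "p_nat"))
})
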