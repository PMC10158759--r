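test_that("baseline estimation handles flat, noisy and published traces", {
  bl <- fit_baseline(rep(1.5, 30))
  expect_equal(bl$baseline_f, 1.5)
  expect_equal(bl$noise_sd, 0)

  # known baseline 1.4 with Gaussian noise, amplification from ~cycle 20
  set.seed(11)
  for (rep_i in 1:5) {
    tr <- 1.4 + stats::rnorm(45, 0, 0.01) + 1e-6 * 1.9^(1:45)
    expect_lt(abs(fit_baseline(tr)$baseline_f - 1.4), 0.02)
  }

  # published excerpt, synthetically in-filled: early cycles ~1.27-1.30
  p <- read_rdes(table1_infilled_path())
  a1 <- which(p$wells$well_id == "A1")
  b <- fit_baseline(p$traces[a1, ], p$axis)$baseline_f
  expect_gte(b, 1.25); expect_lte(b, 1.32)

  expect_error(fit_baseline(c(1, 1, 1)), class = "rdes_insufficient_data")
})

test_that("noiseless exponentials give closed-form E, Cq and N0 to 1e-6 relative", {
  # F_c = 1 + 1e-6 * 2^c: E = 2 exactly, Cq at Nq = 1e-3 is log2(1000)
  tr <- exp_trace(30, 2, 1e-6)
  f <- fit_curve(tr, policy = threshold_policy("fixed", 1e-3))
  expect_equal(f$efficiency_E, 2, tolerance = 1e-6)
  expect_equal(f$cq_threshold, log2(1e3), tolerance = 1e-6)
  expect_equal(f$n0, 1e-6, tolerance = 1e-6)
  expect_length(f$flags, 0)
  expect_gte(f$window[2] - f$window[1], 3)    # window of at least 4 cycles

  # a different efficiency: closed form Cq = (log Nq - log N0)/log E
  tr2 <- exp_trace(40, 1.85, 5e-7, baseline = 1.3)
  f2 <- fit_curve(tr2, policy = threshold_policy("fixed", 2e-3))
  expect_equal(f2$efficiency_E, 1.85, tolerance = 1e-6)
  expect_equal(f2$cq_threshold, log(2e-3 / 5e-7) / log(1.85), tolerance = 1e-6)
  expect_equal(f2$n0, 5e-7, tolerance = 1e-6)
})

test_that("flat traces flag NO_AMPLIFICATION and thresholds above plateau refuse", {
  f <- fit_curve(rep(1.5, 30))
  expect_true("NO_AMPLIFICATION" %in% f$flags)
  expect_true(is.na(f$efficiency_E))

  tr <- exp_trace(30, 2, 1e-6)
  expect_error(call_cq(tr, baseline_f = 1, policy = threshold_policy("fixed", 1e4)),
               class = "rdes_no_crossing")
})

test_that("the delta-Cq law holds exactly on noiseless well pairs", {
  # N0 ratio 8 at E = 2: Cq difference exactly 3 cycles
  nq <- threshold_policy("fixed", 1e-3)
  f1 <- fit_curve(exp_trace(30, 2, 1e-6), policy = nq)
  f2 <- fit_curve(exp_trace(30, 2, 8e-6), policy = nq)
  expect_equal(f1$cq_threshold - f2$cq_threshold, 3, tolerance = 1e-9)

  # generator emits the same law even with a saturating plateau
  sim <- simulate_amplification(n_samples = 2, n_targets = 1, e_true = 2,
                                n0_true = c(1e-8, 8e-8), cv = 0,
                                baseline_noise_sd = 0, n_ref_targets = 0,
                                seed = 1)
  dcq <- diff(sim$plate$wells$reported_cq)
  expect_equal(abs(dcq), 3, tolerance = 1e-9)
})

test_that("doubling N0 advances Cq by one cycle at E = 2 and Cq is monotone in N0", {
  nq <- threshold_policy("fixed", 1e-3)
  cqs <- vapply(c(1, 2, 4, 8) * 1e-6, function(a0)
    fit_curve(exp_trace(30, 2, a0), policy = nq)$cq_threshold, numeric(1))
  expect_equal(diff(cqs), rep(-1, 3), tolerance = 1e-9)
  expect_true(all(diff(cqs) < 0))
})

test_that("Cq and E are invariant under joint scaling of trace and threshold", {
  set.seed(21)
  tr <- (1.4 + 10 * (1e-7 * 1.9^(1:45)) / (1e-7 * 1.9^(1:45) + 1)) *
    (1 + stats::rnorm(45, 0, 0.01))
  for (k in c(0.5, 3, 100)) {
    f1 <- fit_curve(tr, policy = threshold_policy("fixed", 0.8))
    fk <- fit_curve(k * tr, policy = threshold_policy("fixed", k * 0.8))
    expect_equal(fk$cq_threshold, f1$cq_threshold, tolerance = 1e-6)
    expect_equal(fk$efficiency_E, f1$efficiency_E, tolerance = 1e-6)
  }
})

test_that("efficiency is recovered within 0.05 under 1% multiplicative noise", {
  sim <- simulate_amplification(n_samples = 10, n_targets = 4, e_true = rep(1.85, 4),
                                n_ref_targets = 0, seed = 13)
  fits <- analyze_plate(sim$plate)
  err <- abs(fits$efficiency_E - 1.85)
  expect_gte(mean(err <= 0.05), 0.95)
  expect_lt(median(err), 0.03)
})

test_that("second-derivative-maximum Cq sits near the threshold Cq on clean sigmoids", {
  q <- 1e-7 * 1.9^(1:45)
  tr <- 1.4 + 10 * q / (q + 1)
  f <- fit_curve(tr, policy = threshold_policy("fraction_of_plateau", 0.1))
  # SDM of the logistic model in q = n0 E^c space lies within a couple of
  # cycles of the 10%-of-plateau crossing
  expect_lt(abs(f$cq_sdm - f$cq_threshold), 3)
  expect_false(is.na(f$cq_sdm))
})

test_that("initial-quantity projection follows N0 = Nq / E^Cq", {
  expect_equal(estimate_n0(2, 10, 1024), 1)
  expect_equal(estimate_n0(2, 0, 7.5), 7.5)
  expect_error(estimate_n0(1, 10, 1), class = "rdes_domain")
  expect_error(estimate_n0(0.9, 10, 1), class = "rdes_domain")
})

test_that("the reported-Cq audit is self-consistent and catches NTC contamination", {
  sim <- simulate_amplification(n_samples = 4, n_targets = 3, n_cycles = 40, seed = 17)
  plate <- sim$plate
  fits <- analyze_plate(plate)
  # a Cq column produced by the engine itself audits clean
  plate$wells$reported_cq <- fits$cq_threshold
  rep <- audit_reported_cq(plate)
  expect_false("CQ_MISMATCH" %in% rep$warnings$code)

  # an amplifying trace in an NTC well is flagged as contamination
  plate2 <- sim$plate
  plate2$wells$sample_type[1] <- "ntc"
  rep2 <- audit_reported_cq(plate2)
  expect_true("NTC_AMPLIFICATION" %in% rep2$warnings$code)
  expect_equal(rep2$warnings$well_id[rep2$warnings$code == "NTC_AMPLIFICATION"][1],
               plate2$wells$well_id[1])

  # a shifted reported Cq beyond tolerance is a mismatch
  plate3 <- sim$plate
  plate3$wells$reported_cq <- fits$cq_threshold + 2
  rep3 <- audit_reported_cq(plate3, tolerance = 1)
  expect_true(all(plate3$wells$well_id %in%
                    rep3$warnings$well_id[rep3$warnings$code == "CQ_MISMATCH"]))

  # the in-filled excerpt runs end to end with a recomputed Cq per well
  p <- read_rdes(table1_infilled_path())
  repx <- audit_reported_cq(p)
  fitsx <- attr(repx, "fits")
  expect_true(all(!is.na(fitsx$cq_threshold)))
})
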