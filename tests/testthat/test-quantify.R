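# hand-built curve_fits frame for unit-level checks
fits_frame <- function(sample, target, target_type, cq, E = 2, flags = "",
                       nq = 1) {
  df <- data.frame(sample = sample, target = target, target_type = target_type,
                   cq_threshold = cq, efficiency_E = E, flags = flags,
                   stringsAsFactors = FALSE)
  attr(df, "nq") <- nq
  df
}

test_that("assay efficiencies average usable wells and refuse unusable targets", {
  f <- fits_frame(c("s1", "s2"), "g1", "toi", c(20, 21), E = c(1.8, 1.9))
  expect_equal(per_target_efficiency(f), c(g1 = 1.85))

  # flagged wells are excluded; a single usable well is not enough
  f2 <- fits_frame(c("s1", "s2", "s3"), "g1", "toi", c(20, 21, 22),
                   E = c(1.8, 1.9, 1.85),
                   flags = c("", "LOW_R2", ""))
  expect_equal(per_target_efficiency(f2), c(g1 = 1.825))
  f3 <- fits_frame(c("s1", "s2"), "g1", "toi", c(20, 21),
                   flags = c("", "NO_AMPLIFICATION"))
  expect_error(per_target_efficiency(f3), class = "rdes_missing_efficiency")
  expect_error(per_target_efficiency(fits_frame("s1", "g1", "toi", 20)),
               class = "rdes_missing_efficiency")
})

test_that("simulated per-target efficiencies are recovered within 0.03", {
  sim <- simulate_amplification(n_samples = 10, n_targets = 2,
                                e_true = c(1.80, 1.95), n_ref_targets = 0,
                                seed = 19)
  pe <- per_target_efficiency(analyze_plate(sim$plate))
  expect_lt(abs(pe[["Gene_01"]] - 1.80), 0.03)
  expect_lt(abs(pe[["Gene_02"]] - 1.95), 0.03)
})

test_that("normalization follows the efficiency-corrected ratio model", {
  # same Cq, shared E: target quantity equals the reference, ratio 1
  f <- rbind(fits_frame(c("s1", "s1"), c("goi", "ref1"), c("toi", "ref"), c(25, 25)),
             fits_frame(c("s2", "s2"), c("goi", "ref1"), c("toi", "ref"), c(25, 25)))
  attr(f, "nq") <- 1
  q <- normalized_expression(f, efficiencies = c(goi = 2, ref1 = 2))
  expect_equal(q$normalized, c(1, 1))
  expect_equal(q$fold_vs_calibrator, c(1, 1))

  # target one cycle earlier than the reference at E = 2: ratio 2
  f2 <- rbind(fits_frame(c("s1", "s1"), c("goi", "ref1"), c("toi", "ref"), c(24, 25)),
              fits_frame(c("s2", "s2"), c("goi", "ref1"), c("toi", "ref"), c(25, 25)))
  attr(f2, "nq") <- 1
  q2 <- normalized_expression(f2, efficiencies = c(goi = 2, ref1 = 2))
  expect_equal(q2$normalized[q2$sample == "s1"], 2)
  expect_equal(q2$fold_vs_calibrator[q2$sample == "s2"], 0.5)

  # scaling Nq rescales quantities but not normalized values or folds
  q3 <- normalized_expression(f2, efficiencies = c(goi = 2, ref1 = 2), nq = 50)
  expect_equal(q3$normalized, q2$normalized)
  expect_equal(q3$fold_vs_calibrator, q2$fold_vs_calibrator)
  expect_equal(q3$n0, 50 * q2$n0)
})

test_that("reference aggregation is a permutation-invariant geometric mean", {
  f <- rbind(fits_frame("s1", "goi", "toi", 24),
             fits_frame("s1", "refA", "ref", 25),
             fits_frame("s1", "refB", "ref", 27))
  attr(f, "nq") <- 1
  e <- c(goi = 2, refA = 2, refB = 2)
  q_ab <- normalized_expression(f, e, reference_targets = c("refA", "refB"))
  q_ba <- normalized_expression(f, e, reference_targets = c("refB", "refA"))
  expect_equal(q_ab$normalized, q_ba$normalized)
  # geometric mean of 2^-25 and 2^-27 is 2^-26: normalized = 2^(26-24)
  expect_equal(q_ab$normalized, 4)
})

test_that("samples lacking a usable reference become per-sample error entries", {
  f <- rbind(fits_frame(c("s1", "s1"), c("goi", "ref1"), c("toi", "ref"), c(24, 25)),
             fits_frame("s2", "goi", "toi", 25))
  attr(f, "nq") <- 1
  q <- normalized_expression(f, efficiencies = c(goi = 2, ref1 = 2))
  err <- attr(q, "errors")
  expect_equal(err$sample, "s2")
  expect_false("s2" %in% q$sample)
})

test_that("a simulated two-group contrast with true fold 4 is recovered", {
  n0 <- matrix(1e-8, nrow = 8, ncol = 4)
  n0[1:4, 1:3] <- 4e-8                       # group A, targets of interest up 4x
  sim <- simulate_amplification(n_samples = 8, n_targets = 4,
                                e_true = c(1.9, 1.9, 1.9, 1.85),
                                n0_true = as.vector(t(n0)), seed = 5)
  q <- normalized_expression(analyze_plate(sim$plate))
  grp <- ifelse(q$sample %in% sprintf("Sample_%02d", 1:4), "A", "B")
  fold <- vapply(unique(q$target), function(tg) {
    sel <- q$target == tg
    exp(mean(log(q$normalized[sel & grp == "A"]))) /
      exp(mean(log(q$normalized[sel & grp == "B"])))
  }, numeric(1))
  expect_true(all(fold > 3.5 & fold < 4.5))
})

test_that("the Cq-dependent bias curve is exact, monotone and log-linear", {
  flat <- cq_bias_assessment(1.9, 1.9, c(15, 40))
  expect_true(all(flat$fold_error == 1))

  bc <- cq_bias_assessment(1.9, 2.0, c(15, 40))
  # independent oracle: repeated multiplication
  brute <- 1
  for (i in 1:30) brute <- brute * (2.0 / 1.9)
  expect_equal(bc$fold_error[bc$cq == 30], brute, tolerance = 1e-12)
  expect_equal(bc$fold_error[bc$cq == 30], 4.66, tolerance = 0.01)

  expect_gt(bc$fold_error[bc$cq == 35], bc$fold_error[bc$cq == 20])
  # log-linearity: residuals of a straight-line fit vanish
  fit <- lm(log(fold_error) ~ cq, data = bc)
  expect_lt(max(abs(residuals(fit))), 1e-12)
  expect_equal(unname(coef(fit)[2]), log(2.0 / 1.9), tolerance = 1e-12)

  expect_error(cq_bias_assessment(1.0, 2.0), class = "rdes_config")
  expect_error(cq_bias_assessment(1.9, 2.4), class = "rdes_config")
})
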