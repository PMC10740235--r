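# Cluster-robust OLS, the family bootstrap, and the gamma-GLM sensitivity
# model, each cross-checked against an independently coded oracle.

test_that("OLS delta equals the arm mean difference; degenerate variance gives se 0", {
  p <- tiny_participants()
  y <- ifelse(p$arm == "INT", 10, 7)
  # a perfect fit makes lm's summary grumble; the sandwich is still exact
  est <- suppressWarnings(estimate_difference_ols(y, p$arm, p$family_id))
  expect_equal(est$delta, 3)
  expect_equal(est$se, 0)
  expect_equal(est$delta, est$delta_raw)

  set.seed(8)
  for (rep in 1:10) {
    y <- rlnorm(8, 5, 1)
    est <- estimate_difference_ols(y, p$arm, p$family_id)
    expect_equal(est$delta,
                 mean(y[p$arm == "INT"]) - mean(y[p$arm == "TAU"]),
                 tolerance = 1e-12)
    expect_equal(est$delta, est$delta_raw, tolerance = 1e-12)
  }

  expect_error(estimate_difference_ols(y, rep("TAU", 8), p$family_id),
               "constant")
  expect_error(
    estimate_difference_ols(y[1:4], c("TAU", "TAU", "INT", "INT"),
                            rep("F1", 4)),
    "split across arms")
})

test_that("cluster-robust SE matches the closed-form sandwich oracle to 1e-10", {
  # fixed 6-observation / 3-family instance
  m <- micro_instance()
  est <- estimate_difference_ols(m$y, m$arm, m$cluster)
  ora <- oracle_cluster_vcov(m$y, as.integer(m$arm == "INT"), m$cluster)
  expect_equal(est$delta, ora$beta[2], tolerance = 1e-10)
  expect_equal(est$se, sqrt(ora$vcov[2, 2]), tolerance = 1e-10)

  # and random instances on the 4-family fixture
  p <- tiny_participants()
  set.seed(19)
  for (rep in 1:5) {
    y <- rlnorm(8, 5, 1.2)
    est <- estimate_difference_ols(y, p$arm, p$family_id)
    ora <- oracle_cluster_vcov(y, as.integer(p$arm == "INT"), p$family_id)
    expect_equal(est$delta, ora$beta[2], tolerance = 1e-10)
    expect_equal(est$se, sqrt(ora$vcov[2, 2]), tolerance = 1e-10)
  }
})

test_that("singleton clusters reduce the sandwich to the HC0-type robust SE", {
  set.seed(23)
  n <- 40
  arm <- rep(c("TAU", "INT"), each = n / 2)
  fam <- paste0("F", seq_len(n))           # every child its own family
  y <- rlnorm(n, 5, 1)
  est <- estimate_difference_ols(y, arm, fam)
  fit <- stats::lm(y ~ I(arm == "INT"))
  hc <- sandwich::vcovHC(fit, type = "HC0") * n / (n - 1)
  expect_equal(est$se, sqrt(hc[2, 2]), tolerance = 1e-10)
})

test_that("permuted arm labels give mean delta near zero", {
  trial <- generate_trial(trial_config(n_families = 40), seed = 5,
                          dropout = FALSE)
  p <- trial$participants
  ann <- annualize(trial)
  fams <- unique(p$family_id)
  set.seed(31)
  deltas <- replicate(300, {
    fam_arm <- stats::setNames(sample(rep(cua_arms, length.out =
                                            length(fams))), fams)
    estimate_difference_ols(ann$annual_total, fam_arm[p$family_id],
                            p$family_id)$delta
  })
  expect_lt(abs(mean(deltas)), 3 * stats::sd(deltas) / sqrt(length(deltas)))
})

test_that("family bootstrap is seed-deterministic, collapses under no variation, centers on delta", {
  p <- tiny_participants()
  y_const <- rep(5, 8)
  # with only 4 families some resamples collapse to one arm and are
  # discarded with a warning; the surviving replicates are all zero
  b <- suppressWarnings(bootstrap_ci(y_const, p$arm, p$family_id, B = 200,
                                     seed = 1))
  expect_equal(c(b$ci_low, b$ci_high), c(0, 0))

  trial <- generate_trial(trial_config(n_families = 50), seed = 14,
                          dropout = FALSE)
  pp <- trial$participants
  ann <- annualize(trial)
  b1 <- bootstrap_ci(ann$annual_total, pp$arm, pp$family_id, B = 2000,
                     seed = 77)
  b2 <- bootstrap_ci(ann$annual_total, pp$arm, pp$family_id, B = 2000,
                     seed = 77)
  expect_identical(b1$deltas, b2$deltas)
  expect_true(b1$ci_low <= b1$ci_high)

  obs <- estimate_difference_ols(ann$annual_total, pp$arm,
                                 pp$family_id)$delta
  expect_lt(abs(mean(b1$deltas) - obs),
            3 * stats::sd(b1$deltas) / sqrt(length(b1$deltas)) +
              0.02 * stats::sd(b1$deltas))
  expect_true(obs >= b1$ci_low && obs <= b1$ci_high)
  expect_error(bootstrap_ci(ann$annual_total, pp$arm, pp$family_id, B = 50),
               "B must be")
})

test_that("gamma GLM matches the hand-rolled IRLS oracle to 1e-6 and is scale-equivariant", {
  p <- tiny_participants()
  set.seed(47)
  y <- rlnorm(8, 5, 0.8)
  est <- estimate_difference_glm(y, p$arm, p$family_id)
  ora <- oracle_gamma_irls(y, as.integer(p$arm == "INT"))
  expect_equal(est$delta, ora[2], tolerance = 1e-6)
  expect_equal(est$ratio, exp(ora[2]), tolerance = 1e-6)

  # identical positive distributions across arms -> coefficient ~ 0
  y_null <- rep(c(100, 300, 900, 55), 2)
  est0 <- estimate_difference_glm(y_null, p$arm, p$family_id)
  expect_equal(est0$delta, 0, tolerance = 1e-8)
  expect_equal(est0$ratio, 1, tolerance = 1e-8)

  # log link: scaling all costs leaves the arm coefficient unchanged
  est2 <- estimate_difference_glm(y * 2, p$arm, p$family_id)
  expect_equal(est2$delta, est$delta, tolerance = 1e-8)

  # larger random instance against the oracle
  trial <- generate_trial(trial_config(n_families = 30), seed = 3,
                          dropout = FALSE)
  pp <- trial$participants
  ann <- annualize(trial)
  estL <- estimate_difference_glm(ann$annual_total, pp$arm, pp$family_id)
  yL <- ann$annual_total + 1   # same zero-offset rule as the implementation
  oraL <- oracle_gamma_irls(yL, as.integer(pp$arm == "INT"))
  expect_equal(estL$delta, oraL[2], tolerance = 1e-6)
})

test_that("OLS and gamma GLM agree on significance in null and large-effect regimes", {
  trial <- generate_trial(trial_config(n_families = 80), seed = 21,
                          dropout = FALSE)
  pp <- trial$participants
  ann <- annualize(trial)
  o <- estimate_difference_ols(ann$annual_total, pp$arm, pp$family_id)
  g <- estimate_difference_glm(ann$annual_total, pp$arm, pp$family_id)
  expect_equal(o$p > 0.05, g$p > 0.05)   # null regime: both nonsignificant

  y_eff <- ann$annual_total * ifelse(pp$arm == "INT", 4, 1) + 100
  o2 <- estimate_difference_ols(y_eff, pp$arm, pp$family_id)
  g2 <- estimate_difference_glm(y_eff, pp$arm, pp$family_id)
  expect_true(o2$p <= 0.05 && g2$p <= 0.05)
})
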