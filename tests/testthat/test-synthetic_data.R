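# Generator: structure, calibration, determinism, planted missingness.

test_that("generated trials have the configured family and arm structure", {
  trial <- generate_trial(trial_config(n_families = 60), seed = 1,
                          dropout = FALSE)
  p <- trial$participants
  expect_equal(length(unique(p$family_id[p$arm == "TAU"])), 60)
  expect_equal(length(unique(p$family_id[p$arm == "INT"])), 60)
  sizes <- table(p$family_id)
  expect_true(all(sizes %in% 1:2))
  expect_false(anyNA(trial$costs$cost))
  expect_true(all(trial$costs$cost >= 0))
  expect_true(all(trial$utilities$utility >= 0 &
                    trial$utilities$utility <= 1))
})

test_that("identical seeds give identical bundles; different seeds differ", {
  a <- generate_trial(seed = 555)
  b <- generate_trial(seed = 555)
  expect_identical(a$costs, b$costs)
  expect_identical(a$utilities, b$utilities)
  expect_identical(a$participants, b$participants)
  c <- generate_trial(seed = 556)
  expect_false(identical(a$costs$cost, c$costs$cost))
})

test_that("zero-variance config collapses to identical participants", {
  cfg <- trial_config(n_families = 5,
                      category_means = c(100, 0, 0, 0, 0, 0),
                      category_sds = rep(0, 6),
                      p_use = rep(1, 6), icc = 0,
                      utility_sd = 0, utility_mean = 0.8,
                      dropout_hazard = c(0, 0, 0), p_baseline_missing = 0)
  trial <- generate_trial(cfg, seed = 9)
  inpat <- trial$costs$cost[trial$costs$category == "inpatient"]
  expect_equal(inpat, rep(100, length(inpat)))
  expect_true(all(trial$costs$cost[trial$costs$category != "inpatient"] == 0))
  expect_equal(trial$utilities$utility,
               rep(0.8, nrow(trial$utilities)))
})

test_that("infeasible moment targets are rejected", {
  expect_error(trial_config(category_sds = rep(-1, 6)), "nonnegative")
  # mean >> sd with tiny use probability makes the positive part impossible
  expect_error(trial_config(category_means = c(1000, 0, 0, 0, 0, 0),
                            category_sds = c(1, 0, 0, 0, 0, 0),
                            p_use = c(0.01, 1, 1, 1, 1, 1)),
               "infeasible")
})

test_that("marginal cost and utility moments match the configured targets", {
  # one big trial: per-category means within sampling tolerance of targets
  cfg <- trial_config(n_families = 600)
  trial <- generate_trial(cfg, seed = 202, dropout = FALSE)
  c0 <- trial$costs[trial$costs$wave == 0, ]
  means <- tapply(c0$cost, c0$category, mean)[cua_categories]
  expect_equal(as.vector(means), cfg$category_means, tolerance = 0.15)
  tot <- tapply(c0$cost, c0$participant_id, sum)
  expect_equal(mean(tot), sum(cfg$category_means), tolerance = 0.15)
  # heavy-tailed regime: SD exceeds the mean for the zero-inflated categories
  sds <- tapply(c0$cost, c0$category, sd)[cua_categories]
  expect_true(all(sds > means))
  expect_equal(mean(trial$utilities$utility), 0.76, tolerance = 0.01)
  expect_equal(sd(trial$utilities$utility), 0.07, tolerance = 0.1)

  # replicate-averaged baseline 6-month total cost within 15% of the target
  reps <- vapply(1:50, function(s) {
    tr <- generate_trial(trial_config(), seed = 1000 + s, dropout = FALSE)
    b <- tr$costs[tr$costs$wave == 0, ]
    mean(tapply(b$cost, b$participant_id, sum))
  }, numeric(1))
  expect_equal(mean(reps), 1891.25, tolerance = 0.15)
})

test_that("family clustering induces positive intraclass correlation in utilities", {
  trial <- generate_trial(trial_config(n_families = 300), seed = 404,
                          dropout = FALSE)
  u0 <- trial$utilities[trial$utilities$wave == 0, ]
  fam <- trial$participants$family_id[match(u0$participant_id,
                                            trial$participants$participant_id)]
  fit <- stats::aov(u0$utility ~ fam)
  ms <- summary(fit)[[1]]$`Mean Sq`
  k <- mean(table(fam))
  icc_hat <- (ms[1] - ms[2]) / (ms[1] + (k - 1) * ms[2])
  expect_gt(icc_hat, 0.15)
  expect_lt(icc_hat, 0.45)
})

test_that("dropout is monotone, calibrated, and exactly recorded", {
  cfg <- trial_config()
  # probabilities all 0 -> unchanged; all 1 at t1 -> only baseline observed
  none <- generate_trial(trial_config(dropout_hazard = c(0, 0, 0),
                                      p_baseline_missing = 0), seed = 3)
  expect_true(all(none$utilities$observed))
  all_gone <- generate_trial(trial_config(dropout_hazard = c(1, 1, 1),
                                          p_baseline_missing = 0), seed = 3)
  expect_true(all(all_gone$utilities$observed ==
                    (all_gone$utilities$wave == 0)))

  # monotonicity and ground-truth agreement on default config
  trial <- generate_trial(cfg, seed = 77)
  gt <- attr(trial, "ground_truth")
  um <- matrix(!trial$utilities$observed, nrow = 4)
  dw <- gt$dropout_wave[trial$participants$participant_id]
  for (w in 1:3) {
    expect_equal(unname(um[w + 1, ]),
                 unname(dw <= w))
  }

  # expected missing counts across seeds near the 96/172/~172-of-327 regime
  miss <- t(vapply(1:40, function(s) {
    tr <- generate_trial(cfg, seed = 2000 + s)
    n <- nrow(tr$participants)
    m <- matrix(!tr$utilities$observed, nrow = 4)
    rowSums(m)[2:4] / n
  }, numeric(3)))
  expect_equal(colMeans(miss), c(96, 172, 172) / 327, tolerance = 0.05)
})

test_that("configured treatment effects are recovered by the inference chain", {
  cfg <- trial_config(n_families = 800, delta_qaly = 0.05, delta_cost = 400)
  trial <- generate_trial(cfg, seed = 66, dropout = FALSE)
  p <- trial$participants
  ann <- annualize(trial)
  q <- compute_qalys(trial)
  eq <- estimate_difference_ols(q$qaly_total, p$arm, p$family_id)
  expect_lt(abs(eq$delta - 0.05), 2 * eq$se)
  ec <- estimate_difference_ols(ann$annual_total, p$arm, p$family_id)
  expect_lt(abs(ec$delta - 400), 2 * ec$se)
})

test_that("item-level mode reprices to the generated cost panel", {
  trial <- generate_trial(trial_config(n_families = 10), seed = 12,
                          dropout = FALSE, item_level = TRUE)
  panel <- price_service_use(trial$service_use, trial$unit_costs)
  key <- paste(panel$participant_id, panel$wave, panel$category)
  ref <- trial$costs
  m <- match(paste(ref$participant_id, ref$wave, ref$category), key)
  expect_false(anyNA(m))
  expect_equal(panel$cost[m], ref$cost, tolerance = 1e-9)
})
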