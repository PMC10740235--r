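# Synthetic family-clustered two-arm trials with the statistical structure
# the analysis chain assumes: zero-inflated right-skewed 6-month costs per
# service category, bounded utilities, family-level intraclass correlation,
# monotone dropout, and recorded ground-truth treatment effects.

#' Configuration for a synthetic trial
#'
#' Defaults emulate a German multi-centre family trial: ~105 families per
#' arm with 1-2 children each (mean 1.6), four 6-month waves, six-category
#' costs that are heavily right-skewed with many zeros (baseline 6-month
#' category means summing to about EUR 1,891), utilities near 0.76 (SD
#' 0.07), small or null treatment effects, and monotone dropout reaching
#' about half the sample by the last wave.
#'
#' Per category, 6-month cost is a two-part model: a Bernoulli any-use
#' indicator times a lognormal positive part whose parameters are solved
#' from the target marginal mean and SD given the use probability, so the
#' configured moments hold exactly in expectation. A shared standard-normal
#' family effect takes fraction `icc` of each category's log-scale variance
#' (and of the utility variance), inducing within-family correlation.
#'
#' Treatment effects enter at the post-baseline waves only (the t0 recall
#' window precedes randomization): INT costs at t1-t3 are scaled by a
#' common factor and INT utilities shifted by a constant chosen so that the
#' expected INT - TAU differences in `annual_total` and `qaly_total` equal
#' `delta_cost` and `delta_qaly` exactly.
#'
#' @param n_families Families per arm (default 105).
#' @param children_prob Distribution of children per family, named by count
#'   (default 1 or 2 with probabilities 0.4/0.6, mean 1.6).
#' @param category_means,category_sds Target marginal mean/SD of 6-month
#'   cost per category, EUR (defaults: inpatient 791.57/3808.48, outpatient
#'   206.06/579.93, institutional welfare 224.45/1862.13, ambulant welfare
#'   131.10/529.56, medication 19.89/157.56, school-based 518.18/2306.12).
#' @param p_use Per-category probability of any use in a 6-month window.
#' @param icc Intraclass (within-family) correlation fraction of variance
#'   (default 0.3).
#' @param utility_mean,utility_sd Marginal utility moments (0.76, 0.07);
#'   utilities are truncated to `[0, 1]`.
#' @param delta_cost True INT - TAU difference in average annual total cost
#'   (EUR/year; default 0).
#' @param delta_qaly True INT - TAU difference in average annual QALY
#'   (default 0).
#' @param dropout_hazard Per-wave conditional dropout probabilities at
#'   t1-t3; monotone missingness (a dropped participant stays missing).
#'   Defaults calibrated so the expected numbers of participants needing
#'   LOCF at t1/t2/t3 are about 96/172/172 of 327.
#' @param p_baseline_missing Probability a participant misses baseline cost
#'   and/or utility assessment (default 0.03); such participants are the
#'   baseline-complete filter's target.
#' @return A `cua_trial_config` list.
#' @export
trial_config <- function(n_families = 105,
                         children_prob = c(`1` = 0.4, `2` = 0.6),
                         category_means = c(inpatient = 791.57,
                                            outpatient = 206.06,
                                            institutional_welfare = 224.45,
                                            ambulant_welfare = 131.10,
                                            medication = 19.89,
                                            school_based = 518.18),
                         category_sds = c(3808.48, 579.93, 1862.13, 529.56,
                                          157.56, 2306.12),
                         p_use = c(0.05, 0.25, 0.03, 0.10, 0.10, 0.15),
                         icc = 0.3,
                         utility_mean = 0.76, utility_sd = 0.07,
                         delta_cost = 0, delta_qaly = 0,
                         dropout_hazard = c(96 / 327,
                                            (172 - 96) / (327 - 96), 0),
                         p_baseline_missing = 0.03) {
  stopifnot(length(category_means) == 6L, length(category_sds) == 6L,
            length(p_use) == 6L, length(dropout_hazard) == 3L)
  if (any(category_sds < 0) || any(category_means < 0)) {
    cua_stop("category means and SDs must be nonnegative")
  }
  if (any(p_use <= 0 | p_use > 1)) cua_stop("p_use must be in (0, 1]")
  if (icc < 0 || icc >= 1) cua_stop("icc must be in [0, 1)")
  if (any(dropout_hazard < 0 | dropout_hazard > 1)) {
    cua_stop("dropout hazards must be probabilities")
  }
  # feasibility of the two-part lognormal moment match:
  # var of the positive part must be positive given p_use
  m <- unname(category_means); s <- unname(category_sds); p <- unname(p_use)
  var_pos <- (s^2 + m^2) / p - (m / p)^2
  if (any(m > 0 & var_pos < 0)) {
    cua_stop("infeasible moment targets: positive-part variance < 0 for category ",
             paste(cua_categories[m > 0 & var_pos < 0], collapse = ", "))
  }
  structure(list(n_families = n_families, children_prob = children_prob,
                 category_means = m, category_sds = s, p_use = p, icc = icc,
                 utility_mean = utility_mean, utility_sd = utility_sd,
                 delta_cost = delta_cost, delta_qaly = delta_qaly,
                 dropout_hazard = dropout_hazard,
                 p_baseline_missing = p_baseline_missing),
            class = "cua_trial_config")
}

# lognormal parameters matching a target mean/SD of the positive part;
# var_pos = 0 degenerates to a point mass at mean_pos
lognormal_params <- function(mean_pos, var_pos) {
  s2 <- log(1 + max(var_pos, 0) / mean_pos^2)
  list(mu = log(mean_pos) - s2 / 2, sigma = sqrt(s2))
}

#' Generate a synthetic family-clustered trial
#'
#' Draws a complete trial from a [trial_config()], then (by default)
#' applies [induce_dropout()]. Fully reproducible: identical seeds give
#' identical bundles. The true effect sizes and every planted missing cell
#' are recorded in attribute `"ground_truth"`.
#'
#' @param config A `cua_trial_config`.
#' @param seed Integer seed (default 20151201).
#' @param dropout Apply the configured missingness (default `TRUE`).
#' @param item_level If `TRUE`, additionally emit an item-level service-use
#'   table (two items per category at different unit prices) whose pricing
#'   against the accompanying `unit_costs` reproduces the cost panel; the
#'   generator's native output is category-level costs.
#' @return A `cua_trial`; `attr(x, "ground_truth")` holds the config, seed,
#'   true `delta_cost`/`delta_qaly` (plus their year-wise decomposition),
#'   and after dropout the planted missing sets. With `item_level = TRUE`,
#'   components `service_use` and `unit_costs` are attached.
#' @export
generate_trial <- function(config = trial_config(), seed = 20151201,
                           dropout = TRUE, item_level = FALSE) {
  stopifnot(inherits(config, "cua_trial_config"))
  trial <- with_seed(seed, generate_complete(config))
  gt <- list(config = config, seed = seed,
             delta_cost = config$delta_cost,
             delta_qaly = config$delta_qaly,
             delta_cost_y1 = 2 * config$delta_cost / 3,
             delta_cost_y2 = 4 * config$delta_cost / 3,
             delta_qaly_y1 = 2 * config$delta_qaly / 3,
             delta_qaly_y2 = 4 * config$delta_qaly / 3)
  attr(trial, "ground_truth") <- gt
  if (item_level) trial <- attach_item_level(trial, seed)
  if (dropout) trial <- induce_dropout(trial, config, seed = seed + 1L)
  trial
}

generate_complete <- function(config) {
  # family sizes and arms
  G <- config$n_families
  sizes <- as.integer(names(config$children_prob))[
    sample.int(length(config$children_prob), 2L * G, replace = TRUE,
               prob = config$children_prob)]
  fam_arm <- rep(cua_arms, each = G)
  n <- sum(sizes)
  fam_id <- sprintf("F%03d", seq_len(2L * G))
  participants <- data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    family_id = rep(fam_id, sizes),
    arm = rep(fam_arm, sizes),
    age_years = round(pmin(pmax(stats::rnorm(n, 11.7, 4.4), 3), 19), 1),
    sex = sample(c("female", "male"), n, replace = TRUE),
    baseline_diagnosis = stats::runif(n) < 0.535,
    stringsAsFactors = FALSE)

  # independent family effects for the cost and utility processes: the
  # family induces clustering within each outcome but no cost-utility
  # correlation beyond it
  z_fam_c <- stats::rnorm(2L * G)
  z_fam_u <- stats::rnorm(2L * G)
  z_part <- rep(z_fam_c, sizes)
  z_part_u <- rep(z_fam_u, sizes)
  is_int <- participants$arm == "INT"

  # per-category two-part lognormal costs, canonical (participant, wave,
  # category) order; category index fastest
  ncell <- n * 4L
  cost <- matrix(0, nrow = 6L, ncol = ncell)    # category x (participant,wave)
  for (k in seq_len(6L)) {
    m <- config$category_means[k]
    if (m == 0) next
    p <- config$p_use[k]
    lp <- lognormal_params(m / p,
                           (config$category_sds[k]^2 + m^2) / p - (m / p)^2)
    use <- stats::runif(ncell) < p
    zf <- rep(z_part, each = 4L)                  # per (participant, wave)
    eps <- stats::rnorm(ncell)
    logx <- lp$mu + lp$sigma * (sqrt(config$icc) * zf +
                                  sqrt(1 - config$icc) * eps)
    cost[k, ] <- ifelse(use, exp(logx), 0)
  }
  # treatment effect on costs: scale INT post-baseline waves by a common
  # factor so E[annual_total] differs by delta_cost
  M <- sum(config$category_means)
  if (config$delta_cost != 0) {
    k_fac <- 1 + (2 * config$delta_cost / 3) / M
    if (k_fac < 0) cua_stop("delta_cost too negative for the configured cost level")
    int_cell <- rep(is_int, each = 4L) & rep(0:3, n) >= 1L
    cost[, int_cell] <- cost[, int_cell] * k_fac
  }
  # matrix columns are (participant, wave) cells with category in rows, so
  # as.vector() runs category fastest -> canonical (participant, wave,
  # category) long order
  costs <- data.frame(
    participant_id = rep(participants$participant_id, each = 24L),
    wave = rep(rep(0:3, each = 6L), n),
    category = rep(cua_categories, 4L * n),
    cost = as.vector(cost),
    observed = TRUE, stringsAsFactors = FALSE)

  # utilities: truncated normal around utility_mean with family effect
  u <- config$utility_mean +
    config$utility_sd * (sqrt(config$icc) * rep(z_part_u, each = 4L) +
                           sqrt(1 - config$icc) * stats::rnorm(ncell))
  if (config$delta_qaly != 0) {
    d <- 4 * config$delta_qaly / 3
    u <- u + d * (rep(is_int, each = 4L) & rep(0:3, n) >= 1L)
  }
  u <- pmin(pmax(u, 0), 1)
  utilities <- data.frame(
    participant_id = rep(participants$participant_id, each = 4L),
    wave = rep(0:3, n), utility = u, observed = TRUE,
    stringsAsFactors = FALSE)

  new_trial(participants, costs, utilities)
}

# optional item-level service-use representation: split each category's
# cost over two priced items so price_service_use() reproduces the panel
attach_item_level <- function(trial, seed) {
  unit_costs <- data.frame(
    category = rep(cua_categories, each = 2L),
    item = paste0(rep(cua_categories, each = 2L), c("_item_a", "_item_b")),
    unit = "unit",
    unit_cost_eur = rep(c(250, 40), 6L))
  cc <- trial$costs[trial$costs$observed & trial$costs$cost > 0, ]
  frac <- with_seed(seed + 2L, stats::runif(nrow(cc)))
  a <- cc$cost * frac
  su <- rbind(
    data.frame(participant_id = cc$participant_id, wave = cc$wave,
               category = cc$category,
               item = paste0(cc$category, "_item_a"), units = a / 250,
               assessed = 1L),
    data.frame(participant_id = cc$participant_id, wave = cc$wave,
               category = cc$category,
               item = paste0(cc$category, "_item_b"),
               units = (cc$cost - a) / 40, assessed = 1L))
  # marker rows so assessed zero-use waves stay distinguishable from missing
  assessed <- unique(trial$costs[trial$costs$observed,
                                 c("participant_id", "wave")])
  marker <- data.frame(participant_id = assessed$participant_id,
                       wave = assessed$wave, category = cua_categories[1L],
                       item = paste0(cua_categories[1L], "_item_a"),
                       units = 0, assessed = 1L)
  trial$service_use <- rbind(su, marker)
  trial$unit_costs <- unit_costs
  trial
}

#' Apply configured missingness to a complete trial
#'
#' Two mechanisms, both completely at random: (i) baseline missingness —
#' with probability `p_baseline_missing` a participant misses the t0 cost
#' assessment, the t0 utility, or both (equal thirds); (ii) monotone
#' dropout — each still-present participant drops at wave w with the
#' configured hazard and stays missing (costs and utilities) from then on.
#'
#' @param trial A complete `cua_trial`.
#' @param config The `cua_trial_config` carrying the missingness rates.
#' @param seed Integer seed.
#' @return The trial with `NA`/unobserved cells; the ground-truth attribute
#'   gains `baseline_missing` (ids by variable group) and `dropout_wave`
#'   (first missing wave per participant, `Inf` = never).
#' @export
induce_dropout <- function(trial, config, seed = 20151201) {
  stopifnot(inherits(trial, "cua_trial"))
  n <- nrow(trial$participants)
  ids <- trial$participants$participant_id
  plan <- with_seed(seed, {
    bl <- stats::runif(n) < config$p_baseline_missing
    bl_kind <- sample(c("cost", "utility", "both"), n, replace = TRUE)
    drop_wave <- rep(Inf, n)
    alive <- rep(TRUE, n)
    for (w in 1:3) {
      h <- config$dropout_hazard[w]
      drops <- alive & stats::runif(n) < h
      drop_wave[drops] <- w
      alive <- alive & !drops
    }
    list(bl = bl, bl_kind = bl_kind, drop_wave = drop_wave)
  })

  cost_miss_bl <- ids[plan$bl & plan$bl_kind %in% c("cost", "both")]
  util_miss_bl <- ids[plan$bl & plan$bl_kind %in% c("utility", "both")]

  costs <- trial$costs
  cwave <- costs$wave
  cdrop <- plan$drop_wave[match(costs$participant_id, ids)]
  kill_c <- (cwave >= cdrop) |
    (cwave == 0L & costs$participant_id %in% cost_miss_bl)
  costs$cost[kill_c] <- NA_real_
  costs$observed[kill_c] <- FALSE

  utilities <- trial$utilities
  udrop <- plan$drop_wave[match(utilities$participant_id, ids)]
  kill_u <- (utilities$wave >= udrop) |
    (utilities$wave == 0L & utilities$participant_id %in% util_miss_bl)
  utilities$utility[kill_u] <- NA_real_
  utilities$observed[kill_u] <- FALSE

  out <- new_trial(trial$participants, costs, utilities,
                   service_use = trial$service_use)
  gt <- attr(trial, "ground_truth") %||% list()
  gt$baseline_missing <- list(cost = sort(cost_miss_bl),
                              utility = sort(util_miss_bl))
  gt$dropout_wave <- stats::setNames(plan$drop_wave, ids)
  attr(out, "ground_truth") <- gt
  out$unit_costs <- trial$unit_costs
  out
}
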