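# Decision-analytic layer: the incremental cost-utility ratio on the
# cost-effectiveness plane, its bootstrap uncertainty cloud, the
# cost-effectiveness acceptability curve, and net-monetary-benefit
# regression over a willingness-to-pay grid.

default_lambda_grid <- function() seq(0, 125000, by = 1000)

cep_quadrant <- function(delta_cost, delta_qaly) {
  # ties on the effect axis go to the positive-effect side; the ICUR origin
  # row (cost exactly 0) counts as the south (cost-saving) side
  e_pos <- delta_qaly >= 0
  c_pos <- delta_cost > 0
  ifelse(c_pos & e_pos, "NE",
         ifelse(!c_pos & e_pos, "SE",
                ifelse(c_pos & !e_pos, "NW", "SW")))
}

#' Incremental cost-utility ratio point estimate
#'
#' The ICUR is the cost difference per QALY gained, `delta_cost /
#' delta_qaly`, located on the cost-effectiveness plane: NE = more costly
#' and more effective, SE = cost-saving and more effective (dominant),
#' NW = more costly and less effective (dominated), SW = cost-saving and
#' less effective. Both the EUR-per-QALY scale and the EUR per 0.001 QALY
#' rescaling (`icur / 1000`) are reported.
#'
#' @param delta_cost Incremental annual cost, INT - TAU, in EUR/year.
#' @param delta_qaly Incremental annual QALY, INT - TAU.
#' @return A `cua_icur` list: `delta_cost`, `delta_qaly`, `icur` (EUR/QALY;
#'   `NA` with `defined = FALSE` when `delta_qaly == 0`),
#'   `icur_per_milli_qaly`, `quadrant`, `defined`.
#' @export
icur_point <- function(delta_cost, delta_qaly) {
  stopifnot(is.finite(delta_cost), is.finite(delta_qaly))
  defined <- delta_qaly != 0
  icur <- if (defined) delta_cost / delta_qaly else NA_real_
  structure(list(delta_cost = delta_cost, delta_qaly = delta_qaly,
                 icur = icur,
                 icur_per_milli_qaly = if (defined) icur / 1000 else NA_real_,
                 quadrant = cep_quadrant(delta_cost, delta_qaly),
                 defined = defined),
            class = "cua_icur")
}

#' @export
print.cua_icur <- function(x, ...) {
  cat("<cua_icur> dCost = ", format(x$delta_cost, digits = 6),
      " EUR/yr, dQALY = ", format(x$delta_qaly, digits = 4), "\n", sep = "")
  if (x$defined) {
    cat("  ICUR = ", format(x$icur, big.mark = ",", digits = 6), " EUR/QALY (",
        format(x$icur_per_milli_qaly, digits = 6),
        " EUR per 0.001 QALY), quadrant ", x$quadrant, "\n", sep = "")
  } else {
    cat("  ICUR undefined (dQALY = 0), quadrant ", x$quadrant, "\n", sep = "")
  }
  invisible(x)
}

#' Joint bootstrap cloud of incremental cost and QALY
#'
#' Resamples families with replacement and recomputes both the cost and the
#' QALY arm difference on the same resample, preserving their joint
#' distribution on the cost-effectiveness plane. Quadrant shares use the
#' same tie rule as [icur_point()].
#'
#' @param annual Output of [annualize()] (after any intervention-cost
#'   booking), carrying the cost column named in `cost_var`.
#' @param qalys Output of [compute_qalys()], carrying `qaly_var`.
#' @param participants Participant table (`participant_id`, `family_id`,
#'   `arm`).
#' @param B Replications (default 10000).
#' @param seed Integer seed.
#' @param cost_var,qaly_var Which summary columns to compare
#'   (defaults `annual_total`, `qaly_total`).
#' @return A `cua_cloud` list: `delta_cost` and `delta_qaly` replicate
#'   vectors, `point` (the observed [icur_point()]), `quadrant_shares`
#'   (named proportions over NE/SE/SW/NW summing to 1), `discarded`, `B`,
#'   `seed`.
#' @export
bootstrap_cloud <- function(annual, qalys, participants, B = 10000,
                            seed = 20151201, cost_var = "annual_total",
                            qaly_var = "qaly_total") {
  if (B < 100L) cua_stop("B must be >= 100")
  dat <- align_summaries(annual, qalys, participants, cost_var, qaly_var)
  check_clusters(dat$arm, dat$family_id)
  deltas <- cluster_boot_deltas(cbind(dat$cost, dat$qaly), dat$arm,
                                dat$family_id, B, seed)
  z <- dat$arm == "INT"
  point <- icur_point(mean(dat$cost[z]) - mean(dat$cost[!z]),
                      mean(dat$qaly[z]) - mean(dat$qaly[!z]))
  quad <- cep_quadrant(deltas[, 1L], deltas[, 2L])
  shares <- vapply(c("NE", "SE", "SW", "NW"),
                   function(q) mean(quad == q), numeric(1))
  structure(list(delta_cost = deltas[, 1L], delta_qaly = deltas[, 2L],
                 point = point, quadrant_shares = shares,
                 discarded = attr(deltas, "discarded"), B = B, seed = seed),
            class = "cua_cloud")
}

align_summaries <- function(annual, qalys, participants, cost_var, qaly_var) {
  ids <- annual$participant_id
  mq <- match(ids, qalys$participant_id)
  mp <- match(ids, participants$participant_id)
  if (anyNA(mq) || anyNA(mp)) {
    cua_stop("annual costs, QALYs and participants must cover the same participants")
  }
  data.frame(participant_id = ids, cost = annual[[cost_var]],
             qaly = qalys[[qaly_var]][mq], arm = participants$arm[mp],
             family_id = participants$family_id[mp])
}

#' @export
print.cua_cloud <- function(x, ...) {
  cat("<cua_cloud> ", length(x$delta_cost), " joint bootstrap replicates (seed ",
      x$seed, ")\n", sep = "")
  print(x$point)
  cat("  quadrant shares: ",
      paste(names(x$quadrant_shares),
            sprintf("%.3f", x$quadrant_shares), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value lambda, the probability that the
#' intervention is cost-effective is estimated as the fraction of bootstrap
#' replicates with strictly positive incremental net monetary benefit
#' `lambda * delta_qaly_b - delta_cost_b` (replicates exactly at zero count
#' as not cost-effective).
#'
#' @param cloud A `cua_cloud`.
#' @param lambda Willingness-to-pay grid in EUR/QALY (default 0 to 125,000
#'   in steps of 1,000).
#' @return A `cua_ceac` data frame: `lambda`, `prob_ce`.
#' @export
ceac <- function(cloud, lambda = default_lambda_grid()) {
  stopifnot(inherits(cloud, "cua_cloud"), length(cloud$delta_cost) > 0L)
  prob <- vapply(lambda, function(l)
    mean(l * cloud$delta_qaly - cloud$delta_cost > 0), numeric(1))
  structure(data.frame(lambda = lambda, prob_ce = prob),
            class = c("cua_ceac", "data.frame"))
}

#' Net-monetary-benefit regression over a willingness-to-pay grid
#'
#' For each lambda, each participant's net benefit `lambda * qaly - cost`
#' is regressed on the intervention indicator; the arm coefficient is the
#' incremental NMB, with a family-cluster-robust 95% confidence interval
#' (normal reference). The curve is affine in lambda: slope = incremental
#' QALY, intercept = minus the incremental cost.
#'
#' @inheritParams bootstrap_cloud
#' @param lambda Nonnegative willingness-to-pay grid in EUR/QALY.
#' @param conf_level Confidence level (default 0.95).
#' @return A `cua_nmb` data frame: `lambda`, `nmb`, `se`, `ll`, `ul`.
#' @export
nmb_regression <- function(annual, qalys, participants,
                           lambda = default_lambda_grid(),
                           cost_var = "annual_total",
                           qaly_var = "qaly_total", conf_level = 0.95) {
  if (any(lambda < 0)) cua_stop("lambda grid must be nonnegative")
  dat <- align_summaries(annual, qalys, participants, cost_var, qaly_var)
  check_clusters(dat$arm, dat$family_id)
  rows <- lapply(lambda, function(l) {
    est <- estimate_difference_ols(l * dat$qaly - dat$cost, dat$arm,
                                   dat$family_id, conf_level = conf_level)
    data.frame(lambda = l, nmb = est$delta, se = est$se,
               ll = est$ci_low, ul = est$ci_high)
  })
  structure(do.call(rbind, rows), class = c("cua_nmb", "data.frame"))
}

#' @export
plot.cua_cloud <- function(x, ...) {
  graphics::plot(x$delta_qaly, x$delta_cost, pch = 16, cex = 0.3,
                 col = "grey50", xlab = "Incremental QALY (INT - TAU)",
                 ylab = "Incremental annual cost (EUR, INT - TAU)", ...)
  graphics::abline(h = 0, v = 0, lty = 2)
  graphics::points(x$point$delta_qaly, x$point$delta_cost, pch = 19)
  invisible(x)
}

#' @export
plot.cua_ceac <- function(x, ...) {
  graphics::plot(x$lambda, x$prob_ce, type = "l", ylim = c(0, 1),
                 xlab = "Willingness to pay (EUR/QALY)",
                 ylab = "Probability cost-effective", ...)
  graphics::abline(h = c(0.5, 0.95), lty = 3)
  invisible(x)
}

#' @export
plot.cua_nmb <- function(x, ...) {
  graphics::plot(x$lambda, x$nmb, type = "l", ylim = range(c(x$ll, x$ul)),
                 xlab = "Willingness to pay (EUR/QALY)",
                 ylab = "Incremental net monetary benefit (EUR)", ...)
  graphics::lines(x$lambda, x$ll, lty = 2)
  graphics::lines(x$lambda, x$ul, lty = 2)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
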