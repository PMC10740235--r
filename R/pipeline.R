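# One-command orchestration: load or generate -> baseline filter -> LOCF ->
# costing -> QALYs -> incremental inference -> decision-analytic layer,
# with every output written as plain text plus a run manifest.

#' Run the full cost-utility analysis pipeline
#'
#' Executes the whole chain on either a loaded trial (CSV paths) or a
#' generated synthetic trial, and writes `annual_costs.csv`, `qalys.csv`,
#' `sixmonth_costs.csv`, `incremental_estimates.csv`, `icur.json`,
#' `ceac.csv`, `nmb.csv`, `cloud.csv` and `manifest.json` to `out_dir`.
#' Stage errors are re-raised with the failing stage named.
#'
#' @param trial A `cua_trial`, or `NULL` to use `csv_dir` / `config`.
#' @param csv_dir Directory holding `participants.csv`, `service_use.csv`,
#'   `utilities.csv`, `unit_costs.csv` (used when `trial` is `NULL`).
#' @param config A [trial_config()] for synthetic generation when neither
#'   `trial` nor `csv_dir` is given.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed: drives generation (if any), the bootstrap CIs
#'   and the ICUR cloud.
#' @param B_ci Bootstrap replications for incremental-estimate CIs
#'   (default 2000).
#' @param B_cloud Replications for the ICUR cloud (default 10000).
#' @param lambda Willingness-to-pay grid (default 0-125,000 by 1,000).
#' @param intervention_cost_child Per-child intervention cost booked into
#'   year 1 of the INT arm (default `NULL` = none).
#' @param glm_sensitivity Also fit the gamma-GLM sensitivity model per cost
#'   outcome (default `TRUE`).
#' @return Invisibly, a list with all in-memory results (`trial`,
#'   `exclusions`, `annual`, `qalys`, `estimates`, `icur`, `cloud`,
#'   `ceac`, `nmb`, `manifest`).
#' @export
run_pipeline <- function(trial = NULL, csv_dir = NULL, config = NULL,
                         out_dir, seed = 20151201, B_ci = 2000,
                         B_cloud = 10000, lambda = default_lambda_grid(),
                         intervention_cost_child = NULL,
                         glm_sensitivity = TRUE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cua_stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
               class = "cua_pipeline_error")
    })
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  trial <- stage("trial_data", {
    if (is.null(trial)) {
      if (!is.null(csv_dir)) {
        load_trial(file.path(csv_dir, "participants.csv"),
                   file.path(csv_dir, "service_use.csv"),
                   file.path(csv_dir, "utilities.csv"),
                   file.path(csv_dir, "unit_costs.csv"), quiet = TRUE)
      } else {
        generate_trial(config %||% trial_config(), seed = seed)
      }
    } else trial
  })

  flt <- stage("trial_data", filter_baseline_complete(trial))
  completed <- stage("trial_data", locf_impute(flt$trial))
  parts <- completed$participants

  annual <- stage("costing", annualize(completed))
  if (!is.null(intervention_cost_child)) {
    annual <- stage("costing",
                    add_intervention_cost(annual, parts,
                                          intervention_cost_child))
  }
  qalys <- stage("outcomes", compute_qalys(completed))

  estimates <- stage("inference", {
    fam <- parts$family_id
    arm <- parts$arm
    out <- list()
    specs <- list(cost_total = annual$annual_total,
                  cost_y1 = annual$annual_y1,
                  cost_y2 = annual$annual_y2,
                  qaly_total = qalys$qaly_total,
                  qaly_y1 = qalys$qaly_y1,
                  qaly_y2 = qalys$qaly_y2)
    for (i in seq_along(specs)) {
      nm <- names(specs)[i]
      est <- estimate_difference_ols(specs[[i]], arm, fam, outcome = nm)
      bci <- bootstrap_ci(specs[[i]], arm, fam, B = B_ci, seed = seed + i)
      est$ci_low <- bci$ci_low
      est$ci_high <- bci$ci_high
      est$method <- "ols_bootstrap"
      est$B <- B_ci
      est$seed <- seed + i
      out[[nm]] <- est
      if (glm_sensitivity && startsWith(nm, "cost")) {
        g <- estimate_difference_glm(specs[[i]], arm, fam, outcome = nm)
        g$B <- NA_integer_; g$seed <- NA_integer_
        g$delta_raw <- NA_real_
        out[[paste0(nm, "_glm")]] <-
          g[, c("outcome", "method", "delta", "delta_raw", "se", "p",
                "ci_low", "ci_high", "B", "seed")]
      }
    }
    do.call(rbind, lapply(out, function(d)
      d[, c("outcome", "method", "delta", "se", "p", "ci_low", "ci_high",
            "B", "seed")]))
  })

  cea_res <- stage("cea", {
    cloud <- bootstrap_cloud(annual, qalys, parts, B = B_cloud,
                             seed = seed + 100L)
    list(cloud = cloud, ceac = ceac(cloud, lambda),
         nmb = nmb_regression(annual, qalys, parts, lambda))
  })

  stage("write_outputs", {
    utils::write.csv(annual, file.path(out_dir, "annual_costs.csv"),
                     row.names = FALSE)
    utils::write.csv(qalys, file.path(out_dir, "qalys.csv"),
                     row.names = FALSE)
    utils::write.csv(completed$costs,
                     file.path(out_dir, "sixmonth_costs.csv"),
                     row.names = FALSE)
    utils::write.csv(estimates,
                     file.path(out_dir, "incremental_estimates.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(cea_res$ceac),
                     file.path(out_dir, "ceac.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(cea_res$nmb),
                     file.path(out_dir, "nmb.csv"), row.names = FALSE)
    utils::write.csv(data.frame(replicate = seq_along(cea_res$cloud$delta_cost),
                                delta_cost = cea_res$cloud$delta_cost,
                                delta_qaly = cea_res$cloud$delta_qaly),
                     file.path(out_dir, "cloud.csv"), row.names = FALSE)
    pt <- cea_res$cloud$point
    jsonlite::write_json(
      list(delta_cost = pt$delta_cost, delta_qaly = pt$delta_qaly,
           icur = pt$icur, icur_per_milli_qaly = pt$icur_per_milli_qaly,
           quadrant = pt$quadrant,
           quadrant_shares = as.list(cea_res$cloud$quadrant_shares)),
      file.path(out_dir, "icur.json"), auto_unbox = TRUE, digits = NA)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("cuakit")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed, B_ci = B_ci, B_cloud = B_cloud,
    lambda = list(min = min(lambda), max = max(lambda),
                  step = if (length(lambda) > 1L) lambda[2L] - lambda[1L] else NA),
    intervention_cost_child = intervention_cost_child,
    n_participants = nrow(parts),
    n_families = length(unique(parts$family_id)),
    excluded = flt$report,
    locf = attr(completed, "locf_report"),
    synthetic_config = if (!is.null(attr(trial, "ground_truth")))
      attr(trial, "ground_truth")[c("delta_cost", "delta_qaly", "seed")]
    else NULL)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")

  invisible(list(trial = completed, exclusions = flt$report, annual = annual,
                 qalys = qalys, estimates = estimates,
                 icur = cea_res$cloud$point, cloud = cea_res$cloud,
                 ceac = cea_res$ceac, nmb = cea_res$nmb,
                 manifest = manifest))
}

#' Generate a synthetic trial and write its CSV bundle
#'
#' Convenience wrapper: [generate_trial()] then [write_trial()], plus a
#' `ground_truth.json` recording the true effects and seed.
#'
#' @inheritParams generate_trial
#' @param dir Output directory.
#' @return Invisibly, the generated `cua_trial`.
#' @export
simulate_trial <- function(config = trial_config(), seed = 20151201, dir) {
  trial <- generate_trial(config, seed = seed)
  write_trial(trial, dir)
  gt <- attr(trial, "ground_truth")
  jsonlite::write_json(
    list(seed = gt$seed, delta_cost = gt$delta_cost,
         delta_qaly = gt$delta_qaly,
         baseline_missing = gt$baseline_missing,
         n_dropped_by_wave = as.list(table(
           gt$dropout_wave[is.finite(gt$dropout_wave)]))),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(trial)
}
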