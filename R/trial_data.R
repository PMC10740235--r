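# Trial data model: long-format panel tables for a two-arm trial with
# children nested in families, four 6-month assessment waves (t0..t3),
# baseline-complete-case filtering, and LOCF imputation.

#' Service categories recognised by the costing model
#'
#' The six categories of health and psychosocial care tracked per 6-month
#' recall window: psychiatric/medical inpatient and outpatient treatment,
#' institutional and ambulant child/adolescent welfare, medication, and
#' school-based services.
#'
#' @format Character vector of length 6.
#' @export
cua_categories <- c("inpatient", "outpatient", "institutional_welfare",
                    "ambulant_welfare", "medication", "school_based")

#' Trial arms
#'
#' Arm labels: `TAU` (treatment as usual, the control condition) and `INT`
#' (the intervention arm). Randomization is at the family level, so every
#' child of a family is in the same arm.
#'
#' @format Character vector of length 2.
#' @export
cua_arms <- c("TAU", "INT")

cua_waves <- 0:3

#' Construct and validate a trial bundle
#'
#' Assembles the three panel tables into a validated `cua_trial` object.
#' The cost panel and utility panel are completed to the full
#' participant x wave (x category) grid; waves never assessed are `NA` with
#' `observed = FALSE`.
#'
#' @param participants Data frame with columns `participant_id`, `family_id`,
#'   `arm` (`"TAU"`/`"INT"`), `age_years`, `sex`, `baseline_diagnosis`.
#' @param costs Long cost panel: `participant_id`, `wave` (0-3), `category`,
#'   `cost` (EUR per 6 months, `NA` if unassessed), `observed` (logical).
#' @param utilities Utility panel: `participant_id`, `wave`, `utility`
#'   (`NA` if unassessed), `observed`.
#' @param service_use Optional raw service-use table kept alongside.
#' @return A `cua_trial` list with canonically ordered components
#'   `participants`, `costs` (with an `imputed` flag column), `utilities`.
#' @export
new_trial <- function(participants, costs, utilities, service_use = NULL) {
  check_columns(participants,
                c("participant_id", "family_id", "arm", "age_years", "sex",
                  "baseline_diagnosis"), "participants")
  check_columns(costs, c("participant_id", "wave", "category", "cost",
                         "observed"), "costs")
  check_columns(utilities, c("participant_id", "wave", "utility", "observed"),
                "utilities")

  participants$participant_id <- as.character(participants$participant_id)
  participants$family_id <- as.character(participants$family_id)
  if (anyDuplicated(participants$participant_id)) {
    cua_stop("participant_id values must be unique")
  }
  bad_arm <- setdiff(unique(participants$arm), cua_arms)
  if (length(bad_arm) > 0L) {
    cua_stop("unknown arm value(s): ", paste(bad_arm, collapse = ", "))
  }
  # family-level randomization: family -> arm must be a function
  split_fams <- tapply(participants$arm, participants$family_id,
                       function(a) length(unique(a)))
  if (any(split_fams > 1L)) {
    cua_stop("family assigned to both arms: ",
             paste(names(split_fams)[split_fams > 1L], collapse = ", "))
  }

  bad_cat <- setdiff(unique(as.character(costs$category)), cua_categories)
  if (length(bad_cat) > 0L) {
    cua_stop("unknown service category value(s): ",
             paste(bad_cat, collapse = ", "))
  }
  for (tab in list(costs, utilities)) {
    extra <- setdiff(unique(as.character(tab$participant_id)),
                     participants$participant_id)
    if (length(extra) > 0L) {
      cua_stop("participant(s) in panel table absent from participant table: ",
               paste(utils::head(extra, 5L), collapse = ", "))
    }
    if (!all(tab$wave %in% cua_waves)) {
      cua_stop("wave must be coded 0, 1, 2 or 3")
    }
  }
  if (any(costs$cost < 0, na.rm = TRUE)) cua_stop("costs must be >= 0")

  ids <- participants$participant_id
  costs <- complete_cost_grid(costs, ids)
  utilities <- complete_utility_grid(utilities, ids)
  if (!"imputed" %in% names(costs)) costs$imputed <- FALSE
  if (!"imputed" %in% names(utilities)) utilities$imputed <- FALSE

  structure(list(participants = participants, costs = costs,
                 utilities = utilities, service_use = service_use),
            class = "cua_trial")
}

# Expand to the full participant x wave x category grid in canonical order
# (participant, then wave, then category). Absent cells are unobserved NA.
complete_cost_grid <- function(costs, ids) {
  grid <- expand.grid(category = cua_categories, wave = cua_waves,
                      participant_id = ids, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)[, 3:1]
  key_g <- paste(grid$participant_id, grid$wave, grid$category)
  key_c <- paste(costs$participant_id, costs$wave, costs$category)
  if (anyDuplicated(key_c)) cua_stop("duplicate (participant, wave, category) cost rows")
  m <- match(key_g, key_c)
  grid$cost <- costs$cost[m]
  grid$observed <- !is.na(m) & costs$observed[m] %in% TRUE
  grid$cost[!grid$observed & is.na(m)] <- NA_real_
  grid$imputed <- if ("imputed" %in% names(costs)) costs$imputed[m] %in% TRUE else FALSE
  rownames(grid) <- NULL
  grid
}

complete_utility_grid <- function(utilities, ids) {
  grid <- expand.grid(wave = cua_waves, participant_id = ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, 2:1]
  key_g <- paste(grid$participant_id, grid$wave)
  key_u <- paste(utilities$participant_id, utilities$wave)
  if (anyDuplicated(key_u)) cua_stop("duplicate (participant, wave) utility rows")
  m <- match(key_g, key_u)
  grid$utility <- utilities$utility[m]
  grid$observed <- !is.na(m) & utilities$observed[m] %in% TRUE
  grid$imputed <- if ("imputed" %in% names(utilities)) utilities$imputed[m] %in% TRUE else FALSE
  rownames(grid) <- NULL
  grid
}

#' @export
print.cua_trial <- function(x, ...) {
  p <- x$participants
  cat("<cua_trial> ", nrow(p), " participants in ",
      length(unique(p$family_id)), " families (",
      sum(p$arm == "INT"), " INT / ", sum(p$arm == "TAU"), " TAU)\n", sep = "")
  obs <- tapply(x$utilities$observed, x$utilities$wave, sum)
  cat("  utility observations by wave t0..t3: ",
      paste(obs, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Load a trial from its CSV tables
#'
#' Reads the participant, service-use and utility tables (UTF-8 CSV with
#' header rows, waves coded 0-3), validates enum values and key consistency,
#' and prices service use into the six-category cost panel.
#'
#' The service-use dialect distinguishes zero use from a missed assessment:
#' an assessed participant-wave carries at least one row (`assessed = 1`,
#' possibly with `units = 0`), while a wave with no rows at all — or rows
#' flagged `assessed = 0` — is unobserved and later subject to LOCF.
#'
#' @param participants_csv,service_use_csv,utilities_csv Paths to the three
#'   tables. `service_use.csv` columns: `participant_id`, `wave`, `category`,
#'   `item`, `units`, `assessed`. `utilities.csv` columns: `participant_id`,
#'   `wave`, `utility`, `assessed`.
#' @param unit_costs_csv Path to the unit-cost table (`category`, `item`,
#'   `unit`, `unit_cost_eur`).
#' @param quiet Suppress the per-arm row-count log message.
#' @return A validated [new_trial()] bundle.
#' @export
load_trial <- function(participants_csv, service_use_csv, utilities_csv,
                       unit_costs_csv, quiet = FALSE) {
  for (f in c(participants_csv, service_use_csv, utilities_csv, unit_costs_csv)) {
    if (!file.exists(f)) cua_stop("file not found: ", f)
  }
  participants <- utils::read.csv(participants_csv, stringsAsFactors = FALSE)
  service_use <- utils::read.csv(service_use_csv, stringsAsFactors = FALSE)
  utilities <- utils::read.csv(utilities_csv, stringsAsFactors = FALSE)
  unit_costs <- utils::read.csv(unit_costs_csv, stringsAsFactors = FALSE)

  check_columns(service_use, c("participant_id", "wave", "category", "item",
                               "units", "assessed"), "service_use")
  check_columns(utilities, c("participant_id", "wave", "utility", "assessed"),
                "utilities")
  service_use$participant_id <- as.character(service_use$participant_id)
  utilities$participant_id <- as.character(utilities$participant_id)

  costs <- price_service_use(service_use, unit_costs)
  utilities$observed <- utilities$assessed %in% c(1L, TRUE)
  utilities$utility[!utilities$observed] <- NA_real_

  trial <- new_trial(participants, costs, utilities, service_use = service_use)
  if (!quiet) {
    p <- trial$participants
    message("loaded ", nrow(p), " participants (INT=", sum(p$arm == "INT"),
            ", TAU=", sum(p$arm == "TAU"), "); utility observations per wave: ",
            paste(tapply(trial$utilities$observed, trial$utilities$wave, sum),
                  collapse = "/"))
  }
  trial
}

#' Write a trial bundle to CSV tables
#'
#' Serialises a bundle to the same dialect [load_trial()] reads:
#' `participants.csv`, `service_use.csv`, `utilities.csv` and
#' `unit_costs.csv`. Category-level costs are written as one pseudo-item
#' `"(direct)"` per category priced at 1 EUR per unit, so a written trial
#' reprices to exactly the same cost panel on re-read.
#'
#' @param trial A `cua_trial`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the four file paths.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "cua_trial"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("participants.csv", "service_use.csv",
                            "utilities.csv", "unit_costs.csv"))
  utils::write.csv(trial$participants, paths[1], row.names = FALSE)

  cc <- trial$costs[!trial$costs$imputed, ]
  su <- data.frame(participant_id = cc$participant_id, wave = cc$wave,
                   category = cc$category, item = "(direct)",
                   units = ifelse(cc$observed, cc$cost, NA_real_),
                   assessed = as.integer(cc$observed))
  su <- su[su$assessed == 1L, ]
  utils::write.csv(su, paths[2], row.names = FALSE)

  uu <- trial$utilities[!trial$utilities$imputed, ]
  utils::write.csv(data.frame(participant_id = uu$participant_id,
                              wave = uu$wave, utility = uu$utility,
                              assessed = as.integer(uu$observed)),
                   paths[3], row.names = FALSE)
  utils::write.csv(data.frame(category = cua_categories, item = "(direct)",
                              unit = "eur", unit_cost_eur = 1),
                   paths[4], row.names = FALSE)
  invisible(paths)
}

#' Drop participants without complete baseline data
#'
#' Intention-to-treat analysis requires an anchor observation: participants
#' missing their baseline (t0) cost assessment or baseline utility are
#' removed, and a per-arm exclusion report is returned. All retained
#' participants have observed t0 cost and utility, so LOCF can complete
#' every later wave.
#'
#' @param trial A `cua_trial`.
#' @return List with `trial` (the retained bundle) and `report`: a data frame
#'   of per-arm participant and family exclusion counts, with the excluded
#'   ids in attribute `"excluded_ids"`.
#' @export
filter_baseline_complete <- function(trial) {
  stopifnot(inherits(trial, "cua_trial"))
  c0 <- trial$costs[trial$costs$wave == 0L, ]
  cost_missing <- tapply(!c0$observed, c0$participant_id, any)
  u0 <- trial$utilities[trial$utilities$wave == 0L, ]
  util_missing <- !u0$observed[match(names(cost_missing), u0$participant_id)]
  drop <- names(cost_missing)[cost_missing | util_missing]

  p <- trial$participants
  keep_ids <- setdiff(p$participant_id, drop)
  if (length(keep_ids) == 0L) cua_stop("no participants remain after baseline filtering")

  dropped <- p[p$participant_id %in% drop, ]
  report <- data.frame(
    arm = cua_arms,
    excluded_participants = vapply(cua_arms, function(a)
      sum(dropped$arm == a), integer(1)),
    excluded_families = vapply(cua_arms, function(a)
      length(unique(dropped$family_id[dropped$arm == a])), integer(1)),
    row.names = NULL)
  attr(report, "excluded_ids") <- sort(drop)

  keep <- p$participant_id %in% keep_ids
  trial2 <- new_trial(p[keep, , drop = FALSE],
                      trial$costs[trial$costs$participant_id %in% keep_ids, ],
                      trial$utilities[trial$utilities$participant_id %in% keep_ids, ],
                      service_use = trial$service_use)
  list(trial = trial2, report = report)
}

#' Last-observation-carried-forward imputation
#'
#' Replaces each missing wave-level value — per cost category and per
#' utility — with the participant's most recent observed value of the same
#' variable. Observed values are never altered, and a later observed value
#' is never overwritten by a carried-forward one. Requires complete
#' baselines (run [filter_baseline_complete()] first); a baseline gap is a
#' hard error because there is nothing to carry forward.
#'
#' @param trial A baseline-complete `cua_trial`.
#' @return The completed bundle; imputed cells have `imputed = TRUE` and
#'   retain `observed = FALSE`. Attribute `"locf_report"` holds, per wave
#'   t1-t3, the number of participants with at least one imputed cost value
#'   and with an imputed utility.
#' @export
locf_impute <- function(trial) {
  stopifnot(inherits(trial, "cua_trial"))
  ids <- trial$participants$participant_id
  n <- length(ids)

  # costs: series = participant x category over waves, canonical order
  # (participant, wave, category) => array dims (category, wave, participant)
  cv <- ifelse(trial$costs$observed | trial$costs$imputed,
               trial$costs$cost, NA_real_)
  arr <- array(cv, dim = c(6L, 4L, n))
  if (anyNA(arr[, 1L, ])) {
    cua_stop("baseline cost values missing; run filter_baseline_complete() first")
  }
  uv <- ifelse(trial$utilities$observed | trial$utilities$imputed,
               trial$utilities$utility, NA_real_)
  um <- matrix(uv, nrow = 4L)              # waves x participants
  if (anyNA(um[1L, ])) {
    cua_stop("baseline utility values missing; run filter_baseline_complete() first")
  }
  for (w in 2:4) {
    slice <- arr[, w, , drop = FALSE]
    prev <- arr[, w - 1L, , drop = FALSE]
    gap <- is.na(slice)
    slice[gap] <- prev[gap]
    arr[, w, ] <- slice
    ug <- is.na(um[w, ])
    um[w, ug] <- um[w - 1L, ug]
  }

  costs <- trial$costs
  filled_c <- is.na(cv) & !is.na(as.vector(arr))
  costs$cost <- as.vector(arr)
  costs$imputed <- costs$imputed | filled_c
  utilities <- trial$utilities
  filled_u <- is.na(uv) & !is.na(as.vector(um))
  utilities$utility <- as.vector(um)
  utilities$imputed <- utilities$imputed | filled_u

  out <- new_trial(trial$participants, costs, utilities,
                   service_use = trial$service_use)
  # per-wave counts of participants with >= 1 imputed value
  cost_imp <- apply(array(costs$imputed, dim = c(6L, 4L, n)), c(2L, 3L), any)
  util_imp <- matrix(utilities$imputed, nrow = 4L)
  attr(out, "locf_report") <- data.frame(
    wave = 1:3,
    cost_imputed = rowSums(cost_imp)[2:4],
    utility_imputed = rowSums(util_imp)[2:4])
  out
}
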