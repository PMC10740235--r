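# Costing: price service use against a unit-cost table, aggregate the
# four 6-month cost measures into annual summaries, and handle the
# intervention's own delivery cost.

#' Price a service-use table into a six-category cost panel
#'
#' Multiplies reported service units by their unit costs and sums within
#' category, per participant and wave. Every `(category, item)` pair in the
#' service-use table must be priced; an unpriced item is a hard error naming
#' the item. An assessed wave with no use in a category costs zero; a wave
#' whose rows are flagged `assessed = 0` (or that has no rows at all, after
#' grid completion in [new_trial()]) is missing, not zero.
#'
#' @param service_use Data frame: `participant_id`, `wave`, `category`,
#'   `item`, `units` (per 6 months), `assessed` (0/1).
#' @param unit_costs Data frame: `category`, `item`, `unit_cost_eur` (> 0).
#' @return Long cost panel (`participant_id`, `wave`, `category`, `cost`,
#'   `observed`) covering every assessed participant-wave.
#' @export
price_service_use <- function(service_use, unit_costs) {
  check_columns(service_use, c("participant_id", "wave", "category", "item",
                               "units", "assessed"), "service_use")
  check_columns(unit_costs, c("category", "item", "unit_cost_eur"),
                "unit_costs")
  if (any(unit_costs$unit_cost_eur <= 0)) {
    cua_stop("unit costs must be strictly positive")
  }
  bad_cat <- setdiff(unique(as.character(service_use$category)), cua_categories)
  if (length(bad_cat) > 0L) {
    cua_stop("unknown service category value(s): ",
             paste(bad_cat, collapse = ", "))
  }
  if (any(service_use$units < 0, na.rm = TRUE)) {
    cua_stop("service units must be >= 0")
  }

  su <- service_use[service_use$assessed %in% c(1L, TRUE), , drop = FALSE]
  use_rows <- su[!is.na(su$units) & su$units > 0, , drop = FALSE]
  key <- paste(use_rows$category, use_rows$item, sep = "\r")
  price_key <- paste(unit_costs$category, unit_costs$item, sep = "\r")
  m <- match(key, price_key)
  if (anyNA(m)) {
    unpriced <- unique(paste0(use_rows$category[is.na(m)], "/",
                              use_rows$item[is.na(m)]))
    cua_stop("no unit cost for item(s): ", paste(unpriced, collapse = ", "))
  }
  use_rows$line_cost <- use_rows$units * unit_costs$unit_cost_eur[m]

  # one cell per assessed participant x wave x category; zero where unused
  cells <- unique(su[, c("participant_id", "wave")])
  grid <- merge(cells, data.frame(category = cua_categories), by = NULL)
  agg_key <- paste(use_rows$participant_id, use_rows$wave, use_rows$category)
  sums <- tapply(use_rows$line_cost, agg_key, sum)
  grid$cost <- as.numeric(sums[paste(grid$participant_id, grid$wave,
                                     grid$category)])
  grid$cost[is.na(grid$cost)] <- 0
  grid$observed <- TRUE
  grid[order(grid$participant_id, grid$wave,
             match(grid$category, cua_categories)), , drop = FALSE]
}

#' Annualize the four 6-month cost measures
#'
#' With assessments at baseline and 6, 12 and 18 months, each covering the
#' preceding 6 months, the average annual cost over the 24-month horizon is
#' `(C_t0 + C_t1 + C_t2 + C_t3) / 2`; the first study year costs
#' `C_t0 + C_t1` and the second `C_t2 + C_t3`. The t0 window precedes
#' randomization, which anchors the overall average but makes it partly
#' insensitive to the intervention — hence the two per-year summaries.
#'
#' @param trial A `cua_trial` whose cost panel is complete (post-LOCF), or a
#'   long cost panel with no missing assessed values.
#' @return Data frame: `participant_id`, `annual_total`, `annual_y1`,
#'   `annual_y2` (EUR/year). `annual_total == (annual_y1 + annual_y2) / 2`
#'   holds exactly.
#' @export
annualize <- function(trial) {
  costs <- if (inherits(trial, "cua_trial")) trial$costs else trial
  check_columns(costs, c("participant_id", "wave", "category", "cost"),
                "cost panel")
  ids <- unique(costs$participant_id)
  if (anyNA(costs$cost)) {
    cua_stop("cost panel has missing waves; run locf_impute() first")
  }
  key <- paste(costs$participant_id, costs$wave)
  wave_tot <- tapply(costs$cost, key, sum)
  per_wave <- matrix(wave_tot[paste(rep(ids, each = 4L), rep(0:3, length(ids)))],
                     nrow = 4L)
  if (anyNA(per_wave)) cua_stop("cost panel has missing waves; all four waves required")
  y1 <- per_wave[1L, ] + per_wave[2L, ]
  y2 <- per_wave[3L, ] + per_wave[4L, ]
  data.frame(participant_id = ids, annual_total = (y1 + y2) / 2,
             annual_y1 = y1, annual_y2 = y2)
}

#' Intervention delivery cost per family
#'
#' Staff cost of delivering the family intervention: hourly staff rate times
#' total contact hours per family.
#'
#' @param hourly_rate Staff cost in EUR per hour (default 102.57, the
#'   average of a psychiatrist's and a psychologist's hourly rate).
#' @param total_hours Total intervention time per family in hours
#'   (default 7, the average over the session schedule).
#' @return EUR per family.
#' @export
intervention_cost_per_family <- function(hourly_rate = 102.57,
                                         total_hours = 7) {
  if (hourly_rate < 0 || total_hours < 0) {
    cua_stop("hourly_rate and total_hours must be nonnegative")
  }
  hourly_rate * total_hours
}

#' Intervention delivery cost per child
#'
#' Divides the per-family cost by the mean number of participating children
#' per family, optionally rounding to a budgeting granularity.
#'
#' @param per_family_cost EUR per family, e.g. from
#'   [intervention_cost_per_family()].
#' @param children_per_family Mean children per family (default 1.6).
#' @param round_to Optional rounding granularity in EUR (e.g. `50` rounds
#'   448.74 to 450); `NULL` for no rounding.
#' @return EUR per child.
#' @export
intervention_cost_per_child <- function(per_family_cost,
                                        children_per_family = 1.6,
                                        round_to = NULL) {
  if (children_per_family <= 0) cua_stop("children_per_family must be > 0")
  x <- per_family_cost / children_per_family
  if (!is.null(round_to)) x <- round(x / round_to) * round_to
  x
}

#' Book the per-child intervention cost into annual cost summaries
#'
#' The intervention is delivered during the first study year, so its
#' per-child cost is added to `annual_y1` for intervention-arm participants
#' only; `annual_total` averages over two years and therefore gains half of
#' it. Control-arm participants are untouched.
#'
#' @param annual Output of [annualize()].
#' @param participants Participant table carrying `participant_id` and `arm`.
#' @param per_child_cost EUR per child (>= 0).
#' @return `annual` with the intervention cost booked.
#' @export
add_intervention_cost <- function(annual, participants, per_child_cost) {
  if (per_child_cost < 0) cua_stop("per_child_cost must be >= 0")
  arm <- participants$arm[match(annual$participant_id,
                                participants$participant_id)]
  if (anyNA(arm)) cua_stop("participant(s) in annual summary missing from participant table")
  is_int <- arm == "INT"
  annual$annual_y1 <- annual$annual_y1 + is_int * per_child_cost
  annual$annual_total <- annual$annual_total + is_int * per_child_cost / 2
  annual
}
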