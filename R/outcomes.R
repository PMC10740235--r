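# Outcomes: instrument-to-utility mapping and QALYs as area under the
# utility curve over the four assessment waves.

#' Read an additive utility-mapping table
#'
#' The mapping CSV carries one intercept row (`item = "(intercept)"`,
#' `response_level` empty or `NA`) and one row per item x response level
#' with its additive coefficient. The valuation coefficients themselves are
#' user-supplied — published tariff sets are not bundled.
#'
#' @param path CSV with columns `item`, `response_level`, `coefficient`.
#' @return A `cua_utility_mapping` list with `intercept` and a coefficient
#'   lookup table.
#' @export
read_utility_mapping <- function(path) {
  if (!file.exists(path)) cua_stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(tab, c("item", "response_level", "coefficient"),
                "utility mapping")
  ic <- tab$item == "(intercept)"
  if (sum(ic) != 1L) cua_stop("utility mapping needs exactly one (intercept) row")
  structure(list(intercept = tab$coefficient[ic],
                 coefficients = tab[!ic, , drop = FALSE]),
            class = "cua_utility_mapping")
}

#' Map instrument item responses to a utility score
#'
#' Deterministic additive valuation: utility = intercept + the sum of the
#' coefficient attached to each item's observed response level, clamped to
#' the declared utility range.
#'
#' @param responses Named list or vector: item -> response level.
#' @param mapping A `cua_utility_mapping` from [read_utility_mapping()], or a
#'   list with `intercept` and `coefficients` (data frame `item`,
#'   `response_level`, `coefficient`).
#' @param bounds Numeric length-2 clamp range within `[-1, 1]`
#'   (default `c(-1, 1)`, i.e. no effective clamping for typical tariffs).
#' @return Utility score (dimensionless).
#' @export
map_to_utility <- function(responses, mapping, bounds = c(-1, 1)) {
  stopifnot(length(bounds) == 2L, bounds[1] <= bounds[2],
            bounds[1] >= -1, bounds[2] <= 1)
  co <- mapping$coefficients
  items <- names(responses)
  if (is.null(items)) cua_stop("responses must be named by item")
  total <- mapping$intercept
  for (it in items) {
    rows <- co[co$item == it, , drop = FALSE]
    if (nrow(rows) == 0L) cua_stop("no mapping coefficients for item: ", it)
    hit <- rows$response_level == responses[[it]]
    if (!any(hit)) {
      cua_stop("response level ", responses[[it]], " out of range for item ", it)
    }
    total <- total + rows$coefficient[which(hit)[1L]]
  }
  min(max(total, bounds[1]), bounds[2])
}

#' Compute QALYs as area under the utility curve
#'
#' With two utility assessments per year, each wave represents 0.5 QALYs, so
#' the average annual QALY over the 24-month horizon is the plain mean of
#' the four wave utilities; the per-year QALYs are the means of their two
#' waves. (A trapezoid AUC is available via `method = "trapezoid"`, which
#' interpolates between adjacent waves; with equally spaced waves it differs
#' from the plain mean only through the half-weighted endpoints. The plain
#' mean is the default convention.)
#'
#' @param trial A `cua_trial` with a complete utility panel (post-LOCF), or
#'   the utility panel itself.
#' @param method `"mean"` (default) or `"trapezoid"` for `qaly_total`.
#' @return Data frame: `participant_id`, `qaly_total`, `qaly_y1`, `qaly_y2`
#'   (QALY/year). Under the default, `qaly_total == (qaly_y1 + qaly_y2) / 2`
#'   exactly.
#' @export
compute_qalys <- function(trial, method = c("mean", "trapezoid")) {
  method <- match.arg(method)
  utilities <- if (inherits(trial, "cua_trial")) trial$utilities else trial
  check_columns(utilities, c("participant_id", "wave", "utility"),
                "utility panel")
  if (anyNA(utilities$utility)) {
    cua_stop("utility panel has missing waves; run locf_impute() first")
  }
  ids <- unique(utilities$participant_id)
  key <- paste(utilities$participant_id, utilities$wave)
  u <- matrix(utilities$utility[match(paste(rep(ids, each = 4L),
                                            rep(0:3, length(ids))), key)],
              nrow = 4L)
  if (anyNA(u)) cua_stop("utility panel must contain all four waves per participant")
  qaly_y1 <- (u[1L, ] + u[2L, ]) / 2
  qaly_y2 <- (u[3L, ] + u[4L, ]) / 2
  qaly_total <- if (method == "mean") {
    (qaly_y1 + qaly_y2) / 2        # = mean of the four waves, exactly
  } else {
    # trapezoid over 4 equally spaced waves spanning 18 months, rescaled to
    # an annual rate: half-weight on the endpoint waves
    (u[1L, ] / 2 + u[2L, ] + u[3L, ] + u[4L, ] / 2) / 3
  }
  data.frame(participant_id = ids, qaly_total = qaly_total,
             qaly_y1 = qaly_y1, qaly_y2 = qaly_y2)
}
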