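# Incremental estimation with family-cluster-robust uncertainty.
# Children of the same family share unobserved environment, so all variance
# estimation treats the family as the sampling/resampling unit.

arm_indicator <- function(arm) {
  bad <- setdiff(unique(arm), cua_arms)
  if (length(bad) > 0L) cua_stop("unknown arm value(s): ", paste(bad, collapse = ", "))
  as.integer(arm == "INT")
}

check_clusters <- function(arm, cluster) {
  if (length(unique(arm)) < 2L) cua_stop("arm indicator is constant; need both arms")
  split_arm <- tapply(arm, cluster, function(a) length(unique(a)))
  if (any(split_arm > 1L)) cua_stop("cluster split across arms")
  if (length(unique(cluster)) < 2L) {
    cua_stop("single cluster: cluster-robust variance needs at least 2 families")
  }
  invisible(NULL)
}

#' Arm difference by cluster-robust OLS
#'
#' Regresses the outcome on an intervention indicator (intercept + indicator
#' model, no covariates) and reports the indicator coefficient — identical to
#' the difference in arm means — with a family-cluster-robust sandwich
#' standard error (CR1, i.e. HC0 meat scaled by G/(G-1) over G clusters).
#'
#' @param y Numeric outcome per participant (annual cost, QALY, or a
#'   6-month category cost).
#' @param arm Arm labels (`"TAU"`/`"INT"`) per participant.
#' @param cluster Family id per participant.
#' @param outcome Label recorded on the estimate.
#' @param df Reference distribution for the p-value and CI: `"normal"`
#'   (default) or `"t"` with G-1 degrees of freedom.
#' @param conf_level Confidence level (default 0.95; alpha 0.05).
#' @return A one-row `cua_estimate` data frame: `outcome`, `method`,
#'   `delta` (INT - TAU), `delta_raw` (raw mean difference, equal to `delta`
#'   here), `se`, `p`, `ci_low`, `ci_high`.
#' @export
estimate_difference_ols <- function(y, arm, cluster, outcome = "outcome",
                                    df = c("normal", "t"),
                                    conf_level = 0.95) {
  df <- match.arg(df)
  check_clusters(arm, cluster)
  z <- arm_indicator(arm)
  fit <- stats::lm(y ~ z)
  delta <- unname(stats::coef(fit)["z"])
  vc <- sandwich::vcovCL(fit, cluster = cluster, type = "HC0", cadjust = TRUE)
  se <- sqrt(vc["z", "z"])
  G <- length(unique(cluster))
  stat <- if (se > 0) delta / se else ifelse(delta == 0, 0, Inf * sign(delta))
  if (df == "normal") {
    p <- 2 * stats::pnorm(-abs(stat))
    q <- stats::qnorm(1 - (1 - conf_level) / 2)
  } else {
    p <- 2 * stats::pt(-abs(stat), df = G - 1L)
    q <- stats::qt(1 - (1 - conf_level) / 2, df = G - 1L)
  }
  structure(data.frame(outcome = outcome, method = "ols_robust",
                       delta = delta,
                       delta_raw = mean(y[z == 1L]) - mean(y[z == 0L]),
                       se = se, p = p,
                       ci_low = delta - q * se, ci_high = delta + q * se),
            class = c("cua_estimate", "data.frame"))
}

# Family-level resampling engine shared by bootstrap_ci() and
# bootstrap_cloud(): families drawn with replacement from the pooled list;
# every child of a drawn family enters (repeatedly for repeated draws).
# Returns a B x ncol(Y) matrix of INT-TAU mean differences.
cluster_boot_deltas <- function(Y, arm, cluster, B, seed,
                                max_discard_frac = 0.01) {
  Y <- as.matrix(Y)
  z <- arm_indicator(arm)
  fams <- sort(unique(cluster))
  G <- length(fams)
  fi <- match(cluster, fams)
  S <- rowsum(Y, fi, reorder = TRUE)               # G x k per-family sums
  nf <- as.vector(rowsum(rep(1, length(fi)), fi, reorder = TRUE))
  fam_int <- as.vector(rowsum(z, fi, reorder = TRUE)) > 0

  res <- with_seed(seed, {
    idx <- matrix(sample.int(G, G * B, replace = TRUE), nrow = G)
    n_int <- colSums(matrix((nf * fam_int)[idx], nrow = G))
    n_tau <- colSums(matrix((nf * !fam_int)[idx], nrow = G))
    deltas <- matrix(NA_real_, nrow = B, ncol = ncol(Y))
    for (j in seq_len(ncol(Y))) {
      s_int <- colSums(matrix((S[, j] * fam_int)[idx], nrow = G))
      s_tau <- colSums(matrix((S[, j] * !fam_int)[idx], nrow = G))
      deltas[, j] <- s_int / n_int - s_tau / n_tau
    }
    list(deltas = deltas, bad = n_int == 0 | n_tau == 0)
  })
  n_bad <- sum(res$bad)
  if (n_bad > 0L) {
    if (n_bad > max_discard_frac * B) {
      warning(sprintf("cluster bootstrap discarded %d of %d replicates (> %.0f%%) that collapsed to a single arm",
                      n_bad, B, 100 * max_discard_frac), call. = FALSE)
    }
    res$deltas <- res$deltas[!res$bad, , drop = FALSE]
  }
  attr(res$deltas, "discarded") <- n_bad
  res$deltas
}

#' Nonparametric cluster-bootstrap confidence interval for an arm difference
#'
#' Resamples families with replacement (all children of a drawn family
#' enter, repeated families enter repeatedly), recomputes the INT - TAU
#' difference per replicate, and returns the percentile 2.5/97.5 interval.
#' Replicates whose resample contains only one arm are discarded and
#' counted; more than 1% discarded triggers a warning.
#'
#' @inheritParams estimate_difference_ols
#' @param B Number of bootstrap replications (>= 100; default 2000).
#' @param seed Integer seed; identical seeds give identical intervals.
#' @param conf_level Confidence level (default 0.95).
#' @return List: `ci_low`, `ci_high`, `deltas` (the replicate differences),
#'   `discarded`, `B`, `seed`.
#' @export
bootstrap_ci <- function(y, arm, cluster, B = 2000, seed = 20151201,
                         conf_level = 0.95) {
  if (B < 100L) cua_stop("B must be >= 100")
  check_clusters(arm, cluster)
  deltas <- cluster_boot_deltas(matrix(y, ncol = 1L), arm, cluster, B, seed)
  alpha <- (1 - conf_level) / 2
  qs <- stats::quantile(deltas[, 1L], c(alpha, 1 - alpha), names = FALSE,
                        type = 7)
  list(ci_low = qs[1L], ci_high = qs[2L], deltas = deltas[, 1L],
       discarded = attr(deltas, "discarded"), B = B, seed = seed)
}

#' Gamma-GLM sensitivity model for skewed cost differences
#'
#' Fits a gamma-family generalized linear model with log link to costs,
#' with a family-cluster-robust standard error, as a sensitivity check on
#' the OLS inference for heavily right-skewed cost data. Because the gamma
#' support excludes zero, a configurable positive offset (default 1 EUR) is
#' added to all costs whenever any cost is nonpositive.
#'
#' @inheritParams estimate_difference_ols
#' @param zero_offset EUR added to every cost when zeros are present
#'   (default 1).
#' @return A one-row `cua_estimate`: `delta` is the arm coefficient on the
#'   log scale, `ratio` its exponential (INT/TAU mean-cost ratio), and
#'   `delta_eur` the marginalized EUR difference
#'   `mean(offset costs | TAU) * (ratio - 1)`; `se`, `p`, `ci_low`,
#'   `ci_high` are on the log-coefficient scale.
#' @export
estimate_difference_glm <- function(y, arm, cluster, outcome = "outcome",
                                    zero_offset = 1, conf_level = 0.95) {
  check_clusters(arm, cluster)
  z <- arm_indicator(arm)
  y_adj <- y
  if (any(y <= 0)) {
    if (zero_offset <= 0) cua_stop("zero_offset must be > 0 when costs include zeros")
    y_adj <- y + zero_offset
  }
  ctl <- stats::glm.control(maxit = 200)
  fit <- tryCatch(
    stats::glm(y_adj ~ z, family = stats::Gamma(link = "log"), control = ctl),
    error = function(e) cua_stop("gamma GLM failed: ", conditionMessage(e)),
    warning = function(w) {
      f <- suppressWarnings(stats::glm(y_adj ~ z,
                                       family = stats::Gamma(link = "log"),
                                       control = ctl))
      if (!f$converged) {
        cua_stop("gamma GLM did not converge after ", f$iter, " iterations")
      }
      f
    })
  if (!fit$converged) {
    cua_stop("gamma GLM did not converge after ", fit$iter, " iterations")
  }
  delta <- unname(stats::coef(fit)["z"])
  vc <- sandwich::vcovCL(fit, cluster = cluster, type = "HC0", cadjust = TRUE)
  se <- sqrt(vc["z", "z"])
  stat <- if (se > 0) delta / se else 0
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(outcome = outcome, method = "glm_gamma",
                    delta = delta, ratio = exp(delta),
                    delta_eur = mean(y_adj[z == 0L]) * (exp(delta) - 1),
                    se = se, p = 2 * stats::pnorm(-abs(stat)),
                    ci_low = delta - q * se, ci_high = delta + q * se)
  structure(out, class = c("cua_estimate", "data.frame"))
}

#' @export
print.cua_estimate <- function(x, ...) {
  cat("<cua_estimate> ", x$outcome[1], " [", x$method[1], "]\n", sep = "")
  print.data.frame(format(as.data.frame(x), digits = 4), row.names = FALSE)
  invisible(x)
}
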