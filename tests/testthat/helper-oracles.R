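# Independent oracles and tiny in-code fixtures shared across test files.

# Closed-form cluster-robust sandwich: (X'X)^-1 [G/(G-1) * sum_g s_g s_g']
# (X'X)^-1 with s_g = X_g' e_g, written out directly from the definition.
oracle_cluster_vcov <- function(y, x, cluster) {
  X <- cbind(1, x)
  bread <- solve(t(X) %*% X)
  beta <- bread %*% t(X) %*% y
  e <- as.vector(y - X %*% beta)
  G <- length(unique(cluster))
  meat <- matrix(0, 2, 2)
  for (g in unique(cluster)) {
    i <- cluster == g
    s <- t(X[i, , drop = FALSE]) %*% e[i]
    meat <- meat + s %*% t(s)
  }
  list(beta = as.vector(beta),
       vcov = bread %*% (G / (G - 1) * meat) %*% bread)
}

# Hand-rolled IRLS for a gamma GLM with log link. For this family/link the
# IRLS weights are identically 1, so each step is OLS on the working
# response z = eta + (y - mu) / mu.
oracle_gamma_irls <- function(y, x, tol = 1e-12, maxit = 100) {
  X <- cbind(1, x)
  beta <- c(log(mean(y)), 0)
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    beta_new <- as.vector(solve(t(X) %*% X, t(X) %*% z))
    if (max(abs(beta_new - beta)) < tol) return(beta_new)
    beta <- beta_new
  }
  beta
}

# An 8-participant / 4-family deterministic micro-trial used across modules
# (two families per arm, two children each).
tiny_participants <- function() {
  data.frame(
    participant_id = paste0("P", 1:8),
    family_id = rep(c("F1", "F2", "F3", "F4"), each = 2),
    arm = rep(c("TAU", "TAU", "INT", "INT"), each = 2),
    age_years = c(8, 11, 14, 9, 12, 16, 7, 13),
    sex = rep(c("female", "male"), 4),
    baseline_diagnosis = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

# The 6-observation / 3-family instance used for closed-form oracle checks.
micro_instance <- function() {
  list(y = c(120, 340, 80, 95, 410, 60),
       arm = c("TAU", "TAU", "TAU", "TAU", "INT", "INT"),
       cluster = c("F1", "F1", "F2", "F2", "F3", "F3"))
}

# Full observed cost/utility panels with simple recognisable values.
tiny_trial <- function(base_cost = 100, utility = 0.8) {
  p <- tiny_participants()
  costs <- expand.grid(category = cua_categories, wave = 0:3,
                       participant_id = p$participant_id,
                       KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)[, 3:1]
  costs$cost <- base_cost
  costs$observed <- TRUE
  utilities <- expand.grid(wave = 0:3, participant_id = p$participant_id,
                           KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)[, 2:1]
  utilities$utility <- utility
  utilities$observed <- TRUE
  new_trial(p, costs, utilities)
}

# Mark a set of (participant, wave) cells missing in both panels.
blank_waves <- function(trial, participant_id, waves,
                        what = c("cost", "utility")) {
  if ("cost" %in% what) {
    i <- trial$costs$participant_id == participant_id &
      trial$costs$wave %in% waves
    trial$costs$cost[i] <- NA_real_
    trial$costs$observed[i] <- FALSE
  }
  if ("utility" %in% what) {
    i <- trial$utilities$participant_id == participant_id &
      trial$utilities$wave %in% waves
    trial$utilities$utility[i] <- NA_real_
    trial$utilities$observed[i] <- FALSE
  }
  new_trial(trial$participants, trial$costs, trial$utilities)
}
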