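# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

cua_stop <- function(..., class = "cua_error") {
  stop(errorCondition(paste0(...), class = unique(c(class, "cua_error"))))
}

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `code` with the global random-number-generator state set from `seed`
#' and restores the previous state afterwards, so seeded operations do not
#' disturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = env, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = env), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env), add = TRUE)
  }
  set.seed(seed)
  code
}

# Required-column check with a readable error.
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    cua_stop(what, " is missing required column(s): ",
             paste(missing, collapse = ", "))
  }
  invisible(df)
}
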