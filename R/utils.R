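# Internal helpers shared across modules.

# Run code under a temporary RNG state. If seed is NULL the global stream is
# used (and advanced); otherwise the global .Random.seed is restored on exit
# so seeded computations do not perturb the caller's stream.
with_rng <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_config <- function(msg, field = NULL) {
  abort(msg, class = "hippnet_error_config", field = field)
}

stop_degenerate <- function(msg) {
  abort(msg, class = "hippnet_error_degenerate")
}

stop_schema <- function(msg) {
  abort(msg, class = "hippnet_error_schema")
}

stop_collinear <- function(msg) {
  abort(msg, class = "hippnet_error_collinear")
}

stop_range <- function(msg) {
  abort(msg, class = "hippnet_error_range")
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

is_prob <- function(x, open_left = TRUE, closed_right = TRUE) {
  if (length(x) != 1 || !is.numeric(x) || !is.finite(x)) return(FALSE)
  lo <- if (open_left) x > 0 else x >= 0
  hi <- if (closed_right) x <= 1 else x < 1
  lo && hi
}

# round-half-away-from-zero (base round() is banker's rounding)
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

require_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_schema(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
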