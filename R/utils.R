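# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going up (half-up), the
#' convention used throughout the cohort summaries. Base [round()] uses
#' banker's rounding, which would turn e.g. 0.5 into 0.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

stop_data <- function(...) stop(sprintf(...), call. = FALSE)

assert_prop <- function(x, name) {
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad)) {
    stop_data("'%s' must lie in [0, 1]; offending value(s): %s",
              name, paste(utils::head(x[bad], 3), collapse = ", "))
  }
  invisible(x)
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_data("%s is missing required column(s): %s",
              what, paste(missing, collapse = ", "))
  }
  invisible(df)
}

# collapse a character vector of rule ids for the audit tables
collapse_reasons <- function(reasons) {
  if (length(reasons) == 0) "" else paste(reasons, collapse = ",")
}
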