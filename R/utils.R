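# internal argument checks shared across modules

check_number <- function(x, name, min = -Inf, max = Inf,
                         allow_inf = FALSE, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name),
          class = "actotug_invalid_parameter")
  }
  if (!allow_inf && !is.finite(x)) {
    abort(sprintf("`%s` must be finite.", name),
          class = "actotug_invalid_parameter")
  }
  too_low <- if (strict_min) x <= min else x < min
  if (too_low || x > max) {
    cmp <- if (strict_min) ">" else ">="
    abort(sprintf("`%s` must be %s %g and <= %g (got %g).",
                  name, cmp, min, max, x),
          class = "actotug_invalid_parameter")
  }
  invisible(x)
}

check_positive <- function(x, name, allow_inf = FALSE) {
  check_number(x, name, min = 0, allow_inf = allow_inf, strict_min = TRUE)
}

check_columns <- function(df, cols, name = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing column(s): %s.",
                  name, paste(missing, collapse = ", ")),
          class = "actotug_invalid_input")
  }
  invisible(df)
}
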