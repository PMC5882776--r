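check_columns <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    abort(paste0(what, " is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "pcpredox_schema_error")
  }
  invisible(data)
}

check_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (strict && x <= min) || (!strict && x < min)) {
    abort(paste0("`", name, "` must be a finite number ",
                 if (strict) "> " else ">= ", min),
          class = "pcpredox_invalid_argument")
  }
  invisible(as.numeric(x))
}
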