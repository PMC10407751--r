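# Internal validation helpers shared across modules.

check_number <- function(x, name, min = NULL, allow_fractional = TRUE) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x)) {
    abort(sprintf("`%s` must be numeric and non-missing.", name))
  }
  if (!is.null(min) && any(x < min)) {
    abort(sprintf("`%s` must be >= %s (got %s).", name, min,
                  paste(unique(x[x < min]), collapse = ", ")))
  }
  if (!allow_fractional && any(x != trunc(x))) {
    abort(sprintf("`%s` must be whole numbers.", name))
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  if (!is.data.frame(df)) {
    abort(sprintf("%s must be a data frame.", what))
  }
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Format an amount in Saudi riyals for display
#'
#' All internal computation is done at full precision; this helper applies
#' the 2-decimal display convention used in reports.
#'
#' @param x Numeric vector of amounts in SAR.
#' @param digits Decimal places to show (default 2).
#' @return Character vector like `"SAR 74.28"`.
#' @export
#' @examples
#' format_sar(c(35, 73.5795))
format_sar <- function(x, digits = 2) {
  paste0("SAR ", formatC(x, format = "f", digits = digits, big.mark = ","))
}
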