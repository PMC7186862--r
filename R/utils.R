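#' Format a P-value at 3 significant figures in scientific notation
#'
#' Display helper used in reports and run metadata; computation always keeps
#' full precision.
#'
#' @param p numeric vector of P-values.
#' @param digits significant figures (default 3).
#' @return character vector, e.g. `"4.98e-05"`.
#' @export
#' @examples
#' format_pvalue(0.05 / 1005)
format_pvalue <- function(p, digits = 3) {
  sprintf(paste0("%.", digits - 1L, "e"), signif(p, digits))
}

# internal: stop with a classed condition so callers/tests can discriminate
stop_crossmr <- function(msg, class) {
  stop(structure(
    class = c(class, "crossmr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# full-precision numeric serialization for TSV output
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    sprintf("%.17g", v)
  }, character(1))
  out
}
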