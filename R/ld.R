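# Symmetric pairwise LD lookups. Absent pairs are "unknown" (NA), which is
# deliberately distinct from r2 = 0: locus splitting treats unknown LD as
# linkage, so only demonstrated equilibrium separates loci.

#' Build a symmetric LD lookup from a data frame
#'
#' @param pairs data frame with columns `snp_a`, `snp_b`, `r2` and optional
#'   `d_prime`. Both orderings of a pair resolve identically; self-pairs need
#'   not be listed (they are 1 by definition).
#' @return an object of class `"ld_table"`.
#' @export
ld_table <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  if (!all(c("snp_a", "snp_b", "r2") %in% names(pairs))) {
    stop_crossmr("LD table needs columns snp_a, snp_b, r2",
                 "crossmr_config_error")
  }
  if (!"d_prime" %in% names(pairs)) pairs$d_prime <- NA_real_
  pairs$r2 <- as.numeric(pairs$r2)
  pairs$d_prime <- as.numeric(pairs$d_prime)
  if (any(!is.na(pairs$r2) & (pairs$r2 < 0 | pairs$r2 > 1))) {
    stop_crossmr("r2 outside [0,1]", "crossmr_input_error")
  }
  if (any(!is.na(pairs$d_prime) & (pairs$d_prime < 0 | pairs$d_prime > 1))) {
    stop_crossmr("d_prime outside [0,1]", "crossmr_input_error")
  }
  env <- new.env(parent = emptyenv(), size = max(16L, nrow(pairs)))
  for (i in seq_len(nrow(pairs))) {
    key <- ld_key(pairs$snp_a[i], pairs$snp_b[i])
    assign(key, c(r2 = pairs$r2[i], d_prime = pairs$d_prime[i]), envir = env)
  }
  structure(list(env = env, n_pairs = nrow(pairs)), class = "ld_table")
}

ld_key <- function(a, b) paste(sort(c(a, b)), collapse = "\r")

#' Read a 4-column LD table from TSV
#'
#' Expects columns `snp_a`, `snp_b`, `r2` and optionally `d_prime`.
#'
#' @param path tab-delimited file path.
#' @return an `"ld_table"` lookup.
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) {
    stop_crossmr(sprintf("file not found: %s", path), "crossmr_input_error")
  }
  ld_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Query pairwise LD
#'
#' @param ld an `"ld_table"`, or `NULL` (every query unknown).
#' @param a,b rsIDs.
#' @return named numeric vector `c(r2 =, d_prime =)`; `NA` components mean
#'   the pair is unknown to the table (not zero LD). Self-pairs return 1/1.
#' @export
ld_query <- function(ld, a, b) {
  if (a == b) return(c(r2 = 1, d_prime = 1))
  if (is.null(ld)) return(c(r2 = NA_real_, d_prime = NA_real_))
  stopifnot(inherits(ld, "ld_table"))
  key <- ld_key(a, b)
  if (exists(key, envir = ld$env, inherits = FALSE)) {
    get(key, envir = ld$env, inherits = FALSE)
  } else {
    c(r2 = NA_real_, d_prime = NA_real_)
  }
}

#' @export
print.ld_table <- function(x, ...) {
  cat("<ld_table> ", x$n_pairs, " stored pair(s)\n", sep = "")
  invisible(x)
}
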