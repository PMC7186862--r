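# Readers and writers for the tabular formats every other module consumes.
# All tables are plain TSV with a header; positions are 1-based; alleles are
# upper-cased single nucleotides (indels are rejected with a logged reason).

#' Read and validate a GWAS summary-statistic table
#'
#' Reads a tab-delimited file into a validated data frame of per-SNP
#' association records. Rows failing validation (non-positive SE,
#' non-nucleotide or identical alleles, P outside (0,1], position < 1,
#' missing required fields) are dropped and itemized in an exclusion log
#' attached as the `"exclusions"` attribute (also retrievable with
#' [exclusions()]). If the dialect declares the effect column an odds ratio,
#' betas are stored as its natural logarithm and the conversion is recorded
#' in the `"conversions"` attribute.
#'
#' @param path path to a tab-delimited file with a header row.
#' @param dialect a [sumstats_dialect()]; defaults to canonical column names.
#' @param trait optional phenotype label stamped on every record when the
#'   file has no trait column.
#' @return a `data.frame` with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`,
#'   `trait`; attributes `exclusions` (data frame of dropped rows with
#'   reasons) and `conversions` (character vector of transformations
#'   applied).
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(), trait = NULL) {
  if (!file.exists(path)) {
    stop_crossmr(sprintf("file not found: %s", path), "crossmr_input_error")
  }
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0L) {
    stop_crossmr(sprintf("empty summary-statistic file: %s", path),
                 "crossmr_input_error")
  }
  required <- c("snp_id", "effect_allele", "other_allele", "beta", "se",
                "pvalue")
  cols <- dialect$cols
  missing_req <- required[!cols[required] %in% names(raw)]
  if (length(missing_req)) {
    stop_crossmr(sprintf(
      "required column(s) missing from %s: %s (dialect maps them to: %s)",
      path, paste(missing_req, collapse = ", "),
      paste(cols[missing_req], collapse = ", ")),
      "crossmr_config_error")
  }
  get_col <- function(field) {
    if (cols[[field]] %in% names(raw)) raw[[cols[[field]]]] else NA_character_
  }
  df <- data.frame(
    snp_id        = get_col("snp_id"),
    chrom         = get_col("chrom"),
    pos           = suppressWarnings(as.numeric(get_col("pos"))),
    effect_allele = toupper(trimws(get_col("effect_allele"))),
    other_allele  = toupper(trimws(get_col("other_allele"))),
    eaf           = suppressWarnings(as.numeric(get_col("eaf"))),
    beta          = suppressWarnings(as.numeric(get_col("beta"))),
    se            = suppressWarnings(as.numeric(get_col("se"))),
    pvalue        = suppressWarnings(as.numeric(get_col("pvalue"))),
    n             = suppressWarnings(as.numeric(get_col("n"))),
    trait         = get_col("trait"),
    stringsAsFactors = FALSE
  )
  if (!is.null(trait)) df$trait <- trait

  conversions <- character(0)
  if (dialect$effect_is_or) {
    df$beta <- log(df$beta)
    conversions <- c(conversions, "odds ratios natural-log transformed to beta")
  }

  reason <- rep(NA_character_, nrow(df))
  flag <- function(cond, why) {
    hit <- is.na(reason) & cond
    reason[hit] <<- why
  }
  nt <- c("A", "C", "G", "T")
  flag(is.na(df$snp_id) | df$snp_id == "" | is.na(df$beta) | is.na(df$se) |
         is.na(df$pvalue), "missing required field")
  flag(!(df$effect_allele %in% nt) | !(df$other_allele %in% nt),
       "non-SNP or invalid allele")
  flag(df$effect_allele == df$other_allele, "identical alleles")
  flag(df$se <= 0, "nonpositive SE")
  flag(df$pvalue <= 0 | df$pvalue > 1, "pvalue outside (0,1]")
  flag(!is.na(df$pos) & df$pos < 1, "position < 1")
  flag(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1), "EAF outside [0,1]")

  bad <- !is.na(reason)
  excl <- data.frame(row = which(bad), snp_id = df$snp_id[bad],
                     reason = reason[bad], stringsAsFactors = FALSE)
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  attr(out, "conversions") <- conversions
  class(out) <- c("sumstats_df", "data.frame")
  out
}

#' Retrieve the exclusion log attached by a reader
#'
#' @param x an object returned by [read_sumstats()], [read_catalog()] or
#'   [harmonize_datasets()].
#' @return a data frame of excluded rows with reasons (possibly 0-row).
#' @export
exclusions <- function(x) {
  attr(x, "exclusions") %||%
    data.frame(row = integer(0), snp_id = character(0),
               reason = character(0), stringsAsFactors = FALSE)
}

#' Read genome-wide-significant associations from a catalog-style table
#'
#' Filters a GWAS-catalog association download to rows whose trait label
#' matches any of the supplied search terms (case-insensitive substring
#' match by default) and whose P-value passes the genome-wide-significance
#' threshold.
#'
#' @param path tab-delimited catalog file.
#' @param trait_terms non-empty character vector of trait-label patterns.
#' @param p_max P-value threshold (default genome-wide significance,
#'   `5e-8`); rows with `pvalue > p_max` are excluded.
#' @param dialect a [catalog_dialect()].
#' @param fixed if `TRUE` (default) terms are literal substrings; if `FALSE`
#'   they are treated as regular expressions.
#' @return data frame with columns `snp_id`, `chrom`, `pos`, `trait_label`,
#'   `pvalue`, `study_id`, `ancestry`; attribute `exclusions` logs rows
#'   dropped for invalid position or P-value. Zero matches yields an empty
#'   data frame with a warning, not an error.
#' @export
read_catalog <- function(path, trait_terms, p_max = 5e-8,
                         dialect = catalog_dialect(), fixed = TRUE) {
  if (!length(trait_terms)) {
    stop_crossmr("trait_terms must be non-empty", "crossmr_config_error")
  }
  if (!file.exists(path)) {
    stop_crossmr(sprintf("file not found: %s", path), "crossmr_input_error")
  }
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  cols <- dialect$cols
  need <- c("snp_id", "trait_label", "pvalue")
  missing_req <- need[!cols[need] %in% names(raw)]
  if (length(missing_req)) {
    stop_crossmr(sprintf("required catalog column(s) missing: %s",
                         paste(cols[missing_req], collapse = ", ")),
                 "crossmr_config_error")
  }
  get_col <- function(field) {
    if (cols[[field]] %in% names(raw)) raw[[cols[[field]]]] else NA_character_
  }
  df <- data.frame(
    snp_id      = get_col("snp_id"),
    chrom       = get_col("chrom"),
    pos         = suppressWarnings(as.numeric(get_col("pos"))),
    trait_label = get_col("trait_label"),
    pvalue      = suppressWarnings(as.numeric(get_col("pvalue"))),
    study_id    = get_col("study_id"),
    ancestry    = get_col("ancestry"),
    stringsAsFactors = FALSE
  )
  reason <- rep(NA_character_, nrow(df))
  bad_p <- is.na(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1
  reason[bad_p] <- "invalid pvalue"
  excl <- data.frame(row = which(!is.na(reason)),
                     snp_id = df$snp_id[!is.na(reason)],
                     reason = reason[!is.na(reason)],
                     stringsAsFactors = FALSE)
  df <- df[is.na(reason), , drop = FALSE]

  hit <- Reduce(`|`, lapply(trait_terms, function(term) {
    grepl(tolower(term), tolower(df$trait_label), fixed = fixed)
  }), init = rep(FALSE, nrow(df)))
  out <- df[hit & df$pvalue <= p_max, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    warning("no catalog rows matched the trait terms at P <= ", p_max)
  }
  attr(out, "exclusions") <- excl
  attr(out, "p_max") <- p_max
  out
}

#' Write a results table with full-precision floats and a metadata sidecar
#'
#' Writes any of the package's tabular outputs as tab-delimited text with a
#' header. Numeric columns are serialized at full double precision so that a
#' write/read round trip is the identity. When `metadata` is supplied (or by
#' default), a JSON sidecar `<path>.meta.json` records the package version,
#' timestamp and any user-supplied provenance (input paths, thresholds,
#' seeds).
#'
#' @param records a data frame (all records share one schema).
#' @param path output file path.
#' @param metadata named list of provenance values for the sidecar; `NULL`
#'   suppresses the sidecar.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, metadata = list()) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_crossmr(sprintf("cannot write %s: %s", path,
                         conditionMessage(ok)), "crossmr_io_error")
  }
  if (!is.null(metadata)) {
    meta <- c(list(package = "crossmr",
                   version = as.character(utils::packageVersion("crossmr")),
                   written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   n_records = nrow(records)),
              metadata)
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
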