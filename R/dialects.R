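#' Column dialects for summary-statistic and catalog files
#'
#' Consortium summary-statistic files ship with heterogeneous headers, and a
#' silent misread of the effect-allele column is the dominant failure mode in
#' cross-study work. `crossmr` therefore never guesses: every reader takes an
#' explicit dialect that maps the package's canonical field names onto the
#' file's column names. Presets for common releases are shipped, and a custom
#' dialect is a one-liner.
#'
#' Canonical fields for summary statistics: `snp_id`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`, `eaf`, `beta` (or an odds-ratio column,
#' see `effect_is_or`), `se`, `pvalue`, `n`, `trait`. Required fields:
#' `snp_id`, `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`.
#'
#' @param ... named arguments `canonical = "FILE_COLUMN"` overriding the
#'   defaults (canonical names map to themselves when not overridden).
#' @param effect_is_or logical; if `TRUE` the effect column holds odds
#'   ratios, which are natural-log transformed on read (the conversion is
#'   recorded in the reader's metadata).
#' @return an object of class `"sumstats_dialect"`.
#' @export
#' @examples
#' # a PGC-style file where the effect is an odds ratio
#' sumstats_dialect(snp_id = "SNP", chrom = "CHR", pos = "BP",
#'                  effect_allele = "A1", other_allele = "A2",
#'                  beta = "OR", se = "SE", pvalue = "P",
#'                  effect_is_or = TRUE)
sumstats_dialect <- function(..., effect_is_or = FALSE) {
  canonical <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pvalue", "n", "trait")
  cols <- setNames(canonical, canonical)
  override <- list(...)
  if (length(override)) {
    bad <- setdiff(names(override), canonical)
    if (length(bad)) {
      stop_crossmr(sprintf("unknown dialect field(s): %s",
                           paste(bad, collapse = ", ")),
                   "crossmr_config_error")
    }
    cols[names(override)] <- vapply(override, as.character, character(1))
  }
  structure(list(cols = cols, effect_is_or = isTRUE(effect_is_or)),
            class = "sumstats_dialect")
}

#' Shipped dialect presets
#'
#' `dialect_preset()` returns a ready-made [sumstats_dialect()] for common
#' summary-statistic releases. The presets reflect widely used header styles
#' (psychiatric case-control files reporting odds ratios; anthropometric
#' meta-analyses reporting betas); always eyeball the first lines of a new
#' file against the preset before trusting it.
#'
#' @param name one of `"canonical"`, `"pgc"`, `"giant"`, `"ssgac"`.
#' @return a `"sumstats_dialect"` object.
#' @export
dialect_preset <- function(name = c("canonical", "pgc", "giant", "ssgac")) {
  name <- match.arg(name)
  switch(name,
    canonical = sumstats_dialect(),
    pgc = sumstats_dialect(snp_id = "SNP", chrom = "CHR", pos = "BP",
                           effect_allele = "A1", other_allele = "A2",
                           eaf = "FRQ_A", beta = "OR", se = "SE",
                           pvalue = "P", effect_is_or = TRUE),
    giant = sumstats_dialect(snp_id = "SNP", chrom = "Chr", pos = "Pos",
                             effect_allele = "Tested_Allele",
                             other_allele = "Other_Allele", eaf = "Freq_Tested_Allele",
                             beta = "BETA", se = "SE", pvalue = "P", n = "N"),
    ssgac = sumstats_dialect(snp_id = "MarkerName", chrom = "CHR", pos = "POS",
                             effect_allele = "A1", other_allele = "A2",
                             eaf = "EAF", beta = "Beta", se = "SE",
                             pvalue = "Pval")
  )
}

#' Dialect for GWAS-catalog association tables
#'
#' Maps the canonical catalog fields (`snp_id`, `chrom`, `pos`,
#' `trait_label`, `pvalue`, `study_id`, `ancestry`) onto file columns. The
#' default follows the catalog's v1.0 association-download headers.
#'
#' @param ... named overrides `canonical = "FILE_COLUMN"`.
#' @return an object of class `"catalog_dialect"`.
#' @export
catalog_dialect <- function(...) {
  cols <- c(snp_id = "SNPS", chrom = "CHR_ID", pos = "CHR_POS",
            trait_label = "DISEASE/TRAIT", pvalue = "P-VALUE",
            study_id = "STUDY ACCESSION", ancestry = "INITIAL SAMPLE SIZE")
  override <- list(...)
  if (length(override)) {
    bad <- setdiff(names(override), names(cols))
    if (length(bad)) {
      stop_crossmr(sprintf("unknown catalog field(s): %s",
                           paste(bad, collapse = ", ")),
                   "crossmr_config_error")
    }
    cols[names(override)] <- vapply(override, as.character, character(1))
  }
  structure(list(cols = cols), class = "catalog_dialect")
}
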