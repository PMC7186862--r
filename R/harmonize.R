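# Allele harmonization between exposure and outcome summary statistics.
# Two-sample MR requires both studies' effects to be expressed per copy of
# the same allele; studies may report the opposite allele (sign flip) or the
# opposite strand (complement relabelling). Palindromic SNPs (A/T, C/G) are
# strand-ambiguous and are removed under the default strict mode.

NT_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Is an allele pair palindromic?
#'
#' A palindromic (ambiguous-strand) SNP has alleles that are reverse
#' complements of each other: \{A,T\} or \{C,G\}. For such SNPs the strand
#' cannot be resolved from the alleles alone, so two studies may silently
#' report effects for complementary alleles.
#'
#' @param a1,a2 single-character alleles in A/C/G/T (vectorized).
#' @return logical vector.
#' @export
#' @examples
#' is_palindromic("A", "T")  # TRUE
#' is_palindromic("A", "G")  # FALSE
is_palindromic <- function(a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  if (!all(a1 %in% names(NT_COMPLEMENT)) ||
      !all(a2 %in% names(NT_COMPLEMENT))) {
    stop_crossmr("alleles must be one of A, C, G, T", "crossmr_domain_error")
  }
  unname(NT_COMPLEMENT[a1] == a2)
}

#' Harmonize one SNP's exposure and outcome records
#'
#' Aligns the outcome record to the exposure's effect allele. Matching
#' alleles are kept as-is; swapped alleles (outcome effect allele equals the
#' exposure's other allele) negate the outcome beta; pairs that match only
#' after strand complement are relabelled and then treated the same way.
#' Palindromic SNPs are excluded in `"strict"` mode; in `"eaf-infer"` mode
#' they are kept when the effect-allele frequency is informative (outside
#' `eaf_window` in both studies), using frequency agreement to resolve the
#' strand. Any remaining mismatch is excluded as `"ambiguous"`.
#'
#' @param exp,out single records (one-row data frames or named lists) with
#'   at least `snp_id`, `effect_allele`, `other_allele`, `beta`, `se`, and
#'   optionally `eaf`. Must share `snp_id`.
#' @param mode `"strict"` (drop palindromic; default) or `"eaf-infer"`.
#' @param eaf_window frequency interval within which a palindromic SNP's EAF
#'   is considered uninformative (default `c(0.42, 0.58)`).
#' @return a list: `$instrument` (one-row data frame, or `NULL` when
#'   excluded) and `$reason` (`NA` when kept; otherwise `"palindromic"`,
#'   `"palindromic (uninformative EAF)"` or `"ambiguous"`).
#' @export
harmonize_pair <- function(exp, out, mode = c("strict", "eaf-infer"),
                           eaf_window = c(0.42, 0.58)) {
  mode <- match.arg(mode)
  exp <- as.list(exp); out <- as.list(out)
  if (!identical(as.character(exp$snp_id), as.character(out$snp_id))) {
    stop_crossmr("exposure and outcome records must share snp_id",
                 "crossmr_domain_error")
  }
  ea_e <- toupper(exp$effect_allele); oa_e <- toupper(exp$other_allele)
  ea_o <- toupper(out$effect_allele); oa_o <- toupper(out$other_allele)
  beta_out <- out$beta
  eaf_out <- out$eaf %||% NA_real_
  eaf_exp <- exp$eaf %||% NA_real_
  flipped <- FALSE
  pal <- is_palindromic(ea_e, oa_e)

  keep <- function() {
    list(instrument = data.frame(
      snp_id = as.character(exp$snp_id),
      effect_allele = ea_e, other_allele = oa_e,
      beta_exp = exp$beta, se_exp = exp$se,
      beta_out = beta_out, se_out = out$se,
      eaf_exp = as.numeric(eaf_exp), eaf_out = as.numeric(eaf_out),
      flipped = flipped, palindromic = pal,
      stringsAsFactors = FALSE), reason = NA_character_)
  }
  drop <- function(reason) list(instrument = NULL, reason = reason)

  if (pal) {
    if (mode == "strict") return(drop("palindromic"))
    # eaf-infer: alleles of a palindromic SNP are the same pair on either
    # strand, so only the frequency can orient the outcome record
    if (is.na(eaf_exp) || is.na(eaf_out)) {
      return(drop("palindromic (uninformative EAF)"))
    }
    uninformative <- function(f) f >= eaf_window[1] && f <= eaf_window[2]
    if (uninformative(eaf_exp) || uninformative(eaf_out)) {
      return(drop("palindromic (uninformative EAF)"))
    }
    # pick the labelling that makes the outcome EAF side agree with exposure
    direct <- ea_o == ea_e && oa_o == oa_e
    swapped <- ea_o == oa_e && oa_o == ea_e
    if (!direct && !swapped) return(drop("ambiguous"))
    eaf_aligned <- if (direct) eaf_out else 1 - eaf_out
    if (swapped) { beta_out <- -beta_out; flipped <- TRUE }
    if ((eaf_exp < 0.5) != (eaf_aligned < 0.5)) {
      # frequencies disagree: the outcome study reported the other strand,
      # which for a palindrome is equivalent to the opposite allele
      beta_out <- -beta_out
      flipped <- !flipped
      eaf_aligned <- 1 - eaf_aligned
    }
    eaf_out <- eaf_aligned
    return(keep())
  }

  if (ea_o == ea_e && oa_o == oa_e) {
    return(keep())
  }
  if (ea_o == oa_e && oa_o == ea_e) {
    beta_out <- -beta_out
    eaf_out <- if (is.na(eaf_out)) NA_real_ else 1 - eaf_out
    flipped <- TRUE
    return(keep())
  }
  ea_oc <- unname(NT_COMPLEMENT[ea_o]); oa_oc <- unname(NT_COMPLEMENT[oa_o])
  if (ea_oc == ea_e && oa_oc == oa_e) {
    return(keep())
  }
  if (ea_oc == oa_e && oa_oc == ea_e) {
    beta_out <- -beta_out
    eaf_out <- if (is.na(eaf_out)) NA_real_ else 1 - eaf_out
    flipped <- TRUE
    return(keep())
  }
  drop("ambiguous")
}

#' Harmonize whole exposure and outcome tables into MR-ready instruments
#'
#' Inner-joins the two tables on `snp_id` and applies [harmonize_pair()] to
#' every shared SNP. The exclusion log enumerates SNPs absent from the
#' outcome table and SNPs removed as palindromic or ambiguous, so that
#' `|exposure ∩ outcome| = retained + excluded` always holds.
#'
#' @param exposure,outcome data frames with canonical summary-statistic
#'   columns (as returned by [read_sumstats()] or [simulate_mr_study()]).
#' @param mode `"strict"` or `"eaf-infer"`; see [harmonize_pair()].
#' @return a data frame of harmonized instruments (one row per retained
#'   SNP, columns as in [harmonize_pair()]), with attribute `exclusions`
#'   (`snp_id`, `reason`) including `"absent from outcome"` entries.
#' @export
harmonize_datasets <- function(exposure, outcome,
                               mode = c("strict", "eaf-infer")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(exposure), is.data.frame(outcome))
  exposure <- exposure[!duplicated(exposure$snp_id), , drop = FALSE]
  outcome <- outcome[!duplicated(outcome$snp_id), , drop = FALSE]
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (length(shared) == 0L) {
    stop_crossmr("no usable instruments: exposure and outcome share no SNPs",
                 "crossmr_pipeline_error")
  }
  absent <- setdiff(exposure$snp_id, outcome$snp_id)
  out_idx <- match(shared, outcome$snp_id)
  exp_idx <- match(shared, exposure$snp_id)

  # vectorized allele reconciliation; [harmonize_pair()] is the scalar
  # reference for the same logic and handles the eaf-infer palindromes
  e <- exposure[exp_idx, , drop = FALSE]
  o <- outcome[out_idx, , drop = FALSE]
  ea_e <- toupper(e$effect_allele); oa_e <- toupper(e$other_allele)
  ea_o <- toupper(o$effect_allele); oa_o <- toupper(o$other_allele)
  ea_oc <- unname(NT_COMPLEMENT[ea_o]); oa_oc <- unname(NT_COMPLEMENT[oa_o])
  pal <- unname(NT_COMPLEMENT[ea_e]) == oa_e
  direct <- (ea_o == ea_e & oa_o == oa_e) | (ea_oc == ea_e & oa_oc == oa_e)
  swapped <- (ea_o == oa_e & oa_o == ea_e) | (ea_oc == oa_e & oa_oc == ea_e)

  eaf_exp <- if ("eaf" %in% names(e)) as.numeric(e$eaf) else
    rep(NA_real_, nrow(e))
  eaf_out <- if ("eaf" %in% names(o)) as.numeric(o$eaf) else
    rep(NA_real_, nrow(o))

  status <- rep("kept", length(shared))
  status[!direct & !swapped] <- "ambiguous"
  status[pal] <- if (mode == "strict") "palindromic" else "eaf-infer"

  beta_out <- ifelse(swapped & !direct, -o$beta, o$beta)
  eaf_out_al <- ifelse(swapped & !direct, 1 - eaf_out, eaf_out)
  flipped <- swapped & !direct

  insts <- data.frame(
    snp_id = shared, effect_allele = ea_e, other_allele = oa_e,
    beta_exp = e$beta, se_exp = e$se,
    beta_out = beta_out, se_out = o$se,
    eaf_exp = eaf_exp, eaf_out = eaf_out_al,
    flipped = flipped, palindromic = pal, stringsAsFactors = FALSE)

  reasons <- character(0); reason_ids <- character(0)
  keep_mask <- status == "kept"
  if (any(status == "eaf-infer")) {
    # palindromes under eaf-infer need frequency logic; defer to the
    # scalar reference implementation row by row
    for (i in which(status == "eaf-infer")) {
      res <- harmonize_pair(e[i, , drop = FALSE], o[i, , drop = FALSE],
                            mode = "eaf-infer")
      if (is.null(res$instrument)) {
        reasons <- c(reasons, res$reason)
        reason_ids <- c(reason_ids, shared[i])
      } else {
        insts[i, names(res$instrument)] <- res$instrument
        keep_mask[i] <- TRUE
      }
    }
  }
  dropped <- !keep_mask & !(status == "eaf-infer")
  reasons <- c(status[dropped], reasons)
  reason_ids <- c(shared[dropped], reason_ids)
  insts <- insts[keep_mask, , drop = FALSE]
  rownames(insts) <- NULL
  excl <- data.frame(
    snp_id = c(reason_ids, absent),
    reason = c(reasons, rep("absent from outcome", length(absent))),
    stringsAsFactors = FALSE)
  if (nrow(insts) == 0L) {
    warning("all shared SNPs were excluded during harmonization")
  }
  attr(insts, "exclusions") <- excl
  attr(insts, "mode") <- mode
  class(insts) <- c("mr_instruments", "data.frame")
  insts
}
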