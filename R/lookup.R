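# Cross-trait look-up: cluster anthropometric catalog SNPs into independent
# loci, test them in mental-phenotype summary statistics against a
# Bonferroni threshold, pick lead SNPs, and tabulate effect-direction
# concordance.

#' Bonferroni-corrected per-test significance threshold
#'
#' @param alpha family-wise error rate, in (0,1).
#' @param n_tests number of tests, a positive integer.
#' @return `alpha / n_tests` at full precision. Use [format_pvalue()] for
#'   the 3-significant-figure display form.
#' @export
#' @examples
#' format_pvalue(bonferroni_threshold(0.05, 1005))  # "4.98e-05"
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1) {
    stop_crossmr("alpha must lie in (0,1)", "crossmr_domain_error")
  }
  if (!is_scalar_number(n_tests) || n_tests < 1 ||
      n_tests != as.integer(n_tests)) {
    stop_crossmr("n_tests must be a positive integer", "crossmr_domain_error")
  }
  alpha / n_tests
}

chrom_rank <- function(chrom) {
  chrom <- toupper(as.character(chrom))
  num <- suppressWarnings(as.numeric(chrom))
  num[chrom == "X"] <- 23
  num[chrom == "Y"] <- 24
  num[chrom %in% c("MT", "M")] <- 25
  num[is.na(num)] <- 26
  num
}

#' Cluster associated SNPs into independent genomic loci
#'
#' Two-stage partition. (1) Positional clustering per chromosome: SNPs are
#' sorted by position and greedily merged left to right while each candidate
#' lies within `window_kb` of the running cluster midpoint
#' (`(min + max)/2` of member positions, recomputed after every merge).
#' (2) LD splitting within each positional cluster: a SNP pair is in
#' demonstrated linkage equilibrium when its *known* `r2 < r2_max` **and**
#' *known* `d_prime < dprime_max`; pairs with unknown LD count as linked.
#' Single-linkage connected components of the linked relation become
#' separate loci — so only demonstrated equilibrium ever splits a positional
#' cluster. Loci are numbered consecutively in genomic order.
#'
#' @param snps data frame with `snp_id`, `chrom`, `pos` and optionally
#'   `trait_label` (e.g. from [read_catalog()]). Duplicate `snp_id`s are
#'   collapsed (trait labels unioned); rows without a position are excluded
#'   with a logged reason.
#' @param window_kb half-window in kb around the running midpoint
#'   (default 500).
#' @param ld an [ld_table()] or `NULL` (no LD known; positional clusters
#'   are never split).
#' @param r2_max,dprime_max equilibrium thresholds (default 0.01 each).
#' @return an object of class `"locus_set"`: list with `loci` (data frame
#'   `locus_id`, `chrom`, `start`, `end`, `n_members`, `lead_snp`,
#'   `anthro_traits`), `members` (`snp_id`, `locus_id`, `chrom`, `pos`,
#'   `trait_label`) and `exclusions`.
#' @export
define_loci <- function(snps, window_kb = 500, ld = NULL,
                        r2_max = 0.01, dprime_max = 0.01) {
  stopifnot(is.data.frame(snps), window_kb > 0)
  if (!all(c("snp_id", "chrom", "pos") %in% names(snps))) {
    stop_crossmr("snps needs columns snp_id, chrom, pos",
                 "crossmr_config_error")
  }
  if (!"trait_label" %in% names(snps)) snps$trait_label <- NA_character_
  snps$pos <- as.numeric(snps$pos)

  bad <- is.na(snps$pos) | is.na(snps$chrom) | snps$chrom == ""
  excl <- data.frame(snp_id = snps$snp_id[bad],
                     reason = rep("missing position or chromosome", sum(bad)),
                     stringsAsFactors = FALSE)
  snps <- snps[!bad, , drop = FALSE]

  # collapse duplicate SNPs (same variant reported for several traits)
  traits_by_snp <- tapply(snps$trait_label, snps$snp_id, function(x) {
    sort(unique(x[!is.na(x) & x != ""]))
  }, simplify = FALSE)
  snps <- snps[!duplicated(snps$snp_id), , drop = FALSE]

  ord <- order(chrom_rank(snps$chrom), snps$pos, snps$snp_id)
  snps <- snps[ord, , drop = FALSE]
  window_bp <- window_kb * 1000

  clusters <- list()
  for (chr in unique(snps$chrom)) {
    sub <- snps[snps$chrom == chr, , drop = FALSE]
    cur <- 1L
    lo <- sub$pos[1]; hi <- sub$pos[1]
    idx <- rep(NA_integer_, nrow(sub)); idx[1] <- 1L
    k <- 1L
    for (i in seq_len(nrow(sub))[-1]) {
      mid <- (lo + hi) / 2
      if (abs(sub$pos[i] - mid) <= window_bp) {
        hi <- max(hi, sub$pos[i]); lo <- min(lo, sub$pos[i])
      } else {
        k <- k + 1L
        lo <- sub$pos[i]; hi <- sub$pos[i]
      }
      idx[i] <- k
    }
    for (g in seq_len(k)) {
      clusters[[length(clusters) + 1L]] <- sub[idx == g, , drop = FALSE]
    }
  }

  # LD splitting: connected components of the "linked" relation
  split_cluster <- function(cl) {
    n <- nrow(cl)
    if (n == 1L || is.null(ld)) return(list(cl))
    linked <- matrix(TRUE, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        q <- ld_query(ld, cl$snp_id[i], cl$snp_id[j])
        in_equilibrium <- !is.na(q[["r2"]]) && !is.na(q[["d_prime"]]) &&
          q[["r2"]] < r2_max && q[["d_prime"]] < dprime_max
        linked[i, j] <- linked[j, i] <- !in_equilibrium
      }
    }
    comp <- rep(NA_integer_, n)
    nc <- 0L
    for (s in seq_len(n)) {
      if (!is.na(comp[s])) next
      nc <- nc + 1L
      stack <- s
      while (length(stack)) {
        v <- stack[[1]]; stack <- stack[-1]
        if (!is.na(comp[v])) next
        comp[v] <- nc
        stack <- c(stack, which(linked[v, ] & is.na(comp)))
      }
    }
    lapply(seq_len(nc), function(g) cl[comp == g, , drop = FALSE])
  }
  clusters <- unlist(lapply(clusters, split_cluster), recursive = FALSE)

  # genomic ordering and consecutive numbering
  starts <- vapply(clusters, function(cl) min(cl$pos), numeric(1))
  chroms <- vapply(clusters, function(cl) cl$chrom[1], character(1))
  clusters <- clusters[order(chrom_rank(chroms), starts)]

  loci <- do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    traits <- sort(unique(unlist(traits_by_snp[cl$snp_id])))
    data.frame(locus_id = i, chrom = cl$chrom[1],
               start = min(cl$pos), end = max(cl$pos),
               n_members = nrow(cl), lead_snp = NA_character_,
               anthro_traits = paste(traits, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  members <- do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    data.frame(snp_id = cl$snp_id, locus_id = i, chrom = cl$chrom,
               pos = cl$pos, stringsAsFactors = FALSE)
  }))
  over_1mb <- loci$locus_id[loci$end - loci$start > 1e6]
  if (length(over_1mb)) {
    message("locus span exceeds 1 Mb for locus id(s): ",
            paste(over_1mb, collapse = ", "))
  }
  structure(list(loci = loci, members = members, exclusions = excl,
                 window_kb = window_kb, r2_max = r2_max,
                 dprime_max = dprime_max),
            class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("<locus_set> %d loci from %d SNPs (window %g kb)\n",
              nrow(x$loci), nrow(x$members), x$window_kb))
  print(utils::head(x$loci, 10))
  invisible(x)
}

# align a summary-stat beta to a reference record's effect allele; lookup
# tables are assumed strand-consistent, so palindromes resolve by label
align_beta_to <- function(ref, rec) {
  ea_r <- toupper(ref$effect_allele); oa_r <- toupper(ref$other_allele)
  ea <- toupper(rec$effect_allele); oa <- toupper(rec$other_allele)
  if (ea == ea_r && oa == oa_r) return(rec$beta)
  if (ea == oa_r && oa == ea_r) return(-rec$beta)
  eac <- unname(NT_COMPLEMENT[ea]); oac <- unname(NT_COMPLEMENT[oa])
  if (eac == ea_r && oac == oa_r) return(rec$beta)
  if (eac == oa_r && oac == ea_r) return(-rec$beta)
  NA_real_
}

#' Look up SNPs across a panel of phenotype summary-statistic tables
#'
#' Joins the query SNPs to every phenotype table by rsID and classifies each
#' hit against a significance threshold. When `anthro_stats` is supplied,
#' each hit's beta is sign-aligned to the anthropometric effect allele so
#' that downstream direction tables are allele-consistent; otherwise betas
#' are reported on the phenotype's own effect allele. SNPs absent from a
#' table are counted in a per-phenotype coverage report (proxy SNPs are
#' never substituted).
#'
#' @param snps data frame with `snp_id` (duplicates collapsed).
#' @param phenotype_tables named list of summary-statistic data frames, one
#'   per mental phenotype.
#' @param threshold per-test significance threshold in (0,1); hits with
#'   `pvalue < threshold` are flagged significant.
#' @param anthro_stats optional summary-statistic data frame for the
#'   anthropometric trait, used to sign-align betas.
#' @return data frame of hits (`snp_id`, `phenotype`, `pvalue`, `beta`,
#'   `effect_allele`, `other_allele`, `significant`) with attribute
#'   `coverage` (`phenotype`, `n_queried`, `n_found`, `n_absent`) and
#'   attribute `threshold`.
#' @export
crosstrait_lookup <- function(snps, phenotype_tables, threshold,
                              anthro_stats = NULL) {
  stopifnot(is.data.frame(snps))
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold >= 1) {
    stop_crossmr("threshold must lie in (0,1)", "crossmr_domain_error")
  }
  if (!length(phenotype_tables) || is.null(names(phenotype_tables))) {
    stop_crossmr("phenotype_tables must be a named list",
                 "crossmr_config_error")
  }
  ids <- unique(snps$snp_id)
  hit_rows <- list()
  cov_rows <- list()
  for (ph in names(phenotype_tables)) {
    tab <- phenotype_tables[[ph]]
    m <- match(ids, tab$snp_id)
    found <- !is.na(m)
    for (i in which(found)) {
      rec <- tab[m[i], , drop = FALSE]
      beta <- rec$beta
      ea <- rec$effect_allele; oa <- rec$other_allele
      if (!is.null(anthro_stats)) {
        a <- anthro_stats[match(ids[i], anthro_stats$snp_id), , drop = FALSE]
        if (nrow(a) == 1L && !is.na(a$snp_id[1])) {
          aligned <- align_beta_to(as.list(a), as.list(rec))
          if (!is.na(aligned)) {
            beta <- aligned
            ea <- a$effect_allele; oa <- a$other_allele
          }
        }
      }
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        snp_id = ids[i], phenotype = ph, pvalue = rec$pvalue, beta = beta,
        effect_allele = ea, other_allele = oa,
        significant = rec$pvalue < threshold, stringsAsFactors = FALSE)
    }
    cov_rows[[length(cov_rows) + 1L]] <- data.frame(
      phenotype = ph, n_queried = length(ids), n_found = sum(found),
      n_absent = sum(!found), stringsAsFactors = FALSE)
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(snp_id = character(0), phenotype = character(0),
               pvalue = numeric(0), beta = numeric(0),
               effect_allele = character(0), other_allele = character(0),
               significant = logical(0), stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  attr(hits, "coverage") <- do.call(rbind, cov_rows)
  attr(hits, "threshold") <- threshold
  hits
}

#' Select the lead SNP of a locus
#'
#' Among the locus members: (1) the SNP with the highest number of
#' significant mental-phenotype hits; (2) ties broken by the lowest P-value
#' across that SNP's significant hits (or all its hits when none is
#' significant); (3) any remaining tie broken by rsID lexicographic order
#' for determinism (a message is emitted when this final rule decides).
#'
#' @param members character vector of member rsIDs (>= 1).
#' @param hits hits table from [crosstrait_lookup()].
#' @return the lead rsID.
#' @export
select_lead_snp <- function(members, hits) {
  if (!length(members)) {
    stop_crossmr("locus must have at least one member", "crossmr_domain_error")
  }
  members <- sort(unique(members))
  if (length(members) == 1L) return(members)
  n_sig <- vapply(members, function(s) {
    sum(hits$significant[hits$snp_id == s]) }, numeric(1))
  min_p <- vapply(members, function(s) {
    h <- hits[hits$snp_id == s, , drop = FALSE]
    hs <- h[h$significant, , drop = FALSE]
    p <- if (nrow(hs)) hs$pvalue else h$pvalue
    if (length(p)) min(p) else Inf
  }, numeric(1))
  cand <- members[n_sig == max(n_sig)]
  cand <- cand[min_p[cand] == min(min_p[cand])]
  if (length(cand) > 1L) {
    message("lead-SNP tie at ", paste(cand, collapse = "/"),
            "; resolved by rsID order")
  }
  cand[1]
}

#' Fill lead SNPs for every locus in a locus set
#'
#' @param locus_set a `"locus_set"` from [define_loci()].
#' @param hits hits table from [crosstrait_lookup()].
#' @return the locus set with `loci$lead_snp` populated.
#' @export
select_lead_snps <- function(locus_set, hits) {
  stopifnot(inherits(locus_set, "locus_set"))
  locus_set$loci$lead_snp <- vapply(locus_set$loci$locus_id, function(id) {
    mem <- locus_set$members$snp_id[locus_set$members$locus_id == id]
    select_lead_snp(mem, hits)
  }, character(1))
  locus_set
}

#' Effect-direction concordance between anthropometric and mental traits
#'
#' For every locus with at least one significant hit in a phenotype, asks
#' whether the anthropometric-trait-increasing allele moves the mental
#' phenotype in the same direction. The locus is represented by its member
#' hit with the lowest P-value in that phenotype; both betas are aligned to
#' the anthropometric effect allele before comparing signs. Zero betas are
#' flagged indeterminate and excluded from the counts with a message.
#' Counts are stratified into loci whose anthropometric traits include a
#' BMI-type label versus loci unique to BMI-adjusted measures.
#'
#' @param hits hits table from [crosstrait_lookup()].
#' @param locus_set a `"locus_set"` (lead SNPs not required).
#' @param anthro_stats anthropometric summary statistics (canonical
#'   columns) providing the reference effect direction per SNP.
#' @param mental_stats named list of phenotype summary-statistic tables
#'   (same tables used for the lookup).
#' @param bmi_terms trait labels (substrings, case-insensitive) defining
#'   the BMI stratum.
#' @return list with `entries` (`locus_id`, `phenotype`, `snp_id`,
#'   `concordant`, `stratum`) and `counts` (`phenotype`, `stratum`, `same`,
#'   `opposite`).
#' @export
direction_concordance <- function(hits, locus_set, anthro_stats,
                                  mental_stats,
                                  bmi_terms = c("body mass index", "bmi",
                                                "obesity")) {
  stopifnot(inherits(locus_set, "locus_set"))
  sig <- hits[hits$significant, , drop = FALSE]
  sig$locus_id <- locus_set$members$locus_id[
    match(sig$snp_id, locus_set$members$snp_id)]
  sig <- sig[!is.na(sig$locus_id), , drop = FALSE]

  stratum_of <- function(locus_id) {
    traits <- tolower(locus_set$loci$anthro_traits[
      locus_set$loci$locus_id == locus_id])
    if (any(vapply(bmi_terms, function(t) grepl(t, traits, fixed = TRUE),
                   logical(1)))) "bmi" else "adjusted-only"
  }

  rows <- list()
  indeterminate <- 0L
  for (key in unique(paste(sig$locus_id, sig$phenotype, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    lid <- as.integer(parts[1]); ph <- parts[2]
    sub <- sig[sig$locus_id == lid & sig$phenotype == ph, , drop = FALSE]
    rep_hit <- sub[which.min(sub$pvalue), , drop = FALSE]
    a <- anthro_stats[match(rep_hit$snp_id, anthro_stats$snp_id), ,
                      drop = FALSE]
    if (nrow(a) != 1L || is.na(a$snp_id[1])) next
    mtab <- mental_stats[[ph]]
    m <- mtab[match(rep_hit$snp_id, mtab$snp_id), , drop = FALSE]
    if (nrow(m) != 1L || is.na(m$snp_id[1])) next
    beta_mental <- align_beta_to(as.list(a), as.list(m))
    if (is.na(beta_mental)) next
    # orient to the anthropometric-trait-increasing allele
    orient <- sign(a$beta)
    if (orient == 0 || beta_mental == 0) {
      indeterminate <- indeterminate + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      locus_id = lid, phenotype = ph, snp_id = rep_hit$snp_id,
      concordant = sign(beta_mental * orient) > 0,
      stratum = stratum_of(lid), stringsAsFactors = FALSE)
  }
  if (indeterminate) {
    message(indeterminate,
            " locus-phenotype pair(s) indeterminate (zero beta); excluded")
  }
  entries <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus_id = integer(0), phenotype = character(0),
               snp_id = character(0), concordant = logical(0),
               stratum = character(0), stringsAsFactors = FALSE)
  counts <- if (nrow(entries)) {
    agg <- stats::aggregate(cbind(same = entries$concordant,
                           opposite = !entries$concordant),
                     by = list(phenotype = entries$phenotype,
                               stratum = entries$stratum), FUN = sum)
    agg[order(agg$phenotype, agg$stratum), , drop = FALSE]
  } else {
    data.frame(phenotype = character(0), stratum = character(0),
               same = integer(0), opposite = integer(0),
               stringsAsFactors = FALSE)
  }
  rownames(counts) <- NULL
  list(entries = entries, counts = counts)
}

#' Confirmatory look-up in an independent summary-statistic table
#'
#' Re-tests previously significant hits in an independent study at the same
#' threshold. Hits absent from the independent table are counted as "not
#' assessable", never as failures.
#'
#' @param prior_hits hits table (typically the significant subset of a
#'   discovery lookup).
#' @param independent_table summary statistics of the independent study.
#' @param threshold significance threshold (same as discovery).
#' @param locus_set optional `"locus_set"` to add locus-level counts.
#' @param discovery_path,independent_path optional file paths recorded for
#'   provenance; identical paths are an error (the confirmatory table must
#'   be an independent file).
#' @return list with `snp_report` (per SNP: `pvalue_independent`,
#'   `status` in replicated/not-replicated/not-assessable), `n_replicated`,
#'   `n_tested`, `n_not_assessable`, and when `locus_set` is given
#'   `n_loci_replicated`, `n_loci_tested`.
#' @export
confirmatory_lookup <- function(prior_hits, independent_table, threshold,
                                locus_set = NULL, discovery_path = NULL,
                                independent_path = NULL) {
  if (!is.null(discovery_path) && !is.null(independent_path) &&
      normalizePath(discovery_path, mustWork = FALSE) ==
      normalizePath(independent_path, mustWork = FALSE)) {
    stop_crossmr("confirmatory table must be independent of the discovery table",
                 "crossmr_config_error")
  }
  ids <- unique(prior_hits$snp_id)
  m <- match(ids, independent_table$snp_id)
  p_ind <- ifelse(is.na(m), NA_real_, independent_table$pvalue[m])
  status <- ifelse(is.na(p_ind), "not-assessable",
                   ifelse(p_ind < threshold, "replicated", "not-replicated"))
  rep_df <- data.frame(snp_id = ids, pvalue_independent = p_ind,
                       status = status, stringsAsFactors = FALSE)
  out <- list(snp_report = rep_df,
              n_replicated = sum(status == "replicated"),
              n_tested = sum(status != "not-assessable"),
              n_not_assessable = sum(status == "not-assessable"),
              threshold = threshold,
              discovery_path = discovery_path,
              independent_path = independent_path)
  if (!is.null(locus_set)) {
    lid <- locus_set$members$locus_id[match(ids, locus_set$members$snp_id)]
    assessed <- !is.na(lid) & status != "not-assessable"
    out$n_loci_tested <- length(unique(lid[assessed]))
    out$n_loci_replicated <- length(unique(lid[!is.na(lid) &
                                                 status == "replicated"]))
  }
  out
}

#' Run the whole cross-trait look-up pipeline
#'
#' Convenience wrapper: Bonferroni threshold over the unique catalog SNPs,
#' locus definition, lookup across all phenotype tables, lead-SNP
#' selection, and (when anthropometric summary statistics are supplied)
#' direction-concordance tables.
#'
#' @param catalog catalog associations (from [read_catalog()] or
#'   [simulate_lookup_study()]).
#' @param phenotype_tables named list of mental-phenotype summary
#'   statistics.
#' @param ld optional [ld_table()].
#' @param window_kb locus half-window in kb (default 500).
#' @param alpha family-wise error rate (default 0.05).
#' @param n_tests number of tests for the Bonferroni correction; defaults
#'   to the number of unique catalog SNPs (correction across SNPs only).
#'   Set `per_phenotype_correction = TRUE` for the stricter SNP-by-phenotype
#'   family.
#' @param anthro_stats optional anthropometric summary statistics for
#'   allele alignment and direction tables.
#' @param per_phenotype_correction multiply `n_tests` by the number of
#'   phenotype tables (default `FALSE`).
#' @return list with `threshold`, `loci` (a `"locus_set"` with lead SNPs),
#'   `hits`, `coverage`, `significant_loci` (locus ids with >= 1
#'   significant hit), and `directions` (or `NULL`).
#' @export
lookup_pipeline <- function(catalog, phenotype_tables, ld = NULL,
                            window_kb = 500, alpha = 0.05, n_tests = NULL,
                            anthro_stats = NULL,
                            per_phenotype_correction = FALSE) {
  n_tests <- n_tests %||% length(unique(catalog$snp_id))
  if (per_phenotype_correction) {
    n_tests <- n_tests * length(phenotype_tables)
  }
  threshold <- bonferroni_threshold(alpha, n_tests)
  loci <- define_loci(catalog, window_kb = window_kb, ld = ld)
  hits <- crosstrait_lookup(catalog, phenotype_tables, threshold,
                            anthro_stats = anthro_stats)
  loci <- select_lead_snps(loci, hits)
  sig_snps <- unique(hits$snp_id[hits$significant])
  sig_loci <- sort(unique(loci$members$locus_id[
    loci$members$snp_id %in% sig_snps]))
  directions <- if (!is.null(anthro_stats)) {
    direction_concordance(hits, loci, anthro_stats, phenotype_tables)
  }
  list(threshold = threshold, loci = loci, hits = hits,
       coverage = attr(hits, "coverage"),
       significant_loci = sig_loci, directions = directions)
}
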