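# Synthetic summary-statistic studies with known ground truth. The MR
# generator realizes the generative model the estimators assume: per-SNP
# exposure effects gamma_j, direct (pleiotropic) outcome effects alpha_j
# drawn independently of gamma_j (InSIDE holds by default), latent outcome
# effect true_beta*gamma_j + alpha_j, and sampling noise whose SE follows
# the standard 1/sqrt(2*MAF*(1-MAF)*N) approximation so that F statistics
# and power calculations are internally consistent.

#' Configuration for a synthetic two-sample MR study
#'
#' Defaults emulate a body-fat-distribution exposure (large anthropometric
#' meta-analysis, ~319 instruments, mean per-SNP F near 90) against a
#' psychiatric case-control outcome of ~105k subjects with ~39% cases.
#'
#' @param n_snps instrument count (default 319).
#' @param true_beta causal effect of exposure on outcome (default 0).
#' @param gamma_mean,gamma_sd mean and SD of the per-SNP exposure effect
#'   magnitude (absolute value of a normal draw; defaults 0.017, 0.006).
#' @param pleio_mean,pleio_sd mean and SD of the direct (pleiotropic)
#'   outcome effects; `pleio_mean != 0` is directional pleiotropy
#'   (defaults 0, 0).
#' @param n_exposure,n_outcome GWAS sample sizes driving the SE scale
#'   (defaults 694649 and 105318).
#' @param case_fraction proportion of cases in a binary outcome study, or
#'   `NA` for a continuous outcome (default 40675/105318).
#' @param maf_range minor-allele-frequency interval, within (0, 0.5]
#'   (default c(0.1, 0.5)).
#' @param frac_palindromic fraction of SNPs given A/T or C/G allele pairs
#'   (default 9/328, the rate seen in large anthropometric instrument
#'   sets after catalog filtering).
#' @param palindromic_idx optional explicit 1-based indices to make
#'   palindromic (overrides `frac_palindromic`).
#' @param inside_violation correlation knob in `[0,1]`: fraction of the
#'   pleiotropic effect proportional to `gamma_j`, violating InSIDE when
#'   positive (default 0, InSIDE holds).
#' @param seed integer seed (default 1).
#' @return a list of class `"synthetic_mr_config"`.
#' @export
mr_config <- function(n_snps = 319L, true_beta = 0, gamma_mean = 0.017,
                      gamma_sd = 0.006, pleio_mean = 0, pleio_sd = 0,
                      n_exposure = 694649, n_outcome = 105318,
                      case_fraction = 40675 / 105318,
                      maf_range = c(0.1, 0.5), frac_palindromic = 9 / 328,
                      palindromic_idx = NULL, inside_violation = 0,
                      seed = 1L) {
  stopifnot(n_snps >= 1, gamma_sd >= 0, pleio_sd >= 0,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            frac_palindromic >= 0, frac_palindromic <= 1,
            inside_violation >= 0, inside_violation <= 1)
  structure(as.list(environment()), class = "synthetic_mr_config")
}

NONPAL_PAIRS <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
PAL_PAIRS <- list(c("A", "T"), c("C", "G"))

#' Simulate a two-sample MR study
#'
#' Draws per-SNP minor-allele frequencies, exposure effects, pleiotropic
#' effects and sampling noise according to the configuration, and returns
#' exposure and outcome summary-statistic tables in the package's canonical
#' schema plus a truth record holding every latent value. Identical
#' configurations (including seed) reproduce identical tables.
#'
#' @param cfg a [mr_config()].
#' @return list with `exposure`, `outcome` (canonical summary-statistic
#'   data frames) and `truth` (list: `gamma`, `alpha`, `maf`,
#'   `latent_outcome`, `palindromic_idx`, `config`).
#' @export
simulate_mr_study <- function(cfg = mr_config()) {
  stopifnot(inherits(cfg, "synthetic_mr_config"))
  set.seed(cfg$seed)
  n <- cfg$n_snps
  maf <- stats::runif(n, cfg$maf_range[1], cfg$maf_range[2])
  gamma <- abs(stats::rnorm(n, cfg$gamma_mean, cfg$gamma_sd))
  alpha_raw <- stats::rnorm(n, cfg$pleio_mean, cfg$pleio_sd)
  # optional InSIDE violation: part of the direct effect scales with gamma
  alpha <- if (cfg$inside_violation > 0) {
    (1 - cfg$inside_violation) * alpha_raw +
      cfg$inside_violation * cfg$pleio_sd *
        (gamma - mean(gamma)) / max(stats::sd(gamma), 1e-12) +
      cfg$inside_violation * cfg$pleio_mean
  } else {
    alpha_raw
  }
  se_exp <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_exposure)
  out_var_factor <- if (is.na(cfg$case_fraction)) 1 else
    cfg$case_fraction * (1 - cfg$case_fraction)
  se_out <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_outcome * out_var_factor)
  latent_out <- cfg$true_beta * gamma + alpha
  beta_exp <- gamma + stats::rnorm(n, 0, se_exp)
  beta_out <- latent_out + stats::rnorm(n, 0, se_out)

  pal_idx <- if (!is.null(cfg$palindromic_idx)) {
    as.integer(cfg$palindromic_idx)
  } else if (cfg$frac_palindromic > 0) {
    k <- round(cfg$frac_palindromic * n)
    if (k > 0) sort(sample.int(n, k)) else integer(0)
  } else integer(0)
  pair_pick <- sample.int(length(NONPAL_PAIRS), n, replace = TRUE)
  ea <- vapply(pair_pick, function(i) NONPAL_PAIRS[[i]][1], character(1))
  oa <- vapply(pair_pick, function(i) NONPAL_PAIRS[[i]][2], character(1))
  if (length(pal_idx)) {
    pp <- sample.int(length(PAL_PAIRS), length(pal_idx), replace = TRUE)
    ea[pal_idx] <- vapply(pp, function(i) PAL_PAIRS[[i]][1], character(1))
    oa[pal_idx] <- vapply(pp, function(i) PAL_PAIRS[[i]][2], character(1))
  }

  ids <- sprintf("rs%07d", seq_len(n))
  chrom <- as.character(rep_len(1:22, n))
  pos <- 1e6 + 1e4 * seq_len(n)
  z_exp <- beta_exp / se_exp
  z_out <- beta_out / se_out
  exposure <- data.frame(
    snp_id = ids, chrom = chrom, pos = pos,
    effect_allele = ea, other_allele = oa, eaf = maf,
    beta = beta_exp, se = se_exp,
    pvalue = 2 * stats::pnorm(-abs(z_exp)),
    n = cfg$n_exposure, trait = "exposure", stringsAsFactors = FALSE)
  outcome <- data.frame(
    snp_id = ids, chrom = chrom, pos = pos,
    effect_allele = ea, other_allele = oa, eaf = maf,
    beta = beta_out, se = se_out,
    pvalue = 2 * stats::pnorm(-abs(z_out)),
    n = cfg$n_outcome, trait = "outcome", stringsAsFactors = FALSE)
  list(exposure = exposure, outcome = outcome,
       truth = list(gamma = gamma, alpha = alpha, maf = maf,
                    latent_outcome = latent_out,
                    palindromic_idx = pal_idx, config = cfg))
}

#' Configuration for a synthetic cross-trait look-up study
#'
#' Defaults emulate the structure of an anthropometric look-up panel: 40
#' well-separated planted loci of 2 catalog SNPs each, screened across 15
#' mental phenotypes, with every locus carrying one true sub-threshold
#' association and one third of those concordant in direction.
#'
#' @param n_loci planted locus count (default 40).
#' @param snps_per_locus catalog SNPs per locus (default 2).
#' @param locus_spacing_bp gap between locus anchors; must exceed 1 Mb so
#'   planted loci are unambiguous under a 500 kb window (default 2e6).
#' @param locus_span_bp positional spread of members within a locus
#'   (default 1e5).
#' @param n_phenotypes number of mental-phenotype tables (default 15).
#' @param overlap_fraction fraction of loci given a true mental-phenotype
#'   effect (default 1).
#' @param concordant_fraction fraction of overlapping loci whose planted
#'   effect direction matches the anthropometric direction (default 1/3).
#' @param effect_p P-value planted on true associations (default 1e-6).
#' @param null_p_floor minimum P for non-associations (default 0.01; keep
#'   it above the Bonferroni threshold implied by the study size).
#' @param seed integer seed (default 1).
#' @return a list of class `"synthetic_lookup_config"`.
#' @export
lookup_config <- function(n_loci = 40L, snps_per_locus = 2L,
                          locus_spacing_bp = 2e6, locus_span_bp = 1e5,
                          n_phenotypes = 15L, overlap_fraction = 1,
                          concordant_fraction = 1 / 3, effect_p = 1e-6,
                          null_p_floor = 0.01, seed = 1L) {
  stopifnot(n_loci >= 1, snps_per_locus >= 1,
            locus_spacing_bp > 2 * 5e5,
            overlap_fraction >= 0, overlap_fraction <= 1,
            concordant_fraction >= 0, concordant_fraction <= 1,
            effect_p > 0, effect_p < 1, null_p_floor > effect_p,
            null_p_floor < 1)
  structure(as.list(environment()), class = "synthetic_lookup_config")
}

#' Simulate a cross-trait look-up study with planted truth
#'
#' Generates a catalog of genome-wide-significant anthropometric SNPs
#' arranged in well-separated loci, one summary-statistic table per mental
#' phenotype, and an anthropometric summary-statistic table for direction
#' alignment. For each overlapping locus a designated member SNP receives
#' the planted P-value in one randomly chosen phenotype, with effect
#' direction set by `concordant_fraction`; every other SNP-phenotype pair
#' draws its P-value above `null_p_floor`.
#'
#' @param cfg a [lookup_config()].
#' @return list with `catalog`, `phenotypes` (named list of tables),
#'   `anthro_stats`, and `truth` (data frame: one row per planted locus
#'   with `locus_index`, `chrom`, `anchor_pos`, `designated_snp`,
#'   `overlapping`, `phenotype`, `concordant`).
#' @export
simulate_lookup_study <- function(cfg = lookup_config()) {
  stopifnot(inherits(cfg, "synthetic_lookup_config"))
  set.seed(cfg$seed)
  n_loci <- cfg$n_loci
  k <- cfg$snps_per_locus
  phenos <- sprintf("phenotype_%02d", seq_len(cfg$n_phenotypes))

  chrom <- as.character(rep_len(1:22, n_loci))
  within_chr <- stats::ave(seq_len(n_loci), chrom, FUN = seq_along)
  anchor <- 1e6 + (within_chr - 1) * cfg$locus_spacing_bp

  n_overlap <- round(cfg$overlap_fraction * n_loci)
  overlap_loci <- if (n_overlap > 0) sort(sample.int(n_loci, n_overlap)) else
    integer(0)
  n_conc <- round(cfg$concordant_fraction * n_overlap)
  conc_loci <- if (n_conc > 0) sort(sample(overlap_loci, n_conc)) else
    integer(0)

  cat_rows <- vector("list", n_loci)
  truth_rows <- vector("list", n_loci)
  all_ids <- character(0)
  designated <- rep(NA_character_, n_loci)
  planted_pheno <- rep(NA_character_, n_loci)
  for (l in seq_len(n_loci)) {
    ids <- sprintf("rs%03d%03d", l, seq_len(k))
    pos <- anchor[l] + sort(sample.int(cfg$locus_span_bp + 1, k)) - 1
    cat_rows[[l]] <- data.frame(
      snp_id = ids, chrom = chrom[l], pos = pos,
      trait_label = "body mass index",
      pvalue = 10^-stats::runif(k, 8.5, 30),
      study_id = "SYNTH1", ancestry = "synthetic European-like",
      stringsAsFactors = FALSE)
    if (l %in% overlap_loci) {
      designated[l] <- ids[sample.int(k, 1)]
      planted_pheno[l] <- phenos[sample.int(length(phenos), 1)]
    }
    truth_rows[[l]] <- data.frame(
      locus_index = l, chrom = chrom[l], anchor_pos = anchor[l],
      designated_snp = designated[l],
      overlapping = l %in% overlap_loci,
      phenotype = planted_pheno[l],
      concordant = if (l %in% overlap_loci) l %in% conc_loci else NA,
      stringsAsFactors = FALSE)
    all_ids <- c(all_ids, ids)
  }
  catalog <- do.call(rbind, cat_rows)
  truth <- do.call(rbind, truth_rows)

  n_snps <- length(all_ids)
  pair_pick <- sample.int(length(NONPAL_PAIRS), n_snps, replace = TRUE)
  ea <- vapply(pair_pick, function(i) NONPAL_PAIRS[[i]][1], character(1))
  oa <- vapply(pair_pick, function(i) NONPAL_PAIRS[[i]][2], character(1))
  maf <- stats::runif(n_snps, 0.1, 0.5)

  # anthropometric stats: effect allele is the trait-increasing allele
  anthro <- data.frame(
    snp_id = all_ids, chrom = catalog$chrom, pos = catalog$pos,
    effect_allele = ea, other_allele = oa, eaf = maf,
    beta = stats::runif(n_snps, 0.01, 0.05),
    se = stats::runif(n_snps, 0.002, 0.004),
    pvalue = catalog$pvalue, n = 500000,
    trait = "body mass index", stringsAsFactors = FALSE)

  snp_locus <- rep(seq_len(n_loci), each = k)
  phenotypes <- setNames(lapply(phenos, function(ph) {
    p <- stats::runif(n_snps, cfg$null_p_floor, 1)
    beta <- stats::rnorm(n_snps, 0, 0.005)
    se <- stats::runif(n_snps, 0.008, 0.012)
    planted <- which(!is.na(designated[snp_locus]) &
                       all_ids == designated[snp_locus] &
                       planted_pheno[snp_locus] == ph)
    if (length(planted)) {
      p[planted] <- cfg$effect_p
      dir <- ifelse(truth$concordant[snp_locus[planted]], 1, -1)
      beta[planted] <- dir * stats::runif(length(planted), 0.02, 0.05)
    }
    data.frame(snp_id = all_ids, chrom = catalog$chrom, pos = catalog$pos,
               effect_allele = ea, other_allele = oa, eaf = maf,
               beta = beta, se = se, pvalue = p, n = 300000,
               trait = ph, stringsAsFactors = FALSE)
  }), phenos)

  list(catalog = catalog, phenotypes = phenotypes, anthro_stats = anthro,
       truth = truth)
}
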