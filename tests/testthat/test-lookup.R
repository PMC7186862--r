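test_that("Bonferroni threshold is exact division with guarded domain", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 100), 1e-4)
  expect_error(bonferroni_threshold(0.05, 0), class = "crossmr_domain_error")
  expect_error(bonferroni_threshold(1.2, 10), class = "crossmr_domain_error")
})

toy_snps <- function(pos, chrom = "1") {
  data.frame(snp_id = sprintf("rs%d", seq_along(pos)), chrom = chrom,
             pos = pos, stringsAsFactors = FALSE)
}

test_that("locus definition follows the window and equilibrium rules", {
  # distance beyond the window splits
  ls <- define_loci(toy_snps(c(1e6, 2.2e6)), window_kb = 500)
  expect_equal(nrow(ls$loci), 2)
  # close pair in strong LD merges
  ld <- ld_table(data.frame(snp_a = "rs1", snp_b = "rs2",
                            r2 = 0.5, d_prime = 0.9))
  ls <- define_loci(toy_snps(c(1e6, 1.1e6)), window_kb = 500, ld = ld)
  expect_equal(nrow(ls$loci), 1)
  # demonstrated equilibrium (both r2 and D' below 0.01) splits
  ld <- ld_table(data.frame(snp_a = "rs1", snp_b = "rs2",
                            r2 = 0.005, d_prime = 0.005))
  ls <- define_loci(toy_snps(c(1e6, 1.1e6)), window_kb = 500, ld = ld)
  expect_equal(nrow(ls$loci), 2)
  # unknown LD counts as linked: one locus
  ls <- define_loci(toy_snps(c(1e6, 1.1e6)), window_kb = 500, ld = NULL)
  expect_equal(nrow(ls$loci), 1)
  # r2 below but D' above threshold: still linked
  ld <- ld_table(data.frame(snp_a = "rs1", snp_b = "rs2",
                            r2 = 0.005, d_prime = 0.5))
  ls <- define_loci(toy_snps(c(1e6, 1.1e6)), window_kb = 500, ld = ld)
  expect_equal(nrow(ls$loci), 1)
})

test_that("locus definition is a partition, order-free, and loci are coherent", {
  for (s in 1:15) {
    inst <- rand_loci_instance(1000 + s)
    ld <- if (is.null(inst$ld_pairs)) NULL else ld_table(inst$ld_pairs)
    ls <- define_loci(inst$snps, window_kb = 500, ld = ld)
    # partition: every SNP in exactly one locus
    expect_setequal(ls$members$snp_id, unique(inst$snps$snp_id))
    expect_false(any(duplicated(ls$members$snp_id)))
    # member positions inside the locus bounds, one chromosome per locus
    for (i in seq_len(nrow(ls$loci))) {
      mem <- ls$members[ls$members$locus_id == ls$loci$locus_id[i], ]
      expect_true(all(mem$pos >= ls$loci$start[i] &
                        mem$pos <= ls$loci$end[i]))
      expect_equal(length(unique(mem$chrom)), 1L)
    }
    # permuting the input changes nothing
    perm <- inst$snps[sample(nrow(inst$snps)), , drop = FALSE]
    ls2 <- define_loci(perm, window_kb = 500, ld = ld)
    expect_identical(locusset_partition(ls), locusset_partition(ls2))
  }
})

test_that("locus definition matches the brute-force clustering oracle", {
  for (s in 1:30) {
    inst <- rand_loci_instance(2000 + s)
    ld <- if (is.null(inst$ld_pairs)) NULL else ld_table(inst$ld_pairs)
    ls <- define_loci(inst$snps, window_kb = 500, ld = ld)
    expect_identical(
      locusset_partition(ls),
      loci_oracle_partition(inst$snps, 500, inst$ld_pairs),
      info = paste("instance seed", 2000 + s))
  }
})

test_that("cross-trait lookup reports joins, boundaries and coverage", {
  sim <- simulate_lookup_study(lookup_config(n_loci = 6, seed = 9))
  snps <- sim$catalog[1:2, ]
  # a SNP present in only some tables yields hits there and absences elsewhere
  tabs <- sim$phenotypes
  tabs[[1]] <- tabs[[1]][tabs[[1]]$snp_id != snps$snp_id[1], ]
  hits <- crosstrait_lookup(snps, tabs, threshold = 1e-4)
  cov <- attr(hits, "coverage")
  expect_equal(cov$n_absent[1], 1)
  expect_equal(sum(hits$phenotype == names(tabs)[1]), 1)
  # threshold boundary is strict: P just below is significant
  tab <- data.frame(snp_id = "rsX", chrom = "1", pos = 1, effect_allele = "A",
                    other_allele = "G", eaf = 0.3, beta = 0.1, se = 0.01,
                    pvalue = 4.97e-5, n = 1000, trait = "t")
  h <- crosstrait_lookup(data.frame(snp_id = "rsX"), list(pheno = tab),
                         threshold = 4.98e-5)
  expect_true(h$significant)
  h <- crosstrait_lookup(data.frame(snp_id = "rsX"), list(pheno = tab),
                         threshold = 4.97e-5)
  expect_false(h$significant)
})

test_that("lowering the threshold never adds significant hits", {
  sim <- simulate_lookup_study(lookup_config(seed = 33))
  thr <- c(1e-2, 1e-3, 1e-4, 1e-5, 1e-6, 1e-7)
  counts <- vapply(thr, function(t) {
    sum(crosstrait_lookup(sim$catalog, sim$phenotypes, t)$significant)
  }, numeric(1))
  expect_true(!is.unsorted(rev(counts)))
})

test_that("lead-SNP selection applies hit count, then P-value, then rsID", {
  hits <- data.frame(
    snp_id = c("rsA", "rsA", "rsA", "rsA", "rsB", "rsB", "rsC"),
    phenotype = c("p1", "p2", "p3", "p4", "p1", "p2", "p1"),
    pvalue = c(1e-6, 1e-6, 1e-6, 1e-6, 1e-9, 1e-9, 1e-8),
    significant = TRUE, stringsAsFactors = FALSE)
  expect_identical(select_lead_snp(c("rsA", "rsB"), hits), "rsA")
  # tied hit counts: lowest P wins
  hits2 <- data.frame(snp_id = c("rsD", "rsE"), phenotype = "p1",
                      pvalue = c(1e-6, 1e-8), significant = TRUE,
                      stringsAsFactors = FALSE)
  expect_identical(select_lead_snp(c("rsD", "rsE"), hits2), "rsE")
  # full tie: lexicographic rsID, deterministically
  hits3 <- data.frame(snp_id = c("rsF", "rsG"), phenotype = "p1",
                      pvalue = c(1e-6, 1e-6), significant = TRUE,
                      stringsAsFactors = FALSE)
  expect_message(out <- select_lead_snp(c("rsG", "rsF"), hits3), "tie")
  expect_identical(out, "rsF")
  expect_identical(select_lead_snp("rsZ", hits), "rsZ")
  expect_error(select_lead_snp(character(0), hits),
               class = "crossmr_domain_error")
})

test_that("direction concordance recovers planted counts and sign conventions", {
  cfg <- lookup_config(n_loci = 15, n_phenotypes = 1,
                       concordant_fraction = 5 / 15, seed = 14)
  sim <- simulate_lookup_study(cfg)
  res <- lookup_pipeline(sim$catalog, sim$phenotypes,
                         anthro_stats = sim$anthro_stats)
  counts <- res$directions$counts
  expect_equal(sum(counts$same), 5)
  expect_equal(sum(counts$opposite), 10)
  # per-locus calls match the planted truth
  ent <- res$directions$entries
  mem <- res$loci$members
  planted <- sim$truth[sim$truth$overlapping, ]
  lid <- mem$locus_id[match(planted$designated_snp, mem$snp_id)]
  expect_equal(ent$concordant[match(lid, ent$locus_id)], planted$concordant)
})

test_that("concordance is invariant under allele relabelling of either table", {
  sim <- simulate_lookup_study(lookup_config(n_loci = 10, n_phenotypes = 3,
                                             seed = 15))
  base <- lookup_pipeline(sim$catalog, sim$phenotypes,
                          anthro_stats = sim$anthro_stats)
  # relabel alleles (swap + negate) in one phenotype table
  flip <- sim$phenotypes
  tb <- flip[[2]]
  tmp <- tb$effect_allele; tb$effect_allele <- tb$other_allele
  tb$other_allele <- tmp; tb$beta <- -tb$beta; tb$eaf <- 1 - tb$eaf
  flip[[2]] <- tb
  relab <- lookup_pipeline(sim$catalog, flip,
                           anthro_stats = sim$anthro_stats)
  expect_equal(base$directions$counts, relab$directions$counts)
  # and in the anthropometric table
  at <- sim$anthro_stats
  tmp <- at$effect_allele; at$effect_allele <- at$other_allele
  at$other_allele <- tmp; at$beta <- -at$beta; at$eaf <- 1 - at$eaf
  relab2 <- lookup_pipeline(sim$catalog, sim$phenotypes, anthro_stats = at)
  expect_equal(base$directions$counts, relab2$directions$counts)
})

test_that("confirmatory lookup counts replications and unassessable SNPs", {
  prior <- data.frame(snp_id = sprintf("rs%d", 1:7), pvalue = 1e-6,
                      significant = TRUE, stringsAsFactors = FALSE)
  indep <- data.frame(snp_id = sprintf("rs%d", 1:6),
                      pvalue = c(1e-6, 1e-7, 2e-5, 0.2, 0.9, 1e-9),
                      stringsAsFactors = FALSE)
  rep <- confirmatory_lookup(prior, indep, threshold = 4.98e-5)
  expect_equal(rep$n_replicated, 4)
  expect_equal(rep$n_tested, 6)
  expect_equal(rep$n_not_assessable, 1)
  expect_identical(
    rep$snp_report$status[rep$snp_report$snp_id == "rs7"], "not-assessable")
  expect_error(
    confirmatory_lookup(prior, indep, 4.98e-5,
                        discovery_path = "a.tsv", independent_path = "a.tsv"),
    class = "crossmr_config_error")
})

test_that("replication fraction tracks a planted true-effect rate", {
  set.seed(88)
  n <- 500
  true_frac <- 0.6
  is_true <- runif(n) < true_frac
  prior <- data.frame(snp_id = sprintf("rs%d", 1:n), pvalue = 1e-6,
                      significant = TRUE, stringsAsFactors = FALSE)
  # high power: true effects replicate with tiny P, nulls draw uniform P
  indep <- data.frame(
    snp_id = prior$snp_id,
    pvalue = ifelse(is_true, 10^-runif(n, 6, 12), runif(n, 0.001, 1)),
    stringsAsFactors = FALSE)
  rep <- confirmatory_lookup(prior, indep, threshold = 4.98e-5)
  frac <- rep$n_replicated / rep$n_tested
  expect_lt(abs(frac - true_frac), 3 * sqrt(true_frac * 0.4 / n) + 0.01)
})
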