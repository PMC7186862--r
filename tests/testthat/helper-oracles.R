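# Independent oracles used by the property tests. Each re-derives the
# quantity under test from first principles via a different route than the
# package implementation (matrix normal equations, exhaustive grid scans,
# brute-force transitive closure), so agreement is evidence, not tautology.

# random instrument sets ------------------------------------------------

rand_insts <- function(n, seed, b_true = 0.2, pleio_sd = 0,
                       exposure_noise = TRUE) {
  set.seed(seed)
  gamma <- runif(n, 0.05, 0.2) * sample(c(-1, 1), n, replace = TRUE)
  se_exp <- if (exposure_noise) runif(n, 0.002, 0.01) else rep(0, n)
  se_out <- runif(n, 0.01, 0.05)
  bx <- gamma + rnorm(n, 0, se_exp)
  by <- b_true * gamma + rnorm(n, 0, pleio_sd) + rnorm(n, 0, se_out)
  data.frame(snp_id = sprintf("rs%04d", seq_len(n)),
             beta_exp = bx, se_exp = se_exp,
             beta_out = by, se_out = se_out,
             stringsAsFactors = FALSE)
}

# IVW: weighted least squares through the origin via explicit matrix algebra
ivw_wls_oracle <- function(insts) {
  x <- insts$beta_exp
  y <- insts$beta_out
  w <- 1 / insts$se_out^2
  xtwx <- sum(w * x * x)
  est <- sum(w * x * y) / xtwx
  list(estimate = est, se_fixed = sqrt(1 / xtwx))
}

# MR-Egger: 2x2 weighted normal equations solved with solve(), after the
# same exposure-positive orientation the estimator defines
egger_ne_oracle <- function(insts) {
  s <- ifelse(insts$beta_exp < 0, -1, 1)
  x <- insts$beta_exp * s
  y <- insts$beta_out * s
  w <- 1 / insts$se_out^2
  X <- cbind(1, x)
  XtWX <- t(X) %*% (w * X)
  bhat <- solve(XtWX, t(X) %*% (w * y))
  resid <- y - X %*% bhat
  sigma2 <- sum(w * resid^2) / (nrow(insts) - 2)
  cv <- solve(XtWX) * sigma2
  infl <- 1 / min(1, sqrt(sigma2))
  list(intercept = bhat[1], slope = bhat[2],
       intercept_se = sqrt(cv[1, 1]) * infl,
       slope_se = sqrt(cv[2, 2]) * infl)
}

# RAPS (l2, tau2 = 0): exhaustive scan of the profile score over a fine
# grid, root located at the sign change
raps_grid_oracle <- function(insts, lo = -2, hi = 2, step = 1e-6) {
  b <- seq(lo, hi, by = step)
  score <- numeric(length(b))
  for (j in seq_len(nrow(insts))) {
    s2 <- insts$se_out[j]^2 + b^2 * insts$se_exp[j]^2
    s <- sqrt(s2)
    t_j <- (insts$beta_out[j] - b * insts$beta_exp[j]) / s
    dt <- -(insts$beta_exp[j] / s) - t_j * b * insts$se_exp[j]^2 / s2
    score <- score + t_j * dt
  }
  sgn <- sign(score)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(flip)) stop("grid oracle found no sign change")
  (b[flip[1]] + b[flip[1] + 1]) / 2
}

# numeric delta-method oracle for the second-order Wald ratio SE
wald_se2_fd_oracle <- function(bx, by, sx, sy, h = 1e-7) {
  f <- function(x, y) y / x
  gx <- (f(bx + h, by) - f(bx - h, by)) / (2 * h)
  gy <- (f(bx, by + h) - f(bx, by - h)) / (2 * h)
  sqrt(gx^2 * sx^2 + gy^2 * sy^2)
}

# locus clustering oracle ------------------------------------------------

# Naive transcription of the clustering definition: per chromosome, scan
# sorted SNPs recomputing min/max from scratch each step; then split on
# demonstrated equilibrium using boolean-matrix transitive closure for the
# connected components. Returns the partition as a canonical string.
loci_oracle_partition <- function(snps, window_kb, ld_pairs = NULL,
                                  r2_max = 0.01, dprime_max = 0.01) {
  snps <- snps[!is.na(snps$pos), , drop = FALSE]
  snps <- snps[!duplicated(snps$snp_id), , drop = FALSE]
  window_bp <- window_kb * 1000
  look <- function(a, b) {
    if (is.null(ld_pairs)) return(c(NA_real_, NA_real_))
    hit <- (ld_pairs$snp_a == a & ld_pairs$snp_b == b) |
      (ld_pairs$snp_a == b & ld_pairs$snp_b == a)
    if (!any(hit)) return(c(NA_real_, NA_real_))
    c(ld_pairs$r2[which(hit)[1]], ld_pairs$d_prime[which(hit)[1]])
  }
  groups <- list()
  for (chr in unique(snps$chrom)) {
    sub <- snps[snps$chrom == chr, , drop = FALSE]
    sub <- sub[order(sub$pos, sub$snp_id), , drop = FALSE]
    current <- sub$snp_id[1]
    for (i in seq_len(nrow(sub))[-1]) {
      ps <- sub$pos[match(current, sub$snp_id)]
      mid <- (min(ps) + max(ps)) / 2
      if (abs(sub$pos[i] - mid) <= window_bp) {
        current <- c(current, sub$snp_id[i])
      } else {
        groups[[length(groups) + 1]] <- current
        current <- sub$snp_id[i]
      }
    }
    groups[[length(groups) + 1]] <- current
  }
  # LD split by transitive closure of the linked relation
  out <- list()
  for (g in groups) {
    n <- length(g)
    if (n == 1) { out[[length(out) + 1]] <- g; next }
    linked <- matrix(TRUE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      q <- look(g[i], g[j])
      if (!is.na(q[1]) && !is.na(q[2]) && q[1] < r2_max && q[2] < dprime_max) {
        linked[i, j] <- FALSE
      }
    }
    reach <- linked
    for (k in seq_len(n)) {
      reach <- reach | (reach %*% reach > 0)
    }
    seen <- rep(FALSE, n)
    for (i in seq_len(n)) {
      if (seen[i]) next
      comp <- which(reach[i, ] | seq_len(n) == i)
      seen[comp] <- TRUE
      out[[length(out) + 1]] <- g[comp]
    }
  }
  canonical_partition(out)
}

canonical_partition <- function(sets) {
  paste(sort(vapply(sets, function(s) paste(sort(s), collapse = ","),
                    character(1))), collapse = " | ")
}

locusset_partition <- function(ls) {
  canonical_partition(split(ls$members$snp_id, ls$members$locus_id))
}

# random clustering instance: clumped positions, a partially observed LD
# table with values straddling the equilibrium thresholds
rand_loci_instance <- function(seed, max_snps = 60) {
  set.seed(seed)
  n <- sample.int(max_snps, 1)
  chrom <- as.character(sample(1:3, n, replace = TRUE))
  # mixture of tight clumps and scattered positions
  pos <- ifelse(runif(n) < 0.6,
                sample(1:5, n, replace = TRUE) * 1e6 +
                  round(runif(n, -3e5, 3e5)),
                round(runif(n, 1, 8e6)))
  snps <- data.frame(snp_id = sprintf("rs%05d", sample.int(99999, n)),
                     chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  n_pairs <- sample.int(max(1, n), 1)
  ld_pairs <- NULL
  if (n >= 2 && n_pairs > 0) {
    a <- sample(snps$snp_id, n_pairs, replace = TRUE)
    b <- sample(snps$snp_id, n_pairs, replace = TRUE)
    keep <- a != b
    if (any(keep)) {
      ld_pairs <- data.frame(
        snp_a = a[keep], snp_b = b[keep],
        r2 = sample(c(0.001, 0.005, 0.009, 0.011, 0.3, 0.9),
                    sum(keep), replace = TRUE),
        d_prime = sample(c(0.001, 0.009, 0.011, 0.5, 1),
                         sum(keep), replace = TRUE),
        stringsAsFactors = FALSE)
      ld_pairs <- ld_pairs[!duplicated(t(apply(
        ld_pairs[, c("snp_a", "snp_b")], 1, sort))), , drop = FALSE]
    }
  }
  list(snps = snps, ld_pairs = ld_pairs)
}

# misc -------------------------------------------------------------------

write_tsv_fixture <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# instrument tables with alleles, for harmonization round trips
alleled_insts <- function(n, seed, palindromic_idx = integer(0)) {
  sim <- simulate_mr_study(mr_config(
    n_snps = n, frac_palindromic = 0, palindromic_idx = palindromic_idx,
    seed = seed))
  list(exposure = sim$exposure, outcome = sim$outcome, truth = sim$truth)
}
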