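# Two-sample MR estimators and diagnostics.
#
# Notation: for instrument j, (bx_j, sx_j) are the exposure association and
# its SE, (by_j, sy_j) the outcome association and its SE, all per copy of
# the shared effect allele. The Wald ratio is by_j/bx_j; IVW pools ratios
# with weights w_j = bx_j^2/sy_j^2, equivalent to weighted least squares of
# by on bx through the origin; MR-Egger frees the intercept to absorb
# directional pleiotropy; RAPS profiles out the exposure measurement error.

check_instruments <- function(insts, min_n = 1L, caller = "MR") {
  stopifnot(is.data.frame(insts))
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  if (!all(need %in% names(insts))) {
    stop_crossmr(sprintf("%s needs columns %s", caller,
                         paste(need, collapse = ", ")),
                 "crossmr_config_error")
  }
  if (nrow(insts) < min_n) {
    stop_crossmr(sprintf("%s requires >= %d instruments, got %d",
                         caller, min_n, nrow(insts)),
                 "crossmr_method_error")
  }
  if (any(insts$se_out <= 0) || any(insts$se_exp < 0)) {
    stop_crossmr("instrument SEs must be positive", "crossmr_domain_error")
  }
  insts
}

new_mr_result <- function(method, estimate, se, pvalue, n_snps,
                          intercept = NA_real_, intercept_se = NA_real_,
                          intercept_p = NA_real_, q_stat = NA_real_,
                          q_df = NA_integer_, q_p = NA_real_,
                          tau2 = NA_real_, converged = TRUE,
                          model = NA_character_) {
  structure(list(method = method, estimate = estimate, se = se,
                 pvalue = pvalue, n_snps = n_snps, intercept = intercept,
                 intercept_se = intercept_se, intercept_p = intercept_p,
                 q_stat = q_stat, q_df = q_df, q_p = q_p, tau2 = tau2,
                 converged = converged, model = model),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result: %s>  n_snps = %d\n", x$method, x$n_snps))
  cat(sprintf("  estimate = %.6g  (SE %.6g)  P = %s\n",
              x$estimate, x$se, format_pvalue(x$pvalue)))
  if (!is.na(x$intercept)) {
    cat(sprintf("  intercept = %.6g  (SE %.6g)  P = %s\n",
                x$intercept, x$intercept_se, format_pvalue(x$intercept_p)))
  }
  if (!is.na(x$q_stat)) {
    cat(sprintf("  Q = %.6g on %d df, P = %s\n",
                x$q_stat, x$q_df, format_pvalue(x$q_p)))
  }
  if (!is.na(x$tau2)) cat(sprintf("  tau2 = %.6g\n", x$tau2))
  if (!isTRUE(x$converged)) cat("  ** solver did not converge **\n")
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(method = x$method, estimate = x$estimate, se = x$se,
             pvalue = x$pvalue, n_snps = x$n_snps, intercept = x$intercept,
             intercept_se = x$intercept_se, intercept_p = x$intercept_p,
             q_stat = x$q_stat, q_df = x$q_df, q_p = x$q_p, tau2 = x$tau2,
             converged = x$converged, model = x$model,
             stringsAsFactors = FALSE)
}

#' Per-SNP Wald ratio estimates
#'
#' The ratio estimate `beta_out / beta_exp` with, by default, the
#' first-order delta-method SE `se_out / |beta_exp|` (exposure-side
#' uncertainty is handled by [raps()], not inflated into the ratio SE). The
#' second-order SE additionally propagates `se_exp`.
#'
#' @param insts harmonized instruments (data frame with `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`).
#' @param second_order if `TRUE`, use
#'   `sqrt(se_out^2/beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)`.
#' @return data frame with columns `estimate`, `se` (one row per
#'   instrument; `snp_id` carried through when present).
#' @export
wald_ratio <- function(insts, second_order = FALSE) {
  insts <- check_instruments(insts, 1L, "wald_ratio")
  if (any(insts$beta_exp == 0)) {
    stop_crossmr("null instrument: beta_exp = 0 has no Wald ratio",
                 "crossmr_domain_error")
  }
  est <- insts$beta_out / insts$beta_exp
  se <- if (second_order) {
    sqrt(insts$se_out^2 / insts$beta_exp^2 +
           insts$beta_out^2 * insts$se_exp^2 / insts$beta_exp^4)
  } else {
    insts$se_out / abs(insts$beta_exp)
  }
  out <- data.frame(estimate = est, se = se)
  if ("snp_id" %in% names(insts)) out <- cbind(snp_id = insts$snp_id, out)
  out
}

#' Inverse-variance-weighted causal estimate
#'
#' Pools the per-SNP Wald ratios with weights `w_j = beta_exp^2 / se_out^2`
#' — algebraically identical to a fixed-effect meta-analysis of the ratios
#' and to weighted least squares of `beta_out` on `beta_exp` through the
#' origin. The default multiplicative-random-effects model inflates the
#' fixed-effects SE by `max(1, sqrt(Q/(n-1)))`, so under-dispersion never
#' shrinks the SE below the fixed-effects value. Two-sided P-values come
#' from the standard normal.
#'
#' @param insts harmonized instruments.
#' @param model `"mre"` (multiplicative random effects, default) or
#'   `"fixed"`. A single instrument forces `"fixed"` with a warning.
#' @return an `"mr_result"` with Cochran's Q attached (`q_df = n - 1`).
#' @export
ivw <- function(insts, model = c("mre", "fixed")) {
  model <- match.arg(model)
  insts <- check_instruments(insts, 1L, "ivw")
  n <- nrow(insts)
  w <- insts$beta_exp^2 / insts$se_out^2
  theta <- insts$beta_out / insts$beta_exp
  # beta_exp = 0 contributes zero weight; the w*theta product is then 0/0,
  # but the limit (and the WLS formulation) gives 0, so compute via WLS form
  num <- sum(insts$beta_exp * insts$beta_out / insts$se_out^2)
  den <- sum(insts$beta_exp^2 / insts$se_out^2)
  if (den == 0) {
    stop_crossmr("all instruments have beta_exp = 0", "crossmr_domain_error")
  }
  est <- num / den
  se_fixed <- 1 / sqrt(den)
  ok <- insts$beta_exp != 0
  q <- sum(w[ok] * (theta[ok] - est)^2)
  q_df <- n - 1L
  q_p <- if (q_df >= 1) stats::pchisq(q, q_df, lower.tail = FALSE) else NA_real_
  if (model == "mre" && n < 2L) {
    warning("multiplicative random effects needs >= 2 instruments; using fixed")
    model <- "fixed"
  }
  se <- if (model == "mre") se_fixed * max(1, sqrt(q / (n - 1))) else se_fixed
  p <- 2 * stats::pnorm(-abs(est / se))
  new_mr_result("ivw", est, se, p, n,
                q_stat = q, q_df = q_df, q_p = q_p, model = model)
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome associations on the exposure
#' associations with a free intercept and weights `1/se_out^2`, after
#' orienting every instrument so its exposure effect is positive (Egger's
#' slope is not invariant to allele orientation; the exposure-positive
#' convention makes it well defined). The slope estimates the causal effect;
#' the intercept estimates the average directional pleiotropic effect, and
#' its test is the pleiotropy diagnostic. SEs use the weighted-regression
#' residual variance floored at 1 (multiplicative random effects that never
#' deflate below the fixed-effect SE); P-values are two-sided on `n - 2` df.
#'
#' @param insts harmonized instruments (at least 3).
#' @return an `"mr_result"` with `intercept*` fields and heterogeneity
#'   about the Egger fit (`q_df = n - 2`).
#' @export
egger <- function(insts) {
  insts <- check_instruments(insts, 3L, "MR-Egger")
  n <- nrow(insts)
  flip <- ifelse(insts$beta_exp < 0, -1, 1)
  bx <- insts$beta_exp * flip
  by <- insts$beta_out * flip
  w <- 1 / insts$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  cf <- summary(fit)$coefficients
  sigma <- summary(fit)$sigma
  infl <- 1 / min(1, sigma)   # floor residual SD at 1: inflate, never deflate
  slope <- cf["bx", "Estimate"]
  slope_se <- cf["bx", "Std. Error"] * infl
  int <- cf["(Intercept)", "Estimate"]
  int_se <- cf["(Intercept)", "Std. Error"] * infl
  slope_p <- 2 * stats::pt(-abs(slope / slope_se), df = n - 2)
  int_p <- 2 * stats::pt(-abs(int / int_se), df = n - 2)
  q <- sum(w * stats::residuals(fit)^2)
  q_df <- n - 2L
  new_mr_result("egger", slope, slope_se, slope_p, n,
                intercept = int, intercept_se = int_se, intercept_p = int_p,
                q_stat = q, q_df = q_df,
                q_p = stats::pchisq(q, q_df, lower.tail = FALSE),
                model = "mre")
}

# standardized profile residual and its b-derivative
raps_t <- function(b, tau2, insts) {
  s <- sqrt(insts$se_out^2 + b^2 * insts$se_exp^2 + tau2)
  r <- insts$beta_out - b * insts$beta_exp
  list(t = r / s, s = s, r = r)
}

raps_score <- function(b, tau2, insts, rho_prime) {
  z <- raps_t(b, tau2, insts)
  dt_db <- -(insts$beta_exp / z$s) -
    z$t * b * insts$se_exp^2 / z$s^2
  sum(rho_prime(z$t) * dt_db)
}

#' Robust adjusted profile score (RAPS) estimator
#'
#' Profiles the exposure measurement error out of the likelihood: the
#' standardized residual of instrument j at causal effect `b` and
#' overdispersion `tau2` is
#' `t_j = (beta_out_j - b*beta_exp_j) / sqrt(se_out_j^2 + b^2*se_exp_j^2 + tau2)`,
#' and the estimate solves the profile-score equation
#' `sum(rho'(t_j) * dt_j/db) = 0`. The simple mode fixes `tau2 = 0`; the
#' overdispersed mode additionally solves `sum(t_j^2 - 1) = 0` for
#' `tau2 >= 0`, absorbing systematic (balanced) pleiotropy. The robust loss
#' is Huber with tuning constant 1.345. The solver is damped Newton on the
#' score with a bracketing/bisection fallback over `b` in `[-10, 10]`
#' (tolerance 1e-8 on the score); failure is reported via `converged =
#' FALSE`, never an exception. The SE is the M-estimation sandwich.
#'
#' @param insts harmonized instruments (at least 3).
#' @param overdispersed estimate `tau2` (default `FALSE`).
#' @param loss `"l2"` (default) or `"huber"`.
#' @param huber_k Huber tuning constant (1.345).
#' @param tol convergence tolerance on the score.
#' @param max_iter Newton iteration budget.
#' @return an `"mr_result"`; `tau2` is filled in overdispersed mode.
#' @export
raps <- function(insts, overdispersed = FALSE, loss = c("l2", "huber"),
                 huber_k = 1.345, tol = 1e-8, max_iter = 100L) {
  loss <- match.arg(loss)
  insts <- check_instruments(insts, 3L, "RAPS")
  n <- nrow(insts)
  rho_prime <- if (loss == "l2") {
    function(t) t
  } else {
    function(t) pmax(pmin(t, huber_k), -huber_k)
  }

  solve_b <- function(tau2, b0) {
    score <- function(b) raps_score(b, tau2, insts, rho_prime)
    b <- b0
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      s0 <- score(b)
      if (abs(s0) < tol) { ok <- TRUE; break }
      h <- max(1e-6, 1e-6 * abs(b))
      ds <- (score(b + h) - score(b - h)) / (2 * h)
      if (!is.finite(ds) || ds == 0) break
      step <- s0 / ds
      # damping: halve until the score magnitude decreases
      lambda <- 1
      repeat {
        b_new <- b - lambda * step
        if (abs(b_new) <= 10 && is.finite(score(b_new)) &&
            abs(score(b_new)) < abs(s0)) break
        lambda <- lambda / 2
        if (lambda < 1e-10) { b_new <- b; break }
      }
      if (b_new == b) break
      b <- b_new
    }
    if (!ok || abs(score(b)) >= tol) {
      # bisection fallback: scan for a sign change over [-10, 10]
      grid <- seq(-10, 10, length.out = 2001)
      sv <- vapply(grid, score, numeric(1))
      sgn <- sign(sv)
      idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
      if (length(idx)) {
        # take the bracket closest to the IVW start
        pick <- idx[which.min(abs(grid[idx] - b0))]
        root <- stats::uniroot(score, c(grid[pick], grid[pick + 1]),
                               tol = 1e-12)
        b <- root$root
        ok <- abs(score(b)) < max(tol, 1e-6)
      } else {
        ok <- FALSE
      }
    }
    list(b = b, converged = ok)
  }

  b0 <- ivw(insts, model = "fixed")$estimate
  tau2 <- 0
  if (!overdispersed) {
    sol <- solve_b(0, b0)
  } else {
    # alternate: solve b given tau2, then tau2 given b (sum t^2 = n), until
    # both stabilize; the tau2 moment equation always uses the l2 residuals
    sol <- solve_b(0, b0)
    for (it in seq_len(50L)) {
      moment <- function(t2) sum(raps_t(sol$b, t2, insts)$t^2) - n
      tau2_new <- if (moment(0) <= 0) 0 else {
        upper <- 1
        while (moment(upper) > 0 && upper < 1e6) upper <- upper * 10
        stats::uniroot(moment, c(0, upper), tol = 1e-12)$root
      }
      sol_new <- solve_b(tau2_new, sol$b)
      done <- abs(tau2_new - tau2) < tol * (1 + tau2) &&
        abs(sol_new$b - sol$b) < tol * (1 + abs(sol$b))
      tau2 <- tau2_new
      sol <- sol_new
      if (done) break
    }
  }

  # sandwich variance: psi_j = rho'(t_j) dt_j/db; A = d(sum psi)/db, B = sum psi^2
  z <- raps_t(sol$b, tau2, insts)
  dt_db <- -(insts$beta_exp / z$s) - z$t * sol$b * insts$se_exp^2 / z$s^2
  psi <- rho_prime(z$t) * dt_db
  h <- max(1e-6, 1e-6 * abs(sol$b))
  A <- (raps_score(sol$b + h, tau2, insts, rho_prime) -
          raps_score(sol$b - h, tau2, insts, rho_prime)) / (2 * h)
  se <- if (is.finite(A) && A != 0) sqrt(sum(psi^2)) / abs(A) else NA_real_
  p <- if (is.finite(se) && se > 0) 2 * stats::pnorm(-abs(sol$b / se)) else NA_real_
  new_mr_result("raps", sol$b, se, p, n,
                tau2 = if (overdispersed) tau2 else NA_real_,
                converged = sol$converged,
                model = paste0(loss, if (overdispersed) "+overdispersed"))
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_j * (theta_j - estimate)^2)` over the Wald ratios `theta_j`
#' with IVW weights `w_j = beta_exp^2/se_out^2`; `df = n - 1`; P from the
#' upper chi-square tail. Large Q signals heterogeneous ratio estimates —
#' possible pleiotropy or invalid instruments.
#'
#' @param insts harmonized instruments (at least 2).
#' @param estimate the pooled estimate to measure dispersion around;
#'   defaults to the fixed-effects IVW estimate.
#' @return list with `q_stat`, `q_df`, `q_p`.
#' @export
cochran_q <- function(insts, estimate = NULL) {
  insts <- check_instruments(insts, 2L, "Cochran's Q")
  if (is.null(estimate)) estimate <- ivw(insts, model = "fixed")$estimate
  if (!is_scalar_number(estimate)) {
    stop_crossmr("estimate must be a finite scalar", "crossmr_domain_error")
  }
  ok <- insts$beta_exp != 0
  w <- insts$beta_exp[ok]^2 / insts$se_out[ok]^2
  theta <- insts$beta_out[ok] / insts$beta_exp[ok]
  q <- sum(w * (theta - estimate)^2)
  q_df <- nrow(insts) - 1L
  list(q_stat = q, q_df = q_df,
       q_p = stats::pchisq(q, q_df, lower.tail = FALSE))
}

#' Instrument-strength F statistic
#'
#' Two conventions are in circulation and reports should state which was
#' used, so both are provided. `"mean-per-snp"` averages the per-SNP
#' squared z-statistics `(beta_exp/se_exp)^2`. `"overall-r2"` uses the
#' regression identity `F = (n - k - 1)/k * r2/(1 - r2)` from the
#' exposure-study sample size `n`, instrument count `k` and the variance
#' `r2` the instruments jointly explain.
#'
#' @param insts harmonized instruments (required for `"mean-per-snp"`, and
#'   supplies `k` for `"overall-r2"` unless `n_snps` is given).
#' @param mode `"mean-per-snp"` or `"overall-r2"`.
#' @param n_exposure exposure-study sample size (overall-r2 mode).
#' @param r2 variance explained by the instruments (overall-r2 mode).
#' @param n_snps instrument count override for overall-r2 mode.
#' @return the F statistic (scalar). Values well above 10 indicate that
#'   weak-instrument bias is negligible.
#' @export
f_statistic <- function(insts = NULL, mode = c("mean-per-snp", "overall-r2"),
                        n_exposure = NULL, r2 = NULL, n_snps = NULL) {
  mode <- match.arg(mode)
  if (mode == "mean-per-snp") {
    if (is.null(insts)) {
      stop_crossmr("mean-per-snp mode needs instruments",
                   "crossmr_config_error")
    }
    insts <- check_instruments(insts, 1L, "f_statistic")
    if (any(insts$se_exp <= 0)) {
      stop_crossmr("mean-per-snp F needs positive exposure SEs",
                   "crossmr_config_error")
    }
    return(mean((insts$beta_exp / insts$se_exp)^2))
  }
  k <- n_snps %||% if (!is.null(insts)) nrow(insts) else NULL
  if (is.null(n_exposure) || is.null(r2) || is.null(k)) {
    stop_crossmr("overall-r2 mode needs n_exposure, r2 and an instrument count",
                 "crossmr_config_error")
  }
  if (r2 < 0 || r2 >= 1) {
    stop_crossmr("r2 must lie in [0, 1)", "crossmr_domain_error")
  }
  (n_exposure - k - 1) / k * r2 / (1 - r2)
}

#' Single-SNP (per-instrument) causal estimates and funnel-plot data
#'
#' One Wald ratio per instrument with its normal-theory P-value, a
#' significance flag at two-sided `alpha`, and funnel-plot coordinates
#' (estimate against precision `1/se`).
#'
#' @param insts harmonized instruments.
#' @param alpha per-SNP significance level (default 0.05).
#' @return data frame with `snp_id`, `estimate`, `se`, `pvalue`,
#'   `significant`, `funnel_x`, `funnel_y`.
#' @export
single_snp_table <- function(insts, alpha = 0.05) {
  insts <- check_instruments(insts, 1L, "single_snp_table")
  wr <- wald_ratio(insts)
  p <- 2 * stats::pnorm(-abs(wr$estimate / wr$se))
  out <- data.frame(
    snp_id = if ("snp_id" %in% names(insts)) insts$snp_id else
      paste0("snp", seq_len(nrow(insts))),
    estimate = wr$estimate, se = wr$se, pvalue = p,
    significant = p < alpha,
    funnel_x = wr$estimate, funnel_y = 1 / wr$se,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Leave-one-out IVW sensitivity analysis
#'
#' Recomputes the IVW estimate `n` times, each omitting one instrument, to
#' expose single variants that drive the pooled estimate. Rows whose
#' estimate changes sign relative to the full-set estimate are flagged.
#'
#' @param insts harmonized instruments (at least 2).
#' @param model IVW model passed through to [ivw()].
#' @return data frame with `snp_id` (the omitted SNP), `estimate`, `se`,
#'   `pvalue`, `sign_change`.
#' @export
leave_one_out <- function(insts, model = c("mre", "fixed")) {
  model <- match.arg(model)
  insts <- check_instruments(insts, 2L, "leave_one_out")
  full <- ivw(insts, model = model)$estimate
  ids <- if ("snp_id" %in% names(insts)) insts$snp_id else
    paste0("snp", seq_len(nrow(insts)))
  rows <- lapply(seq_len(nrow(insts)), function(i) {
    r <- suppressWarnings(ivw(insts[-i, , drop = FALSE], model = model))
    data.frame(snp_id = ids[i], estimate = r$estimate, se = r$se,
               pvalue = r$pvalue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$sign_change <- sign(out$estimate) != sign(full)
  rownames(out) <- NULL
  out
}

#' Plot-ready data tables for scatter, forest and funnel displays
#'
#' Emits plain tables rather than styled figures: `scatter` holds the
#' per-SNP exposure/outcome effects with error bars plus fitted lines for
#' each supplied estimator; `forest` holds per-SNP Wald estimates with 95%
#' CIs and one summary row per estimator; `funnel` is the single-SNP table's
#' precision plot.
#'
#' @param insts harmonized instruments.
#' @param results optional list of `"mr_result"` objects to overlay.
#' @return list of data frames `scatter`, `scatter_lines`, `forest`,
#'   `funnel`.
#' @export
mr_plot_data <- function(insts, results = list()) {
  insts <- check_instruments(insts, 1L, "mr_plot_data")
  ss <- single_snp_table(insts)
  z <- stats::qnorm(0.975)
  forest <- data.frame(
    label = ss$snp_id, estimate = ss$estimate,
    ci_low = ss$estimate - z * ss$se, ci_high = ss$estimate + z * ss$se,
    kind = "snp", stringsAsFactors = FALSE)
  lines <- data.frame(method = character(0), intercept = numeric(0),
                      slope = numeric(0), stringsAsFactors = FALSE)
  for (r in results) {
    forest <- rbind(forest, data.frame(
      label = r$method, estimate = r$estimate,
      ci_low = r$estimate - z * r$se, ci_high = r$estimate + z * r$se,
      kind = "summary", stringsAsFactors = FALSE))
    lines <- rbind(lines, data.frame(
      method = r$method,
      intercept = if (is.na(r$intercept)) 0 else r$intercept,
      slope = r$estimate, stringsAsFactors = FALSE))
  }
  scatter <- data.frame(
    snp_id = ss$snp_id,
    beta_exp = insts$beta_exp, se_exp = insts$se_exp,
    beta_out = insts$beta_out, se_out = insts$se_out,
    stringsAsFactors = FALSE)
  list(scatter = scatter, scatter_lines = lines, forest = forest,
       funnel = ss[, c("snp_id", "funnel_x", "funnel_y")])
}

#' Run the full MR estimator battery
#'
#' Convenience wrapper: IVW, MR-Egger, RAPS (simple and overdispersed),
#' Cochran's Q, both F statistics, single-SNP and leave-one-out tables.
#'
#' @param insts harmonized instruments (at least 3).
#' @param n_exposure,r2 optional inputs for the overall-r2 F statistic.
#' @param ivw_model IVW model (`"mre"` default).
#' @return list with `results` (data frame, one row per estimator),
#'   `f_mean_per_snp`, `f_overall_r2` (NA when inputs absent), `q`,
#'   `single_snp`, `leave_one_out`, `plot_data`.
#' @export
mr_analysis <- function(insts, n_exposure = NULL, r2 = NULL,
                        ivw_model = c("mre", "fixed")) {
  ivw_model <- match.arg(ivw_model)
  insts <- check_instruments(insts, 3L, "mr_analysis")
  fits <- list(ivw(insts, model = ivw_model), egger(insts),
               raps(insts, overdispersed = FALSE),
               raps(insts, overdispersed = TRUE))
  results <- do.call(rbind, lapply(fits, as.data.frame))
  f_overall <- if (!is.null(n_exposure) && !is.null(r2)) {
    f_statistic(insts, mode = "overall-r2", n_exposure = n_exposure, r2 = r2)
  } else NA_real_
  f_mean <- if (all(insts$se_exp > 0)) f_statistic(insts) else NA_real_
  list(results = results,
       f_mean_per_snp = f_mean,
       f_overall_r2 = f_overall,
       q = cochran_q(insts),
       single_snp = single_snp_table(insts),
       leave_one_out = leave_one_out(insts, model = ivw_model),
       plot_data = mr_plot_data(insts, fits[1:2]))
}
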