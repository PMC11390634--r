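# Causal estimators on harmonized summary statistics. All p-values are
# two-sided normal; confidence intervals use the conventional 1.959964
# multiplier (summary-statistic MR convention, no t-correction).

.z975 <- 1.959964

#' Construct an MR estimate
#'
#' Wraps a causal log-odds effect and its standard error with the derived
#' odds ratio, 95% CI and two-sided normal p-value.
#'
#' @param method One of `"wald"`, `"ivw_fixed"`, `"ivw_mre"`, `"egger"`.
#' @param beta Causal effect on the outcome log-odds scale per unit
#'   exposure.
#' @param se Standard error of `beta` (> 0).
#' @param n_snp Number of SNPs behind the estimate.
#' @return Object of class `"mr_estimate"`: list with method, beta, se,
#'   or_, ci_low, ci_high, pval, n_snp.
#' @export
mr_estimate <- function(method, beta, se, n_snp) {
  stopifnot(is.finite(beta), is.finite(se), se > 0)
  structure(list(
    method = method, beta = beta, se = se,
    or_ = exp(beta),
    ci_low = exp(beta - .z975 * se),
    ci_high = exp(beta + .z975 * se),
    pval = 2 * stats::pnorm(-abs(beta / se)),
    n_snp = as.integer(n_snp)
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s, %d SNP%s]\n", x$method, x$n_snp,
              if (x$n_snp == 1) "" else "s"))
  cat(sprintf("  OR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$or_, x$ci_low, x$ci_high, x$pval))
  invisible(x)
}

#' Reconstruct an MR estimate from a printed OR confidence interval
#'
#' Inverts the normal-theory CI: beta is the midpoint of the log bounds and
#' se the half-width divided by 1.959964. Useful for consistency checks on
#' reported OR/CI lines — the reconstructed OR must reproduce the printed
#' point estimate.
#'
#' @param ci_low,ci_high Printed OR confidence bounds.
#' @param method,n_snp Passed through to [mr_estimate()].
#' @return An `mr_estimate`.
#' @export
estimate_from_ci <- function(ci_low, ci_high, method = "ivw_mre", n_snp = NA) {
  stopifnot(ci_low > 0, ci_high > ci_low)
  beta <- (log(ci_low) + log(ci_high)) / 2
  se <- (log(ci_high) - log(ci_low)) / (2 * .z975)
  mr_estimate(method, beta, se, n_snp)
}

.check_pairs <- function(pairs, min_k = 1) {
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  stopifnot(all(need %in% names(pairs)))
  if (anyNA(pairs[need])) stop("pairs contain missing betas/SEs; run kept_pairs() first", call. = FALSE)
  if (nrow(pairs) < min_k) {
    stop(sprintf("at least %d SNP(s) required, got %d", min_k, nrow(pairs)),
         call. = FALSE)
  }
  invisible(pairs)
}

#' Wald ratio: single-SNP causal estimate
#'
#' beta = beta_out / beta_exp, with first-order delta-method standard error
#' se_out / |beta_exp|.
#'
#' @param pairs One harmonized pair (a 1-row tibble).
#' @return An `mr_estimate` with method `"wald"`.
#' @export
wald_ratio <- function(pairs) {
  .check_pairs(pairs, 1)
  pairs <- pairs[1, , drop = FALSE]
  if (pairs$beta_exp == 0) stop("Wald ratio undefined: beta_exp = 0", call. = FALSE)
  mr_estimate("wald",
              beta = pairs$beta_out / pairs$beta_exp,
              se = pairs$se_out / abs(pairs$beta_exp),
              n_snp = 1)
}

#' Inverse-variance weighted estimator
#'
#' Zero-intercept weighted regression of outcome on exposure effects with
#' weights 1/se_out^2 — equivalently the inverse-variance meta-analysis of
#' per-SNP Wald ratios. The fixed-effect SE is 1/sqrt(sum w beta_exp^2);
#' the multiplicative random-effects (MRE) model scales it by
#' sqrt(max(Q/(k-1), 1)) so heterogeneity widens but never narrows the
#' interval. A single pair delegates to [wald_ratio()].
#'
#' @param pairs Harmonized pairs (kept rows).
#' @param model `"mre"` (default; the primary model) or `"fixed"`.
#' @return An `mr_estimate`.
#' @export
ivw <- function(pairs, model = c("mre", "fixed")) {
  model <- match.arg(model)
  .check_pairs(pairs, 1)
  k <- nrow(pairs)
  if (k == 1) return(wald_ratio(pairs))
  x <- pairs$beta_exp
  y <- pairs$beta_out
  w <- 1 / pairs$se_out^2
  sxx <- sum(w * x^2)
  if (sxx == 0) stop("all exposure betas are zero", call. = FALSE)
  beta <- sum(w * x * y) / sxx
  se_fixed <- sqrt(1 / sxx)
  if (model == "fixed") return(mr_estimate("ivw_fixed", beta, se_fixed, k))
  q <- sum(w * (y - beta * x)^2)
  phi <- max(q / (k - 1), 1)
  mr_estimate("ivw_mre", beta, se_fixed * sqrt(phi), k)
}

#' Cochran's Q heterogeneity statistic
#'
#' Q = sum w_i (beta_out_i - beta_ivw * beta_exp_i)^2 with w_i = 1/se_out^2,
#' referred to a chi-square with k - 1 degrees of freedom.
#'
#' @param pairs Harmonized pairs (k >= 2).
#' @param beta_ivw Pooled IVW slope; recomputed if omitted.
#' @return List with `q`, `df`, `pval`.
#' @export
cochran_q <- function(pairs, beta_ivw = NULL) {
  .check_pairs(pairs, 2)
  if (is.null(beta_ivw)) beta_ivw <- ivw(pairs, "fixed")$beta
  w <- 1 / pairs$se_out^2
  q <- sum(w * (pairs$beta_out - beta_ivw * pairs$beta_exp)^2)
  df <- nrow(pairs) - 1L
  list(q = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with a free
#' intercept, weights 1/se_out^2, after orienting all exposure betas
#' non-negative (the InSIDE convention). A non-zero intercept indicates
#' directional pleiotropy; the slope is a pleiotropy-adjusted causal
#' estimate. Both SEs are scaled by sqrt(max(Q_egger/(k-2), 1)). Requires
#' k >= 3; smaller sets return a not-computed marker rather than an error.
#'
#' @param pairs Harmonized pairs.
#' @return List with `computed` flag and, when computed: `slope` (an
#'   `mr_estimate` with method `"egger"`), `intercept`, `intercept_se`,
#'   `intercept_pval`, `q`, `df`.
#' @export
egger <- function(pairs) {
  if (nrow(pairs) < 3) return(list(computed = FALSE))
  .check_pairs(pairs, 3)
  s <- ifelse(pairs$beta_exp < 0, -1, 1)
  x <- s * pairs$beta_exp
  y <- s * pairs$beta_out
  w <- 1 / pairs$se_out^2
  if (stats::var(x) == 0) stop("exposure betas collinear: Egger undefined", call. = FALSE)
  k <- length(x)
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  inter <- (swxx * swy - swx * swxy) / det
  q <- sum(w * (y - inter - slope * x)^2)
  phi <- max(q / (k - 2), 1)
  se_slope <- sqrt(sw / det * phi)
  se_inter <- sqrt(swxx / det * phi)
  list(
    computed = TRUE,
    slope = mr_estimate("egger", slope, se_slope, k),
    intercept = inter, intercept_se = se_inter,
    intercept_pval = 2 * stats::pnorm(-abs(inter / se_inter)),
    q = q, df = k - 2L
  )
}

#' Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure versus the
#' outcome, aggregating per-SNP r^2 = z^2/(z^2 + n). Causality is oriented
#' exposure -> outcome iff the exposure r^2 is larger; the p-value comes
#' from a z-test on the Fisher-transformed aggregate correlations with
#' sampling variances 1/(n - 3).
#'
#' @param pairs Harmonized pairs.
#' @param n_exp,n_out GWAS sample sizes (> 3).
#' @return List with `direction` (`"exposure_to_outcome"`,
#'   `"outcome_to_exposure"` or `"not_established"`),
#'   `correct_direction` (logical: exposure r^2 strictly larger), `pval`,
#'   `r2_exp`, `r2_out`.
#' @export
steiger <- function(pairs, n_exp, n_out) {
  .check_pairs(pairs, 1)
  if (n_exp <= 3 || n_out <= 3) stop("sample sizes must exceed 3", call. = FALSE)
  agg_r2 <- function(beta, se, n) {
    z <- beta / se
    sum(z^2 / (z^2 + n))
  }
  r2_exp <- agg_r2(pairs$beta_exp, pairs$se_exp, n_exp)
  r2_out <- agg_r2(pairs$beta_out, pairs$se_out, n_out)
  fz <- function(r2) atanh(sqrt(min(r2, 1 - 1e-12)))
  zstat <- (fz(r2_exp) - fz(r2_out)) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  direction <- if (r2_exp > r2_out) {
    "exposure_to_outcome"
  } else if (r2_exp < r2_out) {
    "outcome_to_exposure"
  } else "not_established"
  list(
    direction = direction,
    correct_direction = r2_exp > r2_out,
    pval = 2 * stats::pnorm(-abs(zstat)),
    r2_exp = r2_exp, r2_out = r2_out
  )
}

#' Leave-one-out analysis
#'
#' Re-estimates the causal effect omitting each SNP in turn; a result that
#' hinges on a single variant shows up as a large deviation from the full
#' estimate. Requires k >= 3 (so every reduced set still has >= 2 SNPs).
#'
#' @param pairs Harmonized pairs.
#' @param model IVW model for the reduced fits.
#' @return List with `computed` flag and, when computed: `estimates`
#'   (tibble: variant_id, beta, se, pval for each omitted SNP), `full`
#'   (the all-SNP `mr_estimate`), `max_abs_dev`.
#' @export
leave_one_out <- function(pairs, model = c("mre", "fixed")) {
  model <- match.arg(model)
  if (nrow(pairs) < 3) return(list(computed = FALSE))
  .check_pairs(pairs, 3)
  full <- ivw(pairs, model)
  ests <- lapply(seq_len(nrow(pairs)), function(i) ivw(pairs[-i, , drop = FALSE], model))
  list(
    computed = TRUE,
    estimates = tibble::tibble(
      variant_id = pairs$variant_id,
      beta = vapply(ests, `[[`, 0, "beta"),
      se = vapply(ests, `[[`, 0, "se"),
      pval = vapply(ests, `[[`, 0, "pval")
    ),
    full = full,
    max_abs_dev = max(abs(vapply(ests, `[[`, 0, "beta") - full$beta))
  )
}

#' Re-orient exposure effects to a 1-unit decline
#'
#' Negates every exposure beta (outcome effects untouched) so that the
#' downstream odds ratios are expressed per 1 mmHg decline in SBP — the
#' direction in which antihypertensive drugs act. Applying twice is the
#' identity.
#'
#' @param pairs Harmonized pairs (exposure betas per 1 mmHg increase).
#' @return The pairs with `beta_exp` negated.
#' @export
orient_per_mmhg_decline <- function(pairs) {
  pairs$beta_exp <- -pairs$beta_exp
  pairs
}

#' Run the full sensitivity battery on one harmonized set
#'
#' Cochran's Q (against the IVW slope), MR-Egger intercept, MR-PRESSO,
#' Steiger directionality and leave-one-out. Tests whose minimum SNP count
#' is not met are reported as not computed, never as failures.
#'
#' @param pairs Harmonized pairs (kept rows).
#' @param n_exp,n_out GWAS sample sizes for the Steiger test.
#' @param presso_nsim Simulations for the MR-PRESSO null (default 1000).
#' @param seed Seed for MR-PRESSO.
#' @return List of class `"sensitivity_report"`: q, q_df, q_pval,
#'   egger_intercept, egger_intercept_se, egger_intercept_pval, presso
#'   (full [mr_presso()] result or NULL), steiger_direction, steiger_pval,
#'   loo (leave-one-out result).
#' @export
sensitivity_battery <- function(pairs, n_exp, n_out, presso_nsim = 1000,
                                seed = 1L) {
  k <- nrow(pairs)
  qres <- if (k >= 2) cochran_q(pairs) else list(q = NA, df = NA, pval = NA)
  eg <- egger(pairs)
  presso <- if (k >= 2) {
    mr_presso(pairs, nsim = presso_nsim, seed = seed)
  } else NULL
  st <- steiger(pairs, n_exp, n_out)
  structure(list(
    q = qres$q, q_df = qres$df, q_pval = qres$pval,
    egger_intercept = if (eg$computed) eg$intercept else NA_real_,
    egger_intercept_se = if (eg$computed) eg$intercept_se else NA_real_,
    egger_intercept_pval = if (eg$computed) eg$intercept_pval else NA_real_,
    presso = presso,
    steiger_direction = st$correct_direction,
    steiger_pval = st$pval,
    loo = leave_one_out(pairs)
  ), class = "sensitivity_report")
}
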