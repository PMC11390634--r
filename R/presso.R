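# MR-PRESSO: pleiotropy residual sum and outlier test, implemented on the
# leave-one-out IVW residual scale with a parametric simulation null.

.loo_slopes <- function(x, y, w) {
  sxy <- sum(w * x * y)
  sxx <- sum(w * x^2)
  (sxy - w * x * y) / (sxx - w * x^2)
}

#' MR-PRESSO global, outlier and distortion tests
#'
#' The observed residual sum of squares is
#' RSS = sum w_i (beta_out_i - b_(-i) beta_exp_i)^2, where b_(-i) is the
#' IVW slope with SNP i left out and w_i = 1/se_out_i^2. The null
#' distribution comes from `nsim` parametric draws
#' beta_out_i* ~ Normal(b_(-i) beta_exp_i, se_out_i^2), with leave-one-out
#' slopes recomputed on every simulated dataset. P-values use the add-one
#' rule (1 + b)/(nsim + 1) so they are never exactly zero.
#'
#' Per-SNP outlier p-values compare each SNP's observed weighted squared
#' residual against its own simulated distribution, Bonferroni-adjusted by
#' k; SNPs below `outlier_alpha` after adjustment are flagged (only when
#' k >= 4 — smaller sets get the global test only). When outliers are
#' found, the corrected estimate is IVW on the remaining SNPs and the
#' distortion test compares the observed shift in the slope against a
#' bootstrap of outlier-free subsets.
#'
#' @param pairs Harmonized pairs (k >= 2).
#' @param nsim Simulations for the global/outlier null (default 1000;
#'   below 100 a warning is issued).
#' @param outlier_alpha Family-wise outlier threshold (default 0.05).
#' @param seed Integer seed; results are deterministic given it.
#' @param n_boot Bootstrap draws for the distortion test (default 1000).
#' @return List: `global_rss`, `global_pval`, `outliers` (variant ids),
#'   `outlier_pvals` (Bonferroni-adjusted, named; NULL when k < 4),
#'   `distortion_pval` (NA when no outliers), `corrected` (an
#'   `mr_estimate` on non-outliers, NULL when no outliers), `nsim`.
#' @export
mr_presso <- function(pairs, nsim = 1000, outlier_alpha = 0.05, seed = 1L,
                      n_boot = 1000) {
  .check_pairs(pairs, 2)
  if (nsim < 100) warning("nsim < 100 gives a coarse null; increase nsim")
  k <- nrow(pairs)
  x <- pairs$beta_exp
  y <- pairs$beta_out
  se <- pairs$se_out
  w <- 1 / se^2

  b_loo <- .loo_slopes(x, y, w)
  mu <- b_loo * x
  d_obs <- w * (y - mu)^2
  rss_obs <- sum(d_obs)

  withr::with_seed(as.integer(seed), {
    ystar <- matrix(stats::rnorm(nsim * k, mean = rep(mu, each = nsim),
                                 sd = rep(se, each = nsim)), nrow = nsim)
    # vectorized leave-one-out slopes per simulated dataset
    wx <- w * x
    sxy_star <- as.vector(ystar %*% wx)            # length nsim
    sxx <- sum(w * x^2)
    num <- sweep(-sweep(ystar, 2, wx, `*`), 1, sxy_star, `+`)
    den <- sxx - w * x^2
    b_star <- sweep(num, 2, den, `/`)              # nsim x k
    resid_star <- ystar - sweep(b_star, 2, x, `*`)
    d_star <- sweep(resid_star^2, 2, w, `*`)
    rss_star <- rowSums(d_star)

    global_pval <- (1 + sum(rss_star >= rss_obs)) / (nsim + 1)

    outliers <- character(0)
    outlier_pvals <- NULL
    if (k >= 4) {
      p_raw <- (1 + colSums(sweep(d_star, 2, d_obs, `>=`))) / (nsim + 1)
      p_adj <- pmin(p_raw * k, 1)
      names(p_adj) <- pairs$variant_id
      outliers <- pairs$variant_id[p_adj < outlier_alpha]
      outlier_pvals <- p_adj
    }

    distortion_pval <- NA_real_
    corrected <- NULL
    keep <- !(pairs$variant_id %in% outliers)
    if (length(outliers) > 0 && sum(keep) >= 2) {
      corrected <- ivw(pairs[keep, , drop = FALSE], "mre")
      b_all <- ivw(pairs, "fixed")$beta
      b_clean <- ivw(pairs[keep, , drop = FALSE], "fixed")$beta
      d_shift <- abs(b_all - b_clean)
      idx_keep <- which(keep)
      shift_boot <- vapply(seq_len(n_boot), function(b) {
        bi <- sample(idx_keep, k, replace = TRUE)
        xb <- x[bi]; yb <- y[bi]; wb <- w[bi]
        abs(sum(wb * xb * yb) / sum(wb * xb^2) - b_clean)
      }, 0)
      distortion_pval <- (1 + sum(shift_boot >= d_shift)) / (n_boot + 1)
    }
  })

  list(
    global_rss = rss_obs, global_pval = global_pval,
    outliers = outliers, outlier_pvals = outlier_pvals,
    distortion_pval = distortion_pval, corrected = corrected,
    nsim = nsim
  )
}
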