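# Study orchestration: positive-control gating on CAD, the drug-class x
# pain-outcome scan, Bonferroni tiering and reporting.

#' Bonferroni-corrected significance threshold
#'
#' The family-wise threshold is `family_alpha / n_classes`, where the
#' denominator is the number of drug classes originally tested (not the
#' number surviving the control gate). A 4-decimal display form is reported
#' alongside the exact value (0.05/12 displays as 0.0042).
#'
#' @param n_classes Number of classes tested (>= 1).
#' @param family_alpha Family-wise error rate (default 0.05).
#' @return List with `alpha` (exact) and `display` (rounded to 4 decimals).
#' @export
bonferroni_alpha <- function(n_classes, family_alpha = 0.05) {
  if (n_classes < 1) stop("n_classes must be >= 1", call. = FALSE)
  alpha <- family_alpha / n_classes
  list(alpha = alpha, display = round(alpha, 4))
}

#' Evidence tier for a scan p-value
#'
#' `"strong"` below the Bonferroni threshold, `"suggestive"` in
#' \[threshold, 0.05), `"none"` at or above 0.05. The three tiers partition
#' (0, 1].
#'
#' @param pval P-value(s) in (0, 1].
#' @param alpha_bonferroni Bonferroni threshold (exact form).
#' @return Character vector of tier labels.
#' @export
tier <- function(pval, alpha_bonferroni) {
  if (any(is.na(pval)) || any(pval <= 0 | pval > 1)) {
    stop("pval must lie in (0, 1]", call. = FALSE)
  }
  ifelse(pval < alpha_bonferroni, "strong",
         ifelse(pval < 0.05, "suggestive", "none"))
}

.estimate_cell <- function(pairs) {
  if (nrow(pairs) == 1) wald_ratio(pairs) else ivw(pairs, "mre")
}

#' Positive-control gate against CAD
#'
#' Validates each class's instruments against the control outcome: the
#' instruments are harmonized to CAD, oriented per 1 mmHg SBP decline, and
#' estimated (Wald if a single SNP, else IVW-MRE). A class passes iff its
#' CAD p-value is below `gate_alpha` AND the odds ratio is protective
#' (OR < 1 per 1 mmHg decline) — antihypertensive proxies must lower
#' coronary risk. Failing classes are excluded from the scan with a logged
#' reason.
#'
#' @param instruments Named list from [build_instruments()].
#' @param cad_outcome Control-outcome summary-statistic tibble.
#' @param gate_alpha Gate significance level (default 0.05).
#' @param ld_table,proxies Passed to [harmonize()].
#' @return Tibble: class_name, n_snp, beta, or, pval, passed, reason.
#' @export
control_gate <- function(instruments, cad_outcome, gate_alpha = 0.05,
                         ld_table = NULL, proxies = "none") {
  rows <- lapply(instruments, function(ins) {
    cl <- ins$class_name
    base <- tibble::tibble(class_name = cl, n_snp = 0L, beta = NA_real_,
                           or = NA_real_, pval = NA_real_, passed = FALSE,
                           reason = "no instruments")
    if (nrow(ins$records) == 0) return(base)
    pairs <- kept_pairs(harmonize(ins$records, cad_outcome,
                                  proxies = proxies, ld_table = ld_table))
    if (nrow(pairs) == 0) return(base)
    est <- .estimate_cell(orient_per_mmhg_decline(pairs))
    passed <- est$pval < gate_alpha && est$or_ < 1
    reason <- if (passed) {
      "protective and significant"
    } else if (est$pval >= gate_alpha) {
      "not significant"
    } else "direction"
    tibble::tibble(class_name = cl, n_snp = nrow(pairs), beta = est$beta,
                   or = est$or_, pval = est$pval, passed = passed,
                   reason = reason)
  })
  do.call(rbind, rows)
}

#' Drug-class x outcome MR scan
#'
#' For every gated class and every outcome in the panel: harmonize (with
#' the configured proxy policy), apply the confounder blocklist, orient per
#' 1 mmHg SBP decline, estimate (Wald for a single SNP, IVW-MRE otherwise),
#' run the full sensitivity battery, and tier the p-value against the
#' Bonferroni threshold computed from the number of classes originally
#' tested. If MR-PRESSO flags outliers, the outlier-corrected estimate is
#' recorded in the notes alongside — not instead of — the primary estimate.
#' A missing or empty cell is marked failed and the scan continues.
#'
#' @param instruments Named list of gated instrument sets.
#' @param outcomes Named list of outcome summary-statistic tibbles.
#' @param n_classes_tested Bonferroni denominator (classes before gating).
#' @param n_exp,n_out Exposure and outcome GWAS sample sizes (used by the
#'   Steiger test; per-outcome n columns take precedence when present).
#' @param blocklist Optional blocklist tibble.
#' @param ld_table,proxies Passed to [harmonize()].
#' @param presso_nsim MR-PRESSO simulations per cell.
#' @param family_alpha Family-wise error rate.
#' @param seed Base seed; each cell derives its own offset so reruns are
#'   byte-identical.
#' @return Tibble in the [write_results()] schema plus a `notes` column;
#'   the per-cell sensitivity details are attached as the
#'   `"details"` attribute (named list keyed by "class|outcome").
#' @export
run_scan <- function(instruments, outcomes, n_classes_tested,
                     n_exp = NULL, n_out = NULL, blocklist = NULL,
                     ld_table = NULL, proxies = "none", presso_nsim = 1000,
                     family_alpha = 0.05, seed = 1L) {
  alpha <- bonferroni_alpha(n_classes_tested, family_alpha)$alpha
  details <- list()
  rows <- list()
  cell_idx <- 0L
  for (ins in instruments) {
    for (oc in names(outcomes)) {
      cell_idx <- cell_idx + 1L
      key <- paste(ins$class_name, oc, sep = "|")
      fail_row <- function(note) tibble::tibble(
        class = ins$class_name, outcome = oc, method = NA_character_,
        n_snp = 0L, beta = NA_real_, se = NA_real_, or = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, pval = NA_real_,
        q_pval = NA_real_, egger_intercept_pval = NA_real_,
        presso_global_pval = NA_real_, steiger_direction = NA,
        steiger_pval = NA_real_, tier = NA_character_, notes = note
      )
      outcome_tbl <- outcomes[[oc]]
      if (is.null(outcome_tbl)) {
        rows[[key]] <- fail_row("failed: missing outcome data")
        next
      }
      recs <- apply_blocklist(ins$records, blocklist)
      pairs <- kept_pairs(harmonize(recs, outcome_tbl, proxies = proxies,
                                    ld_table = ld_table))
      if (nrow(pairs) == 0) {
        rows[[key]] <- fail_row("failed: no harmonizable instruments")
        next
      }
      pairs <- orient_per_mmhg_decline(pairs)
      est <- .estimate_cell(pairs)
      ne <- if (!is.null(n_exp)) n_exp else stats::median(recs$n, na.rm = TRUE)
      no <- if (all(!is.na(outcome_tbl$n))) {
        stats::median(outcome_tbl$n)
      } else n_out
      sens <- sensitivity_battery(pairs, n_exp = ne, n_out = no,
                                  presso_nsim = presso_nsim,
                                  seed = as.integer(seed) + cell_idx)
      notes <- character(0)
      n_proxy <- sum(!is.na(pairs$proxy_id))
      if (n_proxy > 0) notes <- c(notes, sprintf("%d proxy substitution(s)", n_proxy))
      if (!sens$loo$computed) notes <- c(notes, "leave-one-out not computed (k < 3)")
      if (is.na(sens$egger_intercept_pval)) notes <- c(notes, "Egger not computed (k < 3)")
      if (!is.null(sens$presso) && length(sens$presso$outliers) > 0) {
        corr <- sens$presso$corrected
        notes <- c(notes, sprintf(
          "PRESSO outliers: %s; corrected OR %.4f (p = %.3g)",
          paste(sens$presso$outliers, collapse = ","),
          if (!is.null(corr)) corr$or_ else NA, if (!is.null(corr)) corr$pval else NA
        ))
      }
      rows[[key]] <- tibble::tibble(
        class = ins$class_name, outcome = oc, method = est$method,
        n_snp = est$n_snp, beta = est$beta, se = est$se, or = est$or_,
        ci_low = est$ci_low, ci_high = est$ci_high, pval = est$pval,
        q_pval = sens$q_pval,
        egger_intercept_pval = sens$egger_intercept_pval,
        presso_global_pval = if (!is.null(sens$presso)) sens$presso$global_pval else NA_real_,
        steiger_direction = sens$steiger_direction,
        steiger_pval = sens$steiger_pval,
        tier = tier(est$pval, alpha),
        notes = if (length(notes) > 0) paste(notes, collapse = "; ") else ""
      )
      details[[key]] <- list(estimate = est, sensitivity = sens)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "details") <- details
  out
}

#' Plot-ready diagnostic tables for one analysis cell
#'
#' Emits the data behind the conventional MR diagnostics as plain tibbles:
#' per-SNP scatter (exposure vs outcome effects with the fitted slopes),
#' funnel (Wald ratio vs its precision), and leave-one-out forest.
#'
#' @param pairs Harmonized, oriented pairs for the cell.
#' @param model IVW model for the fitted slope.
#' @return List of tibbles: `scatter`, `funnel`, `loo` (NULL when k < 3).
#' @export
plot_tables <- function(pairs, model = "mre") {
  .check_pairs(pairs, 1)
  est <- .estimate_cell(pairs)
  eg <- egger(pairs)
  ratio <- pairs$beta_out / pairs$beta_exp
  ratio_se <- pairs$se_out / abs(pairs$beta_exp)
  loo <- leave_one_out(pairs)
  list(
    scatter = tibble::tibble(
      variant_id = pairs$variant_id, beta_exp = pairs$beta_exp,
      se_exp = pairs$se_exp, beta_out = pairs$beta_out,
      se_out = pairs$se_out, slope_ivw = est$beta,
      slope_egger = if (eg$computed) eg$slope$beta else NA_real_,
      intercept_egger = if (eg$computed) eg$intercept else NA_real_
    ),
    funnel = tibble::tibble(
      variant_id = pairs$variant_id, ratio = ratio,
      precision = 1 / ratio_se, pooled = est$beta
    ),
    loo = if (loo$computed) loo$estimates else NULL
  )
}
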