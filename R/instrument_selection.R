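#' Select cis candidate instruments for one drug class
#'
#' A variant is a candidate iff its exposure p-value is below `p_threshold`
#' and it lies on the same chromosome within `window_bp` (inclusive at both
#' edges) of at least one target gene of the class. Target genes missing
#' from the annotation are logged and skipped; a class whose genes are all
#' missing yields an empty set with a warning, not an error.
#'
#' @param exposure Exposure summary-statistic tibble.
#' @param gene_regions Tibble from [read_gene_regions()].
#' @param target_genes Character vector of gene symbols for the class.
#' @param p_threshold Genome-wide significance threshold (default 5e-8).
#' @param window_bp Cis window half-width in bp (default 100000, inclusive).
#' @return Candidate rows of `exposure` with an extra `genes` column
#'   (comma-separated tags of the window(s) hit).
#' @export
select_candidates <- function(exposure, gene_regions, target_genes,
                              p_threshold = 5e-8, window_bp = 100000L) {
  missing <- setdiff(target_genes, gene_regions$gene_symbol)
  if (length(missing) > 0) {
    message(sprintf("no annotation for gene(s): %s; skipped",
                    paste(missing, collapse = ", ")))
  }
  present <- intersect(target_genes, gene_regions$gene_symbol)
  if (length(present) == 0) {
    warning("no target genes present in the annotation; empty candidate set",
            call. = FALSE)
    out <- exposure[0, , drop = FALSE]
    out$genes <- character(0)
    return(out)
  }
  gr <- gene_regions[gene_regions$gene_symbol %in% present, , drop = FALSE]
  sig <- exposure$pval < p_threshold
  hit_genes <- vapply(seq_len(nrow(exposure)), function(i) {
    if (!sig[i]) return(NA_character_)
    inwin <- gr$chrom == exposure$chrom[i] &
      exposure$pos[i] >= gr$start - window_bp &
      exposure$pos[i] <= gr$end + window_bp
    if (!any(inwin)) return(NA_character_)
    paste(gr$gene_symbol[inwin], collapse = ",")
  }, character(1))
  out <- exposure[!is.na(hit_genes), , drop = FALSE]
  out$genes <- hit_genes[!is.na(hit_genes)]
  out
}

#' Greedy LD clumping
#'
#' Sorts candidates by ascending p-value (ties broken by lexicographically
#' smaller variant_id, which makes the result invariant to input row order)
#' and accepts a variant iff its r-squared with every already-accepted
#' variant is below `r2_threshold`. Pairs absent from the LD table count as
#' unlinked. Output is sorted by chromosome and position.
#'
#' @param candidates Candidate tibble (needs variant_id, chrom, pos, pval).
#' @param ld_table Pairwise r-squared tibble, or NULL.
#' @param r2_threshold Acceptance threshold; retained pairs satisfy
#'   r-squared strictly below it (default 0.1).
#' @return The retained rows, position-sorted.
#' @export
clump <- function(candidates, ld_table = NULL, r2_threshold = 0.1) {
  if (nrow(candidates) == 0) return(candidates)
  ord <- order(candidates$pval, candidates$variant_id)
  cand <- candidates[ord, , drop = FALSE]
  keep <- character(0)
  for (i in seq_len(nrow(cand))) {
    id <- cand$variant_id[i]
    if (length(keep) == 0 ||
        all(ld_r2(ld_table, id, keep) < r2_threshold)) {
      keep <- c(keep, id)
    }
  }
  out <- cand[cand$variant_id %in% keep, , drop = FALSE]
  out[order(out$chrom, out$pos, out$variant_id), , drop = FALSE]
}

#' Find an LD proxy for a variant absent from the outcome data
#'
#' Returns the available variant with maximal r-squared to `variant_id`,
#' subject to r-squared strictly greater than `r2_min` (the conventional
#' proxy bound is r-squared > 0.80). Ties break toward the smaller
#' variant_id; `NA` when no variant qualifies.
#'
#' @param variant_id Missing variant.
#' @param available_ids Variants present in the outcome table.
#' @param ld_table Pairwise r-squared tibble.
#' @param r2_min Strict lower bound (default 0.8).
#' @return A single variant id, or `NA_character_`.
#' @export
find_proxy <- function(variant_id, available_ids, ld_table, r2_min = 0.8) {
  available_ids <- setdiff(as.character(available_ids), variant_id)
  if (length(available_ids) == 0) return(NA_character_)
  r2 <- ld_r2(ld_table, variant_id, available_ids)
  ok <- r2 > r2_min
  if (!any(ok)) return(NA_character_)
  best <- max(r2[ok])
  cands <- sort(available_ids[ok & r2 == best])
  cands[1]
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")
.is_palindromic <- function(ea, oa) .complement[ea] == oa

#' Harmonize exposure and outcome effects to a shared effect allele
#'
#' Palindromic variants (A/T or G/C) are dropped unconditionally — their
#' strand cannot be resolved from alleles alone. If the outcome's alleles
#' are swapped relative to the exposure (directly or after strand
#' complementing), the outcome beta is negated; if the alleles are neither
#' identical nor swapped, the pair is dropped. Variants absent from the
#' outcome are substituted by an LD proxy (r-squared > `proxy_r2`) when
#' `proxies = "lookup"`, else dropped. A proxy's outcome effect is used
#' as reported, under a positive-phase assumption (the r-squared-only LD
#' table carries no phase information); palindromic proxies are never used.
#'
#' @param exposure_records Instrument rows of the exposure table.
#' @param outcome Outcome summary-statistic tibble.
#' @param proxies `"none"` or `"lookup"`.
#' @param ld_table LD tibble (required for proxy lookup).
#' @param proxy_r2 Strict proxy threshold (default 0.8).
#' @return Tibble with one row per exposure record: variant_id, proxy_id,
#'   effect_allele, other_allele, beta_exp, se_exp, eaf_exp, beta_out,
#'   se_out, action. Actions: kept_as_is, allele_flipped,
#'   dropped_palindromic, dropped_missing, dropped_mismatch. Dropped rows
#'   carry NA betas.
#' @export
harmonize <- function(exposure_records, outcome, proxies = c("none", "lookup"),
                      ld_table = NULL, proxy_r2 = 0.8) {
  proxies <- match.arg(proxies)
  k <- nrow(exposure_records)
  out <- tibble::tibble(
    variant_id = exposure_records$variant_id,
    proxy_id = NA_character_,
    effect_allele = exposure_records$effect_allele,
    other_allele = exposure_records$other_allele,
    beta_exp = exposure_records$beta, se_exp = exposure_records$se,
    eaf_exp = exposure_records$eaf,
    beta_out = NA_real_, se_out = NA_real_,
    action = NA_character_
  )
  out_pal <- .is_palindromic(outcome$effect_allele, outcome$other_allele)
  for (i in seq_len(k)) {
    ea <- out$effect_allele[i]
    oa <- out$other_allele[i]
    if (.is_palindromic(ea, oa)) {
      out$action[i] <- "dropped_palindromic"
      next
    }
    j <- match(out$variant_id[i], outcome$variant_id)
    via_proxy <- FALSE
    if (is.na(j) && proxies == "lookup" && !is.null(ld_table)) {
      avail <- outcome$variant_id[!out_pal]
      px <- find_proxy(out$variant_id[i], avail, ld_table, r2_min = proxy_r2)
      if (!is.na(px)) {
        j <- match(px, outcome$variant_id)
        out$proxy_id[i] <- px
        via_proxy <- TRUE
      }
    }
    if (is.na(j)) {
      out$action[i] <- "dropped_missing"
      next
    }
    if (via_proxy) {
      # alleles of a different variant cannot be compared; positive phase
      # assumed, effect used as reported
      out$beta_out[i] <- outcome$beta[j]
      out$se_out[i] <- outcome$se[j]
      out$action[i] <- "kept_as_is"
      next
    }
    oea <- outcome$effect_allele[j]
    ooa <- outcome$other_allele[j]
    flip_none <- (oea == ea && ooa == oa) ||
      (.complement[oea] == ea && .complement[ooa] == oa)
    flip_swap <- (oea == oa && ooa == ea) ||
      (.complement[oea] == oa && .complement[ooa] == ea)
    if (flip_none) {
      out$beta_out[i] <- outcome$beta[j]
      out$se_out[i] <- outcome$se[j]
      out$action[i] <- "kept_as_is"
    } else if (flip_swap) {
      out$beta_out[i] <- -outcome$beta[j]
      out$se_out[i] <- outcome$se[j]
      out$action[i] <- "allele_flipped"
    } else {
      out$action[i] <- "dropped_mismatch"
    }
  }
  out
}

#' Keep only harmonized pairs that survived
#'
#' @param pairs Output of [harmonize()].
#' @return Rows with a kept action and non-missing betas.
#' @export
kept_pairs <- function(pairs) {
  pairs[pairs$action %in% c("kept_as_is", "allele_flipped") &
          !is.na(pairs$beta_out), , drop = FALSE]
}

#' Instrument strength: per-SNP F statistics and variance explained
#'
#' Standard summary-statistic approximations with z = beta / se:
#' PVE = z^2 / (z^2 + n) and F = (n - 2) PVE / (1 - PVE). The conventional
#' weak-instrument bound is F > 10; `all_strong` flags whether every SNP
#' clears it.
#'
#' @param records Tibble with beta, se and (unless overridden) n.
#' @param n Sample size(s); defaults to the records' n column.
#' @return List with `per_snp` (tibble: variant_id, z, pve, f),
#'   `total_pve`, `mean_f`, `all_strong`.
#' @export
instrument_strength <- function(records, n = records$n) {
  if (any(is.na(n))) stop("sample size n required for strength metrics", call. = FALSE)
  if (any(n <= 2)) stop("n must exceed 2", call. = FALSE)
  z <- records$beta / records$se
  pve <- z^2 / (z^2 + n)
  f <- (n - 2) * pve / (1 - pve)
  list(
    per_snp = tibble::tibble(variant_id = records$variant_id, z = z,
                             pve = pve, f = f),
    total_pve = sum(pve),
    mean_f = mean(f),
    all_strong = length(f) > 0 && all(f > 10)
  )
}

#' Remove blocklisted variants (local confounder screen)
#'
#' Drops any record whose variant appears in the blocklist (a local
#' stand-in for an external confounder-association screen). A variant
#' listed under several confounders is removed once; every label is logged.
#'
#' @param records Summary-statistic or harmonized tibble with variant_id.
#' @param blocklist Tibble from [read_blocklist()], or NULL.
#' @return The retained rows.
#' @export
apply_blocklist <- function(records, blocklist) {
  if (is.null(blocklist) || nrow(blocklist) == 0) return(records)
  hit <- blocklist[blocklist$variant_id %in% records$variant_id, , drop = FALSE]
  if (nrow(hit) > 0) {
    message(sprintf(
      "blocklist removed %d variant(s): %s",
      length(unique(hit$variant_id)),
      paste(sprintf("%s (%s)", hit$variant_id, hit$confounder), collapse = "; ")
    ))
  }
  records[!(records$variant_id %in% blocklist$variant_id), , drop = FALSE]
}

#' Build per-class instrument sets
#'
#' Runs the full selection chain per drug class: cis candidate filter,
#' greedy LD clumping, and strength metrics. Classes with no candidates are
#' kept with empty record sets so downstream reporting stays complete.
#'
#' @param exposure Exposure summary-statistic tibble.
#' @param gene_regions Gene annotation tibble.
#' @param classes Named list from [read_drug_classes()].
#' @param ld_table LD tibble.
#' @param p_threshold,window_bp,r2_threshold Selection parameters.
#' @return Named list; each element is a list with `class_name`, `records`
#'   (position-sorted instrument rows) and `strength` (or NULL when empty).
#' @export
build_instruments <- function(exposure, gene_regions, classes, ld_table = NULL,
                              p_threshold = 5e-8, window_bp = 100000L,
                              r2_threshold = 0.1) {
  out <- lapply(names(classes), function(cl) {
    cand <- select_candidates(exposure, gene_regions, classes[[cl]],
                              p_threshold = p_threshold, window_bp = window_bp)
    recs <- if (nrow(cand) > 0) clump(cand, ld_table, r2_threshold) else cand
    strength <- if (nrow(recs) > 0 && !all(is.na(recs$n))) {
      instrument_strength(recs)
    } else NULL
    list(class_name = cl, records = recs, strength = strength)
  })
  stats::setNames(out, names(classes))
}
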