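#' Simulation configuration for synthetic summary-statistic pairs
#'
#' The generator emulates a two-sample MR setting on summary statistics: an
#' exposure GWAS whose true per-SNP effects are concentrated inside drug
#' target gene windows, and a downstream binary outcome whose log-odds
#' effects are `true_effect` times the true exposure effects, plus direct
#' (pleiotropic) effects for a configurable fraction of instruments.
#'
#' Effect sizes are calibrated on the noncentrality scale: each causal SNP's
#' true standardized effect z is drawn so that z-squared is uniform on
#' `f_range`, which puts single-SNP F-statistics in the tens — the strength
#' regime typical of cis blood-pressure instruments. Standard errors follow
#' the standard summary-statistic approximation
#' `se = 1 / sqrt(2 n eaf (1 - eaf))`, with effect-allele frequencies uniform
#' on \[0.05, 0.5\]. Linkage disequilibrium is block-diagonal: each gene's
#' SNPs form one positively-phased block with pairwise r-squared
#' `ld_block_r2`, realised as equicorrelated noise (correlation
#' `sqrt(ld_block_r2)`) and proportionally shared true effects.
#'
#' @param n_genes Number of target genes (one LD block each).
#' @param window_bp Half-width of the cis window in bp (default 100000).
#' @param snps_per_gene Causal SNPs placed inside each gene.
#' @param n_null_snps SNPs with zero true effect placed far from all genes.
#' @param n_exp,n_out Exposure / outcome GWAS sample sizes.
#' @param true_effect Causal effect of the exposure on outcome log-odds per
#'   1 unit of exposure (per 1 mmHg when the exposure is SBP).
#' @param pleiotropy_frac Fraction of causal SNPs given direct outcome
#'   effects (exclusion-restriction violations).
#' @param pleiotropy_mean,pleiotropy_sd Normal distribution of the direct
#'   effects, on the outcome log-odds scale.
#' @param ld_block_r2 Pairwise r-squared within a gene's LD block.
#' @param palindrome_frac Fraction of variants given A/T or G/C alleles.
#' @param f_range Range of the per-SNP noncentrality (expected chi-square)
#'   for causal SNPs; default `c(40, 70)`.
#' @param seed Integer seed; all randomness in [simulate_pair()] derives
#'   from it and the global RNG state is restored afterwards.
#' @return A list of class `"sim_config"`.
#' @export
simulation_config <- function(n_genes = 12, window_bp = 100000L,
                              snps_per_gene = 3, n_null_snps = 50,
                              n_exp = 100000, n_out = 100000,
                              true_effect = 0, pleiotropy_frac = 0,
                              pleiotropy_mean = 0, pleiotropy_sd = 0.02,
                              ld_block_r2 = 0.3, palindrome_frac = 0.15,
                              f_range = c(40, 70), seed = 1L) {
  cfg <- list(
    n_genes = n_genes, window_bp = as.integer(window_bp),
    snps_per_gene = snps_per_gene, n_null_snps = n_null_snps,
    n_exp = n_exp, n_out = n_out, true_effect = true_effect,
    pleiotropy_frac = pleiotropy_frac, pleiotropy_mean = pleiotropy_mean,
    pleiotropy_sd = pleiotropy_sd, ld_block_r2 = ld_block_r2,
    palindrome_frac = palindrome_frac, f_range = f_range,
    seed = as.integer(seed)
  )
  counts <- c("n_genes", "snps_per_gene", "n_null_snps")
  if (any(unlist(cfg[counts]) < 0)) stop("counts must be >= 0", call. = FALSE)
  if (cfg$n_exp <= 0 || cfg$n_out <= 0) stop("sample sizes must be > 0", call. = FALSE)
  fracs <- c("pleiotropy_frac", "ld_block_r2", "palindrome_frac")
  if (any(unlist(cfg[fracs]) < 0 | unlist(cfg[fracs]) > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

.draw_alleles <- function(n, palindrome_frac) {
  pal <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"), ncol = 2, byrow = TRUE)
  nonpal <- matrix(c(
    "A", "C", "A", "G", "C", "A", "C", "T",
    "G", "A", "G", "T", "T", "C", "T", "G"
  ), ncol = 2, byrow = TRUE)
  is_pal <- stats::runif(n) < palindrome_frac
  idx_p <- sample.int(nrow(pal), n, replace = TRUE)
  idx_n <- sample.int(nrow(nonpal), n, replace = TRUE)
  ea <- ifelse(is_pal, pal[idx_p, 1], nonpal[idx_n, 1])
  oa <- ifelse(is_pal, pal[idx_p, 2], nonpal[idx_n, 2])
  cbind(ea, oa)
}

# Equicorrelated N(0,1) noise within blocks: corr = rho for distinct SNPs
# sharing a block id, 0 across blocks.
.block_noise <- function(block_id, rho) {
  n <- length(block_id)
  own <- stats::rnorm(n)
  if (rho <= 0) return(own)
  shared <- stats::rnorm(length(unique(block_id)))
  names(shared) <- unique(block_id)
  unname(sqrt(rho) * shared[as.character(block_id)] + sqrt(1 - rho) * own)
}

#' Simulate an exposure/outcome summary-statistic pair with known truth
#'
#' Returns the five artifacts every downstream stage consumes: exposure and
#' outcome summary-statistic tables, gene regions, a pairwise LD table, and
#' a truth table recording each SNP's true effects and instrument validity.
#' Deterministic for a fixed `config$seed`.
#'
#' Genes are laid out on chromosomes 1-22 with 5 Mb spacing so cis windows
#' never overlap; null SNPs sit at least 50 Mb from any gene. Observed betas
#' are true betas plus block-correlated noise scaled by the per-study SE;
#' the exposure and outcome noise draws are independent (non-overlapping
#' GWAS samples).
#'
#' @param config A [simulation_config()].
#' @return List with elements `exposure`, `outcome` (summary-stat tibbles),
#'   `gene_regions`, `ld` (pairwise r-squared tibble), `truth` (tibble with
#'   variant_id, true_exposure_beta, true_direct_outcome_beta,
#'   is_instrument_valid, ld_block_id).
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .simulate_pair_impl(config))
}

.simulate_pair_impl <- function(cfg) {
  gene_len <- 50000L
  gi <- seq_len(cfg$n_genes)
  gene_chrom <- as.character(((gi - 1L) %% 22L) + 1L)
  gene_start <- 1000000L + ((gi - 1L) %/% 22L) * 5000000L
  gene_regions <- tibble::tibble(
    gene_symbol = sprintf("GENE%02d", gi), chrom = gene_chrom,
    start = gene_start, end = gene_start + gene_len
  )

  n_causal <- cfg$n_genes * cfg$snps_per_gene
  n_tot <- n_causal + cfg$n_null_snps
  if (n_tot == 0) {
    empty_ss <- tibble::tibble(
      variant_id = character(), chrom = character(), pos = integer(),
      effect_allele = character(), other_allele = character(),
      eaf = numeric(), beta = numeric(), se = numeric(), pval = numeric(),
      n = numeric()
    )
    return(structure(list(
      exposure = empty_ss, outcome = empty_ss, gene_regions = gene_regions,
      ld = tibble::tibble(id_a = character(), id_b = character(), r2 = numeric()),
      truth = tibble::tibble(
        variant_id = character(), true_exposure_beta = numeric(),
        true_direct_outcome_beta = numeric(), is_instrument_valid = logical(),
        ld_block_id = character()
      )
    ), config = cfg))
  }

  gene_of <- rep(gi, each = cfg$snps_per_gene)
  pos_causal <- if (n_causal > 0) {
    gene_start[gene_of] +
      as.integer(round(stats::runif(n_causal, 0, gene_len)))
  } else integer(0)
  chrom_causal <- gene_chrom[gene_of]

  # Null SNPs live on a far arm of cycling chromosomes, > window from genes.
  ni <- seq_len(cfg$n_null_snps)
  chrom_null <- as.character(((ni - 1L) %% 22L) + 1L)
  pos_null <- 200000000L + ni * 1000000L

  variant_id <- sprintf("rs%06d", seq_len(n_tot))
  chrom <- c(chrom_causal, chrom_null)
  pos <- c(pos_causal, pos_null)
  block <- c(
    if (n_causal > 0) sprintf("block%02d", gene_of) else character(0),
    if (cfg$n_null_snps > 0) sprintf("null%04d", ni) else character(0)
  )
  eaf <- stats::runif(n_tot, 0.05, 0.5)
  alleles <- .draw_alleles(n_tot, cfg$palindrome_frac)

  se_exp <- 1 / sqrt(2 * cfg$n_exp * eaf * (1 - eaf))
  se_out <- 1 / sqrt(2 * cfg$n_out * eaf * (1 - eaf))

  # True exposure effects: noncentrality uniform on f_range; one sign per
  # block and LD-proportional sharing (effect scales with correlation to
  # the block haplotype), so clumped lead SNPs carry full-strength effects.
  true_beta <- numeric(n_tot)
  if (n_causal > 0) {
    lam <- stats::runif(n_causal, cfg$f_range[1], cfg$f_range[2])
    sgn <- sample(c(-1, 1), cfg$n_genes, replace = TRUE)[gene_of]
    true_beta[seq_len(n_causal)] <- sgn * sqrt(lam) * se_exp[seq_len(n_causal)]
  }

  rho <- sqrt(cfg$ld_block_r2)
  beta_exp <- true_beta + .block_noise(block, rho) * se_exp

  direct <- numeric(n_tot)
  if (n_causal > 0 && cfg$pleiotropy_frac > 0) {
    k_pleio <- round(cfg$pleiotropy_frac * n_causal)
    if (k_pleio > 0) {
      idx <- sample(seq_len(n_causal), k_pleio)
      # direct effects act on the exposure-raising allele: directional
      # pleiotropy (mean != 0) must survive the sign orientation MR-Egger
      # applies, so the draw is flipped with the SNP's exposure sign
      direct[idx] <- sign(true_beta[idx]) *
        stats::rnorm(k_pleio, cfg$pleiotropy_mean, cfg$pleiotropy_sd)
    }
  }
  true_out <- cfg$true_effect * true_beta + direct
  beta_out <- true_out + .block_noise(block, rho) * se_out

  mk <- function(beta, se, n) tibble::tibble(
    variant_id = variant_id, chrom = chrom, pos = as.integer(pos),
    effect_allele = alleles[, 1], other_allele = alleles[, 2], eaf = eaf,
    beta = beta, se = se, pval = 2 * stats::pnorm(-abs(beta / se)), n = n
  )

  ld <- NULL
  if (n_causal > 0 && cfg$snps_per_gene >= 2) {
    pairs <- do.call(rbind, lapply(gi, function(g) {
      ids <- variant_id[seq_len(n_causal)][gene_of == g]
      if (length(ids) < 2) return(NULL)
      cmb <- utils::combn(ids, 2)
      data.frame(id_a = cmb[1, ], id_b = cmb[2, ], r2 = cfg$ld_block_r2)
    }))
    ld <- tibble::as_tibble(pairs)
  }
  if (is.null(ld)) {
    ld <- tibble::tibble(id_a = character(), id_b = character(), r2 = numeric())
  }

  structure(list(
    exposure = mk(beta_exp, se_exp, cfg$n_exp),
    outcome = mk(beta_out, se_out, cfg$n_out),
    gene_regions = gene_regions,
    ld = ld,
    truth = tibble::tibble(
      variant_id = variant_id, true_exposure_beta = true_beta,
      true_direct_outcome_beta = direct,
      is_instrument_valid = direct == 0, ld_block_id = block
    )
  ), config = cfg)
}

#' Simulate an additional outcome for an existing exposure GWAS
#'
#' A scan pairs one exposure GWAS with many outcome GWAS. Given a
#' [simulate_pair()] result, this draws a fresh outcome table over the same
#' variants (same positions, alleles and frequencies; new independent
#' block-correlated noise). The causal effect may be uniform
#' (`true_effect`) or target-specific via `gene_effects`, a named vector
#' mapping gene symbols to per-gene causal effects — the drug-target
#' reading in which modulating different targets affects different
#' outcomes. Genes absent from `gene_effects` get effect 0.
#'
#' @param sim A [simulate_pair()] result.
#' @param true_effect Uniform causal effect per unit exposure (ignored when
#'   `gene_effects` is given).
#' @param gene_effects Optional named numeric vector keyed by gene_symbol.
#' @param n_out Outcome GWAS sample size (default: the generating config's).
#' @param seed Integer seed for the outcome noise.
#' @return An outcome summary-statistic tibble over the sim's variants.
#' @export
simulate_outcome <- function(sim, true_effect = 0, gene_effects = NULL,
                             n_out = NULL, seed = 1L) {
  cfg <- attr(sim, "config")
  stopifnot(!is.null(cfg))
  if (is.null(n_out)) n_out <- cfg$n_out
  ex <- sim$exposure
  if (nrow(ex) == 0) return(ex)
  eff <- rep_len(true_effect, nrow(ex))
  if (!is.null(gene_effects)) {
    block_gene <- sprintf("block%02d", match(names(gene_effects),
                                             sim$gene_regions$gene_symbol))
    eff <- unname(ifelse(
      sim$truth$ld_block_id %in% block_gene,
      gene_effects[match(sim$truth$ld_block_id, block_gene)], 0
    ))
  }
  true_out <- eff * sim$truth$true_exposure_beta
  se_out <- 1 / sqrt(2 * n_out * ex$eaf * (1 - ex$eaf))
  beta_out <- withr::with_seed(as.integer(seed), {
    true_out + .block_noise(sim$truth$ld_block_id, sqrt(cfg$ld_block_r2)) * se_out
  })
  tibble::tibble(
    variant_id = ex$variant_id, chrom = ex$chrom, pos = ex$pos,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    eaf = ex$eaf, beta = beta_out, se = se_out,
    pval = 2 * stats::pnorm(-abs(beta_out / se_out)), n = n_out
  )
}

#' Inject pleiotropic outliers into an outcome table
#'
#' Shifts the outcome beta of exactly `k` currently-valid instruments by
#' `magnitude` outcome standard errors (random sign per SNP) and flips their
#' truth flags to invalid. Used to exercise MR-PRESSO outlier recovery
#' against known truth.
#'
#' @param outcome Outcome summary-statistic tibble from [simulate_pair()].
#' @param truth Matching truth tibble.
#' @param k Number of outliers to inject.
#' @param magnitude Shift in multiples of each SNP's outcome SE.
#' @param seed Integer seed.
#' @return List with modified `outcome` and updated `truth`.
#' @export
inject_outliers <- function(outcome, truth, k, magnitude, seed = 1L) {
  valid <- truth$variant_id[truth$is_instrument_valid &
                              truth$true_exposure_beta != 0]
  if (k > length(valid)) {
    stop(sprintf("k = %d exceeds the %d available valid instruments",
                 k, length(valid)), call. = FALSE)
  }
  if (k == 0) return(list(outcome = outcome, truth = truth))
  withr::with_seed(as.integer(seed), {
    chosen <- sample(valid, k)
    sgn <- sample(c(-1, 1), k, replace = TRUE)
  })
  i <- match(chosen, outcome$variant_id)
  outcome$beta[i] <- outcome$beta[i] + sgn * magnitude * outcome$se[i]
  outcome$pval[i] <- 2 * stats::pnorm(-abs(outcome$beta[i] / outcome$se[i]))
  j <- match(chosen, truth$variant_id)
  truth$is_instrument_valid[j] <- FALSE
  truth$true_direct_outcome_beta[j] <- truth$true_direct_outcome_beta[j] +
    sgn * magnitude * outcome$se[i]
  list(outcome = outcome, truth = truth)
}
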