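# Fixture builders shared across the suite. Everything is generated in
# code; seeds are always explicit.

# A minimal harmonized-pairs tibble straight from effect vectors.
make_pairs <- function(beta_exp, beta_out, se_out, se_exp = 0.005,
                       ids = sprintf("rs%03d", seq_along(beta_exp))) {
  tibble::tibble(
    variant_id = ids,
    proxy_id = NA_character_,
    effect_allele = "A", other_allele = "G",
    beta_exp = beta_exp, se_exp = rep_len(se_exp, length(beta_exp)),
    eaf_exp = 0.3,
    beta_out = beta_out, se_out = rep_len(se_out, length(beta_exp)),
    action = "kept_as_is"
  )
}

# Random pairs under a linear model beta_out = b * beta_exp + noise.
random_pairs <- function(k, b = 0.1, seed = 1) {
  withr::with_seed(seed, {
    se_out <- runif(k, 0.005, 0.02)
    beta_exp <- runif(k, 0.02, 0.08) * sample(c(-1, 1), k, TRUE)
    make_pairs(beta_exp, b * beta_exp + rnorm(k, 0, se_out), se_out)
  })
}

# A small exposure-style summary-stat tibble built by hand.
make_sumstats <- function(n = 5, seed = 1) {
  withr::with_seed(seed, {
    eaf <- runif(n, 0.1, 0.5)
    beta <- rnorm(n, 0, 0.03)
    se <- runif(n, 0.004, 0.01)
    tibble::tibble(
      variant_id = sprintf("rs%05d", seq_len(n)),
      chrom = as.character(sample(1:3, n, TRUE)),
      pos = as.integer(sample(1e6, n)),
      effect_allele = sample(c("A", "C"), n, TRUE),
      other_allele = sample(c("G", "T"), n, TRUE),
      eaf = eaf, beta = beta, se = se,
      pval = 2 * pnorm(-abs(beta / se)), n = 50000
    )
  })
}

# Brute-force instrument selection oracle: literal filter + greedy clump,
# written independently of the package's vectorized path.
brute_force_select <- function(exposure, gene_regions, target_genes, ld,
                               p_threshold = 5e-8, window_bp = 100000,
                               r2_threshold = 0.1) {
  keep <- logical(nrow(exposure))
  for (i in seq_len(nrow(exposure))) {
    if (exposure$pval[i] >= p_threshold) next
    for (g in seq_len(nrow(gene_regions))) {
      if (!(gene_regions$gene_symbol[g] %in% target_genes)) next
      if (exposure$chrom[i] != gene_regions$chrom[g]) next
      if (exposure$pos[i] >= gene_regions$start[g] - window_bp &&
          exposure$pos[i] <= gene_regions$end[g] + window_bp) {
        keep[i] <- TRUE
        break
      }
    }
  }
  cand <- exposure[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(character(0))
  cand <- cand[order(cand$pval, cand$variant_id), , drop = FALSE]
  accepted <- character(0)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (a in accepted) {
      hit <- ld[(ld$id_a == cand$variant_id[i] & ld$id_b == a) |
                  (ld$id_b == cand$variant_id[i] & ld$id_a == a), ]
      r2 <- if (nrow(hit) > 0) hit$r2[1] else 0
      if (r2 >= r2_threshold) { ok <- FALSE; break }
    }
    if (ok) accepted <- c(accepted, cand$variant_id[i])
  }
  sort(accepted)
}

# Pull the instrument pairs for one simulated gene-window study: selects
# per a single pseudo-class covering all genes, harmonizes, orients not.
sim_study_pairs <- function(sim, proxies = "none") {
  ins <- build_instruments(
    sim$exposure, sim$gene_regions,
    classes = list(all = sim$gene_regions$gene_symbol),
    ld_table = sim$ld
  )
  kept_pairs(harmonize(ins$all$records, sim$outcome, proxies = proxies,
                       ld_table = sim$ld))
}
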