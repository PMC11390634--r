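#!/usr/bin/env Rscript

# Step 1 — simulate the study's data layer.
#
# One synthetic exposure GWAS (systolic blood pressure) with cis signal in
# twelve drug-target genes, a CAD control outcome in which eleven of the
# twelve targets carry the expected blood-pressure-mediated risk effect
# (the aldosterone-antagonist target does not, so it should fail the
# gate), and 29 pain outcomes of which three carry target-specific causal
# signal: a harmful migraine-without-aura effect through the adrenergic
# neuron blocker target, a protective panniculitis effect through the loop
# diuretic target, and a weaker protective limb-pain effect through the
# vasodilator target. Everything downstream must rediscover this truth.

suppressPackageStartupMessages(library(drugtargetmr))

base_seed <- 20260930L
out_dir <- file.path("results", "synthetic")
dir.create(file.path(out_dir, "outcomes"), recursive = TRUE, showWarnings = FALSE)

classes <- read_drug_classes()
genes_per_class <- 8L   # independent cis signals per class after clumping

cfg <- simulation_config(
  n_genes = length(classes) * genes_per_class, snps_per_gene = 3,
  n_null_snps = 200, n_exp = 100000, n_out = 100000,
  ld_block_r2 = 0.3,   # within-block LD exceeds the clump threshold, so
  palindrome_frac = 0.15,   # each block contributes one lead SNP
  seed = base_seed
)
sim <- simulate_pair(cfg)

# each drug class is proxied by a bank of simulated target-gene windows
class_gene <- data.frame(
  class = rep(names(classes), each = genes_per_class),
  gene = sim$gene_regions$gene_symbol
)
genes_of <- function(cl) class_gene$gene[class_gene$class == cl]

# CAD control: SBP raises coronary risk through every target except the
# aldosterone-antagonist ones (whose instruments should then fail the gate)
cad_effects <- setNames(rep(0.3, nrow(class_gene)), class_gene$gene)
cad_effects[genes_of("psd_aldosterone_antagonists")] <- 0
cad <- simulate_outcome(sim, gene_effects = cad_effects, seed = base_seed + 1L)

# pain panel: three target-specific causal effects, the rest null
panel <- read_outcome_panel()
pain_truth <- list(
  migraine_without_aura = c(-0.5, "adrenergic_neuron_blockers"), # risk per decline
  panniculitis          = c(0.6,  "loop_diuretics"),             # protective
  limb_pain             = c(0.25, "vasodilator_antihypertensives")
)

for (i in seq_along(panel)) {
  oc <- panel[i]
  ge <- NULL
  if (oc %in% names(pain_truth)) {
    eff <- as.numeric(pain_truth[[oc]][1])
    gene <- genes_of(pain_truth[[oc]][2])
    ge <- setNames(rep(eff, length(gene)), gene)
  }
  tbl <- simulate_outcome(sim, gene_effects = ge, seed = base_seed + 10L + i)
  write_sumstats(tbl, file.path(out_dir, "outcomes", paste0(oc, ".tsv")))
}

write_sumstats(sim$exposure, file.path(out_dir, "exposure_sbp.tsv"))
write_sumstats(cad, file.path(out_dir, "control_cad.tsv"))
write.table(sim$gene_regions[, c("chrom", "start", "end", "gene_symbol")],
            file.path(out_dir, "gene_regions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$ld, file.path(out_dir, "ld_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$truth, file.path(out_dir, "truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(class_gene, file.path(out_dir, "class_gene_map.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(
  "simulated %d variants (%d causal in %d gene windows, %d null), %d outcomes\n",
  nrow(sim$exposure), sum(sim$truth$true_exposure_beta != 0),
  nrow(sim$gene_regions), sum(sim$truth$true_exposure_beta == 0),
  length(panel) + 1L
))
cat(sprintf("true pain signals: %s\n",
            paste(names(pain_truth), collapse = ", ")))
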