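test_that("cis window is inclusive at exactly +/-100 kb", {
  genes <- tibble::tibble(gene_symbol = "G1", chrom = "1",
                          start = 1000000L, end = 1050000L)
  snp <- function(pos, pval, id) tibble::tibble(
    variant_id = id, chrom = "1", pos = as.integer(pos),
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = 0.03, se = 0.005, pval = pval, n = 1e5
  )
  exposure <- rbind(
    snp(1000000 - 100000, 1e-9, "rs_edge_in"),
    snp(1000000 - 100001, 1e-300, "rs_edge_out"),
    snp(1050000 + 100000, 1e-9, "rs_edge_in_right"),
    snp(1050000 + 100001, 1e-300, "rs_edge_out_right")
  )
  got <- select_candidates(exposure, genes, "G1")
  expect_setequal(got$variant_id, c("rs_edge_in", "rs_edge_in_right"))
})

test_that("candidate filter matches a hand-enumerated 10-SNP case", {
  genes <- tibble::tibble(gene_symbol = "G1", chrom = "1",
                          start = 5000000L, end = 5100000L)
  inside <- function(i, p) tibble::tibble(
    variant_id = sprintf("in%d", i), chrom = "1",
    pos = 5000000L + i * 1000L, effect_allele = "A", other_allele = "G",
    eaf = 0.3, beta = 0.03, se = 0.005, pval = p, n = 1e5
  )
  outside <- function(i) tibble::tibble(
    variant_id = sprintf("out%d", i), chrom = "2",
    pos = 5000000L, effect_allele = "A", other_allele = "G",
    eaf = 0.3, beta = 0.03, se = 0.005, pval = 1e-300, n = 1e5
  )
  exposure <- rbind(
    inside(1, 1e-9), inside(2, 1e-10), inside(3, 4.9e-8),
    inside(4, 1e-6), inside(5, 1e-6),
    do.call(rbind, lapply(6:10, outside))
  )
  got <- select_candidates(exposure, genes, "G1")
  expect_setequal(got$variant_id, c("in1", "in2", "in3"))
})

test_that("missing gene annotation degrades gracefully", {
  genes <- tibble::tibble(gene_symbol = "G1", chrom = "1",
                          start = 1L, end = 10L)
  exposure <- make_sumstats(3)
  expect_message(select_candidates(exposure, genes, c("G1", "GX")), "GX")
  expect_warning(out <- select_candidates(exposure, genes, "GZ"),
                 "no target genes")
  expect_equal(nrow(out), 0)
})

test_that("greedy clumping follows p-value order with the stated tie-break", {
  cand <- tibble::tibble(
    variant_id = c("rsA", "rsB", "rsC"), chrom = "1",
    pos = c(100L, 200L, 300L), effect_allele = "A", other_allele = "G",
    eaf = 0.3, beta = 0.03, se = 0.005,
    pval = c(1e-10, 1e-9, 1e-8), n = 1e5
  )
  ld <- tibble::tibble(id_a = c("rsA", "rsA", "rsB"),
                       id_b = c("rsB", "rsC", "rsC"),
                       r2 = c(0.5, 0.05, 0.02))
  expect_equal(clump(cand, ld)$variant_id, c("rsA", "rsC"))

  # no LD -> everything retained, sorted by position
  expect_equal(clump(cand[c(3, 1, 2), ], NULL)$variant_id,
               c("rsA", "rsB", "rsC"))

  # identical p-values in LD: lexicographically smaller id wins
  tie <- cand
  tie$pval <- 1e-9
  ld2 <- tibble::tibble(id_a = "rsA", id_b = "rsB", r2 = 0.9)
  expect_setequal(clump(tie, ld2)$variant_id, c("rsA", "rsC"))
})

test_that("clumping is invariant to input row order on random fixtures", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      n <- 15
      cand <- make_sumstats(n, seed = seed)
      cand$pval <- 10^runif(n, -12, -8)
      ids <- cand$variant_id
      pairs <- t(combn(ids, 2))
      pick <- runif(nrow(pairs)) < 0.2
      ld <- tibble::tibble(id_a = pairs[pick, 1], id_b = pairs[pick, 2],
                           r2 = runif(sum(pick)))
      a <- clump(cand, ld)
      b <- clump(cand[sample(n), ], ld)
      expect_equal(a$variant_id, b$variant_id)
    })
  }
})

test_that("proxy search takes the strict argmax with deterministic ties", {
  ld <- tibble::tibble(
    id_a = c("rsX", "rsX", "rsX", "rsX"),
    id_b = c("rsP1", "rsP2", "rsP3", "rsP4"),
    r2 = c(0.95, 0.85, 0.80, 0.95)
  )
  avail <- c("rsP1", "rsP2", "rsP3", "rsP4")
  expect_equal(find_proxy("rsX", c("rsP1", "rsP2"), ld), "rsP1")
  expect_equal(find_proxy("rsX", "rsP3", ld), NA_character_)  # 0.80 is strict
  expect_equal(find_proxy("rsX", avail, ld), "rsP1")           # tie at 0.95
  expect_equal(find_proxy("rsY", avail, ld), NA_character_)
})

test_that("harmonization covers the four allele configurations and drops the rest", {
  exp1 <- tibble::tibble(
    variant_id = sprintf("rs%d", 1:6), chrom = "1", pos = 1:6,
    effect_allele = c("A", "A", "A", "A", "A", "A"),
    other_allele = c("G", "G", "G", "G", "T", "G"),
    eaf = 0.3, beta = 0.03, se = 0.005, pval = 1e-9, n = 1e5
  )
  outc <- tibble::tibble(
    variant_id = sprintf("rs%d", 1:5), chrom = "1", pos = 1:5,
    effect_allele = c("A", "G", "T", "C", "A"),
    other_allele = c("G", "A", "C", "T", "T"),
    eaf = 0.3, beta = 0.12, se = 0.01, pval = 0.5, n = 2e5
  )
  h <- harmonize(exp1, outc)
  expect_equal(h$action, c("kept_as_is", "allele_flipped", "kept_as_is",
                           "allele_flipped", "dropped_palindromic",
                           "dropped_missing"))
  expect_equal(h$beta_out, c(0.12, -0.12, 0.12, -0.12, NA, NA))

  # the complement-swap configuration is resolvable, a true mismatch is not
  outc_cswap <- outc[1, ]
  outc_cswap$effect_allele <- "C"   # complement of C/T is G/A = swapped A/G
  outc_cswap$other_allele <- "T"
  expect_equal(harmonize(exp1[1, ], outc_cswap)$action, "allele_flipped")
  outc2 <- outc[1, ]
  outc2$effect_allele <- "A"
  outc2$other_allele <- "C"
  expect_equal(harmonize(exp1[1, ], outc2)$action, "dropped_mismatch")

  # re-harmonizing a harmonized set is the identity
  k <- kept_pairs(h)
  exp_back <- tibble::tibble(
    variant_id = k$variant_id, chrom = "1", pos = seq_along(k$variant_id),
    effect_allele = k$effect_allele, other_allele = k$other_allele,
    eaf = k$eaf_exp, beta = k$beta_exp, se = k$se_exp, pval = 1e-9, n = 1e5
  )
  out_back <- tibble::tibble(
    variant_id = k$variant_id, chrom = "1", pos = seq_along(k$variant_id),
    effect_allele = k$effect_allele, other_allele = k$other_allele,
    eaf = 0.3, beta = k$beta_out, se = k$se_out, pval = 0.5, n = 2e5
  )
  again <- kept_pairs(harmonize(exp_back, out_back))
  expect_equal(again$beta_out, k$beta_out)
  expect_equal(again$beta_exp, k$beta_exp)
  expect_true(all(again$action == "kept_as_is"))
})

test_that("proxy policy substitutes high-LD variants and skips palindromic proxies", {
  exp1 <- tibble::tibble(
    variant_id = "rsMISS", chrom = "1", pos = 100L,
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = 0.03, se = 0.005, pval = 1e-9, n = 1e5
  )
  outc <- tibble::tibble(
    variant_id = c("rsPROX", "rsPAL"), chrom = "1", pos = c(120L, 130L),
    effect_allele = c("C", "A"), other_allele = c("T", "T"),
    eaf = 0.3, beta = c(0.07, 0.2), se = 0.01, pval = 0.5, n = 2e5
  )
  ld <- tibble::tibble(id_a = c("rsMISS", "rsMISS"),
                       id_b = c("rsPROX", "rsPAL"), r2 = c(0.9, 0.99))
  expect_equal(harmonize(exp1, outc)$action, "dropped_missing")
  h <- harmonize(exp1, outc, proxies = "lookup", ld_table = ld)
  expect_equal(h$proxy_id, "rsPROX")  # rsPAL is palindromic despite higher r2
  expect_equal(h$beta_out, 0.07)
})

test_that("F and PVE follow the summary-statistic formulas and flag weak sets", {
  recs <- tibble::tibble(variant_id = "rs1", beta = 0.03, se = 0.005, n = 1e5)
  s <- instrument_strength(recs)
  expect_equal(s$per_snp$z, 6)
  expect_equal(s$per_snp$pve, 36 / 100036, tolerance = 1e-12)
  expect_equal(s$per_snp$f, (1e5 - 2) * (36 / 100036) / (1 - 36 / 100036),
               tolerance = 1e-12)
  expect_equal(s$per_snp$f, 36.0, tolerance = 1e-3)
  expect_true(s$all_strong)

  z0 <- instrument_strength(tibble::tibble(variant_id = "rs1", beta = 0,
                                           se = 0.01, n = 1e5))
  expect_equal(z0$per_snp$pve, 0)
  expect_equal(z0$per_snp$f, 0)
  expect_false(z0$all_strong)

  # z^2 = n puts PVE at exactly 1/2 and F near n - 2
  n <- 400
  zn <- instrument_strength(tibble::tibble(variant_id = "rs1",
                                           beta = sqrt(n) * 0.01, se = 0.01,
                                           n = n))
  expect_equal(zn$per_snp$pve, 0.5)
  expect_equal(zn$per_snp$f, n - 2)

  # monotone in |z| at fixed n
  zs <- seq(0.5, 10, by = 0.5)
  st <- instrument_strength(tibble::tibble(variant_id = as.character(zs),
                                           beta = zs * 0.01, se = 0.01,
                                           n = 5e4))
  expect_true(all(diff(st$per_snp$pve) > 0))
  expect_true(all(diff(st$per_snp$f) > 0))

  expect_error(instrument_strength(tibble::tibble(variant_id = "r", beta = 1,
                                                  se = 1, n = 2)), "n must")
})

test_that("blocklist removes listed variants once and keeps the rest", {
  recs <- make_sumstats(12, seed = 8)
  expect_identical(apply_blocklist(recs, NULL), recs)
  bl <- tibble::tibble(variant_id = c(recs$variant_id[2], recs$variant_id[5],
                                      recs$variant_id[5]),
                       confounder = c("insomnia", "obesity", "smoking"))
  expect_message(out <- apply_blocklist(recs, bl), "insomnia")
  expect_equal(nrow(out), 10)
  expect_false(any(bl$variant_id %in% out$variant_id))
})

test_that("selection plus clumping matches the brute-force oracle on random fixtures", {
  for (seed in 1:12) {
    withr::with_seed(seed, {
      genes <- tibble::tibble(
        gene_symbol = c("G1", "G2"), chrom = c("1", "2"),
        start = c(1000000L, 2000000L), end = c(1050000L, 2080000L)
      )
      n <- 40
      exposure <- tibble::tibble(
        variant_id = sprintf("rs%03d", sample(999, n)),
        chrom = as.character(sample(1:3, n, TRUE)),
        pos = as.integer(sample(seq(900000, 2300000, by = 1000), n)),
        effect_allele = "A", other_allele = "G", eaf = 0.3,
        beta = 0.03, se = 0.005,
        pval = 10^runif(n, -12, -5), n = 1e5
      )
      pairs <- t(combn(exposure$variant_id, 2))
      pick <- runif(nrow(pairs)) < 0.1
      ld <- tibble::tibble(id_a = pairs[pick, 1], id_b = pairs[pick, 2],
                           r2 = runif(sum(pick)))
      got <- clump(select_candidates(exposure, genes, c("G1", "G2")), ld)
      want <- brute_force_select(exposure, genes, c("G1", "G2"), ld)
      expect_equal(sort(got$variant_id), want)
    })
  }
})
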