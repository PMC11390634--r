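#' Column-map presets for GWAS summary-statistic dialects
#'
#' A column map is a named character vector whose names are the canonical
#' field names used throughout the package and whose values are the column
#' headers found on disk. Two presets ship with the package: `"canonical"`
#' (the package's own output dialect) and `"finngen"` (the
#' rsids/ref/alt/af_alt/beta/sebeta header style used by FinnGen release
#' files).
#'
#' @param preset `"canonical"` or `"finngen"`.
#' @return Named character vector mapping canonical field -> on-disk column.
#' @export
sumstats_columns <- function(preset = c("canonical", "finngen")) {
  preset <- match.arg(preset)
  switch(preset,
    canonical = c(
      variant_id = "variant_id", chrom = "chrom", pos = "pos",
      effect_allele = "effect_allele", other_allele = "other_allele",
      eaf = "eaf", beta = "beta", se = "se", pval = "pval", n = "n"
    ),
    finngen = c(
      variant_id = "rsids", chrom = "#chrom", pos = "pos",
      effect_allele = "alt", other_allele = "ref",
      eaf = "af_alt", beta = "beta", se = "sebeta", pval = "pval", n = "n"
    )
  )
}

.sumstats_required <- c(
  "variant_id", "chrom", "pos", "effect_allele", "other_allele",
  "beta", "se", "pval"
)
.sumstats_fields <- c(.sumstats_required, "eaf", "n")

#' Validate a summary-statistic table
#'
#' Enforces the per-record invariants: alleles are single A/C/G/T bases and
#' differ, `se > 0`, `pval` in (0, 1], `pos >= 1`, and `eaf` (when present)
#' strictly inside (0, 1). `eaf` and `n` may be `NA` — outcome files often
#' lack frequencies — and operations that need them fail per-record at the
#' point of use.
#'
#' @param x A data frame with canonical columns.
#' @param context Label used in error messages (typically the file path).
#' @return `x` invisibly, with alleles upper-cased.
#' @export
validate_sumstats <- function(x, context = "sumstats") {
  missing_cols <- setdiff(.sumstats_required, names(x))
  if (length(missing_cols) > 0) {
    stop(sprintf(
      "%s: missing required column(s): %s", context,
      paste(missing_cols, collapse = ", ")
    ), call. = FALSE)
  }
  if (!("eaf" %in% names(x))) x$eaf <- NA_real_
  if (!("n" %in% names(x))) x$n <- NA_real_
  x$effect_allele <- toupper(x$effect_allele)
  x$other_allele <- toupper(x$other_allele)
  x$chrom <- as.character(x$chrom)

  fail_rows <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      rows <- which(bad)
      stop(sprintf(
        "%s: %s at row(s) %s", context, what,
        paste(utils::head(rows, 5), collapse = ", ")
      ), call. = FALSE)
    }
  }
  for (col in c("pos", "beta", "se", "pval")) {
    fail_rows(!is.finite(x[[col]]), sprintf("non-numeric or missing '%s'", col))
  }
  ok_allele <- function(a) a %in% c("A", "C", "G", "T")
  fail_rows(!ok_allele(x$effect_allele) | !ok_allele(x$other_allele),
            "allele not a single A/C/G/T base")
  fail_rows(x$effect_allele == x$other_allele, "effect_allele == other_allele")
  fail_rows(x$se <= 0, "se <= 0")
  fail_rows(x$pval <= 0 | x$pval > 1, "pval outside (0, 1]")
  fail_rows(x$pos < 1, "pos < 1")
  fail_rows(!is.na(x$eaf) & (x$eaf <= 0 | x$eaf >= 1), "eaf outside (0, 1)")
  fail_rows(!is.na(x$n) & x$n <= 0, "n <= 0")
  invisible(x)
}

#' Read GWAS summary statistics
#'
#' Reads a TSV (optionally gzip-compressed) of per-variant association
#' statistics, renames columns to the canonical schema via `column_map`,
#' validates every record, and returns a tibble in file order. Unknown extra
#' columns are dropped with a message on standard error.
#'
#' @param path File path (TSV, `.gz` allowed).
#' @param column_map Named character vector as from [sumstats_columns()].
#' @return Tibble with columns variant_id, chrom, pos, effect_allele,
#'   other_allele, eaf, beta, se, pval, n.
#' @export
read_sumstats <- function(path, column_map = sumstats_columns("canonical")) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "")
  need <- intersect(.sumstats_fields, names(column_map))
  miss <- setdiff(column_map[need], names(raw))
  if (length(miss) > 0) {
    stop(sprintf("%s: column(s) named in column_map not present in file: %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(raw), column_map[need])
  if (length(extra) > 0) {
    message(sprintf("%s: ignoring %d extra column(s): %s", path, length(extra),
                    paste(extra, collapse = ", ")))
  }
  out <- raw[, column_map[need], drop = FALSE]
  names(out) <- need
  out <- validate_sumstats(out, context = path)
  out <- out[, intersect(.sumstats_fields, names(out)), drop = FALSE]
  message(sprintf("%s: %d records read", path, nrow(out)))
  tibble::as_tibble(out)
}

#' Write summary statistics in the canonical dialect
#'
#' @param x Validated summary-statistic tibble.
#' @param path Output TSV path.
#' @param column_map Optional map to write a non-canonical dialect; the
#'   file's headers are the map's values.
#' @export
write_sumstats <- function(x, path, column_map = sumstats_columns("canonical")) {
  x <- as.data.frame(validate_sumstats(x, context = "write_sumstats"))
  need <- intersect(.sumstats_fields, names(column_map))
  out <- x[, need, drop = FALSE]
  names(out) <- column_map[need]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene regions (BED or 1-based TSV)
#'
#' In-memory coordinates are always 1-based inclusive; BED input (0-based,
#' half-open) is converted on read. The 4 columns are chrom, start, end,
#' gene_symbol in both dialects.
#'
#' @param path File path.
#' @param dialect `"bed"` (0-based half-open) or `"tsv"` (1-based inclusive).
#' @return Tibble with columns gene_symbol, chrom, start, end.
#' @export
read_gene_regions <- function(path, dialect = c("bed", "tsv")) {
  dialect <- match.arg(dialect)
  raw <- utils::read.table(path, header = (dialect == "tsv"), sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "gene_symbol"))
  if (dialect == "bed") raw$start <- raw$start + 1L
  bad <- raw$start > raw$end
  if (any(bad)) {
    stop(sprintf("gene region start > end for: %s",
                 paste(raw$gene_symbol[bad], collapse = ", ")), call. = FALSE)
  }
  dup <- unique(raw$gene_symbol[duplicated(raw$gene_symbol)])
  if (length(dup) > 0) {
    stop(sprintf("duplicate gene_symbol: %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  tibble::tibble(
    gene_symbol = raw$gene_symbol, chrom = as.character(raw$chrom),
    start = as.integer(raw$start), end = as.integer(raw$end)
  )
}

#' Read a pairwise LD table
#'
#' Three tab-separated columns: id_a, id_b, r2. The table is stored
#' unordered; lookups via [ld_r2()] are symmetric and unknown pairs count as
#' r-squared 0 (reference-panel sparsity).
#'
#' @param path File path.
#' @return Tibble with columns id_a, id_b, r2.
#' @export
read_ld_table <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("id_a", "id_b", "r2"))
  if (any(raw$r2 < 0 | raw$r2 > 1)) stop("r2 outside [0, 1]", call. = FALSE)
  tibble::tibble(id_a = as.character(raw$id_a), id_b = as.character(raw$id_b),
                 r2 = raw$r2)
}

#' Symmetric LD lookup
#'
#' @param ld_table Tibble from [read_ld_table()] (or built in memory).
#' @param a,b Variant ids (vectors recycle).
#' @return r-squared values; 0 for pairs absent from the table, 1 for `a == b`.
#' @export
ld_r2 <- function(ld_table, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- ifelse(a == b, 1, 0)
  if (!is.null(ld_table) && nrow(ld_table) > 0) {
    key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\r")
    tab <- stats::setNames(ld_table$r2, key(ld_table$id_a, ld_table$id_b))
    hit <- tab[key(a, b)]
    out <- ifelse(a != b & !is.na(hit), hit, out)
  }
  unname(out)
}

#' Read a confounder blocklist
#'
#' Two tab-separated columns: variant_id, confounder. A variant may appear
#' under several confounders; it is removed once and all labels are logged.
#'
#' @param path File path.
#' @return Tibble with columns variant_id, confounder.
#' @export
read_blocklist <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("variant_id", "confounder"))
  tibble::tibble(variant_id = as.character(raw$variant_id),
                 confounder = as.character(raw$confounder))
}

#' Read the drug-class -> target-gene map
#'
#' YAML with one key per drug class and a list of target gene symbols as the
#' value. Class names must be unique and every gene list non-empty.
#'
#' @param path YAML path; defaults to the curated map shipped with the
#'   package (twelve antihypertensive classes, British National Formulary
#'   grouping, standard pharmacological targets).
#' @return Named list of character vectors.
#' @export
read_drug_classes <- function(path = system.file("extdata", "drug_classes.yaml",
                                                 package = "drugtargetmr")) {
  classes <- yaml::read_yaml(path)
  if (anyDuplicated(names(classes))) {
    stop("duplicate drug class names in config", call. = FALSE)
  }
  empty <- names(classes)[vapply(classes, length, 1L) == 0]
  if (length(empty) > 0) {
    stop(sprintf("drug class with no target genes: %s",
                 paste(empty, collapse = ", ")), call. = FALSE)
  }
  lapply(classes, as.character)
}

#' Read the outcome-panel list
#'
#' @param path YAML path; defaults to the 29 FinnGen-style pain endpoint
#'   names shipped with the package. Names are opaque labels.
#' @return Character vector of outcome names.
#' @export
read_outcome_panel <- function(path = system.file("extdata", "outcome_panel.yaml",
                                                  package = "drugtargetmr")) {
  as.character(unlist(yaml::read_yaml(path)))
}

.results_columns <- c(
  "class", "outcome", "method", "n_snp", "beta", "se", "or", "ci_low",
  "ci_high", "pval", "q_pval", "egger_intercept_pval", "presso_global_pval",
  "steiger_direction", "steiger_pval", "tier"
)

#' Write scan results
#'
#' Stable 16-column TSV; numeric fields keep full double precision so a
#' round-trip through [read_results()] reproduces values to better than
#' 1e-10 relative.
#'
#' @param results Tibble as returned by [run_scan()] (extra columns are
#'   dropped; missing sensitivity fields are written as NA).
#' @param path Output TSV path.
#' @export
write_results <- function(results, path) {
  out <- as.data.frame(results)
  for (col in setdiff(.results_columns, names(out))) out[[col]] <- NA
  out <- out[, .results_columns, drop = FALSE]
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(v) {
    ifelse(is.na(v), NA, sprintf("%.15g", v))
  })
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read scan results written by [write_results()]
#'
#' @param path TSV path.
#' @return Tibble with the 16 canonical result columns.
#' @export
read_results <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = "NA")
  if (!identical(names(raw), .results_columns)) {
    stop(sprintf("unexpected results columns in %s", path), call. = FALSE)
  }
  raw$steiger_direction <- as.logical(raw$steiger_direction)
  tibble::as_tibble(raw)
}
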