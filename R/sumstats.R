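# Reading, validating, harmonizing and writing GWAS/QTL summary statistics.
#
# A summary_stats object is a light S3 container: a data.frame of per-variant
# records plus trait/stratum labels. Every downstream stage consumes only
# (beta, se, p, n) plus identifiers, so this is the universal currency of the
# package.

SUMSTATS_FIELDS <- c("variant_id", "chrom", "pos", "effect_allele",
                     "other_allele", "eaf", "beta", "se", "p", "n")
MANDATORY_FIELDS <- setdiff(SUMSTATS_FIELDS, "eaf")

#' Construct a summary statistics object
#'
#' @param records data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf` (may be `NA`), `beta`, `se`,
#'   `p`, `n`.
#' @param trait_label character label for the trait.
#' @param sex_stratum one of `"female"`, `"male"`, `"combined"`.
#' @param build_label genome build label (opaque; variant IDs are the join key).
#' @param validate check invariants (unique IDs, se > 0, p in (0,1])?
#' @return An object of class `summary_stats`.
#' @export
summary_stats <- function(records, trait_label, sex_stratum = "combined",
                          build_label = NA_character_, validate = TRUE) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(SUMSTATS_FIELDS, names(records))
  if (length(missing_cols))
    stopf("records are missing column(s): %s", paste(missing_cols, collapse = ", "))
  sex_stratum <- match.arg(sex_stratum, c("female", "male", "combined"))
  records <- records[order(records$chrom, records$pos), SUMSTATS_FIELDS,
                     drop = FALSE]
  rownames(records) <- NULL
  if (validate) {
    dup <- records$variant_id[duplicated(records$variant_id)]
    if (length(dup))
      stopf("duplicate variant_id(s): %s", paste(unique(dup), collapse = ", "))
    if (any(records$se <= 0)) stopf("nonpositive SE in records")
    if (any(records$p <= 0 | records$p > 1)) stopf("p outside (0,1] in records")
    if (any(records$effect_allele == records$other_allele))
      stopf("effect_allele equals other_allele for some records")
  }
  structure(list(records = records, trait_label = trait_label,
                 sex_stratum = sex_stratum, build_label = build_label),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("summary_stats: %s (%s), %d variants\n",
              x$trait_label, x$sex_stratum, nrow(x$records)))
  print(head(x$records, 5))
  invisible(x)
}

#' Number of variant records
#' @param x summary_stats object
#' @export
n_variants <- function(x) nrow(x$records)

default_column_map <- function() {
  list(variant_id = c("variant_id", "SNP", "rsid", "ID", "MarkerName"),
       chrom = c("chrom", "CHR", "chromosome", "#CHROM"),
       pos = c("pos", "BP", "position", "POS"),
       effect_allele = c("effect_allele", "A1", "EA", "ALT"),
       other_allele = c("other_allele", "A2", "OA", "NEA", "REF"),
       eaf = c("eaf", "EAF", "FRQ", "af", "MAF"),
       beta = c("beta", "BETA", "b", "Effect"),
       se = c("se", "SE", "StdErr"),
       p = c("p", "P", "PVAL", "p_value", "pval"),
       n = c("n", "N", "n_total", "TotalSampleSize"))
}

#' Read GWAS/QTL summary statistics from delimited text
#'
#' Reads a tab- or whitespace-delimited file with a header row, maps columns
#' to the canonical schema, enforces record invariants (dropping offending
#' rows with a per-reason tally), and returns a validated [summary_stats()].
#' Alleles are upper-cased on read. A YAML column map (field -> column name)
#' may override the built-in synonym list.
#'
#' @param path file path.
#' @param column_map named list mapping canonical field names to the file's
#'   column names, or a path to a YAML file with such a mapping. `NULL` uses
#'   common synonyms (SNP/CHR/BP/A1/A2/FRQ/BETA/SE/P/N etc.).
#' @param trait_label,sex_stratum,build_label passed to [summary_stats()].
#' @param verbose emit a load report to the log?
#' @return A `summary_stats` object.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_label = basename(path),
                          sex_stratum = "combined", build_label = NA_character_,
                          verbose = TRUE) {
  if (is.character(column_map) && length(column_map) == 1L && file.exists(column_map))
    column_map <- yaml::read_yaml(column_map)
  raw <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           showProgress = FALSE)
  cmap <- default_column_map()
  if (!is.null(column_map)) for (f in names(column_map)) cmap[[f]] <- column_map[[f]]
  out <- list()
  for (f in SUMSTATS_FIELDS) {
    hit <- intersect(cmap[[f]], names(raw))
    if (!length(hit)) {
      if (f == "eaf") { out[[f]] <- NA_real_; next }
      stopf("mandatory column '%s' not found in %s (tried: %s)", f, path,
            paste(cmap[[f]], collapse = ", "))
    }
    out[[f]] <- raw[[hit[1]]]
  }
  rec <- as.data.frame(out, stringsAsFactors = FALSE)
  rec$chrom <- as.character(rec$chrom)
  rec$pos <- as.integer(rec$pos)
  rec$effect_allele <- toupper(as.character(rec$effect_allele))
  rec$other_allele <- toupper(as.character(rec$other_allele))
  for (f in c("eaf", "beta", "se", "p")) rec[[f]] <- as.numeric(rec[[f]])
  rec$n <- as.numeric(rec$n)

  drop_reasons <- c(
    "nonpositive SE"        = "se",
    "p outside (0,1]"       = "p",
    "identical alleles"     = "alleles",
    "nonpositive position"  = "pos",
    "nonpositive N"         = "nn",
    "missing mandatory field" = "na")
  bad <- list(
    se  = !is.na(rec$se) & rec$se <= 0,
    p   = !is.na(rec$p) & (rec$p <= 0 | rec$p > 1),
    alleles = rec$effect_allele == rec$other_allele,
    pos = !is.na(rec$pos) & rec$pos < 1,
    nn  = !is.na(rec$n) & rec$n <= 0,
    na  = !complete.cases(rec[MANDATORY_FIELDS]))
  dropped <- rep(FALSE, nrow(rec))
  tally <- integer(0)
  for (reason in names(drop_reasons)) {
    hit <- bad[[drop_reasons[[reason]]]] & !dropped
    if (any(hit)) tally[reason] <- sum(hit)
    dropped <- dropped | bad[[drop_reasons[[reason]]]]
  }
  kept <- rec[!dropped, , drop = FALSE]
  if (!nrow(kept)) stopf("no valid rows in %s after filtering", path)
  dup <- kept$variant_id[duplicated(kept$variant_id)]
  if (length(dup))
    stopf("duplicate variant_id(s) in %s: %s", path,
          paste(unique(dup), collapse = ", "))
  pl_log(sprintf("read %s: kept %d, dropped %d (%s)", path, nrow(kept),
                 sum(dropped),
                 if (length(tally)) paste(names(tally), tally, sep = "=",
                                          collapse = ", ") else "none"),
         verbose = verbose)
  out_eaf_bad <- !is.na(kept$eaf) & (kept$eaf <= 0 | kept$eaf >= 1)
  kept$eaf[out_eaf_bad] <- NA_real_
  summary_stats(kept, trait_label = trait_label, sex_stratum = sex_stratum,
                build_label = build_label)
}

#' Write summary statistics as TSV
#'
#' @param stats summary_stats object.
#' @param path output path.
#' @param header_lines optional character vector of `#`-prefixed header lines.
#' @export
write_sumstats <- function(stats, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  writeLines(paste(SUMSTATS_FIELDS, collapse = "\t"), con)
  rec <- stats$records
  lines <- do.call(paste, c(lapply(SUMSTATS_FIELDS, function(f) {
    v <- rec[[f]]
    if (is.numeric(v)) format(v, digits = 17, trim = TRUE, scientific = NA) else v
  }), sep = "\t"))
  writeLines(lines, con)
  invisible(path)
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(a) {
  # indels / multi-base alleles pass through un-complemented (never flipped)
  single <- nchar(a) == 1L & a %in% names(DNA_COMPLEMENT)
  a[single] <- DNA_COMPLEMENT[a[single]]
  a
}

#' Align variant records to reference alleles
#'
#' Re-expresses each record so its effect allele equals `ref_effect`. If the
#' record's alleles match the reference only after strand complement, the
#' complement is applied first; if effect/other are swapped relative to the
#' reference, `beta` is negated and `eaf` replaced by `1 - eaf`. The operation
#' is an involution: aligning an aligned record is the identity.
#'
#' @param record data.frame of variant records (vectorized).
#' @param ref_effect,ref_other reference alleles (scalar or per-record).
#' @return The aligned records.
#' @export
align_to_reference <- function(record, ref_effect, ref_other) {
  stopifnot(is.data.frame(record))
  k <- nrow(record)
  ref_effect <- toupper(rep_len(ref_effect, k))
  ref_other <- toupper(rep_len(ref_other, k))
  ea <- toupper(record$effect_allele)
  oa <- toupper(record$other_allele)

  direct_same <- ea == ref_effect & oa == ref_other
  direct_swap <- ea == ref_other & oa == ref_effect
  # strand-complement matching applied before swap detection
  ce <- complement_allele(ea)
  co <- complement_allele(oa)
  flip_same <- !direct_same & !direct_swap & ce == ref_effect & co == ref_other
  flip_swap <- !direct_same & !direct_swap & ce == ref_other & co == ref_effect

  bad <- !(direct_same | direct_swap | flip_same | flip_swap)
  if (any(bad)) {
    i <- which(bad)[1]
    stopf("allele mismatch for %s: record (%s/%s) vs reference (%s/%s)",
          record$variant_id[i] %||% i, ea[i], oa[i], ref_effect[i], ref_other[i])
  }
  swap <- direct_swap | flip_swap
  record$effect_allele <- ref_effect
  record$other_allele <- ref_other
  record$beta[swap] <- -record$beta[swap]
  if ("eaf" %in% names(record)) record$eaf[swap] <- 1 - record$eaf[swap]
  record
}

#' Is an allele pair palindromic (strand-ambiguous)?
#' @param effect_allele,other_allele allele vectors
#' @return logical vector; `TRUE` for A/T and C/G pairs.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  e <- toupper(effect_allele); o <- toupper(other_allele)
  (e == "A" & o == "T") | (e == "T" & o == "A") |
    (e == "C" & o == "G") | (e == "G" & o == "C")
}

#' Drop strand-ambiguous (palindromic) variants
#'
#' A/T and C/G variants cannot be strand-resolved from alleles alone and are
#' always excluded (no frequency-based rescue).
#'
#' @param stats summary_stats object.
#' @param verbose log the removal count?
#' @return summary_stats without palindromic variants.
#' @export
drop_ambiguous <- function(stats, verbose = TRUE) {
  rec <- stats$records
  pal <- is_palindromic(rec$effect_allele, rec$other_allele)
  if (all(pal)) warnf("all variants are palindromic; result is empty")
  pl_log(sprintf("drop_ambiguous: removed %d of %d variants", sum(pal), length(pal)),
         verbose = verbose)
  stats$records <- rec[!pal, , drop = FALSE]
  rownames(stats$records) <- NULL
  stats
}
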