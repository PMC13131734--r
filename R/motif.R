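# Promoter-window PWM scanning, allele-level motif disruption, and
# motif-set enrichment.
#
# Match scores are log-likelihood ratios against a background base
# distribution, scaled to [0, 1] as a fraction of the possible score range
# of each motif; matches with scaled score >= 0.85 are retained by default.

DNA_BASES <- c("A", "C", "G", "T")

#' Position weight matrix
#'
#' @param name motif name.
#' @param matrix 4 x L numeric matrix (rows A, C, G, T) of per-position
#'   probabilities or counts (columns are normalized to sum to 1).
#' @param pseudocount added to probabilities before the log transform.
#' @param background base frequencies (default uniform).
#' @return A `pwm` object; `$score_matrix` holds per-position log2
#'   likelihood ratios.
#' @export
pwm <- function(name, matrix, pseudocount = 0.01,
                background = rep(0.25, 4)) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4) stopf("PWM must have 4 rows (A, C, G, T)")
  if (ncol(matrix) < 4) stopf("PWM length must be >= 4")
  if (any(matrix < 0)) stopf("PWM entries must be nonnegative")
  cs <- colSums(matrix)
  if (any(cs <= 0)) stopf("PWM has an all-zero column")
  prob <- sweep(matrix, 2, cs, "/")
  if (max(abs(colSums(prob) - 1)) > 1e-9) stopf("column normalization failed")
  rownames(prob) <- DNA_BASES
  q <- sweep(prob + pseudocount, 2, 1 + 4 * pseudocount, "/")
  score <- log2(q / background)
  structure(list(name = name, matrix = prob, pseudocount = pseudocount,
                 background = background, score_matrix = score,
                 min_score = sum(apply(score, 2, min)),
                 max_score = sum(apply(score, 2, max))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s: length %d, consensus %s\n", x$name, ncol(x$matrix),
              pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM (highest-probability base per position)
#' @param x a [pwm()].
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[apply(x$matrix, 2, which.max)], collapse = "")
}

#' Reverse-complement a PWM
#' @param x a [pwm()].
#' @export
pwm_reverse_complement <- function(x) {
  m <- x$matrix[4:1, rev(seq_len(ncol(x$matrix))), drop = FALSE]
  rownames(m) <- DNA_BASES
  pwm(paste0(x$name, "_rc"), m, x$pseudocount, x$background)
}

#' Read PWMs from a JASPAR-format matrix file
#'
#' Parses the JASPAR text format: a `>ID name` header followed by four rows
#' `A [ counts... ]` (brackets optional).
#'
#' @param path file path.
#' @param pseudocount,background passed to [pwm()].
#' @return named list of [pwm()] objects.
#' @export
read_jaspar <- function(path, pseudocount = 0.01, background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stopf("no JASPAR records (no '>' headers) in %s", path)
  out <- list()
  for (k in seq_along(starts)) {
    i <- starts[k]
    j <- if (k < length(starts)) starts[k + 1] - 1 else length(lines)
    hdr <- sub("^>\\s*", "", lines[i])
    name <- tail(strsplit(trimws(hdr), "\\s+")[[1]], 1)
    body <- lines[(i + 1):j]
    if (length(body) < 4) stopf("motif %s has fewer than 4 matrix rows", name)
    rows <- lapply(body[1:4], function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      as.numeric(strsplit(gsub("[\\[\\]]", " ", l, perl = TRUE), "\\s+")[[1]] |>
                   (\(v) v[nzchar(v)])())
    })
    if (length(unique(lengths(rows))) != 1)
      stopf("ragged matrix rows for motif %s", name)
    out[[name]] <- pwm(name, do.call(rbind, rows), pseudocount, background)
  }
  out
}

#' Motif analysis configuration
#'
#' @param upstream,downstream promoter window half-widths in bp around the
#'   TSS (defaults 1000 upstream, 300 downstream of transcription).
#' @param score_threshold scaled match score retention threshold (0.85).
#' @param enrichment_p_filter report filter for motif-set enrichment (0.05).
#' @export
motif_config <- function(upstream = 1000L, downstream = 300L,
                         score_threshold = 0.85, enrichment_p_filter = 0.05) {
  stopifnot(score_threshold >= 0, score_threshold <= 1,
            enrichment_p_filter >= 0, enrichment_p_filter <= 1)
  structure(list(upstream = as.integer(upstream),
                 downstream = as.integer(downstream),
                 score_threshold = score_threshold,
                 enrichment_p_filter = enrichment_p_filter),
            class = "motif_config")
}

#' Promoter window around a transcription start site
#'
#' Returns the 0-based half-open genomic interval covering `upstream` bp
#' before and `downstream` bp after the TSS in the direction of
#' transcription (the window is reflected on the minus strand).
#'
#' @param tss 1-based TSS position.
#' @param strand `"+"` or `"-"`.
#' @param config a [motif_config()].
#' @param contig_length optional contig length for clipping.
#' @return integer `c(start, end)`, 0-based half-open.
#' @export
promoter_window <- function(tss, strand, config = motif_config(),
                            contig_length = NULL) {
  stopifnot(strand %in% c("+", "-"))
  t0 <- tss - 1L  # 0-based TSS
  win <- if (strand == "+") {
    c(t0 - config$upstream, t0 + config$downstream)
  } else {
    c(t0 - config$downstream + 1L, t0 + config$upstream + 1L)
  }
  if (win[1] < 0) { warnf("window clipped at contig start"); win[1] <- 0L }
  if (!is.null(contig_length) && win[2] > contig_length) {
    warnf("window clipped at contig end"); win[2] <- contig_length
  }
  as.integer(win)
}

encode_seq <- function(sequence) {
  s <- strsplit(toupper(sequence), "")[[1]]
  m <- match(s, DNA_BASES)  # N and anything else -> NA
  m
}

scan_one_strand <- function(enc, score_matrix) {
  L <- ncol(score_matrix)
  n <- length(enc)
  n_off <- n - L + 1L
  if (n_off < 1L) return(numeric(0))
  sc <- numeric(n_off)
  for (k in seq_len(L)) {
    col <- score_matrix[, k]
    idx <- enc[k:(k + n_off - 1L)]
    v <- col[idx]
    sc <- sc + v   # NA propagates for windows containing N
  }
  sc
}

#' Scan a sequence with a PWM
#'
#' Scores every offset on both strands (log2 likelihood ratio vs background
#' with pseudocounts), rescales to `[0, 1]` as a fraction of the motif's
#' possible score range, and returns hits at or above the threshold.
#' Windows containing `N` are skipped.
#'
#' @param sequence character scalar over `{A,C,G,T,N}`.
#' @param pwm a [pwm()].
#' @param threshold scaled-score retention threshold (default 0.85).
#' @param both_strands scan the reverse strand too?
#' @return data.frame of hits: `offset` (0-based), `strand`, `scaled_score`.
#' @export
pwm_scan <- function(sequence, pwm, threshold = 0.85, both_strands = TRUE) {
  enc <- encode_seq(sequence)
  rng <- pwm$max_score - pwm$min_score
  strands <- if (both_strands) c("+", "-") else "+"
  hits <- list()
  for (st in strands) {
    sm <- if (st == "+") pwm$score_matrix else
      pwm_reverse_complement(pwm)$score_matrix
    raw <- scan_one_strand(enc, sm)
    if (!length(raw)) next
    scaled <- pmin(pmax((raw - pwm$min_score) / rng, 0), 1)
    ok <- which(!is.na(scaled) & scaled >= threshold)
    if (length(ok))
      hits[[st]] <- data.frame(offset = ok - 1L, strand = st,
                               scaled_score = scaled[ok],
                               stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(offset = integer(0), strand = character(0),
                      scaled_score = numeric(0)))
  res <- do.call(rbind, hits)
  rownames(res) <- NULL
  res[order(res$offset, res$strand), , drop = FALSE]
}

best_scaled_score <- function(enc, pwm, offsets) {
  # best scaled score over the given 1-based offsets, both strands
  rng <- pwm$max_score - pwm$min_score
  best <- -Inf
  for (sm in list(pwm$score_matrix, pwm_reverse_complement(pwm)$score_matrix)) {
    L <- ncol(sm)
    for (o in offsets) {
      if (o < 1L || o + L - 1L > length(enc)) next
      idx <- enc[o:(o + L - 1L)]
      if (anyNA(idx)) next
      s <- sum(sm[cbind(idx, seq_len(L))])
      best <- max(best, min(max((s - pwm$min_score) / rng, 0), 1))
    }
  }
  best
}

#' Allele-level motif disruption at a variant
#'
#' Scores the best motif match (both strands, all offsets overlapping the
#' variant) for the reference and alternate alleles; the variant is retained
#' when either allele reaches the scaled-score threshold.
#'
#' @param ref_window reference sequence containing the variant.
#' @param var_offset 1-based position of the variant within `ref_window`.
#' @param ref,alt single-nucleotide alleles.
#' @param pwm a [pwm()].
#' @param threshold retention threshold (default 0.85).
#' @return one-row data.frame with `ref_score`, `alt_score`, `delta`
#'   (`alt - ref`), `retained`; or `NULL` for indel alleles.
#' @export
variant_motif_break <- function(ref_window, var_offset, ref, alt, pwm,
                                threshold = 0.85) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (identical(ref, alt)) stopf("ref and alt alleles are identical")
  if (nchar(ref) != 1L || nchar(alt) != 1L) {
    pl_log(sprintf("indel alleles (%s/%s) skipped by motif disruption scoring",
                   ref, alt))
    return(NULL)
  }
  enc_ref <- encode_seq(ref_window)
  if (var_offset < 1L || var_offset > length(enc_ref))
    stopf("variant offset outside the window")
  if (!is.na(enc_ref[var_offset]) &&
      DNA_BASES[enc_ref[var_offset]] != ref)
    warnf("window base %s at offset %d does not match ref allele %s",
          DNA_BASES[enc_ref[var_offset]], var_offset, ref)
  enc_ref[var_offset] <- match(ref, DNA_BASES)
  enc_alt <- enc_ref
  enc_alt[var_offset] <- match(alt, DNA_BASES)
  L <- ncol(pwm$matrix)
  offsets <- seq.int(max(1L, var_offset - L + 1L), var_offset)
  rs <- best_scaled_score(enc_ref, pwm, offsets)
  as <- best_scaled_score(enc_alt, pwm, offsets)
  data.frame(motif = pwm$name, ref_score = rs, alt_score = as,
             delta = as - rs, retained = max(rs, as) >= threshold,
             stringsAsFactors = FALSE)
}

#' Motif-set enrichment between promoter sets
#'
#' A promoter "contains" the motif when [pwm_scan()] yields at least one
#' hit. Over-representation of containing promoters in the target set versus
#' the combined universe is tested with a one-sided hypergeometric tail.
#'
#' @param target_seqs,background_seqs named character vectors of sequences
#'   (e.g. from [read_fasta()] or [simulate_promoters()]).
#' @param pwm a [pwm()].
#' @param threshold scan threshold (default 0.85).
#' @return list with `p` (one-sided hypergeometric), `counts` (2x2 matrix),
#'   and per-set containment fractions.
#' @export
motif_set_enrichment <- function(target_seqs, background_seqs, pwm,
                                 threshold = 0.85) {
  if (!length(target_seqs) || !length(background_seqs))
    stopf("both promoter sets must be non-empty")
  contains <- function(seqs) vapply(seqs, function(s)
    nrow(pwm_scan(s, pwm, threshold)) > 0, logical(1))
  ct <- contains(target_seqs); cb <- contains(background_seqs)
  k <- sum(ct); nT <- length(ct)
  m <- k + sum(cb); N <- nT + length(cb)
  p <- phyper(k - 1, m, N - m, nT, lower.tail = FALSE)
  counts <- matrix(c(k, nT - k, sum(cb), length(cb) - sum(cb)), 2, 2,
                   dimnames = list(c("contains", "lacks"),
                                   c("target", "background")))
  list(p = p, counts = counts, target_fraction = k / nT,
       background_fraction = sum(cb) / length(cb))
}

#' Enrichment report across a motif collection
#'
#' Runs [motif_set_enrichment()] per motif and keeps motifs passing the
#' report p-value filter.
#'
#' @param target_seqs,background_seqs promoter sets.
#' @param pwms named list of [pwm()] objects.
#' @param config a [motif_config()].
#' @return data.frame (possibly empty) of motifs with `p < enrichment_p_filter`.
#' @export
motif_enrichment_report <- function(target_seqs, background_seqs, pwms,
                                    config = motif_config()) {
  rows <- lapply(pwms, function(pw) {
    e <- motif_set_enrichment(target_seqs, background_seqs, pw,
                              config$score_threshold)
    data.frame(motif = pw$name, p = e$p,
               target_fraction = e$target_fraction,
               background_fraction = e$background_fraction,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[res$p < config$enrichment_p_filter, , drop = FALSE]
}

#' Read / write FASTA as named character vectors
#' @param path file path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @param seqs named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
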