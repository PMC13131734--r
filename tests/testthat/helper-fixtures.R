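# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written as direct, brute-force implementations so they do not
# share code paths with the package functions they check.

make_records <- function(n = 5, chrom = "1", seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ea <- sample(bases, n, TRUE)
  oa <- vapply(ea, function(b) sample(setdiff(bases, b), 1), character(1))
  data.frame(variant_id = paste0("rs", seq_len(n)), chrom = chrom,
             pos = seq_len(n) * 1000L, effect_allele = ea, other_allele = oa,
             eaf = runif(n, 0.1, 0.9), beta = rnorm(n, 0, 0.05),
             se = runif(n, 0.01, 0.05), p = runif(n, 0.001, 0.999),
             n = 10000, stringsAsFactors = FALSE)
}

write_fixture_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# brute-force coloc posterior enumeration in linear space: every non-null
# single-causal configuration plus the null
enumerate_coloc <- function(labf1, labf2, p1, p2, p12) {
  bf1 <- exp(labf1); bf2 <- exp(labf2)
  m <- length(bf1)
  h0 <- 1
  h1 <- p1 * sum(bf1)
  h2 <- p2 * sum(bf2)
  h3 <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) if (i != j)
    h3 <- h3 + p1 * p2 * bf1[i] * bf2[j]
  h4 <- p12 * sum(bf1 * bf2)
  v <- c(h0, h1, h2, h3, h4)
  v / sum(v)
}

# brute-force greedy clump assignment straight from the definition
oracle_clump <- function(ids, conjfdr, p_primary, r2mat, thr) {
  ord <- order(conjfdr, p_primary, ids)
  assigned <- setNames(rep(NA_character_, length(ids)), ids)
  for (i in ord) {
    if (!is.na(assigned[ids[i]])) next
    lead <- ids[i]
    assigned[lead] <- lead
    for (j in seq_along(ids)) {
      if (is.na(assigned[ids[j]]) && r2mat[i, j] >= thr)
        assigned[ids[j]] <- lead
    }
  }
  assigned
}

# brute-force PWM scoring: explicit per-position loop, one offset at a time
oracle_pwm_score <- function(seq_chars, score_matrix, offset) {
  L <- ncol(score_matrix)
  s <- 0
  for (k in seq_len(L)) {
    b <- seq_chars[offset + k - 1]
    i <- match(b, c("A", "C", "G", "T"))
    if (is.na(i)) return(NA_real_)
    s <- s + score_matrix[i, k]
  }
  s
}

revcomp <- function(s) {
  m <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(m[strsplit(s, "")[[1]]]), collapse = "")
}

random_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len, TRUE),
                                  collapse = "")

ar_pwm <- function() {
  read_jaspar(system.file("extdata", "synthetic_hormone_motifs.jaspar",
                          package = "pleiomr"))[[1]]
}

# closed-form weighted least squares through the origin (independent of the
# package implementation)
oracle_wls_origin <- function(x, y, w) {
  b <- sum(w * x * y) / sum(w * x^2)
  list(beta = b, se = sqrt(1 / sum(w * x^2)),
       Q = sum(w * (y - b * x)^2))
}

# simulate a two-sample MR dataset on the standardized scale
sim_mr_pair <- function(k = 50, true_effect = 0.2, n_exp = 1e5, n_out = 2e5,
                        invalid_frac = 0, invalid_shift = 0,
                        intercept = 0) {
  g <- runif(k, 0.02, 0.1) * sample(c(-1, 1), k, TRUE)
  se_e <- rep(1 / sqrt(n_exp), k)
  se_o <- rep(1 / sqrt(n_out), k)
  invalid <- seq_len(k) <= round(invalid_frac * k)
  bx <- g + rnorm(k, 0, se_e)
  by <- true_effect * g + invalid_shift * g * invalid + intercept * sign(g) +
    rnorm(k, 0, se_o)
  harmonized_pair(bx, se_e, by, se_o)
}
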