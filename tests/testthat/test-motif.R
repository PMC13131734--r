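test_that("JASPAR parsing yields normalized matrices with the expected consensus", {
  pwms <- read_jaspar(system.file("extdata", "synthetic_hormone_motifs.jaspar",
                                  package = "pleiomr"))
  expect_length(pwms, 2)
  expect_true(all(abs(colSums(pwms[[1]]$matrix) - 1) < 1e-9))
  expect_equal(substr(pwm_consensus(pwms[[1]]), 1, 6), "AGAACA")
  expect_equal(ncol(pwms[[2]]$matrix), 13)
})

test_that("promoter windows follow transcription direction", {
  cfg <- motif_config()
  expect_equal(promoter_window(10000, "+", cfg), c(8999L, 10299L))
  expect_equal(promoter_window(10000, "-", cfg), c(9700L, 11000L))
  # unclipped windows always span upstream + downstream bp
  for (tss in c(5000, 123456)) for (s in c("+", "-")) {
    w <- promoter_window(tss, s, cfg)
    expect_equal(w[2] - w[1], 1300L)
  }
  expect_warning(w <- promoter_window(500, "+", cfg), "clip")
  expect_equal(w[1], 0L)
})

test_that("consensus scores exactly 1 and the worst sequence exactly 0", {
  pw <- ar_pwm()
  cons <- pwm_consensus(pw)
  hit <- pwm_scan(cons, pw, threshold = 0)
  expect_equal(max(hit$scaled_score), 1.0)
  worst <- paste(c("A", "C", "G", "T")[apply(pw$matrix, 2, which.min)],
                 collapse = "")
  sc <- pwm_scan(worst, pw, threshold = 0, both_strands = FALSE)
  expect_equal(min(sc$scaled_score), 0.0)
})

test_that("scanning equals a brute-force per-position oracle and finds planted motifs", {
  pw <- ar_pwm()
  set.seed(12)
  for (i in 1:25) {
    s <- random_dna(40)
    hits <- pwm_scan(s, pw, threshold = 0, both_strands = FALSE)
    chars <- strsplit(s, "")[[1]]
    raw <- vapply(seq_len(40 - ncol(pw$matrix) + 1), function(o)
      oracle_pwm_score(chars, pw$score_matrix, o), numeric(1))
    scaled <- (raw - pw$min_score) / (pw$max_score - pw$min_score)
    expect_equal(hits$scaled_score, scaled[hits$offset + 1], tolerance = 1e-12)
    expect_equal(nrow(hits), sum(!is.na(scaled)))
  }
  # planted consensus at offset 7 (0-based) is the only 0.85 hit
  s <- paste0(substr(random_dna(30), 1, 7), pwm_consensus(pw),
              substr(random_dna(30), 1, 8))
  hits <- pwm_scan(s, pw, threshold = 0.85)
  expect_true(all(hits$offset == 7))
  expect_equal(max(hits$scaled_score), 1)
})

test_that("reverse-complement scanning is strand-symmetric and N windows are skipped", {
  pw <- ar_pwm()
  set.seed(3)
  s <- paste0(random_dna(10), pwm_consensus(pw), random_dna(10))
  fwd <- pwm_scan(s, pw, threshold = 0.5)
  rev <- pwm_scan(revcomp(s), pw, threshold = 0.5)
  expect_equal(sort(fwd$scaled_score), sort(rev$scaled_score))
  expect_setequal(nchar(s) - ncol(pw$matrix) - fwd$offset, rev$offset)

  sN <- paste0("NN", random_dna(20))
  hN <- pwm_scan(sN, pw, threshold = 0)
  expect_true(all(hN$offset >= 2))
  expect_equal(nrow(pwm_scan("ACGT", pw, 0)), 0)  # shorter than the motif
})

test_that("scaled scores are invariant to the overall scale of the count matrix", {
  counts <- matrix(c(8, 1, 1, 1,  1, 8, 1, 1,  1, 1, 8, 1,  1, 1, 1, 8,
                     4, 4, 1, 1), 4, 5)
  p1 <- pwm("m", counts)
  p2 <- pwm("m", counts * 100)
  s <- random_dna(30)
  expect_equal(pwm_scan(s, p1, 0)$scaled_score, pwm_scan(s, p2, 0)$scaled_score)
})

test_that("allele-level disruption is symmetric and respects the retention rule", {
  pw <- ar_pwm()
  cons <- pwm_consensus(pw)
  win <- paste0("ACGTAC", cons, "GTACGT")
  # break the first consensus base (offset 7 in the window, 1-based)
  worst1 <- c("A", "C", "G", "T")[which.min(pw$matrix[, 1])]
  hit <- variant_motif_break(win, 7L, "A", worst1, pw)
  expect_equal(hit$ref_score, 1.0)
  expect_true(hit$retained)
  expect_lt(hit$delta, 0)

  # swapped alleles: equal retention, negated delta
  win_alt <- sub(cons, paste0(worst1, substr(cons, 2, nchar(cons))), win)
  back <- variant_motif_break(win_alt, 7L, worst1, "A", pw)
  expect_equal(back$delta, -hit$delta, tolerance = 1e-12)
  expect_equal(back$retained, hit$retained)

  set.seed(8)
  rnd <- random_dna(60)
  weak <- variant_motif_break(rnd, 30L, substr(rnd, 30, 30),
                              setdiff(c("A", "C", "G", "T"),
                                      substr(rnd, 30, 30))[1], pw)
  expect_false(weak$retained && weak$ref_score < 0.85 && weak$alt_score < 0.85)

  expect_error(variant_motif_break(win, 7L, "A", "A", pw), "identical")
  expect_null(suppressMessages(variant_motif_break(win, 7L, "A", "AT", pw)))
})

test_that("set enrichment reproduces the exact hypergeometric tail and stays calibrated", {
  pw <- ar_pwm()
  pro <- simulate_promoters(10, 40, 120, pw, 1, 0, seed = 44)
  e <- motif_set_enrichment(pro$target, pro$background, pw)
  # all 10 targets contain, no background does: p = 1 / choose(50, 10)
  if (e$counts["contains", "background"] == 0)
    expect_equal(e$p, 1 / choose(50, 10), tolerance = 1e-12)
  expect_equal(sum(e$counts), 50)

  # equal plant rates: the test holds its size (conservative for discrete p)
  ps <- vapply(1:100, function(s) {
    pr <- simulate_promoters(10, 10, 60, pw, 0.3, 0.3, seed = 1000 + s)
    motif_set_enrichment(pr$target, pr$background, pw)$p
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.10)
  expect_gt(mean(ps), 0.4)

  # no hits anywhere: p = 1
  none <- motif_set_enrichment(c(a = "ACACACAC"), c(b = "GTGTGTGT"), pw)
  expect_equal(none$p, 1)

  rep <- motif_enrichment_report(pro$target, pro$background,
                                 list(ar_pwm()), motif_config())
  expect_true(all(rep$p < 0.05))
})
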