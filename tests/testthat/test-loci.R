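clump_input <- function(ids, conjfdr, p = conjfdr, chrom = "1",
                        pos = seq_along(ids) * 1000L) {
  data.frame(variant_id = ids, chrom = chrom, pos = pos, conjfdr = conjfdr,
             p_primary = p, stringsAsFactors = FALSE)
}

test_that("clumping limits: identity LD gives singletons, full LD one clump", {
  v <- clump_input(paste0("s", 1:4), c(0.04, 0.01, 0.03, 0.02))
  ld_id <- ld_matrix(v$variant_id, diag(4))
  out <- ld_clump(v, ld_id, 0.01)
  expect_equal(out$clump, out$variant_id)

  ld_one <- ld_matrix(v$variant_id, matrix(1, 4, 4))
  out2 <- ld_clump(v, ld_one, 0.01)
  expect_true(all(out2$clump == "s2"))   # smallest conjFDR leads
})

test_that("clump membership matches the brute-force greedy oracle", {
  set.seed(7)
  ids <- paste0("v", 1:6)
  r <- matrix(c(1, .9, .1, 0, 0, 0,
                .9, 1, .2, 0, 0, 0,
                .1, .2, 1, .05, 0, 0,
                0, 0, .05, 1, .95, .3,
                0, 0, 0, .95, 1, .25,
                0, 0, 0, .3, .25, 1), 6, 6)
  r <- (r + t(r)) / 2; diag(r) <- 1
  cj <- c(0.03, 0.001, 0.02, 0.04, 0.002, 0.045)
  v <- clump_input(ids, cj)
  out <- ld_clump(v, ld_matrix(ids, r), 0.1, merge_window = 0)
  oracle <- oracle_clump(ids, cj, cj, r^2, 0.1)
  expect_equal(setNames(out$clump, out$variant_id), oracle)
  # partition property and order invariance
  expect_setequal(out$variant_id, ids)
  perm <- sample(6)
  out_p <- ld_clump(v[perm, ], ld_matrix(ids, r), 0.1, merge_window = 0)
  expect_equal(out_p$clump[match(ids, out_p$variant_id)],
               out$clump[match(ids, out$variant_id)])
  expect_error(ld_clump(clump_input("zz", 0.01), ld_matrix(ids, r), 0.1),
               "absent")
})

test_that("the sex heterogeneity Z test matches its closed form", {
  het <- sex_heterogeneity_test(0.02, 0.02, 0.10, 0.02)
  expect_equal(het$z, 2.8284271247, tolerance = 1e-9)
  expect_equal(het$p, 0.0046777350, tolerance = 1e-8)

  expect_equal(sex_heterogeneity_test(0.3, 0.1, 0.3, 0.1)$z, 0)
  expect_equal(sex_heterogeneity_test(0.3, 0.1, 0.3, 0.1)$p, 1)

  a <- sex_heterogeneity_test(0.02, 0.03, 0.08, 0.04)
  b <- sex_heterogeneity_test(0.08, 0.04, 0.02, 0.03)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  expect_error(sex_heterogeneity_test(0.1, 0, 0.1, 0.01), "SE")
})

test_that("heterogeneity test holds its nominal type-I error", {
  set.seed(42)
  n <- 10000
  bw <- rnorm(n, 0, 0.03); bm <- rnorm(n, 0, 0.03)
  het <- sex_heterogeneity_test(bw, 0.03, bm, 0.03)
  expect_lt(abs(mean(het$p < 0.05) - 0.05), 0.01)
})

test_that("fold-difference rule covers ratios, equality, and sign flips", {
  f <- fold_difference_flag(-0.3, -0.1)
  expect_equal(f$fold_ratio, 3)
  expect_true(f$flag)

  f2 <- fold_difference_flag(0.2, 0.2)
  expect_equal(f2$fold_ratio, 1)
  expect_false(f2$flag)

  f3 <- fold_difference_flag(0.1, -0.1)
  expect_true(f3$opposite_signs)
  expect_true(f3$flag)

  expect_true(is.finite(fold_difference_flag(0.1, 0)$fold_ratio))
})

test_that("tier gates follow the het/fold and colocalization criteria", {
  mk_effects <- function(ids, bw, bm, se = 0.02)
    data.frame(variant_id = ids, beta_women = bw, se_women = se,
               beta_men = bm, se_men = se)
  cl <- clump_input("x1", 0.01)
  cl$clump <- "x1"; cl$is_lead <- TRUE

  # het p = 0.2-ish, fold 1.1: fails both Tier-2 gates
  ef <- mk_effects("x1", 0.020, 0.022)
  t3 <- suppressWarnings(assign_tiers(cl, ef))
  expect_equal(t3$tier, 3L)

  # strong heterogeneity + strong colocalization: Tier 1
  ef2 <- mk_effects("x1", 0.10, 0.01)
  co <- data.frame(clump = "x1", pp4 = 0.9, top_shared_variant_id = "x1")
  t1 <- assign_tiers(cl, ef2, co)
  expect_equal(t1$tier, 1L)
  expect_equal(t1$sex_bias_direction, "female")
  expect_true(t1$lead_sex_biased)

  # heterogeneity without coloc result: capped at Tier 2 with warning
  expect_warning(t2 <- assign_tiers(cl, ef2), "capped")
  expect_equal(t2$tier, 2L)

  # sub-threshold PP4: Tier 2
  co2 <- data.frame(clump = "x1", pp4 = 0.5, top_shared_variant_id = "x1")
  expect_equal(assign_tiers(cl, ef2, co2)$tier, 2L)
})

test_that("novelty uses a strict 1 Mb window on the same chromosome", {
  loci <- data.frame(lead_variant_id = "L1", chrom = "1", pos = 5000000)
  expect_false(annotate_novelty(loci, data.frame(chrom = "1", pos = 5900000))$novel)
  expect_true(annotate_novelty(loci, data.frame(chrom = "2", pos = 5000000))$novel)
  # exactly 1 Mb away: distance is not strictly < 1 Mb, so novel
  expect_true(annotate_novelty(loci, data.frame(chrom = "1", pos = 6000000))$novel)
  expect_false(annotate_novelty(loci, data.frame(chrom = "1", pos = 5999999))$novel)
})
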