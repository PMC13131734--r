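test_that("instrument selection filters on p then clumps on r2", {
  rec <- make_records(8)
  rec$p <- c(1e-9, 1e-10, 0.2, 1e-8 / 2, 0.5, 0.9, 0.04, 0.3)
  st <- summary_stats(rec, "expo", validate = FALSE)
  ld <- ld_matrix(rec$variant_id, diag(8))
  iv <- select_instruments(st, ld)
  expect_setequal(iv, c("rs1", "rs2", "rs4"))

  # two correlated genome-wide hits: the smaller p wins
  r <- diag(8); r[1, 2] <- r[2, 1] <- sqrt(0.9)
  iv2 <- select_instruments(st, ld_matrix(rec$variant_id, r))
  expect_true("rs2" %in% iv2 && !("rs1" %in% iv2))

  rec$p <- rep(0.5, 8)
  expect_error(select_instruments(summary_stats(rec, "expo", validate = FALSE),
                                  ld), "no instruments")
})

test_that("harmonization aligns alleles, drops palindromes and missing outcomes", {
  ex <- make_records(5)
  ex$effect_allele <- c("A", "A", "A", "C", "G")
  ex$other_allele <- c("G", "T", "C", "A", "C")   # rs2 (A/T) and rs5 (G/C) palindromic
  out <- ex
  out$beta <- -ex$beta                       # recorded on the opposite allele
  out$effect_allele <- ex$other_allele
  out$other_allele <- ex$effect_allele
  stE <- summary_stats(ex, "expo", validate = FALSE)
  stO <- summary_stats(out, "outc", validate = FALSE)
  hp <- harmonize_pair(stE, stO, ex$variant_id, verbose = FALSE)
  expect_setequal(hp$variant_id, c("rs1", "rs3", "rs4"))
  expect_equal(hp$beta_outcome, hp$beta_exposure)  # negation undone by alignment

  out2 <- summary_stats(out[out$variant_id != "rs3", ], "outc", validate = FALSE)
  hp2 <- harmonize_pair(stE, out2, ex$variant_id, verbose = FALSE)
  expect_setequal(hp2$variant_id, c("rs1", "rs4"))
  expect_error(harmonize_pair(stE, out2, "rs2", verbose = FALSE), "lost")
})

test_that("single-instrument IVW reduces to the first-order Wald ratio", {
  pair <- harmonized_pair(0.5, 0.01, 0.1, 0.02)
  fit <- mr_ivw(pair)
  expect_equal(fit$beta_causal, 0.2)
  expect_equal(fit$se, 0.04)
  expect_match(fit$note, "Wald")
})

test_that("IVW matches the closed-form WLS oracle", {
  pair <- harmonized_pair(c(0.4, 0.25, 0.6), c(0.02, 0.02, 0.03),
                          c(0.09, 0.04, 0.11), c(0.015, 0.02, 0.025))
  fit <- mr_ivw(pair)
  o <- oracle_wls_origin(pair$beta_exposure, pair$beta_outcome,
                         1 / pair$se_outcome^2)
  expect_equal(fit$beta_causal, o$beta, tolerance = 1e-10)
  expect_equal(fit$q_statistic, o$Q, tolerance = 1e-10)
  expect_equal(fit$se, o$se * sqrt(max(o$Q / 2, 1)), tolerance = 1e-10)
  expect_equal(fit$or, exp(fit$beta_causal))
  expect_lt(fit$ci_low, fit$ci_high)
})

test_that("all estimators agree exactly on identical Wald ratios", {
  x <- c(0.2, 0.4, 0.8, 0.5)
  pair <- harmonized_pair(x, rep(0.01, 4), 0.3 * x, rep(0.02, 4))
  ivw <- mr_ivw(pair)
  eg <- mr_egger(pair)
  wm <- mr_weighted_median(pair, n_boot = 100, seed = 1)
  mo <- mr_weighted_mode(pair, 1, n_boot = 100, seed = 1)
  for (fit in list(ivw, eg, wm, mo))
    expect_equal(fit$beta_causal, 0.3, tolerance = 1e-9)
  expect_equal(ivw$q_statistic, 0, tolerance = 1e-18)
  expect_equal(eg$egger_intercept, 0, tolerance = 1e-12)
  expect_equal(cochran_q(pair, "ivw")$Q, 0, tolerance = 1e-18)
  expect_equal(cochran_q(pair, "ivw")$p, 1)
})

test_that("estimates are invariant to allele relabeling (joint sign flips)", {
  set.seed(2)
  pair <- sim_mr_pair(k = 20)
  flip <- rep(c(1, -1), 10)
  pair2 <- harmonized_pair(pair$beta_exposure * flip, pair$se_exposure,
                           pair$beta_outcome * flip, pair$se_outcome)
  expect_equal(mr_ivw(pair2)$beta_causal, mr_ivw(pair)$beta_causal,
               tolerance = 1e-12)
  expect_equal(mr_egger(pair2)$beta_causal, mr_egger(pair)$beta_causal,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(pair2, 50, 3)$beta_causal,
               mr_weighted_median(pair, 50, 3)$beta_causal, tolerance = 1e-12)
})

test_that("weighted median/mode are deterministic given the seed", {
  set.seed(4)
  pair <- sim_mr_pair(k = 15)
  a <- mr_weighted_median(pair, n_boot = 200, seed = 7)
  b <- mr_weighted_median(pair, n_boot = 200, seed = 7)
  expect_identical(a$se, b$se)
  m1 <- mr_weighted_mode(pair, 1, n_boot = 100, seed = 7)
  m2 <- mr_weighted_mode(pair, 2, n_boot = 100, seed = 7)
  expect_true(is.finite(m2$beta_causal))
  expect_false(identical(m1$beta_causal, NA_real_))
})

test_that("Cochran Q matches the two-instrument hand computation", {
  pair <- harmonized_pair(c(1, 1), c(0.01, 0.01), c(0, 0.6), c(0.1, 0.1))
  q <- cochran_q(pair, "ivw")
  expect_equal(q$Q, 18, tolerance = 1e-10)   # w[(0-0.3)^2 + (0.6-0.3)^2], w = 100
  expect_equal(q$df, 1L)
  pair1 <- harmonized_pair(c(1, 1), c(0.01, 0.01), c(0.1, 0.3), c(0.1, 0.1))
  expect_true(is.na(cochran_q(pair1, "egger")$p))  # df = 0: p omitted
})

test_that("Q/df is near 1 under homogeneous simulation", {
  set.seed(10)
  qr <- vapply(1:200, function(i) {
    pair <- sim_mr_pair(k = 20)
    q <- cochran_q(pair, "ivw")
    q$Q / q$df
  }, numeric(1))
  expect_lt(abs(mean(qr) - 1), 0.1)
})

test_that("leave-one-out flags a planted outlier and nothing else", {
  set.seed(6)
  pair <- sim_mr_pair(k = 12)
  base <- leave_one_out(pair)
  expect_equal(nrow(base), 12)
  expect_true(all(abs(base$beta_causal - attr(base, "full_estimate")) <
                    3 * base$se))
  pair$beta_outcome[4] <- pair$beta_outcome[4] + 12 * pair$se_outcome[4]
  loo <- leave_one_out(pair)
  expect_true(loo$flag[4])
})

test_that("the PRESSO global test is seeded and detects displaced instruments", {
  set.seed(20)
  pair <- sim_mr_pair(k = 20)
  a <- presso_global(pair, n_sim = 300, seed = 5)
  b <- presso_global(pair, n_sim = 300, seed = 5)
  expect_identical(a$p, b$p)
  pair$beta_outcome[1] <- pair$beta_outcome[1] + 10 * pair$se_outcome[1]
  expect_lt(presso_global(pair, n_sim = 500, seed = 5)$p, 0.05)
  expect_error(presso_global(sim_mr_pair(k = 3), 100, 1), "at least 4")
})

test_that("overlap adjustment reduces to IVW at zero and inflates monotonically", {
  set.seed(30)
  pair <- sim_mr_pair(k = 25)
  base <- mr_ivw(pair)
  z0 <- overlap_adjusted_ivw(pair, 0, 1e5, 2e5)
  expect_equal(z0$beta_causal, base$beta_causal)
  expect_equal(z0$se, base$se, tolerance = 1e-12)
  ses <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f)
    overlap_adjusted_ivw(pair, f, 1e5, 2e5, phenotype_corr = 0.2)$se,
    numeric(1))
  expect_true(all(diff(ses) > 0))
  expect_gt(ses[5], base$se)
  full <- overlap_adjusted_ivw(pair, 1, 1e5, 2e5, phenotype_corr = 0.2)
  expect_equal(full$beta_causal, base$beta_causal)
})

test_that("multivariable IVW nests univariable IVW and rejects collinearity", {
  set.seed(40)
  k <- 30
  g <- runif(k, 0.03, 0.1)
  rec <- make_records(k)
  rec$effect_allele <- "A"; rec$other_allele <- "G"  # no palindromes
  rec$beta <- g + rnorm(k, 0, 0.003); rec$se <- 0.003
  e1 <- summary_stats(rec, "e1", validate = FALSE)
  rec2 <- rec; rec2$beta <- 0
  e2 <- summary_stats(rec2, "e2", validate = FALSE)
  reco <- rec; reco$beta <- 0.2 * rec$beta + rnorm(k, 0, 0.002)
  reco$se <- 0.002
  outc <- summary_stats(reco, "out", validate = FALSE)

  mv <- mvmr_ivw(outc, list(A = e1, B = e2), rec$variant_id)
  uni <- mr_ivw(harmonize_pair(e1, outc, rec$variant_id, verbose = FALSE))
  expect_equal(mv$beta_causal[mv$exposure == "A"], uni$beta_causal,
               tolerance = 1e-10)
  expect_true(is.na(mv$beta_causal[mv$exposure == "B"]))

  expect_error(mvmr_ivw(outc, list(A = e1, B = e1), rec$variant_id),
               "rank deficient")
})

test_that("BH adjustment matches the hand-executed step-up procedure", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  # families adjusted independently
  p <- c(0.01, 0.02, 0.03, 0.04)
  fam <- c("f", "f", "m", "m")
  expect_equal(bh_fdr(p, fam), c(0.02, 0.02, 0.04, 0.04))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
})
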