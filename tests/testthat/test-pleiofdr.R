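test_that("enrichment defaults match the three-cutoff convention", {
  cfg <- enrichment_config()
  expect_equal(cfg$secondary_cutoffs, c(0.1, 0.01, 0.001))
  expect_error(enrichment_config(c(0.01, 0.1)), "descending")
})

test_that("independent traits show flat enrichment; planted sharing shows ordered curves", {
  cfg <- sim_config(n_variants = 100000, block_size = 1, ld_rho = 0,
                    pi_null = 0.99, pi_A = 0.005, pi_B = 0.005, pi_shared = 0,
                    seed = 31)
  sim <- simulate_gwas_pair(cfg)
  enr <- fold_enrichment(sim$stats_A, sim$stats_B,
                         enrichment_config(primary_grid = seq(0.1, 2, 0.1)))
  # no pleiotropy: curves hover at the reference level where counts are stable
  well <- enr[enr$n_stratum >= 500 & enr$n_tail_stratum >= 100, ]
  expect_gt(nrow(well), 10)
  expect_lt(mean(abs(well$enrichment - 1)), 0.1)
  expect_lt(max(abs(well$enrichment - 1)), 0.4)

  # planted sharing: enrichment increases with stricter conditioning
  means <- rowMeans(sapply(1:20, function(s) {
    cfgS <- sim_config(n_variants = 20000, block_size = 1, ld_rho = 0,
                       pi_null = 0.98, pi_A = 0.005, pi_B = 0.005,
                       pi_shared = 0.01, seed = 100 + s)
    simS <- simulate_gwas_pair(cfgS)
    e <- fold_enrichment(simS$stats_A, simS$stats_B,
                         enrichment_config(primary_grid = 2))
    e$enrichment[match(c(0.1, 0.01, 0.001), e$cutoff)]
  }))
  expect_true(all(diff(means) > 0))
})

test_that("the unconditional stratum reproduces p/ECDF(p) on a hand-built fixture", {
  p1 <- c(0.001, 0.01, 0.02, 0.05, 0.1, 0.2, 0.4, 0.6, 0.8, 1.0)
  p2 <- c(0.05, 0.5, 0.02, 0.9, 0.08, 0.7, 0.01, 0.95, 0.6, 0.99)
  rec <- make_records(10)
  mk <- function(p) {
    r <- rec; r$p <- p
    summary_stats(r, "t", validate = FALSE)
  }
  ld <- ld_blocks(1:10, 0, rec$variant_id)   # identity LD: pruning keeps all
  g <- fit_fdr_grid(mk(p1), mk(p2), ld, pruning_iterations = 1, seed = 1,
                    secondary_cutoffs = c(1, 0.1),
                    primary_breaks = sort(p1), min_stratum = 1)
  # direct enumeration of the stratified ECDFs
  F_all <- vapply(sort(p1), function(b) mean(p1 <= b), numeric(1))
  in_s <- p2 < 0.1
  F_str <- vapply(sort(p1), function(b) mean(p1[in_s] <= b), numeric(1))
  expect_equal(unname(g$cdf[1, ]), F_all)
  expect_equal(unname(g$cdf[2, ]), F_str)

  # p_secondary = 1 selects the unconditional curve: condFDR = p / ECDF(p)
  cf <- condfdr_lookup(g, sort(p1), rep(1, 10))
  expect_equal(cf, pmin(sort(p1) / F_all, 1), tolerance = 1e-12)
  # p_secondary at the tight cutoff: enforced min of the two curves
  cf2 <- condfdr_lookup(g, sort(p1), rep(0.1 - 1e-12, 10))
  expect_equal(cf2, pmin(sort(p1) / F_str, cf), tolerance = 1e-9)
})

test_that("condFDR respects caps and monotonicity in the conditioning stratum", {
  cfg <- sim_config(n_variants = 20000, seed = 33)
  sim <- simulate_gwas_pair(cfg)
  g <- suppressWarnings(fit_fdr_grid(sim$stats_A, sim$stats_B, sim$ld, seed = 2))
  expect_equal(condfdr_lookup(g, 1, 1), 1)
  expect_equal(condfdr_lookup(g, 1, 1e-4), 1)
  ps <- 10^seq(0, -3, length.out = 13)
  for (p1 in c(0.5, 0.05, 1e-3, 1e-6)) {
    cf <- condfdr_lookup(g, rep(p1, length(ps)), ps)
    expect_true(all(diff(cf) <= 1e-12))   # tightening never increases condFDR
    expect_true(all(cf > 0 & cf <= 1))
  }
  # CDF table is monotone along the primary breaks within each stratum
  expect_true(all(apply(g$cdf, 1, function(r) all(diff(r) >= 0))))
})

test_that("under the global null the unconditional FDR estimate approaches 1", {
  cfg <- sim_config(n_variants = 50000, block_size = 1, ld_rho = 0,
                    pi_null = 1, pi_A = 0, pi_B = 0, pi_shared = 0, seed = 35)
  sim <- simulate_gwas_pair(cfg)
  g <- suppressWarnings(
    fit_fdr_grid(sim$stats_A, sim$stats_B, sim$ld, seed = 5))
  grid_p <- 10^seq(-2, 0, length.out = 21)
  cf <- condfdr_lookup(g, grid_p, rep(1, length(grid_p)))
  expect_lt(mean(abs(cf - 1)), 0.05)
})

test_that("pruning with identity LD keeps every variant; banded pruning separates neighbours", {
  expect_true(all(pleiomr:::prune_banded(rep(1L, 100), 0)))
  set.seed(1)
  blk <- rep(1:10, each = 50)
  kept <- pleiomr:::prune_banded(blk, 0.6)
  w <- floor(log(0.1) / (2 * log(0.6)))  # r^2 > 0.1 neighbourhood width
  ik <- which(kept)
  gaps <- diff(ik)
  same_block <- blk[ik[-1]] == blk[ik[-length(ik)]]
  expect_true(all(gaps[same_block] > w))
  # maximality: every removed variant has a kept neighbour within w
  for (i in which(!kept)) {
    nb <- ik[abs(ik - i) <= w & blk[ik] == blk[i]]
    expect_gt(length(nb), 0)
  }
})

test_that("conjFDR is the max of the directional condFDRs and symmetric", {
  cj <- conjfdr(c(0.2, 0.01, 0.5), c(0.04, 0.01, 0.9))
  expect_equal(cj$conjfdr, c(0.2, 0.01, 0.9))
  expect_equal(cj$pleiotropic, c(FALSE, TRUE, FALSE))
  expect_equal(conjfdr(0.3, 0.1)$conjfdr, conjfdr(0.1, 0.3)$conjfdr)
})
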