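region_from <- function(beta, se, ids = paste0("q", seq_along(beta))) {
  rec <- make_records(length(beta))
  rec$variant_id <- ids
  rec$beta <- beta; rec$se <- se
  summary_stats(rec, "region", validate = FALSE)
}

test_that("log ABF matches direct evaluation and its limits", {
  expect_equal(log_abf(0.1, 0.02, 0.04), 10.0686773653, tolerance = 1e-9)
  # z = 0: pure shrinkage penalty, evidence for the null
  r <- 0.04 / (0.01^2 + 0.04)
  expect_equal(log_abf(0, 0.01, 0.04), 0.5 * log(1 - r))
  expect_lt(log_abf(0, 0.01, 0.04), 0)
  # vanishing prior variance: no evidence either way
  expect_lt(abs(log_abf(0.5, 0.05, 1e-12)), 1e-6)
  expect_error(log_abf(0.1, 0, 0.04), "se")
  expect_error(log_abf(0.1, 0.01, -1), "w")
})

test_that("posteriors are a proper distribution and match enumeration", {
  set.seed(5)
  for (i in 1:20) {
    m <- sample(3:12, 1)
    r1 <- region_from(rnorm(m, 0, 0.05), runif(m, 0.01, 0.05))
    r2 <- region_from(rnorm(m, 0, 0.05), runif(m, 0.01, 0.05),
                      ids = r1$records$variant_id)
    r2$records$effect_allele <- r1$records$effect_allele
    r2$records$other_allele <- r1$records$other_allele
    pri <- coloc_priors()
    res <- suppressWarnings(coloc_posteriors(r1, r2, pri))
    expect_equal(sum(res$pp), 1, tolerance = 1e-9)
    oracle <- enumerate_coloc(log_abf(r1$records$beta, r1$records$se, pri$w1),
                              log_abf(r2$records$beta, r2$records$se, pri$w2),
                              pri$p1, pri$p2, pri$p12)
    expect_equal(unname(res$pp), oracle, tolerance = 1e-8)
  }
})

test_that("an overwhelming shared signal yields PP4 near 1", {
  m <- 30
  beta1 <- c(rep(0, 15), 0.9, rep(0, 14))
  beta2 <- c(rep(0, 15), 0.5, rep(0, 14))
  r1 <- region_from(beta1, rep(0.05, m))
  r2 <- region_from(beta2, rep(0.05, m), ids = r1$records$variant_id)
  r2$records$effect_allele <- r1$records$effect_allele
  r2$records$other_allele <- r1$records$other_allele
  res <- coloc_posteriors(r1, r2)
  expect_gt(res$pp[["pp4"]], 0.99)
  expect_equal(res$top_shared_variant_id, r1$records$variant_id[16])
})

test_that("swapping traits (with swapped priors) fixes PP3 and PP4", {
  set.seed(9)
  m <- 15
  r1 <- region_from(rnorm(m, 0, 0.1), runif(m, 0.01, 0.05))
  r2 <- region_from(rnorm(m, 0, 0.1), runif(m, 0.01, 0.05),
                    ids = r1$records$variant_id)
  r2$records$effect_allele <- r1$records$effect_allele
  r2$records$other_allele <- r1$records$other_allele
  a <- coloc_posteriors(r1, r2, coloc_priors(p1 = 2e-4, p2 = 1e-4, w1 = 0.02,
                                             w2 = 0.03))
  b <- coloc_posteriors(r2, r1, coloc_priors(p1 = 1e-4, p2 = 2e-4, w1 = 0.03,
                                             w2 = 0.02))
  expect_equal(a$pp[["pp3"]], b$pp[["pp3"]], tolerance = 1e-12)
  expect_equal(a$pp[["pp4"]], b$pp[["pp4"]], tolerance = 1e-12)
  expect_equal(a$pp[["pp1"]], b$pp[["pp2"]], tolerance = 1e-12)
})

test_that("increasing the shared prior never decreases PP4", {
  set.seed(11)
  m <- 20
  r1 <- region_from(rnorm(m, 0, 0.05), runif(m, 0.01, 0.05))
  r2 <- region_from(rnorm(m, 0, 0.05), runif(m, 0.01, 0.05),
                    ids = r1$records$variant_id)
  r2$records$effect_allele <- r1$records$effect_allele
  r2$records$other_allele <- r1$records$other_allele
  pp4s <- vapply(c(1e-6, 1e-5, 5e-5, 1e-4), function(p12)
    coloc_posteriors(r1, r2, coloc_priors(p12 = p12))$pp[["pp4"]], numeric(1))
  expect_true(all(diff(pp4s) >= 0))
})

test_that("priors are validated", {
  expect_error(coloc_priors(p12 = 1e-3), "p12")
  expect_error(coloc_priors(w1 = 0), "positive")
})

test_that("QTL scan flags strong colocalization and the category collapse keeps the best PP4", {
  sim <- simulate_qtl_region(80, 0.6, 5e4, 5e4, "shared", 0.005, seed = 3)
  tab <- qtl_coloc_scan(sim$stats_gwas, list(
    list(label = "ds1", category = "brain-tissue", feature = "geneA",
         stats = sim$stats_qtl)))
  expect_true(tab$strong[1])

  res <- data.frame(
    feature = "geneA", category = rep("brain-tissue", 3),
    dataset = c("d1", "d2", "d3"), pp4 = c(0.2, 0.8, 0.75))
  agg <- best_pp4_by_category(res)
  expect_equal(agg$best_pp4, 0.8)
  expect_equal(agg$best_dataset, "d2")

  single <- data.frame(feature = "geneB", category = "pQTL",
                       dataset = "d9", pp4 = 0.4)
  expect_equal(best_pp4_by_category(single)$best_pp4, 0.4)
  expect_equal(nrow(best_pp4_by_category(res[0, ])), 0)
})
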