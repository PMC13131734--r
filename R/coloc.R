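# Bayesian colocalization under the single-causal-variant assumption,
# from summary statistics via Wakefield-style approximate Bayes factors.
# Five hypotheses for a region: H0 no association; H1/H2 one trait only;
# H3 both traits, distinct causal variants; H4 one shared causal variant.
# All accumulation is done in log-sum-exp space so |z| > 40 cannot overflow.

#' Colocalization priors
#'
#' @param p1,p2 prior probability that a variant is causal for trait 1 / 2
#'   only (defaults 1e-4).
#' @param p12 prior probability of shared causality (default 1e-5; must not
#'   exceed `min(p1, p2)`).
#' @param w1,w2 prior effect variances for the approximate Bayes factors.
#'   Defaults: `0.15^2` on the log-odds scale for a case-control trait 1 and
#'   `0.2^2` (SD units) for a quantitative trait 2.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         w1 = 0.15^2, w2 = 0.2^2) {
  if (p12 <= 0 || p12 > min(p1, p2))
    stopf("p12 must satisfy 0 < p12 <= min(p1, p2)")
  if (p1 <= 0 || p2 <= 0 || w1 <= 0 || w2 <= 0)
    stopf("priors and prior variances must be positive")
  structure(list(p1 = p1, p2 = p2, p12 = p12, w1 = w1, w2 = w2),
            class = "coloc_priors")
}

#' Log approximate Bayes factor for one association estimate
#'
#' With shrinkage `r = w / (se^2 + w)` and `z = beta / se`:
#' `log ABF = 0.5 * (log(1 - r) + r * z^2)`.
#'
#' @param beta,se effect estimate and standard error (vectorized).
#' @param w prior effect variance.
#' @return log Bayes factors (association vs null).
#' @export
log_abf <- function(beta, se, w) {
  if (any(se <= 0)) stopf("se must be positive")
  if (any(w <= 0)) stopf("prior variance w must be positive")
  r <- w / (se^2 + w)
  z <- beta / se
  0.5 * (log1p(-r) + r * z^2)
}

#' Colocalization posteriors for a region pair
#'
#' Computes per-variant log ABFs for both traits on the intersection of the
#' two regions and the posterior probability of each hypothesis H0-H4.
#'
#' @param region1,region2 [summary_stats()] slices over one region.
#' @param priors a [coloc_priors()].
#' @param align align region2 alleles to region1 before scoring? (the
#'   posteriors depend on z only through z^2, but alignment keeps the
#'   per-variant diagnostics interpretable).
#' @return A `coloc_result`: list with `pp` (named H0..H4 posteriors),
#'   `n_variants`, `top_shared_variant_id`, and `h4_contrib` (per-variant
#'   posterior contribution to H4).
#' @export
coloc_posteriors <- function(region1, region2, priors = coloc_priors(),
                             align = TRUE) {
  a <- region1$records; b <- region2$records
  i <- match(a$variant_id, b$variant_id)
  keep <- !is.na(i)
  if (!any(keep)) stopf("regions share no variants")
  if (sum(keep) < 10)
    warnf("only %d shared variants in region; posteriors may be unstable",
          sum(keep))
  a <- a[keep, , drop = FALSE]; b <- b[i[keep], , drop = FALSE]
  if (align) b <- align_to_reference(b, a$effect_allele, a$other_allele)
  l1 <- log_abf(a$beta, a$se, priors$w1)
  l2 <- log_abf(b$beta, b$se, priors$w2)
  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls12 <- logsumexp(l1 + l2)
  lh <- c(H0 = 0,
          H1 = log(priors$p1) + ls1,
          H2 = log(priors$p2) + ls2,
          H3 = log(priors$p1) + log(priors$p2) + logdiffexp(ls1 + ls2, ls12),
          H4 = log(priors$p12) + ls12)
  pp <- exp(lh - logsumexp(lh))
  pp <- pp / sum(pp)
  h4c <- exp(l1 + l2 - ls12)
  structure(list(pp = setNames(pp, c("pp0", "pp1", "pp2", "pp3", "pp4")),
                 n_variants = nrow(a),
                 top_shared_variant_id = a$variant_id[which.max(h4c)],
                 h4_contrib = setNames(h4c, a$variant_id),
                 priors = priors),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc_result over %d variants\n", x$n_variants))
  print(round(x$pp, 4))
  cat(sprintf("top shared variant: %s (H4 contribution %.3f)\n",
              x$top_shared_variant_id, max(x$h4_contrib)))
  invisible(x)
}

#' Scan a trait region against a panel of QTL datasets
#'
#' Runs [coloc_posteriors()] between the trait region and each QTL slice;
#' rows with `pp4 >= strong_threshold` are flagged strong (the gene/feature
#' nomination rule).
#'
#' @param trait_region [summary_stats()] slice.
#' @param qtl_datasets list of lists with elements `label` (dataset),
#'   `category`, `feature` (gene/feature id), `stats` (summary_stats slice).
#' @param priors a [coloc_priors()].
#' @param strong_threshold PP4 flag threshold (default 0.70).
#' @return data.frame with one row per (feature, dataset): posteriors,
#'   `top_shared_variant_id`, `strong`.
#' @export
qtl_coloc_scan <- function(trait_region, qtl_datasets,
                           priors = coloc_priors(), strong_threshold = 0.70) {
  rows <- list()
  for (d in qtl_datasets) {
    res <- tryCatch(coloc_posteriors(trait_region, d$stats, priors),
                    error = function(e) {
                      warnf("dataset %s skipped: %s", d$label, conditionMessage(e))
                      NULL
                    })
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <- data.frame(
      dataset = d$label, category = d$category, feature = d$feature,
      n_variants = res$n_variants,
      pp0 = res$pp[["pp0"]], pp1 = res$pp[["pp1"]], pp2 = res$pp[["pp2"]],
      pp3 = res$pp[["pp3"]], pp4 = res$pp[["pp4"]],
      top_shared_variant_id = res$top_shared_variant_id,
      strong = res$pp[["pp4"]] >= strong_threshold,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

#' Best PP4 per category
#'
#' Collapses a QTL colocalization table to one row per (feature, category):
#' the maximum PP4 among member datasets, recording which dataset
#' contributed it. Empty categories are omitted.
#'
#' @param results data.frame from [qtl_coloc_scan()] (optionally with a
#'   `locus` column).
#' @return aggregated data.frame.
#' @export
best_pp4_by_category <- function(results) {
  if (!nrow(results)) return(results)
  keys <- c(intersect("locus", names(results)), "feature", "category")
  split_id <- interaction(results[keys], drop = TRUE)
  rows <- lapply(split(results, split_id), function(g) {
    i <- which.max(g$pp4)
    out <- g[i, c(keys, "pp4", "dataset"), drop = FALSE]
    names(out)[names(out) == "pp4"] <- "best_pp4"
    names(out)[names(out) == "dataset"] <- "best_dataset"
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$feature, res$category), , drop = FALSE]
}
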