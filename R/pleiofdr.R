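# Genome-wide pleiotropy quantification: conditional QQ / fold-enrichment
# curves and per-variant conditional and conjunctional FDR.
#
# condFDR(p1 | p2-stratum) estimates the posterior probability that a variant
# is null for the primary trait given its p-values in both traits, as
# p1 / F-hat(p1 | secondary stratum) where F-hat is the stratified empirical
# CDF of primary p-values. The CDF is estimated on random LD-pruned variant
# subsets (one variant kept per r^2 > 0.1 neighborhood, redrawn each
# iteration) and averaged. conjFDR is the maximum of the two directional
# condFDRs; variants with conjFDR < 0.05 are called pleiotropic.

#' Enrichment curve configuration
#'
#' @param secondary_cutoffs strictly descending secondary-trait p-value
#'   cutoffs (default `c(0.1, 0.01, 0.001)`).
#' @param primary_grid evaluation points in `-log10(p)` of the primary trait.
#' @export
enrichment_config <- function(secondary_cutoffs = c(0.1, 0.01, 0.001),
                              primary_grid = seq(0.1, 3, by = 0.1)) {
  if (any(diff(secondary_cutoffs) >= 0) || any(secondary_cutoffs <= 0) ||
      any(secondary_cutoffs > 1))
    stopf("secondary_cutoffs must be strictly descending in (0, 1]")
  structure(list(secondary_cutoffs = secondary_cutoffs,
                 primary_grid = primary_grid), class = "enrichment_config")
}

join_pair <- function(primary, secondary) {
  a <- primary$records; b <- secondary$records
  i <- match(a$variant_id, b$variant_id)
  keep <- !is.na(i)
  list(variant_id = a$variant_id[keep], chrom = a$chrom[keep],
       pos = a$pos[keep],
       p_primary = a$p[keep], p_secondary = b$p[i[keep]],
       idx_primary = which(keep))
}

#' Conditional QQ fold-enrichment curves
#'
#' For each secondary-trait cutoff `c` and each primary threshold `t` on the
#' grid, computes the fraction of variants with `p_secondary < c` that have
#' `p_primary <= t`, divided by the same fraction among all variants. A curve
#' above the reference level 1 indicates pleiotropic enrichment.
#'
#' @param primary,secondary [summary_stats()] joined on variant_id (align
#'   alleles beforehand if betas matter; only p-values are used here).
#' @param config an [enrichment_config()].
#' @return data.frame with columns `cutoff`, `neglog10_p`, `enrichment`,
#'   `n_stratum`, `n_tail_stratum`, `n_tail_all`.
#' @export
fold_enrichment <- function(primary, secondary, config = enrichment_config()) {
  j <- join_pair(primary, secondary)
  if (length(j$p_primary) < 1000)
    stopf("fewer than 1000 shared variants between the traits")
  tvals <- 10^(-config$primary_grid)
  denom <- vapply(tvals, function(t) mean(j$p_primary <= t), numeric(1))
  out <- list()
  for (cc in config$secondary_cutoffs) {
    s <- j$p_secondary < cc
    ns <- sum(s)
    if (!ns) { warnf("empty stratum at cutoff %g; curve omitted", cc); next }
    num <- vapply(tvals, function(t) mean(j$p_primary[s] <= t), numeric(1))
    out[[length(out) + 1L]] <- data.frame(
      cutoff = cc, neglog10_p = config$primary_grid,
      enrichment = num / denom, n_stratum = ns,
      n_tail_stratum = round(num * ns),
      n_tail_all = round(denom * length(j$p_primary)))
  }
  do.call(rbind, out)
}

# --- LD pruning -------------------------------------------------------------

# random-priority greedy maximal independent set on the r^2 > r2 adjacency.
# For banded AR(1) block LD this is iterated local-maximum selection, which
# reproduces the sequential greedy pass in decreasing-priority order exactly,
# in O(log n) vectorized rounds.
prune_banded <- function(block, rho, r2 = 0.1, neighbors = NULL) {
  n <- length(block)
  nb <- neighbors %||% banded_neighbors(block, rho, r2)
  if (!length(nb)) return(rep(TRUE, n))
  u <- runif(n)
  alive <- rep(TRUE, n); kept <- rep(FALSE, n)
  while (any(alive)) {
    ue <- u
    ue[!alive] <- -Inf
    nb_max <- rep(-Inf, n)
    for (e in nb) {
      v <- rep(-Inf, n)
      v[e$i] <- ue[e$j]
      nb_max <- pmax(nb_max, v)
    }
    win <- alive & ue > nb_max           # priorities are a.s. distinct
    if (!any(win)) {                     # numeric-tie fallback
      win <- alive & ue >= nb_max
      win[which(win)[-1]] <- FALSE
    }
    kept[win] <- TRUE
    dead <- win
    for (e in nb) dead[e$j[win[e$i]]] <- TRUE
    alive <- alive & !dead
  }
  kept
}

# per-shift neighbor index pairs (i adjacent to j) for the banded r^2 > r2
# graph implied by within-block AR(1) LD
banded_neighbors <- function(block, rho, r2 = 0.1) {
  n <- length(block)
  w <- if (rho == 0) 0L else floor(log(r2) / (2 * log(rho)))
  if (w < 1) return(list())
  lapply(setdiff(seq.int(-w, w), 0L), function(s) {
    i <- seq_len(n); j <- i + s
    ok <- j >= 1L & j <= n
    ok[ok] <- block[i[ok]] == block[j[ok]]
    list(i = i[ok], j = j[ok])
  })
}

prune_dense <- function(r, r2 = 0.1) {
  n <- nrow(r)
  ord <- sample.int(n)
  kept <- logical(n)
  adj <- r^2 > r2
  diag(adj) <- FALSE
  for (i in ord) if (!any(adj[i, kept])) kept[i] <- TRUE
  kept
}

prune_once <- function(ld, neighbors = NULL) {
  if (inherits(ld, "ld_blocks")) prune_banded(ld$block, ld$rho, neighbors = neighbors)
  else if (inherits(ld, "ld_matrix")) prune_dense(ld$r)
  else stopf("ld must be an ld_blocks or ld_matrix object")
}

#' Default regions excluded from condFDR grid fitting
#'
#' The extended MHC (chr6:25-35 Mb) and the APOE region (chr19:45-46 Mb);
#' both configurable. Variants there are still scorable, just not used to
#' estimate the stratified CDFs.
#' @export
default_excluded_regions <- function() {
  data.frame(chrom = c("6", "19"), start = c(25e6, 45e6), end = c(35e6, 46e6),
             stringsAsFactors = FALSE)
}

in_regions <- function(chrom, pos, regions) {
  hit <- rep(FALSE, length(chrom))
  for (i in seq_len(nrow(regions)))
    hit <- hit | (chrom == regions$chrom[i] & pos >= regions$start[i] &
                    pos <= regions$end[i])
  hit
}

#' Fit a conditional-FDR lookup grid
#'
#' Estimates the conditional empirical CDF of the primary trait's p-values
#' within nested secondary-trait strata (cutoffs including 1.0, i.e.
#' unconditional), on random LD-pruned subsets averaged over
#' `pruning_iterations`, monotone along the primary breaks.
#'
#' @param primary,secondary [summary_stats()] for the two traits.
#' @param ld an `ld_blocks` (genome-wide, AR(1) blocks) or [ld_matrix()].
#' @param pruning_iterations number of random pruning redraws.
#' @param seed integer seed for the pruning RNG.
#' @param secondary_cutoffs nested stratum cutoffs, descending from 1.
#' @param primary_breaks grid of p-values at which the CDF is tabulated.
#' @param excluded_regions data.frame(chrom, start, end) omitted from fitting
#'   (default: extended MHC and the APOE region); still scorable in lookup.
#' @param min_stratum strata with fewer pruned variants are collapsed into
#'   their parent stratum.
#' @return An `fdr_grid` object.
#' @export
fit_fdr_grid <- function(primary, secondary, ld, pruning_iterations = 10L,
                         seed = 1L,
                         secondary_cutoffs = c(1, 0.1, 0.01, 0.001),
                         primary_breaks = 10^seq(-12, 0, length.out = 121),
                         excluded_regions = default_excluded_regions(),
                         min_stratum = 100L) {
  j <- join_pair(primary, secondary)
  fit_ok <- !in_regions(j$chrom, j$pos, excluded_regions)
  stopifnot(all(diff(secondary_cutoffs) < 0), secondary_cutoffs[1] == 1)
  stopifnot(all(diff(primary_breaks) > 0))
  nS <- length(secondary_cutoffs); nB <- length(primary_breaks)
  # LD index set restricted to joined variants
  ld_sub <- ld
  if (inherits(ld, "ld_blocks")) {
    keep <- match(j$variant_id, ld$variant_ids)
    if (anyNA(keep)) stopf("LD information missing for some joined variants")
    ld_sub <- ld_blocks(ld$block[keep], ld$rho, j$variant_id)
  }
  cdf <- matrix(0, nS, nB)
  n_strat <- matrix(0, nS, pruning_iterations)
  nbrs <- if (inherits(ld_sub, "ld_blocks"))
    banded_neighbors(ld_sub$block, ld_sub$rho)
  with_seed(seed, {
    for (it in seq_len(pruning_iterations)) {
      kept <- prune_once(ld_sub, nbrs) & fit_ok
      p1 <- j$p_primary[kept]; p2 <- j$p_secondary[kept]
      sp1 <- sort(p1)
      for (s in seq_len(nS)) {
        cc <- secondary_cutoffs[s]
        sel <- if (cc >= 1) rep(TRUE, length(p1)) else p2 < cc
        ns <- sum(sel)
        n_strat[s, it] <- ns
        if (ns == 0) next
        sp <- if (cc >= 1) sp1 else sort(p1[sel])
        F <- findInterval(primary_breaks, sp) / ns
        cdf[s, ] <- cdf[s, ] + pmax(F, 0.5 / ns)
      }
    }
  })
  mean_n <- rowMeans(n_strat)
  collapsed <- rep(FALSE, nS)
  for (s in seq_len(nS)) {
    if (mean_n[s] > 0 && mean_n[s] >= min_stratum) {
      cdf[s, ] <- cdf[s, ] / pruning_iterations
    } else if (s > 1) {
      warnf("stratum p<%g has %d pruned variants on average; collapsed into parent",
            secondary_cutoffs[s], round(mean_n[s]))
      cdf[s, ] <- cdf[s - 1, ]
      collapsed[s] <- TRUE
    } else {
      cdf[s, ] <- cdf[s, ] / max(pruning_iterations, 1)
    }
  }
  # running maximum: monotone non-decreasing along primary breaks
  for (s in seq_len(nS)) cdf[s, ] <- cummax(pmin(cdf[s, ], 1))
  structure(list(primary_breaks = primary_breaks,
                 secondary_cutoffs = secondary_cutoffs, cdf = cdf,
                 mean_stratum_size = mean_n, collapsed = collapsed,
                 pruning_iterations = pruning_iterations,
                 excluded_regions = excluded_regions,
                 trait_primary = primary$trait_label,
                 trait_secondary = secondary$trait_label,
                 assumptions = c(
                   "prune_r2=0.1",
                   "excluded_regions: MHC/APOE defaults unless configured")),
            class = "fdr_grid")
}

#' Conditional FDR lookup
#'
#' `condFDR = p_primary / F-hat(p_primary | stratum(p_secondary))`,
#' interpolated bilinearly in log10 space between grid nodes (along the
#' primary p breaks and between adjacent secondary strata), capped at 1, and
#' made non-increasing as the secondary stratum tightens.
#'
#' @param grid an `fdr_grid` from [fit_fdr_grid()].
#' @param p_primary,p_secondary p-value vectors (recycled to equal length).
#' @return condFDR values in (0, 1].
#' @export
condfdr_lookup <- function(grid, p_primary, p_secondary) {
  k <- max(length(p_primary), length(p_secondary))
  p1 <- rep_len(p_primary, k); p2 <- rep_len(p_secondary, k)
  if (any(p1 <= 0 | p1 > 1 | p2 <= 0 | p2 > 1))
    stopf("p-values must lie in (0, 1]")
  lx <- log10(pmin(pmax(p1, min(grid$primary_breaks)), 1))
  lb <- log10(grid$primary_breaks)
  nS <- length(grid$secondary_cutoffs)
  # per-stratum condFDR via interpolation of log10(F) along log10(p)
  cf <- matrix(NA_real_, k, nS)
  for (s in seq_len(nS)) {
    lF <- log10(grid$cdf[s, ])
    Fv <- 10^stats::approx(lb, lF, xout = lx, rule = 2)$y
    cf[, s] <- pmin(p1 / Fv, 1)
  }
  # tightening the secondary stratum never increases condFDR
  if (nS > 1) for (s in 2:nS) cf[, s] <- pmin(cf[, s], cf[, s - 1])
  # interpolate between the two strata bracketing p_secondary (log10 scale)
  lc <- log10(grid$secondary_cutoffs)       # descending: 0, -1, -2, ...
  ly <- pmin(pmax(log10(p2), min(lc)), max(lc))
  pos <- findInterval(-ly, -lc, all.inside = TRUE) # index of looser cutoff
  lo <- lc[pos]; hi <- lc[pos + 1]
  wgt <- ifelse(lo == hi, 0, (lo - ly) / (lo - hi))
  out <- (1 - wgt) * cf[cbind(seq_len(k), pos)] +
    wgt * cf[cbind(seq_len(k), pos + 1)]
  pmin(pmax(out, .Machine$double.xmin), 1)
}

#' Conjunctional FDR
#'
#' The maximum of the two directional conditional FDRs; variants with
#' conjFDR below `threshold` (default 0.05) are flagged pleiotropic.
#'
#' @param condfdr_primary condFDR of trait A given trait B.
#' @param condfdr_secondary condFDR of trait B given trait A.
#' @param threshold pleiotropy call threshold.
#' @return data.frame with `conjfdr` and logical `pleiotropic`.
#' @export
conjfdr <- function(condfdr_primary, condfdr_secondary, threshold = 0.05) {
  cj <- pmax(condfdr_primary, condfdr_secondary)
  data.frame(conjfdr = cj, pleiotropic = cj < threshold)
}

#' Per-variant condFDR/conjFDR table for a trait pair
#'
#' Fits both directional FDR grids and scores every shared variant,
#' returning the pleiotropy record table.
#'
#' @inheritParams fit_fdr_grid
#' @param threshold conjFDR call threshold (default 0.05).
#' @param ... passed to [fit_fdr_grid()].
#' @return data.frame with `variant_id`, `chrom`, `pos`, `p_primary`,
#'   `p_secondary`, both directional condFDRs, `conjfdr`, `pleiotropic`.
#' @export
conjfdr_table <- function(primary, secondary, ld, pruning_iterations = 10L,
                          seed = 1L, threshold = 0.05, ...) {
  g_ab <- fit_fdr_grid(primary, secondary, ld,
                       pruning_iterations = pruning_iterations, seed = seed, ...)
  g_ba <- fit_fdr_grid(secondary, primary, ld,
                       pruning_iterations = pruning_iterations,
                       seed = seed + 1L, ...)
  j <- join_pair(primary, secondary)
  cf_ab <- condfdr_lookup(g_ab, j$p_primary, j$p_secondary)
  cf_ba <- condfdr_lookup(g_ba, j$p_secondary, j$p_primary)
  cj <- conjfdr(cf_ab, cf_ba, threshold)
  data.frame(variant_id = j$variant_id, chrom = j$chrom, pos = j$pos,
             p_primary = j$p_primary, p_secondary = j$p_secondary,
             condfdr_primary_given_secondary = cf_ab,
             condfdr_secondary_given_primary = cf_ba,
             conjfdr = cj$conjfdr, pleiotropic = cj$pleiotropic,
             stringsAsFactors = FALSE)
}
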