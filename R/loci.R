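# Collapse pleiotropic variants into independent signals (greedy LD
# clumping) and run the Tier-3 -> Tier-2 -> Tier-1 prioritization:
#   Tier 3: independent pleiotropic signal (conjFDR < 0.05)
#   Tier 2: contains a variant with a sex-biased disease effect
#           (heterogeneity P < 0.05 or > 1.5-fold effect difference)
#   Tier 1: cross-trait colocalization PP4 >= 0.7

#' Tier configuration
#'
#' @param clump_r2 LD clumping threshold (signals independent at r2 below it).
#' @param het_p sex-heterogeneity p-value gate.
#' @param fold_threshold fold effect-size difference gate.
#' @param pp4_threshold colocalization PP4 gate for Tier 1.
#' @param novelty_window bp window for novelty annotation (strict `<`).
#' @param conjfdr_threshold pleiotropy call threshold.
#' @param merge_window bp window within which clumps with correlated leads
#'   are merged into one signal.
#' @export
tier_config <- function(clump_r2 = 0.01, het_p = 0.05, fold_threshold = 1.5,
                        pp4_threshold = 0.7, novelty_window = 1e6,
                        conjfdr_threshold = 0.05, merge_window = 250e3) {
  structure(list(clump_r2 = clump_r2, het_p = het_p,
                 fold_threshold = fold_threshold,
                 pp4_threshold = pp4_threshold,
                 novelty_window = novelty_window,
                 conjfdr_threshold = conjfdr_threshold,
                 merge_window = merge_window), class = "tier_config")
}

ld_r2_lookup <- function(ld, id_a, id_b) {
  if (inherits(ld, "ld_matrix")) {
    ia <- match(id_a, ld$variant_ids); ib <- match(id_b, ld$variant_ids)
    if (anyNA(ia) || anyNA(ib)) stopf("variant absent from LD matrix")
    ld$r[cbind(ia, ib)]^2
  } else if (inherits(ld, "ld_blocks")) {
    ia <- match(id_a, ld$variant_ids); ib <- match(id_b, ld$variant_ids)
    if (anyNA(ia) || anyNA(ib)) stopf("variant absent from LD blocks")
    same <- ld$block[ia] == ld$block[ib]
    ifelse(same, ld$rho^(2 * abs(ia - ib)), 0)
  } else stopf("ld must be an ld_matrix or ld_blocks object")
}

#' Greedy LD clumping of scored variants
#'
#' Repeatedly takes the unassigned variant with the smallest `conjfdr`
#' (ties: smaller `p_primary`, then lexicographic `variant_id`) as a clump
#' lead and assigns every unassigned variant with `r2 >= r2_threshold` to it;
#' the clumps partition the input and are invariant to input ordering.
#' Clumps whose leads lie within `merge_window` bp and have lead r2 at or
#' above the threshold are merged.
#'
#' @param variants data.frame with `variant_id`, `chrom`, `pos`, `conjfdr`,
#'   `p_primary`.
#' @param ld [ld_matrix()] or `ld_blocks` covering all variants.
#' @param r2_threshold clumping r-squared (default 0.01).
#' @param merge_window bp window for the lead-merge rule.
#' @return data.frame of the input plus `clump` (lead variant_id) and
#'   `is_lead`.
#' @export
ld_clump <- function(variants, ld, r2_threshold = 0.01, merge_window = 250e3) {
  stopifnot(all(c("variant_id", "conjfdr", "p_primary") %in% names(variants)))
  v <- variants[order(variants$conjfdr, variants$p_primary,
                      variants$variant_id), , drop = FALSE]
  n <- nrow(v)
  # validate LD coverage up front
  invisible(ld_r2_lookup(ld, v$variant_id, v$variant_id))
  clump <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (!is.na(clump[i])) next
    lead <- v$variant_id[i]
    clump[i] <- lead
    open <- which(is.na(clump))
    if (length(open)) {
      r2 <- ld_r2_lookup(ld, rep(lead, length(open)), v$variant_id[open])
      clump[open[r2 >= r2_threshold]] <- lead
    }
  }
  v$clump <- clump
  # merge clumps with nearby, correlated leads into one signal
  if (all(c("chrom", "pos") %in% names(v))) {
    leads <- v[v$variant_id == v$clump, , drop = FALSE]
    if (nrow(leads) > 1) {
      for (i in 2:nrow(leads)) for (k in 1:(i - 1)) {
        a <- leads$variant_id[i]; b <- leads$clump[k]
        if (leads$chrom[i] == leads$chrom[k] &&
            abs(leads$pos[i] - leads$pos[k]) <= merge_window &&
            ld_r2_lookup(ld, a, b) >= r2_threshold) {
          v$clump[v$clump == a] <- b
          leads$clump[i] <- b
          break
        }
      }
    }
  }
  v$is_lead <- v$variant_id == v$clump
  v[order(match(v$variant_id, variants$variant_id)), , drop = FALSE]
}

#' Sex heterogeneity Z test
#'
#' `z = (beta_men - beta_women) / sqrt(se_men^2 + se_women^2)` with a
#' two-sided normal p-value.
#'
#' @param beta_women,se_women,beta_men,se_men per-variant sex-stratified
#'   effects and standard errors (vectorized).
#' @return data.frame with `z` and `p`.
#' @export
sex_heterogeneity_test <- function(beta_women, se_women, beta_men, se_men) {
  if (any(se_women <= 0) || any(se_men <= 0)) stopf("nonpositive SE")
  z <- (beta_men - beta_women) / sqrt(se_men^2 + se_women^2)
  data.frame(z = z, p = 2 * pnorm(-abs(z)))
}

#' Fold effect-size difference flag
#'
#' `fold_ratio = max(|b_w|, |b_m|) / max(min(|b_w|, |b_m|), eps)`; flagged
#' sex-biased when the ratio exceeds `fold_threshold` or the two betas have
#' opposite signs (both nonzero).
#'
#' @param beta_women,beta_men effect vectors.
#' @param fold_threshold default 1.5.
#' @param eps denominator floor.
#' @return data.frame with `fold_ratio`, `opposite_signs`, `flag`.
#' @export
fold_difference_flag <- function(beta_women, beta_men, fold_threshold = 1.5,
                                 eps = 1e-8) {
  aw <- abs(beta_women); am <- abs(beta_men)
  ratio <- pmax(aw, am) / pmax(pmin(aw, am), eps)
  opp <- (beta_women * beta_men < 0) & aw > 0 & am > 0
  data.frame(fold_ratio = ratio, opposite_signs = opp,
             flag = ratio > fold_threshold | opp)
}

sex_bias_at <- function(effects, config) {
  het <- sex_heterogeneity_test(effects$beta_women, effects$se_women,
                                effects$beta_men, effects$se_men)
  fold <- fold_difference_flag(effects$beta_women, effects$beta_men,
                               config$fold_threshold)
  data.frame(variant_id = effects$variant_id, het_z = het$z, het_p = het$p,
             fold_ratio = fold$fold_ratio,
             sex_biased = het$p < config$het_p | fold$flag,
             direction = ifelse(abs(effects$beta_women) > abs(effects$beta_men),
                                "female", "male"),
             stringsAsFactors = FALSE)
}

#' Assign prioritization tiers to clumped pleiotropic signals
#'
#' Every clump is a Tier-3 signal. A clump advances to Tier 2 when at least
#' one member variant passes the sex-heterogeneity gate or the fold rule,
#' and to Tier 1 when its cross-trait colocalization PP4 meets the gate.
#' `lead_sex_biased` records whether the best-colocalizing variant itself
#' passes the sex-bias criterion (it need not — sex-biased evidence can come
#' from other members of the set).
#'
#' @param clumps output of [ld_clump()] restricted to variants with
#'   `conjfdr` below the call threshold.
#' @param effects data.frame with `variant_id`, `beta_women`, `se_women`,
#'   `beta_men`, `se_men` covering the clump members.
#' @param coloc_results optional data.frame with `clump`, `pp4`,
#'   `top_shared_variant_id` per clump lead.
#' @param config a [tier_config()].
#' @return data.frame of `tiered_locus` rows, one per clump.
#' @export
assign_tiers <- function(clumps, effects, coloc_results = NULL,
                         config = tier_config()) {
  stopifnot(all(c("clump", "variant_id") %in% names(clumps)))
  if (any(clumps$conjfdr >= config$conjfdr_threshold))
    warnf("some clump members have conjfdr >= %g", config$conjfdr_threshold)
  ef <- effects[match(clumps$variant_id, effects$variant_id), , drop = FALSE]
  if (anyNA(ef$beta_women))
    stopf("sex-stratified effects missing for some clump members")
  sb <- sex_bias_at(ef, config)
  out <- list()
  for (lead in unique(clumps$clump)) {
    i <- clumps$clump == lead
    members <- clumps$variant_id[i]
    sbi <- sb[i, , drop = FALSE]
    lead_row <- which(clumps$variant_id == lead & i)
    tier <- 3L
    any_biased <- any(sbi$sex_biased)
    direction <- "none"
    if (any_biased) {
      tier <- 2L
      top <- sbi[sbi$sex_biased, , drop = FALSE]
      direction <- top$direction[which.min(top$het_p)]
    }
    pp4 <- NA_real_; top_var <- NA_character_; lead_sex_biased <- NA
    if (tier == 2L) {
      cr <- if (!is.null(coloc_results)) coloc_results[coloc_results$clump == lead, , drop = FALSE]
      if (is.null(coloc_results) || !nrow(cr)) {
        warnf("no colocalization result for Tier-2 clump %s; capped at Tier 2", lead)
      } else {
        pp4 <- cr$pp4[1]
        top_var <- cr$top_shared_variant_id[1]
        if (is.finite(pp4) && pp4 >= config$pp4_threshold) tier <- 1L
        lead_sex_biased <- if (!is.na(top_var) && top_var %in% sbi$variant_id)
          sbi$sex_biased[match(top_var, sbi$variant_id)] else NA
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      lead_variant_id = lead,
      chrom = clumps$chrom[lead_row][1] %||% NA_character_,
      pos = clumps$pos[lead_row][1] %||% NA_integer_,
      n_members = sum(i),
      members = paste(members, collapse = ","),
      tier = tier,
      het_z = sbi$het_z[match(lead, sbi$variant_id)],
      het_p = sbi$het_p[match(lead, sbi$variant_id)],
      min_het_p = min(sbi$het_p),
      max_fold_ratio = max(sbi$fold_ratio),
      sex_bias_direction = direction,
      coloc_pp4 = pp4,
      top_shared_variant_id = top_var,
      lead_sex_biased = lead_sex_biased,
      conjfdr = min(clumps$conjfdr[i]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res[order(res$tier, res$conjfdr), , drop = FALSE]
}

#' Annotate locus novelty against known risk loci
#'
#' A locus is novel when no known locus on the same chromosome lies strictly
#' within `novelty_window` bp of its lead variant.
#'
#' @param loci data.frame with `chrom` and `pos` of lead variants
#'   (e.g. from [assign_tiers()]).
#' @param known_loci data.frame with `chrom`, `pos` (2-column TSV/BED
#'   resource, user-supplied).
#' @param novelty_window bp window (strict inequality on distance).
#' @return `loci` with a logical `novel` column.
#' @export
annotate_novelty <- function(loci, known_loci, novelty_window = 1e6) {
  loci$novel <- vapply(seq_len(nrow(loci)), function(i) {
    same <- known_loci$chrom == loci$chrom[i]
    if (!any(same)) return(TRUE)
    all(abs(known_loci$pos[same] - loci$pos[i]) >= novelty_window)
  }, logical(1))
  loci
}

#' Write loci as BED (0-based half-open lead positions)
#' @param loci data.frame with `chrom`, `pos`, `lead_variant_id`, `tier`.
#' @param path output path.
#' @export
write_loci_bed <- function(loci, path) {
  bed <- data.frame(chrom = loci$chrom, start = loci$pos - 1L, end = loci$pos,
                    name = loci$lead_variant_id, score = loci$tier)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
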