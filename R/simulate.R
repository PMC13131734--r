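# Seeded generators for synthetic GWAS/QTL summary statistics, promoter
# sequences and an end-to-end synthetic study. LD is AR(1) within blocks
# (r[i,j] = rho^|i-j|), block-diagonal genome-wide: analytically tractable,
# positive definite, and fast. Effects live on the standardized-genotype
# scale, so se = 1/sqrt(n) and z = beta/se for every simulated record.

# evaluate expr under a local RNG stream; global .Random.seed is untouched
with_seed <- function(seed, expr) {
  if (!is_scalar_number(seed)) stopf("seed must be a single finite number")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

#' Simulation configuration
#'
#' Defines the generating model for a pair of GWAS: AR(1) LD blocks, a
#' four-component spike-and-slab over per-variant standardized causal effects
#' (null / trait-A-only / trait-B-only / shared), optional sex-biased blocks,
#' and cross-GWAS sample-overlap noise correlation.
#'
#' @param n_variants total number of variants.
#' @param block_size variants per LD block.
#' @param ld_rho AR(1) LD parameter in `[0, 1)`.
#' @param n_A,n_B GWAS sample sizes.
#' @param pi_null,pi_A,pi_B,pi_shared mixture proportions (must sum to 1).
#' @param effect_sd SD of standardized causal effects.
#' @param sex_bias_loci list of `c(block =, fold =)` pairs; trait-A (or
#'   female) effects in those blocks are multiplied by the fold factor.
#' @param overlap_corr cross-trait noise correlation in `[-1, 1]` induced by
#'   overlapping samples.
#' @param seed integer seed; generators are pure functions of (config, seed).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_variants = 10000L, block_size = 50L, ld_rho = 0.6,
                       n_A = 1e5, n_B = 1e5,
                       pi_null = 0.994, pi_A = 0.002, pi_B = 0.002,
                       pi_shared = 0.002, effect_sd = 0.02,
                       sex_bias_loci = list(), overlap_corr = 0, seed = 1L) {
  pis <- c(pi_null, pi_A, pi_B, pi_shared)
  if (abs(sum(pis) - 1) > 1e-12) stopf("mixture proportions must sum to 1")
  if (any(pis < 0)) stopf("mixture proportions must be nonnegative")
  if (ld_rho < 0 || ld_rho >= 1) stopf("ld_rho must be in [0, 1)")
  if (abs(overlap_corr) > 1) stopf("overlap_corr must be in [-1, 1]")
  structure(list(n_variants = as.integer(n_variants),
                 block_size = as.integer(block_size), ld_rho = ld_rho,
                 n_A = n_A, n_B = n_B, pi_null = pi_null, pi_A = pi_A,
                 pi_B = pi_B, pi_shared = pi_shared, effect_sd = effect_sd,
                 sex_bias_loci = sex_bias_loci, overlap_corr = overlap_corr,
                 seed = seed),
            class = "sim_config")
}

#' AR(1) LD correlation matrix
#'
#' @param m number of variants.
#' @param rho AR(1) parameter in `[0, 1)`.
#' @param variant_ids optional IDs (default `v1..vm`).
#' @return An `ld_matrix`: list with `variant_ids` and correlation matrix `r`.
#' @export
simulate_ld_matrix <- function(m, rho, variant_ids = NULL) {
  if (m < 1) stopf("m must be >= 1")
  if (rho < 0 || rho >= 1) stopf("rho must be in [0, 1)")
  idx <- seq_len(m)
  r <- rho^abs(outer(idx, idx, "-"))
  ids <- variant_ids %||% paste0("v", idx)
  ld_matrix(ids, r)
}

#' Construct an LD matrix object
#' @param variant_ids ordered variant IDs.
#' @param r symmetric correlation matrix with unit diagonal.
#' @export
ld_matrix <- function(variant_ids, r) {
  r <- as.matrix(r)
  stopifnot(length(variant_ids) == nrow(r), nrow(r) == ncol(r))
  if (max(abs(r - t(r))) > 1e-8) stopf("LD matrix must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8) stopf("LD matrix diagonal must be 1")
  dimnames(r) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = variant_ids, r = r), class = "ld_matrix")
}

# Block-diagonal AR(1) LD descriptor for genome-scale sets: stores the block
# id per variant (in record order) and the common rho, instead of a dense
# matrix.
#' @param block integer block id per variant (record order).
#' @param rho shared AR(1) parameter.
#' @param variant_ids variant IDs in record order.
#' @rdname ld_matrix
#' @export
ld_blocks <- function(block, rho, variant_ids) {
  structure(list(block = as.integer(block), rho = rho,
                 variant_ids = variant_ids), class = "ld_blocks")
}

# shared scaffolding: ids, contiguous chrom/pos, random non-identical alleles
variant_frame <- function(n, n_chrom = 22L, spacing = 1000L) {
  per <- ceiling(n / n_chrom)
  chrom <- as.character(rep(seq_len(n_chrom), each = per)[seq_len(n)])
  pos <- as.integer(unlist(lapply(rle(chrom)$lengths,
                                  function(k) seq_len(k) * spacing)))
  bases <- c("A", "C", "G", "T")
  ei <- sample.int(4L, n, replace = TRUE)
  oa <- bases[((ei - 1L + sample.int(3L, n, replace = TRUE)) %% 4L) + 1L]
  data.frame(variant_id = sprintf("v%07d", seq_len(n)), chrom = chrom,
             pos = pos, effect_allele = bases[ei], other_allele = oa,
             stringsAsFactors = FALSE)
}

block_index <- function(n, block_size) ((seq_len(n) - 1L) %/% block_size) + 1L

# z = sqrt(n) R gamma + noise for all complete blocks at once; gamma and
# noise enter as m x nblock matrices
ar1_chol <- function(m, rho) chol(rho^abs(outer(seq_len(m), seq_len(m), "-")))

# marginal mean sqrt(n) * R %*% gamma, by block, for equal-size blocks
blockwise_Rgamma <- function(gamma, m, rho) {
  R <- rho^abs(outer(seq_len(m), seq_len(m), "-"))
  nb <- length(gamma) / m
  as.vector(R %*% matrix(gamma, nrow = m, ncol = nb))
}

zs_to_records <- function(vf, z, n, eaf) {
  se <- 1 / sqrt(n)
  p <- pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)
  cbind(vf, data.frame(eaf = eaf, beta = z * se, se = se, p = p, n = n))
}

#' Simulate a pair of GWAS with shared and trait-specific architecture
#'
#' Per LD block with AR(1) matrix `R`, standardized causal effects are drawn
#' from the four-component spike-and-slab of the config (shared variants get
#' one common effect in both traits); marginal z-scores follow
#' `z_t = sqrt(n_t) R gamma_t + eps_t` with per-trait noise covariance `R`
#' and cross-trait covariance `overlap_corr * R`. Deterministic given the
#' config seed.
#'
#' @param config a [sim_config()].
#' @return list with `stats_A`, `stats_B` ([summary_stats()]), `truth`
#'   (per-variant labels, true effects, block ids) and `ld` (an `ld_blocks`).
#' @export
simulate_gwas_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_variants; m <- config$block_size
    if (n %% m != 0) {
      warnf("block_size does not divide n_variants; truncating last block")
      n <- (n %/% m) * m
    }
    vf <- variant_frame(n)
    blk <- block_index(n, m)
    lab <- sample(c("null", "A", "B", "shared"), n, replace = TRUE,
                  prob = c(config$pi_null, config$pi_A, config$pi_B,
                           config$pi_shared))
    gA <- gB <- numeric(n)
    shared_g <- rnorm(sum(lab == "shared"), 0, config$effect_sd)
    gA[lab == "shared"] <- shared_g
    gB[lab == "shared"] <- shared_g
    gA[lab == "A"] <- rnorm(sum(lab == "A"), 0, config$effect_sd)
    gB[lab == "B"] <- rnorm(sum(lab == "B"), 0, config$effect_sd)
    for (sb in config$sex_bias_loci) gA[blk == sb[["block"]]] <-
      gA[blk == sb[["block"]]] * sb[["fold"]]

    rho <- config$ld_rho
    muA <- sqrt(config$n_A) * blockwise_Rgamma(gA, m, rho)
    muB <- sqrt(config$n_B) * blockwise_Rgamma(gB, m, rho)
    L <- t(ar1_chol(m, rho))          # lower-triangular factor, R = L L'
    nb <- n / m
    u1 <- matrix(rnorm(n), m, nb); u2 <- matrix(rnorm(n), m, nb)
    cc <- config$overlap_corr
    epsA <- as.vector(L %*% u1)
    epsB <- cc * epsA + sqrt(1 - cc^2) * as.vector(L %*% u2)
    eaf <- runif(n, 0.05, 0.95)
    recA <- zs_to_records(vf, muA + epsA, config$n_A, eaf)
    recB <- zs_to_records(vf, muB + epsB, config$n_B, eaf)
    list(stats_A = summary_stats(recA, "trait_A", validate = FALSE),
         stats_B = summary_stats(recB, "trait_B", validate = FALSE),
         truth = list(labels = lab, gamma_A = gA, gamma_B = gB, block = blk,
                      variant_id = vf$variant_id,
                      sex_bias_loci = config$sex_bias_loci),
         ld = ld_blocks(blk, rho, vf$variant_id))
  })
}

#' Simulate sex-stratified GWAS of one trait
#'
#' Causal variants (probability `1 - pi_null` of the config) carry a shared
#' effect plus independent per-sex Gaussian deviations with SD `tau`;
#' designated sex-bias blocks instead enforce an exact female:male effect
#' ratio equal to the fold factor.
#'
#' @param config a [sim_config()]; `n_A`/`n_B` are the female/male sample
#'   sizes and `sex_bias_loci` the sex-biased blocks.
#' @param tau SD of sex-specific effect deviations (>= 0).
#' @return list with `stats_female`, `stats_male`, `truth`, `ld`.
#' @export
simulate_sex_pair <- function(config, tau = 0) {
  stopifnot(inherits(config, "sim_config"), tau >= 0)
  with_seed(config$seed, {
    n <- config$n_variants; m <- config$block_size
    if (n %% m != 0) {
      warnf("block_size does not divide n_variants; truncating last block")
      n <- (n %/% m) * m
    }
    vf <- variant_frame(n)
    blk <- block_index(n, m)
    causal <- runif(n) < (1 - config$pi_null)
    g <- numeric(n)
    g[causal] <- rnorm(sum(causal), 0, config$effect_sd)
    gF <- g; gM <- g
    gF[causal] <- g[causal] + rnorm(sum(causal), 0, tau)
    gM[causal] <- g[causal] + rnorm(sum(causal), 0, tau)
    for (sb in config$sex_bias_loci) {
      i <- blk == sb[["block"]]
      gF[i] <- gM[i] * sb[["fold"]]      # exact planted female:male ratio
    }
    rho <- config$ld_rho
    muF <- sqrt(config$n_A) * blockwise_Rgamma(gF, m, rho)
    muM <- sqrt(config$n_B) * blockwise_Rgamma(gM, m, rho)
    L <- t(ar1_chol(m, rho))
    nb <- n / m
    epsF <- as.vector(L %*% matrix(rnorm(n), m, nb))
    epsM <- as.vector(L %*% matrix(rnorm(n), m, nb))  # disjoint samples
    eaf <- runif(n, 0.05, 0.95)
    recF <- zs_to_records(vf, muF + epsF, config$n_A, eaf)
    recM <- zs_to_records(vf, muM + epsM, config$n_B, eaf)
    list(stats_female = summary_stats(recF, "trait", "female", validate = FALSE),
         stats_male = summary_stats(recM, "trait", "male", validate = FALSE),
         truth = list(causal = causal, gamma_female = gF, gamma_male = gM,
                      block = blk, variant_id = vf$variant_id,
                      sex_bias_loci = config$sex_bias_loci),
         ld = ld_blocks(blk, rho, vf$variant_id))
  })
}

#' Simulate a single-causal-variant QTL/GWAS region pair
#'
#' Generates marginal z-scores for one region under AR(1) LD for a GWAS
#' trait and a molecular QTL, with causal configurations dictated by `mode`:
#' `shared` (same causal variant), `distinct` (two causal variants with
#' pairwise r-squared below `r2_cap`), `gwas_only`, or `null`. The causal
#' variant explains `causal_var_explained` of trait variance, so the expected
#' peak chi-square is about `1 + n * causal_var_explained`.
#'
#' @param m region size (variants).
#' @param rho AR(1) LD parameter.
#' @param n_gwas,n_qtl sample sizes.
#' @param mode one of `"shared"`, `"distinct"`, `"gwas_only"`, `"null"`.
#' @param causal_var_explained proportion of variance explained by the causal
#'   variant.
#' @param seed integer seed.
#' @param r2_cap maximum r-squared between distinct causal variants.
#' @return list with `stats_gwas`, `stats_qtl`, `ld` ([ld_matrix()]), `truth`.
#' @export
simulate_qtl_region <- function(m, rho, n_gwas, n_qtl,
                                mode = c("shared", "distinct", "gwas_only", "null"),
                                causal_var_explained = 0.005, seed = 1L,
                                r2_cap = 0.3) {
  mode <- match.arg(mode)
  with_seed(seed, {
    vf <- variant_frame(m, n_chrom = 1L)
    ld <- simulate_ld_matrix(m, rho, vf$variant_id)
    g_amp <- sqrt(causal_var_explained)
    gG <- gQ <- numeric(m)
    truth <- list(mode = mode, causal_gwas = NA_integer_,
                  causal_qtl = NA_integer_)
    if (mode != "null") {
      j1 <- sample.int(m, 1)
      truth$causal_gwas <- j1
      gG[j1] <- g_amp
      if (mode == "shared") { truth$causal_qtl <- j1; gQ[j1] <- g_amp }
      if (mode == "distinct") {
        ok <- which(ld$r[j1, ]^2 < r2_cap)
        if (!length(ok)) stopf("no feasible distinct causal pair under r2_cap=%g", r2_cap)
        j2 <- if (length(ok) == 1) ok else sample(ok, 1)
        truth$causal_qtl <- j2
        gQ[j2] <- g_amp
      }
    }
    L <- t(chol(ld$r))
    zG <- sqrt(n_gwas) * as.vector(ld$r %*% gG) + as.vector(L %*% rnorm(m))
    zQ <- sqrt(n_qtl) * as.vector(ld$r %*% gQ) + as.vector(L %*% rnorm(m))
    eaf <- runif(m, 0.05, 0.95)
    list(stats_gwas = summary_stats(zs_to_records(vf, zG, n_gwas, eaf),
                                    "gwas_region", validate = FALSE),
         stats_qtl = summary_stats(zs_to_records(vf, zQ, n_qtl, eaf),
                                   "qtl_region", validate = FALSE),
         ld = ld, truth = truth)
  })
}

#' Simulate promoter sequence sets with planted motif occurrences
#'
#' Generates i.i.d. uniform-background promoter sequences for a target and a
#' background gene set; a configurable fraction of each set receives one
#' planted PWM-consensus occurrence at a uniform random position.
#'
#' @param n_target,n_background set sizes.
#' @param length promoter length in bp (must be >= motif length).
#' @param pwm a [pwm()] object whose consensus is planted.
#' @param plant_rate_target,plant_rate_background planting probabilities.
#' @param seed integer seed.
#' @return list with `target`/`background` (named character vectors of
#'   sequences) and `truth` (data.frame of planted positions).
#' @export
simulate_promoters <- function(n_target, n_background, length, pwm,
                               plant_rate_target, plant_rate_background,
                               seed = 1L) {
  stopifnot(inherits(pwm, "pwm"))
  L <- ncol(pwm$matrix)
  if (length < L) stopf("promoter length (%d) is shorter than the motif (%d)",
                        length, L)
  if (plant_rate_target < 0 || plant_rate_target > 1 ||
      plant_rate_background < 0 || plant_rate_background > 1)
    stopf("plant rates must be in [0, 1]")
  cons <- pwm_consensus(pwm)
  with_seed(seed, {
    gen_set <- function(nseq, rate, prefix) {
      seqs <- character(nseq)
      planted <- runif(nseq) < rate
      at <- rep(NA_integer_, nseq)
      for (i in seq_len(nseq)) {
        s <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
        if (planted[i]) {
          at[i] <- sample.int(length - L + 1L, 1L)
          s[at[i]:(at[i] + L - 1L)] <- strsplit(cons, "")[[1]]
        }
        seqs[i] <- paste(s, collapse = "")
      }
      names(seqs) <- sprintf("%s%03d", prefix, seq_len(nseq))
      list(seqs = seqs, planted = planted, at = at)
    }
    tg <- gen_set(n_target, plant_rate_target, "target_")
    bg <- gen_set(n_background, plant_rate_background, "bg_")
    truth <- data.frame(
      seq_id = c(names(tg$seqs), names(bg$seqs)),
      set = rep(c("target", "background"), c(n_target, n_background)),
      planted = c(tg$planted, bg$planted),
      position = c(tg$at, bg$at), stringsAsFactors = FALSE)
    list(target = tg$seqs, background = bg$seqs, truth = truth)
  })
}

#' Simulate a complete synthetic cross-trait study
#'
#' Builds the sex-stratified inputs for the full pipeline: female and male
#' GWAS for a disease trait and a hormone-related trait over AR(1) LD blocks,
#' with a configurable set of planted loci. Locus types: `shared_sexbias`
#' (causal for both traits, female-biased disease effect — colocalizing),
#' `shared_only` (causal for both, no sex bias), `sexbias_only` (disease
#' only, sex-biased), `null` (no effect). Additional hormone-only instrument
#' blocks provide genome-wide-significant instruments for the MR stage; their
#' disease effects equal `mr_true_effect` times the hormone effect.
#'
#' @param n_variants,block_size,ld_rho,n_gwas genome and sample dimensions.
#' @param loci data.frame with columns `type`, `block`, `fold` (female:male
#'   disease effect ratio for sex-biased types). Defaults to the five-locus
#'   design (2 shared+sex-biased, 1 shared-only, 1 sex-biased-only, 1 null).
#' @param gamma_disease,gamma_hormone planted standardized effect sizes.
#' @param n_instrument_blocks hormone-only instrument loci.
#' @param gamma_instrument hormone effect size at instrument loci.
#' @param mr_true_effect causal effect of the hormone trait on the disease
#'   trait propagated to instrument loci.
#' @param seed integer seed.
#' @return list with `ad_female`, `ad_male`, `hormone_female`, `hormone_male`
#'   (summary_stats), `ld` (`ld_blocks`), and `truth` (planted locus table,
#'   causal indices, instrument ids).
#' @export
simulate_study <- function(n_variants = 20000L, block_size = 50L, ld_rho = 0.2,
                           n_gwas = 1e5,
                           loci = NULL,
                           gamma_disease = 0.15, gamma_hormone = 0.1,
                           n_instrument_blocks = 30L,
                           gamma_instrument = 0.04, mr_true_effect = -0.1,
                           seed = 1L) {
  n <- as.integer(n_variants); m <- as.integer(block_size)
  stopifnot(n %% m == 0)
  nb <- n %/% m
  if (is.null(loci)) {
    pick <- round(seq(0.15, 0.85, length.out = 5) * nb)
    loci <- data.frame(type = c("shared_sexbias", "shared_sexbias",
                                "shared_only", "sexbias_only", "null"),
                       block = pick, fold = c(2, 2, 1, 2, 1),
                       stringsAsFactors = FALSE)
  }
  with_seed(seed, {
    vf <- variant_frame(n)
    blk <- block_index(n, m)
    gDF <- gDM <- gHF <- gHM <- numeric(n)   # disease/hormone x female/male
    loci$causal_index <- NA_integer_
    for (i in seq_len(nrow(loci))) {
      b <- loci$block[i]
      j <- which(blk == b)[m %/% 2L]         # causal variant mid-block
      loci$causal_index[i] <- j
      ty <- loci$type[i]; fold <- loci$fold[i]
      if (ty == "null") next
      if (ty %in% c("shared_sexbias", "sexbias_only")) {
        base <- gamma_disease * 2 / (1 + fold)
        gDM[j] <- base
        gDF[j] <- base * fold
      } else if (ty == "shared_only") {
        gDM[j] <- gDF[j] <- gamma_disease
      }
      if (ty %in% c("shared_sexbias", "shared_only")) {
        gHF[j] <- gHM[j] <- gamma_hormone
      }
    }
    # hormone-only instrument blocks, distinct from the planted loci
    free_blocks <- setdiff(seq_len(nb), loci$block)
    inst_blocks <- sort(sample(free_blocks, n_instrument_blocks))
    inst_idx <- integer(n_instrument_blocks)
    for (k in seq_along(inst_blocks)) {
      j <- which(blk == inst_blocks[k])[m %/% 2L]
      inst_idx[k] <- j
      gh <- gamma_instrument * sample(c(-1, 1), 1)
      gHF[j] <- gHM[j] <- gh
      gDF[j] <- gDF[j] + mr_true_effect * gh
      gDM[j] <- gDM[j] + mr_true_effect * gh
    }
    L <- t(ar1_chol(m, ld_rho))
    noise <- function() as.vector(L %*% matrix(rnorm(n), m, n %/% m))
    mk <- function(g, trait, sex) {
      mu <- sqrt(n_gwas) * blockwise_Rgamma(g, m, ld_rho)
      summary_stats(zs_to_records(vf, mu + noise(), n_gwas,
                                  runif(n, 0.05, 0.95)),
                    trait, sex, validate = FALSE)
    }
    list(ad_female = mk(gDF, "AD", "female"),
         ad_male = mk(gDM, "AD", "male"),
         hormone_female = mk(gHF, "hormone", "female"),
         hormone_male = mk(gHM, "hormone", "male"),
         ld = ld_blocks(blk, ld_rho, vf$variant_id),
         truth = list(loci = loci, instrument_index = inst_idx,
                      instrument_id = vf$variant_id[inst_idx],
                      gamma = list(disease_female = gDF, disease_male = gDM,
                                   hormone_female = gHF, hormone_male = gHM),
                      block = blk, variant_id = vf$variant_id,
                      mr_true_effect = mr_true_effect))
  })
}
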