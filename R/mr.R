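# Two-sample Mendelian randomization with the full estimator and
# sensitivity suite: IVW under a multiplicative random-effects model,
# MR-Egger (slope + directional-pleiotropy intercept), weighted median and
# weighted mode with parametric-bootstrap SEs, Cochran Q under both models,
# leave-one-out influence, a PRESSO-style simulated global pleiotropy test,
# sample-overlap SE adjustment, multivariable MR, and per-sex BH FDR.

#' Instrument selection configuration
#'
#' @param p_threshold genome-wide significance filter (default 5e-8).
#' @param clump_r2 LD independence threshold (default 0.001).
#' @export
instrument_config <- function(p_threshold = 5e-8, clump_r2 = 0.001) {
  stopifnot(p_threshold > 0, p_threshold < 1, clump_r2 > 0, clump_r2 < 1)
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2),
            class = "instrument_config")
}

#' Select independent genome-wide-significant instruments
#'
#' Filters exposure variants at `p < p_threshold`, then performs greedy
#' p-ranked clumping at `r2 < clump_r2`, keeping clump leads.
#'
#' @param exposure [summary_stats()] of the exposure trait.
#' @param ld [ld_matrix()] or `ld_blocks` covering the candidates.
#' @param config an [instrument_config()].
#' @return character vector of instrument variant IDs.
#' @export
select_instruments <- function(exposure, ld, config = instrument_config()) {
  rec <- exposure$records
  cand <- rec[rec$p < config$p_threshold, , drop = FALSE]
  if (!nrow(cand))
    stopf("no instruments for %s at p < %g", exposure$trait_label,
          config$p_threshold)
  cand <- cand[order(cand$p, cand$variant_id), , drop = FALSE]
  kept <- character(0)
  for (i in seq_len(nrow(cand))) {
    id <- cand$variant_id[i]
    if (!length(kept) ||
        all(ld_r2_lookup(ld, rep(id, length(kept)), kept) < config$clump_r2))
      kept <- c(kept, id)
  }
  kept
}

#' Harmonize exposure and outcome estimates over an instrument set
#'
#' Aligns outcome records to the exposure effect allele, drops palindromic
#' instruments (strand-ambiguous), and drops instruments absent from the
#' outcome with a log entry.
#'
#' @param exposure,outcome [summary_stats()] objects.
#' @param instruments character vector of instrument variant IDs.
#' @param verbose log dropped instruments?
#' @return A `harmonized_pair`: data.frame with per-instrument
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome` plus
#'   attributes `trait_exposure`, `trait_outcome`, `sex_stratum`.
#' @export
harmonize_pair <- function(exposure, outcome, instruments, verbose = TRUE) {
  ex <- exposure$records
  out <- outcome$records
  ex <- ex[match(instruments, ex$variant_id), , drop = FALSE]
  if (anyNA(ex$variant_id)) stopf("instruments missing from exposure stats")
  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  if (any(pal))
    pl_log(sprintf("harmonize: dropped %d palindromic instrument(s)", sum(pal)),
           verbose = verbose)
  ex <- ex[!pal, , drop = FALSE]
  i <- match(ex$variant_id, out$variant_id)
  if (anyNA(i))
    pl_log(sprintf("harmonize: %d instrument(s) absent from outcome dropped",
                   sum(is.na(i))), verbose = verbose)
  ex <- ex[!is.na(i), , drop = FALSE]
  oc <- out[i[!is.na(i)], , drop = FALSE]
  if (!nrow(ex)) stopf("all instruments lost during harmonization")
  oc <- align_to_reference(oc, ex$effect_allele, ex$other_allele)
  hp <- data.frame(variant_id = ex$variant_id,
                   beta_exposure = ex$beta, se_exposure = ex$se,
                   beta_outcome = oc$beta, se_outcome = oc$se,
                   stringsAsFactors = FALSE)
  structure(hp, class = c("harmonized_pair", "data.frame"),
            trait_exposure = exposure$trait_label,
            trait_outcome = outcome$trait_label,
            sex_stratum = exposure$sex_stratum,
            n_exposure = max(ex$n), n_outcome = max(oc$n))
}

#' Construct a harmonized pair directly from effect vectors
#' @param beta_exposure,se_exposure,beta_outcome,se_outcome numeric vectors.
#' @param variant_id optional IDs.
#' @rdname harmonize_pair
#' @export
harmonized_pair <- function(beta_exposure, se_exposure, beta_outcome,
                            se_outcome, variant_id = NULL) {
  k <- length(beta_exposure)
  stopifnot(k >= 1, all(se_exposure > 0), all(se_outcome > 0))
  structure(data.frame(
    variant_id = variant_id %||% paste0("iv", seq_len(k)),
    beta_exposure = beta_exposure, se_exposure = se_exposure,
    beta_outcome = beta_outcome, se_outcome = se_outcome,
    stringsAsFactors = FALSE),
    class = c("harmonized_pair", "data.frame"))
}

mr_result <- function(method, beta, se, k, q = NA_real_, q_df = NA_integer_,
                      q_p = NA_real_, egger_intercept = NA_real_,
                      egger_intercept_p = NA_real_, note = NA_character_) {
  ci <- beta + c(-1, 1) * qnorm(0.975) * se
  data.frame(method = method, beta_causal = beta, se = se,
             ci_low = ci[1], ci_high = ci[2],
             p = 2 * pnorm(-abs(beta / se)),
             or = exp(beta), or_low = exp(ci[1]), or_high = exp(ci[2]),
             n_instruments = k, q_statistic = q, q_df = q_df, q_p = q_p,
             egger_intercept = egger_intercept,
             egger_intercept_p = egger_intercept_p,
             note = note, stringsAsFactors = FALSE)
}

wald_ratios <- function(pair) {
  r <- pair$beta_outcome / pair$beta_exposure
  se <- pair$se_outcome / abs(pair$beta_exposure)   # first-order delta
  list(ratio = r, se = se, w = 1 / se^2)
}

#' Inverse-variance-weighted MR (multiplicative random effects)
#'
#' Weighted regression of outcome betas on exposure betas through the
#' origin with weights `1/se_outcome^2`; the SE is inflated by
#' `sqrt(max(Q/(k-1), 1))` (multiplicative overdispersion). A single
#' instrument reduces to the first-order Wald ratio and is flagged.
#'
#' @param pair a `harmonized_pair`.
#' @return one-row `MRResult` data.frame.
#' @export
mr_ivw <- function(pair) {
  k <- nrow(pair)
  if (all(pair$beta_exposure == 0)) stopf("all exposure betas are zero")
  w <- 1 / pair$se_outcome^2
  x <- pair$beta_exposure; y <- pair$beta_outcome
  b <- sum(w * x * y) / sum(w * x^2)
  se_fixed <- sqrt(1 / sum(w * x^2))
  if (k == 1)
    return(mr_result("IVW", b, se_fixed, 1L, note = "single-instrument Wald ratio"))
  Q <- sum(w * (y - b * x)^2)
  phi <- max(Q / (k - 1), 1)
  mr_result("IVW", b, se_fixed * sqrt(phi), k, Q, k - 1L,
            pchisq(Q, k - 1L, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure betas with an intercept,
#' after orienting instruments so `beta_exposure >= 0`. The slope is the
#' causal estimate; the intercept and its p-value test directional
#' pleiotropy. SEs use multiplicative random-effects scaling with `k - 2`
#' degrees of freedom; p-values use the normal approximation.
#'
#' @param pair a `harmonized_pair`.
#' @return one-row `MRResult` data.frame.
#' @export
mr_egger <- function(pair) {
  k <- nrow(pair)
  if (k < 3) stopf("MR-Egger requires at least 3 instruments")
  flip <- sign(pair$beta_exposure)
  flip[flip == 0] <- 1
  x <- pair$beta_exposure * flip; y <- pair$beta_outcome * flip
  w <- 1 / pair$se_outcome^2
  X <- cbind(intercept = 1, slope = x)
  A <- crossprod(X, w * X)
  cf <- solve(A, crossprod(X, w * y))
  resid <- y - X %*% cf
  Q <- sum(w * resid^2)
  phi <- max(Q / (k - 2), 1)
  V <- phi * solve(A)
  mr_result("Egger", cf["slope", 1], sqrt(V["slope", "slope"]), k,
            Q, k - 2L, pchisq(Q, k - 2L, lower.tail = FALSE),
            egger_intercept = cf["intercept", 1],
            egger_intercept_p = 2 * pnorm(-abs(cf["intercept", 1] /
                                                 sqrt(V["intercept", "intercept"]))))
}

weighted_median_est <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, rule = 2)$y
}

#' Weighted-median MR
#'
#' Weighted median of per-instrument Wald ratios with inverse-variance
#' weights; SE by seeded parametric bootstrap (ratio estimates redrawn from
#' their normal approximations). Consistent when instruments carrying at
#' least half the weight are valid.
#'
#' @param pair a `harmonized_pair`.
#' @param n_boot bootstrap draws (default 5000).
#' @param seed integer seed.
#' @return one-row `MRResult` data.frame.
#' @export
mr_weighted_median <- function(pair, n_boot = 5000L, seed = 1L) {
  k <- nrow(pair)
  if (k < 3) stopf("weighted median requires at least 3 instruments")
  wr <- wald_ratios(pair)
  est <- weighted_median_est(wr$ratio, wr$w)
  boot <- with_seed(seed, {
    draws <- matrix(rnorm(n_boot * k, wr$ratio, wr$se), k, n_boot)
    apply(draws, 2, weighted_median_est, w = wr$w)
  })
  mr_result("weighted_median", est, sd(boot), k)
}

weighted_mode_est <- function(r, w, bandwidth_factor = 1) {
  wm <- weighted_median_est(r, w)
  madw <- weighted_median_est(abs(r - wm), w) * 1.4826
  if (madw == 0) return(wm)
  h <- bandwidth_factor * 0.9 * madw * length(r)^(-1 / 5)
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 512)
  dens <- vapply(grid, function(g) sum(w * stats::dnorm((g - r) / h)), numeric(1))
  grid[which.max(dens)]
}

#' Weighted-mode MR
#'
#' Mode of the weighted Gaussian-kernel density of Wald ratios; bandwidth is
#' `bandwidth_factor` times a weighted-MAD default. SE by seeded parametric
#' bootstrap. Consistent when the largest group of instruments sharing a
#' ratio is valid (plurality validity).
#'
#' @param pair a `harmonized_pair`.
#' @param bandwidth_factor kernel bandwidth multiplier.
#' @param n_boot bootstrap draws.
#' @param seed integer seed.
#' @return one-row `MRResult` data.frame.
#' @export
mr_weighted_mode <- function(pair, bandwidth_factor = 1, n_boot = 5000L,
                             seed = 1L) {
  k <- nrow(pair)
  if (k < 3) stopf("weighted mode requires at least 3 instruments")
  wr <- wald_ratios(pair)
  est <- weighted_mode_est(wr$ratio, wr$w, bandwidth_factor)
  boot <- with_seed(seed, {
    draws <- matrix(rnorm(n_boot * k, wr$ratio, wr$se), k, n_boot)
    apply(draws, 2, weighted_mode_est, w = wr$w,
          bandwidth_factor = bandwidth_factor)
  })
  mr_result("weighted_mode", est, sd(boot), k)
}

#' Cochran Q heterogeneity statistic
#'
#' `Q = sum w_i (ratio_i - fit_i)^2` on first-order Wald-ratio weights,
#' with `df = k - 1` under IVW and `k - 2` under Egger.
#'
#' @param pair a `harmonized_pair`.
#' @param model `"ivw"` or `"egger"`.
#' @return list with `Q`, `df`, `p` (`p` omitted as `NA` when `df <= 0`).
#' @export
cochran_q <- function(pair, model = c("ivw", "egger")) {
  model <- match.arg(model)
  k <- nrow(pair)
  wr <- wald_ratios(pair)
  if (model == "ivw") {
    fit <- mr_ivw(pair)
    pred <- rep(fit$beta_causal, k)
    df <- k - 1L
  } else if (k == 2) {
    # two instruments: the Egger line fits exactly; Q = 0 with df = 0
    return(list(Q = 0, df = 0L, p = NA_real_))
  } else {
    fit <- mr_egger(pair)
    flip <- sign(pair$beta_exposure); flip[flip == 0] <- 1
    # ratio-scale prediction: slope + intercept / |beta_exposure|
    pred <- fit$beta_causal + fit$egger_intercept / (pair$beta_exposure * flip)
    df <- k - 2L
  }
  Q <- sum(wr$w * (wr$ratio - pred)^2)
  list(Q = Q, df = df,
       p = if (df > 0) pchisq(Q, df, lower.tail = FALSE) else NA_real_)
}

#' Leave-one-out IVW analysis
#'
#' Refits IVW excluding each instrument in turn and flags instruments whose
#' removal shifts the estimate by more than one (full-fit) SE or flips
#' significance at 0.05.
#'
#' @param pair a `harmonized_pair`.
#' @return data.frame with one row per excluded instrument.
#' @export
leave_one_out <- function(pair) {
  k <- nrow(pair)
  if (k < 3) stopf("leave-one-out requires at least 3 instruments")
  full <- mr_ivw(pair)
  rows <- lapply(seq_len(k), function(i) {
    fit <- mr_ivw(pair[-i, , drop = FALSE])
    data.frame(excluded = pair$variant_id[i], beta_causal = fit$beta_causal,
               se = fit$se, p = fit$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  # shift judged against the refit SE: the full-fit SE is overdispersion-
  # inflated by the very instrument under scrutiny
  res$flag <- abs(res$beta_causal - full$beta_causal) > res$se |
    ((res$p < 0.05) != (full$p < 0.05))
  attr(res, "full_estimate") <- full$beta_causal
  res
}

# leave-one-out IVW slopes for an n_sim x k matrix of outcome betas
loo_slopes_matrix <- function(Y, x, w) {
  sxx <- sum(w * x^2)
  wxy <- sweep(Y, 2, w * x, "*")         # n_sim x k of w_i x_i y_i
  sxy <- rowSums(wxy)
  sweep(-wxy, 1, sxy, "+") / (sxx - rep(w * x^2, each = nrow(Y)))
}

#' PRESSO-style global pleiotropy test
#'
#' Observed statistic: weighted residual sum of squares of outcome betas
#' about leave-one-out IVW predictions. The null distribution is obtained by
#' parametric simulation of outcome betas around the leave-one-out fitted
#' values with the observed SEs; the global p is the fraction of simulated
#' RSS at or above the observed RSS.
#'
#' @param pair a `harmonized_pair` (>= 4 instruments).
#' @param n_sim simulated datasets (default 1000).
#' @param seed integer seed.
#' @return list with `rss_observed`, `rss_null` summary, `p`.
#' @export
presso_global <- function(pair, n_sim = 1000L, seed = 1L) {
  k <- nrow(pair)
  if (k < 4) stopf("the global test requires at least 4 instruments")
  x <- pair$beta_exposure; y <- pair$beta_outcome
  w <- 1 / pair$se_outcome^2
  b_loo <- as.vector(loo_slopes_matrix(matrix(y, 1), x, w))
  rss_obs <- sum(w * (y - b_loo * x)^2)
  rss_sim <- with_seed(seed, {
    Y <- matrix(rnorm(n_sim * k, mean = rep(b_loo * x, each = n_sim),
                      sd = rep(pair$se_outcome, each = n_sim)), n_sim, k)
    B <- loo_slopes_matrix(Y, x, w)
    rowSums(sweep((Y - sweep(B, 2, x, "*"))^2, 2, w, "*"))
  })
  list(rss_observed = rss_obs,
       rss_null = c(mean = mean(rss_sim), sd = sd(rss_sim),
                    q95 = unname(quantile(rss_sim, 0.95))),
       p = mean(rss_sim >= rss_obs), n_sim = n_sim)
}

#' Sample-overlap-adjusted IVW
#'
#' Keeps the IVW point estimate and inflates the SE for correlation between
#' instrument-exposure and instrument-outcome errors induced by overlapping
#' samples. The induced correlation is
#' `c = overlap_fraction * min(nE, nO) / sqrt(nE * nO) * phenotype_corr`,
#' propagated through the Wald-ratio variance with worst-case sign:
#' `se_ratio = (se_out + c * se_exp * |ratio|) / |beta_exp|`, a conservative
#' upper bound that reduces to the unadjusted first-order SE at zero
#' overlap and is monotone in the overlap fraction.
#'
#' @param pair a `harmonized_pair`.
#' @param overlap_fraction fraction of the smaller GWAS shared (in `[0, 1]`).
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param phenotype_corr assumed phenotypic correlation among shared
#'   participants (default 0.2).
#' @return one-row `MRResult` data.frame; the assumptions are stamped into
#'   the `note` field.
#' @export
overlap_adjusted_ivw <- function(pair, overlap_fraction, n_exposure,
                                 n_outcome, phenotype_corr = 0.2) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1)
  base <- mr_ivw(pair)
  cc <- overlap_fraction * (min(n_exposure, n_outcome) /
                              sqrt(n_exposure * n_outcome)) * phenotype_corr
  wr <- wald_ratios(pair)
  se_adj <- (pair$se_outcome + cc * pair$se_exposure * abs(wr$ratio)) /
    abs(pair$beta_exposure)
  w_unadj <- wr$w
  # variance of the weighted combination with unadjusted weights
  var_b <- sum(w_unadj^2 * se_adj^2) / sum(w_unadj)^2
  phi <- max(base$q_statistic / max(nrow(pair) - 1, 1), 1, na.rm = TRUE)
  out <- mr_result("IVW_overlap_adjusted", base$beta_causal,
                   sqrt(var_b * phi), nrow(pair),
                   base$q_statistic, base$q_df, base$q_p,
                   note = sprintf(
                     "overlap=%g, phen_corr=%g, induced_corr=%.4g",
                     overlap_fraction, phenotype_corr, cc))
  out
}

#' Multivariable IVW MR
#'
#' Weighted multivariable regression of outcome betas on the matrix of
#' exposure betas, no intercept, weights `1/se_outcome^2`; per-exposure
#' conditional estimates with multiplicative random-effects scaling
#' (`df = k - p`).
#'
#' @param outcome [summary_stats()] of the outcome.
#' @param exposures named list of exposure [summary_stats()].
#' @param instruments union set of instrument variant IDs.
#' @return data.frame with one `MRResult` row per exposure.
#' @export
mvmr_ivw <- function(outcome, exposures, instruments) {
  stopifnot(length(exposures) >= 2)
  labels <- names(exposures) %||% paste0("exposure", seq_along(exposures))
  first <- exposures[[1]]$records
  ids <- instruments
  for (ex in exposures) ids <- intersect(ids, ex$records$variant_id)
  ids <- intersect(ids, outcome$records$variant_id)
  k <- length(ids); p <- length(exposures)
  if (k < p + 1) stopf("need at least %d harmonized instruments, have %d",
                       p + 1, k)
  ref <- first[match(ids, first$variant_id), , drop = FALSE]
  X <- sapply(exposures, function(ex) {
    r <- ex$records[match(ids, ex$records$variant_id), , drop = FALSE]
    r <- align_to_reference(r, ref$effect_allele, ref$other_allele)
    r$beta
  })
  oc <- outcome$records[match(ids, outcome$records$variant_id), , drop = FALSE]
  oc <- align_to_reference(oc, ref$effect_allele, ref$other_allele)
  y <- oc$beta
  w <- 1 / oc$se^2
  # an exposure with no instrument effects contributes nothing: drop it from
  # the fit (its conditional estimate is undefined) rather than failing
  zero_col <- colSums(X != 0) == 0
  Xf <- X[, !zero_col, drop = FALSE]
  pf <- ncol(Xf)
  if (pf == 0) stopf("all exposure betas are zero")
  qrX <- qr(Xf)
  if (qrX$rank < pf) {
    bad <- labels[!zero_col][qrX$pivot[(qrX$rank + 1):pf]]
    stopf("exposure beta matrix is rank deficient (collinear: %s)",
          paste(bad, collapse = ", "))
  }
  A <- crossprod(Xf, w * Xf)
  cf <- solve(A, crossprod(Xf, w * y))
  resid <- y - Xf %*% cf
  Q <- sum(w * resid^2)
  phi <- max(Q / (k - pf), 1)
  V <- phi * solve(A)
  fit_lab <- labels[!zero_col]
  res <- do.call(rbind, lapply(seq_len(pf), function(j)
    mr_result(paste0("MVMR_IVW:", fit_lab[j]), cf[j], sqrt(V[j, j]), k,
              Q, as.integer(k - pf), pchisq(Q, k - pf, lower.tail = FALSE))))
  res$exposure <- fit_lab
  if (any(zero_col)) {
    na_rows <- do.call(rbind, lapply(labels[zero_col], function(l)
      mr_result(paste0("MVMR_IVW:", l), NA_real_, NA_real_, k,
                note = "all instrument effects zero; dropped from fit")))
    na_rows$exposure <- labels[zero_col]
    res <- rbind(res, na_rows)
  }
  res
}

#' Benjamini-Hochberg FDR adjustment within a family
#'
#' Families are per sex stratum: all exposure traits tested against the
#' outcome within one sex form one family.
#'
#' @param p p-values in (0, 1].
#' @param family optional family label(s); adjustment is applied within each
#'   family separately.
#' @return adjusted p-values (same order as input).
#' @export
bh_fdr <- function(p, family = NULL) {
  if (any(p <= 0 | p > 1)) stopf("p-values must be in (0, 1]")
  if (is.null(family)) return(p.adjust(p, method = "BH"))
  out <- numeric(length(p))
  for (f in unique(family)) {
    i <- family == f
    out[i] <- p.adjust(p[i], method = "BH")
  }
  out
}

#' Run the full MR estimator and sensitivity suite for one pair
#'
#' @param pair a `harmonized_pair`.
#' @param n_boot bootstrap draws for median/mode.
#' @param n_sim PRESSO simulations.
#' @param seed integer seed.
#' @return list with `estimates` (IVW/Egger/median/mode table), `q_ivw`,
#'   `q_egger`, `presso`, `loo`.
#' @export
mr_all <- function(pair, n_boot = 5000L, n_sim = 1000L, seed = 1L) {
  est <- rbind(mr_ivw(pair), mr_egger(pair),
               mr_weighted_median(pair, n_boot, seed),
               mr_weighted_mode(pair, 1, n_boot, seed + 1L))
  list(estimates = est,
       q_ivw = cochran_q(pair, "ivw"),
       q_egger = cochran_q(pair, "egger"),
       presso = presso_global(pair, n_sim, seed + 2L),
       loo = leave_one_out(pair))
}
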