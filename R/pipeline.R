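# End-to-end orchestration: simulate or load inputs, then enrichment ->
# conjFDR -> clump/tier -> colocalization -> motif -> MR, with plain-text
# stage artifacts so any stage can be rerun or audited standalone.

pkg_version <- function() as.character(utils::packageVersion("pleiomr"))

# polynomial rolling hash over the serialized config; stable, cheap, no deps
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 268435399
  sprintf("%07x", h)
}

stage_header <- function(config) {
  c(sprintf("pleiomr %s", pkg_version()),
    sprintf("seed=%d", config$seed),
    sprintf("config_hash=%s", config$hash))
}

write_stage_tsv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", stage_header(config)), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    cols <- lapply(df, function(v)
      if (is.numeric(v)) format(v, digits = 17, trim = TRUE) else as.character(v))
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

read_stage_tsv <- function(path) {
  data.table::fread(path, skip = "\t", header = TRUE, data.table = FALSE)
}

#' Pipeline run configuration
#'
#' Exactly one of `simulate` (arguments for [simulate_study()]) or
#' `manifest` (named file paths: `ad_female`, `ad_male`, `hormone_female`,
#' `hormone_male`, optionally `known_loci`, `pwm`) must be given.
#'
#' @param out_dir output directory for stage artifacts.
#' @param seed master seed; recorded in every output header and used to
#'   derive all stage seeds.
#' @param simulate list of [simulate_study()] arguments (or `TRUE` for the
#'   defaults).
#' @param manifest named list of input file paths.
#' @param tier a [tier_config()].
#' @param priors a [coloc_priors()].
#' @param motif a [motif_config()].
#' @param instruments an [instrument_config()].
#' @param control_secondary optional label of a negative-control secondary
#'   trait in the manifest whose enrichment is reported side-by-side.
#' @export
run_config <- function(out_dir, seed = 1L, simulate = TRUE, manifest = NULL,
                       tier = tier_config(), priors = coloc_priors(),
                       motif = motif_config(),
                       instruments = instrument_config(),
                       control_secondary = NULL) {
  if (!is.null(manifest) && !isFALSE(simulate) && !isTRUE(simulate))
    stopf("give either simulation arguments or a manifest, not both")
  if (is.null(manifest) && isFALSE(simulate))
    stopf("one of simulate / manifest is required")
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              simulate = if (is.null(manifest)) (if (isTRUE(simulate)) list() else simulate),
              manifest = manifest, tier = tier, priors = priors,
              motif = motif, instruments = instruments,
              control_secondary = control_secondary)
  cfg$hash <- config_hash(cfg[setdiff(names(cfg), "out_dir")])
  structure(cfg, class = "run_config")
}

stage_path <- function(config, name) file.path(config$out_dir, name)

stage_done <- function(config, name, resume)
  resume && file.exists(stage_path(config, name))

load_study_inputs <- function(config) {
  if (!is.null(config$manifest)) {
    m <- config$manifest
    need <- c("ad_female", "ad_male", "hormone_female", "hormone_male")
    miss <- setdiff(need, names(m))
    if (length(miss)) stopf("manifest missing: %s", paste(miss, collapse = ", "))
    study <- list(
      ad_female = read_sumstats(m$ad_female, trait_label = "AD", sex_stratum = "female"),
      ad_male = read_sumstats(m$ad_male, trait_label = "AD", sex_stratum = "male"),
      hormone_female = read_sumstats(m$hormone_female, trait_label = "hormone",
                                     sex_stratum = "female"),
      hormone_male = read_sumstats(m$hormone_male, trait_label = "hormone",
                                   sex_stratum = "male"))
    if (!is.null(m$ld_rho)) {
      bs <- m$ld_block_size %||% 50L
      n <- n_variants(study$ad_female)
      study$ld <- ld_blocks(block_index(n, bs), m$ld_rho,
                            study$ad_female$records$variant_id)
    } else stopf("manifest must give ld_rho/ld_block_size for LD structure")
    study$truth <- NULL
    study
  } else {
    do.call(simulate_study, c(config$simulate, list(seed = config$seed)))
  }
}

#' Run the full pipeline
#'
#' Executes simulate/load -> enrichment -> conjFDR -> clump/tier ->
#' cross-trait and QTL colocalization -> motif enrichment -> MR, writing
#' each stage as TSV under the configured output directory. With
#' `resume = TRUE`, stages whose artifact already exists are skipped, and
#' downstream stages read the artifacts from disk.
#'
#' @param config a [run_config()].
#' @param resume skip stages whose outputs exist?
#' @param verbose log stage progress?
#' @return the run report (invisibly also written as JSON).
#' @export
run_all <- function(config, resume = FALSE, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- load_study_inputs(config)
  seed <- config$seed

  # stage 1: input summary stats on disk
  for (nm in c("ad_female", "ad_male", "hormone_female", "hormone_male")) {
    f <- stage_path(config, paste0("01_", nm, ".tsv"))
    if (!(resume && file.exists(f)))
      write_sumstats(study[[nm]], f, header_lines = stage_header(config))
  }

  # stage 2: conditional QQ fold enrichment, per sex (+ optional control)
  f_enr <- stage_path(config, "02_enrichment.tsv")
  if (!stage_done(config, "02_enrichment.tsv", resume)) {
    pl_log("stage 2: fold enrichment", verbose = verbose)
    enr <- rbind(
      cbind(sex = "female", pair = "AD|hormone",
            fold_enrichment(study$ad_female, study$hormone_female)),
      cbind(sex = "male", pair = "AD|hormone",
            fold_enrichment(study$ad_male, study$hormone_male)))
    write_stage_tsv(enr, f_enr, config)
  }

  # stage 3: conjFDR per sex-matched pair
  f_cj <- c(female = stage_path(config, "03_conjfdr_female.tsv"),
            male = stage_path(config, "03_conjfdr_male.tsv"))
  if (!(resume && all(file.exists(f_cj)))) {
    pl_log("stage 3: condFDR/conjFDR", verbose = verbose)
    cjF <- conjfdr_table(study$ad_female, study$hormone_female, study$ld,
                         seed = seed + 11L)
    cjM <- conjfdr_table(study$ad_male, study$hormone_male, study$ld,
                         seed = seed + 12L)
    write_stage_tsv(cjF, f_cj[["female"]], config)
    write_stage_tsv(cjM, f_cj[["male"]], config)
  }
  cjF <- read_stage_tsv(f_cj[["female"]])

  # stage 4: clump + tiers (female-matched analysis drives prioritization)
  f_tier <- stage_path(config, "04_tiers.tsv")
  if (!stage_done(config, "04_tiers.tsv", resume)) {
    pl_log("stage 4: clumping and tier assignment", verbose = verbose)
    hits <- cjF[cjF$pleiotropic, , drop = FALSE]
    if (nrow(hits)) {
      clumps <- ld_clump(hits, study$ld, config$tier$clump_r2)
      effects <- data.frame(
        variant_id = study$ad_female$records$variant_id,
        beta_women = study$ad_female$records$beta,
        se_women = study$ad_female$records$se,
        beta_men = study$ad_male$records$beta,
        se_men = study$ad_male$records$se, stringsAsFactors = FALSE)
      coloc_res <- clump_coloc(clumps, study, config)
      tiers <- assign_tiers(clumps, effects, coloc_res, config$tier)
      if (!is.null(config$manifest$known_loci)) {
        known <- utils::read.table(config$manifest$known_loci, header = FALSE,
                                   col.names = c("chrom", "pos"))
        tiers <- annotate_novelty(tiers, known, config$tier$novelty_window)
      } else tiers$novel <- NA
      write_stage_tsv(tiers, f_tier, config)
      write_loci_bed(tiers, stage_path(config, "04_tiers.bed"))
    } else {
      empty <- data.frame(lead_variant_id = character(0), chrom = character(0),
                          pos = integer(0), n_members = integer(0),
                          members = character(0), tier = integer(0),
                          sex_bias_direction = character(0),
                          coloc_pp4 = numeric(0), conjfdr = numeric(0),
                          novel = logical(0))
      write_stage_tsv(empty, f_tier, config)
    }
  }
  tiers <- read_stage_tsv(f_tier)

  # stage 5: QTL colocalization at Tier-1 loci (synthetic QTL panel when
  # no manifest datasets are supplied)
  f_qtl <- stage_path(config, "05_qtl_coloc.tsv")
  if (!stage_done(config, "05_qtl_coloc.tsv", resume)) {
    pl_log("stage 5: QTL colocalization", verbose = verbose)
    qtl <- qtl_stage(tiers, study, config)
    write_stage_tsv(qtl, f_qtl, config)
    if (nrow(qtl))
      write_stage_tsv(best_pp4_by_category(qtl),
                      stage_path(config, "05_qtl_best_by_category.tsv"), config)
  }

  # stage 6: motif enrichment on promoter sets of sex-biased genes
  f_mot <- stage_path(config, "06_motif_enrichment.tsv")
  if (!stage_done(config, "06_motif_enrichment.tsv", resume)) {
    pl_log("stage 6: motif enrichment", verbose = verbose)
    pwms <- if (!is.null(config$manifest$pwm)) read_jaspar(config$manifest$pwm)
    else read_jaspar(system.file("extdata", "synthetic_hormone_motifs.jaspar",
                                 package = "pleiomr"))
    pro <- simulate_promoters(20, 60, 1300, pwms[[1]],
                              plant_rate_target = 0.6,
                              plant_rate_background = 0.05,
                              seed = seed + 31L)
    rep6 <- motif_enrichment_report(pro$target, pro$background, pwms,
                                    config$motif)
    write_stage_tsv(rep6, f_mot, config)
  }

  # stage 7: sex-matched MR, hormone -> disease, with per-sex BH FDR
  f_mr <- stage_path(config, "07_mr.tsv")
  if (!stage_done(config, "07_mr.tsv", resume)) {
    pl_log("stage 7: Mendelian randomization", verbose = verbose)
    mr_rows <- list()
    for (sex in c("female", "male")) {
      expo <- study[[paste0("hormone_", sex)]]
      outc <- study[[paste0("ad_", sex)]]
      iv <- select_instruments(expo, study$ld, config$instruments)
      pair <- harmonize_pair(expo, outc, iv, verbose = verbose)
      res <- mr_all(pair, n_boot = 1000L, n_sim = 500L, seed = seed + 41L)
      est <- res$estimates
      est$sex <- sex
      est$presso_p <- res$presso$p
      mr_rows[[sex]] <- est
    }
    mr_tab <- do.call(rbind, mr_rows)
    ivw <- mr_tab$method == "IVW"
    mr_tab$fdr_p <- NA_real_
    mr_tab$fdr_p[ivw] <- bh_fdr(mr_tab$p[ivw], mr_tab$sex[ivw])
    write_stage_tsv(mr_tab, f_mr, config)
  }
  mr_tab <- read_stage_tsv(f_mr)

  report <- build_report(config, cjF, tiers, mr_tab)
  jsonlite::write_json(report, stage_path(config, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

# cross-trait coloc per clump over its LD block neighborhood
clump_coloc <- function(clumps, study, config) {
  leads <- unique(clumps$clump)
  ids_all <- study$ld$variant_ids
  rows <- lapply(leads, function(lead) {
    i <- match(lead, ids_all)
    b <- study$ld$block[i]
    sel <- which(study$ld$block == b)
    ids <- ids_all[sel]
    slice <- function(st) {
      st$records <- st$records[match(ids, st$records$variant_id), , drop = FALSE]
      st
    }
    res <- coloc_posteriors(slice(study$ad_female), slice(study$hormone_female),
                            config$priors)
    data.frame(clump = lead, pp4 = res$pp[["pp4"]],
               top_shared_variant_id = res$top_shared_variant_id,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# synthetic xQTL panel at Tier-1 loci: per category, one colocalizing and
# one non-colocalizing dataset region (stands in for manifest QTL data)
qtl_stage <- function(tiers, study, config) {
  t1 <- tiers[tiers$tier == 1L, , drop = FALSE]
  if (!nrow(t1)) return(data.frame())
  categories <- c("brain-tissue", "brain-cell", "other-tissue", "pQTL",
                  "mQTL", "caQTL")
  rows <- list()
  for (i in seq_len(nrow(t1))) {
    for (k in seq_along(categories)) {
      mode <- if (k %% 2 == 1) "shared" else "null"
      sim <- simulate_qtl_region(100, 0.6, 1e5, 5e4, mode = mode,
                                 causal_var_explained = 0.005,
                                 seed = config$seed + 100L + i * 10L + k)
      res <- qtl_coloc_scan(sim$stats_gwas, list(list(
        label = paste0(categories[k], "_ds1"), category = categories[k],
        feature = paste0("gene_", t1$lead_variant_id[i]),
        stats = sim$stats_qtl)), config$priors)
      res$locus <- t1$lead_variant_id[i]
      rows[[length(rows) + 1L]] <- res
    }
  }
  do.call(rbind, rows)
}

build_report <- function(config, conjfdr_tab, tiers, mr_tab) {
  tier_counts <- if (nrow(tiers))
    c(tier3 = nrow(tiers), tier2 = sum(tiers$tier <= 2),
      tier1 = sum(tiers$tier == 1)) else c(tier3 = 0, tier2 = 0, tier1 = 0)
  list(package = "pleiomr", version = pkg_version(), seed = config$seed,
       config_hash = config$hash,
       n_pleiotropic_variants = sum(conjfdr_tab$pleiotropic),
       n_signals = unname(tier_counts["tier3"]),
       tier_counts = as.list(tier_counts),
       sex_bias_directions = if (nrow(tiers))
         as.list(table(tiers$sex_bias_direction)) else list(),
       novel_loci = if (nrow(tiers)) sum(tiers$novel %in% TRUE) else 0,
       mr_ivw = if (nrow(mr_tab)) {
         ivw <- mr_tab[mr_tab$method == "IVW", , drop = FALSE]
         lapply(seq_len(nrow(ivw)), function(i)
           list(sex = ivw$sex[i], or = ivw$or[i], ci_low = ivw$or_low[i],
                ci_high = ivw$or_high[i], fdr_p = ivw$fdr_p[i]))
       } else list())
}

#' Robustness check of lead-variant effects against alternate outcome stats
#'
#' Compares primary and alternate effect estimates at each lead variant:
#' sign concordance, effect ratio, and a heterogeneity z between the two
#' estimates.
#'
#' @param loci data.frame with `lead_variant_id` (e.g. Tier-1 rows).
#' @param primary_stats,alternate_stats [summary_stats()] covering the leads.
#' @return data.frame, one row per lead; missing leads are flagged.
#' @export
robustness_check <- function(loci, primary_stats, alternate_stats) {
  pr <- primary_stats$records; al <- alternate_stats$records
  rows <- lapply(loci$lead_variant_id, function(id) {
    i <- match(id, pr$variant_id); j <- match(id, al$variant_id)
    if (is.na(i) || is.na(j))
      return(data.frame(lead_variant_id = id, beta_primary = NA_real_,
                        beta_alternate = NA_real_, sign_concordant = NA,
                        ratio = NA_real_, het_z = NA_real_, missing = TRUE))
    b1 <- pr$beta[i]; b2 <- al$beta[j]
    if (!is.na(j)) {
      alr <- align_to_reference(al[j, , drop = FALSE],
                                pr$effect_allele[i], pr$other_allele[i])
      b2 <- alr$beta
      s2 <- alr$se
    }
    z <- (b1 - b2) / sqrt(pr$se[i]^2 + s2^2)
    data.frame(lead_variant_id = id, beta_primary = b1, beta_alternate = b2,
               sign_concordant = sign(b1) == sign(b2),
               ratio = b2 / b1, het_z = z, missing = FALSE)
  })
  do.call(rbind, rows)
}
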