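#' Pipeline configuration
#'
#' Bundles every stage's parameters. Exactly one of `sim` (a
#' [sim_config()]) or `paths` (a named list with `ped_path`, `map_path` or
#' `vcf_path`, `pedigree_path`, `phenotype_path`) must be supplied.
#'
#' @param sim a [sim_config()] for synthetic input, or NULL.
#' @param paths named list of input file paths, or NULL.
#' @param h2 heritability used for BLUP and deregression (default 0.16).
#' @param fixed fixed-effects formula for the animal model.
#' @param qc named list of [qc_filter()] thresholds.
#' @param rf named list: `n_trees`, `mtry_fraction`, `importance`.
#' @param fraction selection fraction per stage (default 0.01).
#' @param subsamples named list: `n`, `size` (NULL size = half the
#'   genotyped animals, as in the 396 -> 198 design).
#' @param strategy `"both"`, `"common"` or `"highest1"`.
#' @param min_subsample_hits membership rule of the Common-SNP strategy.
#' @param stepwise named list: `sl_entry`, `sl_stay`.
#' @param n_permutations permutation count (default 1000).
#' @param perm_statistic `"adjusted"`, `"raw"` or `"stepwise"`.
#' @param half_width_bp annotation window half-width (default 250000).
#' @param features optional feature-interval data frame or file path.
#' @param n_genotyped,sex_split genotyping-subset size and (M, F) split;
#'   defaults 400 and c(196, 204).
#' @param deregress named list: `c_frac`, `mode`, `r2_floor`.
#' @param out_dir output directory (NULL = nothing written).
#' @param seed master seed; per-stage seeds derive from it via
#'   [stage_seeds()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, paths = NULL, h2 = 0.16,
                            fixed = ~ cg + age,
                            qc = list(), rf = list(), fraction = 0.01,
                            subsamples = list(n = 10, size = NULL),
                            strategy = c("both", "common", "highest1"),
                            min_subsample_hits = 1,
                            stepwise = list(sl_entry = 0.15, sl_stay = 0.15),
                            n_permutations = 1000,
                            perm_statistic = "adjusted",
                            half_width_bp = 250000, features = NULL,
                            n_genotyped = 400, sex_split = c(196, 204),
                            deregress = list(c_frac = 0.5, mode = "full",
                                             r2_floor = 0.1),
                            out_dir = NULL, seed = 1L) {
  strategy <- match.arg(strategy)
  if (is.null(sim) == is.null(paths))
    stopf("supply exactly one of `sim` or `paths`")
  qc <- utils::modifyList(list(sample_call_rate_min = 0.90,
                               snp_call_rate_min = 0.90, maf_min = 0.01,
                               het_sd_limit = 3), qc)
  rf <- utils::modifyList(list(n_trees = 5000, mtry_fraction = 0.10,
                               importance = "permutation"), rf)
  subsamples <- utils::modifyList(list(n = 10, size = NULL), subsamples)
  stepwise <- utils::modifyList(list(sl_entry = 0.15, sl_stay = 0.15),
                                stepwise)
  deregress <- utils::modifyList(list(c_frac = 0.5, mode = "full",
                                      r2_floor = 0.1), deregress)
  structure(list(sim = sim, paths = paths, h2 = h2, fixed = fixed, qc = qc,
                 rf = rf, fraction = fraction, subsamples = subsamples,
                 strategy = strategy, min_subsample_hits = min_subsample_hits,
                 stepwise = stepwise, n_permutations = n_permutations,
                 perm_statistic = perm_statistic,
                 half_width_bp = half_width_bp, features = features,
                 n_genotyped = n_genotyped, sex_split = sex_split,
                 deregress = deregress, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_log <- function(con, stage, fmt, ...) {
  msg <- sprintf("[%s] [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 stage, sprintf(fmt, ...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full association pipeline
#'
#' Executes, in order: data simulation (or ingestion), A-matrix and
#' animal-model BLUP, deregression, genotype QC and median imputation,
#' two-step random-forest selection on the full genotyped sample and on the
#' kinship-minimizing subsamples, the Common-SNP and/or Highest-1%
#' strategies, forward stepwise regression with the permutation bias test,
#' and LD-window annotation. Fully deterministic given the master seed.
#'
#' @param config a [pipeline_config()].
#' @return object of class `run_report`: list with `summary` (one row per
#'   strategy: candidate count, final count, % dEBV variance, permutation
#'   mean/SD), `snp_table` (per final SNP: id, chr, pos, % dEBV, overlapping
#'   features), `counts` (per-stage record counts), `config`, and
#'   intermediate artifacts (`debv`, `qc_report`, `candidates`, `fits`,
#'   `windows`, `annotation`, `ld`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- stage_seeds(config$seed, 8)
  logcon <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    logcon <- file(file.path(config$out_dir, "pipeline.log"), "w")
    on.exit(close(logcon))
  }
  counts <- list()

  # -- stage 1: inputs -------------------------------------------------
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- seeds[1]
    class(sim) <- "sim_config"
    pipeline_log(logcon, "simulate", "pedigree/genotypes/phenotypes (seed %d)",
                 seeds[1])
    ped <- simulate_pedigree(sim)
    geno_all <- simulate_genotypes(ped, sim)
    arch <- trait_architecture(geno_all, sim)
    phen <- simulate_phenotypes(ped, geno_all, arch, sim)
  } else {
    p <- config$paths
    pipeline_log(logcon, "ingest", "reading pedigree/genotypes/phenotypes")
    ped <- read_pedigree(p$pedigree_path)
    geno_all <- if (!is.null(p$vcf_path)) read_vcf_genotypes(p$vcf_path)
                else read_plink(p$ped_path, p$map_path)
    phen <- read_table_tsv(p$phenotype_path)
    arch <- NULL
  }
  counts$pedigree <- nrow(ped)
  counts$phenotyped <- nrow(phen)

  # -- stage 2: BLUP + deregression ------------------------------------
  pipeline_log(logcon, "blup", "animal model on %d records, h2 = %.2f",
               nrow(phen), config$h2)
  A <- build_a_matrix(ped)
  fit <- solve_animal_model(phen, config$fixed, ped, h2 = config$h2)
  debv <- deregress_ebv(fit, ped, c_frac = config$deregress$c_frac,
                        mode = config$deregress$mode,
                        r2_floor = config$deregress$r2_floor)

  # -- stage 3: genotyping subset + QC + imputation --------------------
  if (!is.null(config$sim)) {
    cohort <- ped$animal[ped$cohort %||% rep(TRUE, nrow(ped))]
    n_want <- min(config$n_genotyped, length(cohort))
    split <- config$sex_split
    if (sum(split) != n_want) {
      nm <- round(n_want * split[1] / sum(split))
      split <- c(nm, n_want - nm)
    }
    genotyped_ids <- tryCatch(
      select_genotyping_subset(cohort, fit, ped, n_want, split),
      error = function(e) {
        pipeline_log(logcon, "subset",
                     "sex split infeasible (%s); taking top accuracy",
                     conditionMessage(e))
        acc <- fit$ebv$accuracy[match(cohort, fit$ebv$animal)]
        cohort[order(-acc)][seq_len(n_want)]
      })
    geno <- geno_all[genotyped_ids, ]
  } else {
    geno <- geno_all
  }
  qc <- qc_filter(geno, config$qc$sample_call_rate_min,
                  config$qc$snp_call_rate_min, config$qc$maf_min,
                  config$qc$het_sd_limit)
  pipeline_log(logcon, "qc", "samples %d -> %d, SNPs %d -> %d",
               attr(qc$report, "n_before")["samples"],
               attr(qc$report, "n_after")["samples"],
               attr(qc$report, "n_before")["snps"],
               attr(qc$report, "n_after")["snps"])
  geno_i <- impute_median(qc$genotypes)
  counts$genotyped <- nrow(geno_i$geno)
  counts$snps_post_qc <- ncol(geno_i$geno)
  ids <- rownames(geno_i$geno)
  y <- debv$debv[match(ids, debv$animal)]
  keep <- !is.na(y) & !debv$excluded[match(ids, debv$animal)]
  if (!all(keep)) {
    pipeline_log(logcon, "debv", "dropping %d animals with no usable dEBV",
                 sum(!keep))
    geno_i <- geno_i[keep, ]
    ids <- ids[keep]
    y <- y[keep]
  }

  # -- stage 4: RF selection -------------------------------------------
  pipeline_log(logcon, "rf", "two-step selection: %d animals x %d SNPs, %d trees",
               length(ids), ncol(geno_i$geno), config$rf$n_trees)
  full_run <- two_step_select(geno_i, y, fraction = config$fraction,
                              n_trees = config$rf$n_trees,
                              mtry_fraction = config$rf$mtry_fraction,
                              importance = config$rf$importance,
                              seed = seeds[2])
  strategies <- list()
  if (config$strategy %in% c("both", "highest1"))
    strategies$highest1 <- full_run
  if (config$strategy %in% c("both", "common")) {
    sub_size <- config$subsamples$size %||% floor(length(ids) / 2)
    plan <- build_subsamples(A, ids, n_subsamples = config$subsamples$n,
                             size = sub_size, seed = seeds[3])
    pipeline_log(logcon, "rf", "%d subsamples of %d animals",
                 length(plan), sub_size)
    sub_runs <- lapply(seq_along(plan), function(k) {
      sel <- plan[[k]]
      two_step_select(geno_i[sel, ], y[match(sel, ids)],
                      fraction = config$fraction,
                      n_trees = config$rf$n_trees,
                      mtry_fraction = config$rf$mtry_fraction,
                      importance = config$rf$importance,
                      seed = seeds[4] + k)
    })
    strategies$common <- common_snp_strategy(
      full_run, sub_runs, min_subsample_hits = config$min_subsample_hits)
  }

  # -- stage 5: stepwise + permutation ---------------------------------
  fits <- list()
  summary_rows <- list()
  for (nm in names(strategies)) {
    cand <- strategies[[nm]]
    if (!nrow(cand)) {
      warnf("strategy %s produced no candidates", nm)
      fits[[nm]] <- NULL
      summary_rows[[nm]] <- data.frame(
        strategy = nm, candidate_snps = 0L, final_snps = 0L,
        pct_debv_variance = 0, perm_mean = NA_real_, perm_sd = NA_real_)
      next
    }
    Xc <- geno_i$geno[, cand$snp, drop = FALSE]
    sw <- suppressWarnings(
      forward_stepwise(y, Xc, config$stepwise$sl_entry,
                       config$stepwise$sl_stay))
    perm <- if (length(sw$snps)) {
      permutation_r2(y, geno_i$geno[, sw$snps, drop = FALSE],
                     n_permutations = config$n_permutations,
                     statistic = config$perm_statistic, seed = seeds[5],
                     sl_entry = config$stepwise$sl_entry,
                     sl_stay = config$stepwise$sl_stay)
    } else permutation_r2(y, Xc[, 0, drop = FALSE],
                          n_permutations = config$n_permutations,
                          statistic = config$perm_statistic, seed = seeds[5])
    pipeline_log(logcon, "stepwise",
                 "%s: %d candidates -> %d final SNPs, R2 = %.2f%%, perm %.2f +/- %.2f",
                 nm, nrow(cand), length(sw$snps), 100 * sw$r2,
                 perm$mean, perm$sd)
    fits[[nm]] <- list(stepwise = sw, permutation = perm)
    summary_rows[[nm]] <- data.frame(
      strategy = nm, candidate_snps = nrow(cand),
      final_snps = length(sw$snps), pct_debv_variance = 100 * sw$r2,
      perm_mean = perm$mean, perm_sd = perm$sd)
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL

  # -- stage 6: LD windows + annotation --------------------------------
  report_strategy <- if ("highest1" %in% names(fits)) "highest1"
                     else names(fits)[1]
  snp_table <- NULL
  windows <- NULL
  annotation <- NULL
  ld <- NULL
  if (!is.null(report_strategy) && length(fits[[report_strategy]]$stepwise$snps)) {
    sw <- fits[[report_strategy]]$stepwise
    windows <- snp_windows(sw$snps, geno_i$map,
                           half_width_bp = config$half_width_bp)
    feats <- config$features
    if (is.character(feats)) feats <- read_features(feats)
    if (!is.null(feats)) {
      annotation <- annotate_windows(windows, feats)
    }
    ld <- suppressWarnings(
      pairwise_r2(geno_i[, intersect(geno_i$map$snp, sw$snps)],
                  max_distance_bp = 2 * config$half_width_bp))
    feat_str <- vapply(sw$snps, function(s) {
      if (is.null(annotation)) return(NA_character_)
      paste(unique(annotation$feature[annotation$snp == s]), collapse = ",")
    }, character(1))
    snp_table <- data.frame(snp = sw$snps,
                            chr = windows$chr[match(sw$snps, windows$snp)],
                            pos = windows$pos[match(sw$snps, windows$snp)],
                            pct_debv = 100 * as.numeric(sw$partial_r2),
                            features = feat_str, stringsAsFactors = FALSE)
    snp_table <- snp_table[order(-snp_table$pct_debv), , drop = FALSE]
    rownames(snp_table) <- NULL
  }

  report <- structure(list(summary = summary, snp_table = snp_table,
                           response = data.frame(animal = ids, debv = y,
                                                 stringsAsFactors = FALSE),
                           counts = counts, config = config, debv = debv,
                           qc_report = qc$report, candidates = strategies,
                           fits = fits, windows = windows,
                           annotation = annotation, ld = ld,
                           truth = if (!is.null(arch)) arch else NULL),
                      class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  cat(sprintf("  pedigree %d | phenotyped %d | genotyped %d | SNPs %d\n",
              x$counts$pedigree, x$counts$phenotyped,
              x$counts$genotyped %||% NA, x$counts$snps_post_qc %||% NA))
  print(x$summary)
  invisible(x)
}

#' Write a run report to files
#'
#' Writes `summary.tsv` (one row per strategy: candidate count, final
#' count, % dEBV variance, permutation mean and SD), `snp_table.tsv` (per
#' final SNP, sorted by % dEBV descending), `debv.tsv`, `qc_report.tsv`,
#' and `manifest.json` (every parameter and seed).
#'
#' @param report a `run_report`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  w <- function(df, name) {
    p <- file.path(out_dir, name)
    write_table_tsv(df, p)
    paths <<- c(paths, p)
  }
  w(report$summary, "summary.tsv")
  if (!is.null(report$snp_table)) w(report$snp_table, "snp_table.tsv")
  w(as.data.frame(report$debv), "debv.tsv")
  w(as.data.frame(report$qc_report), "qc_report.tsv")
  if (!is.null(report$annotation)) w(report$annotation, "annotation.tsv")
  if (!is.null(report$ld)) w(report$ld, "ld.tsv")
  cfg <- report$config
  manifest <- list(
    h2 = cfg$h2, qc = cfg$qc, rf = cfg$rf, fraction = cfg$fraction,
    subsamples = cfg$subsamples, strategy = cfg$strategy,
    min_subsample_hits = cfg$min_subsample_hits, stepwise = cfg$stepwise,
    n_permutations = cfg$n_permutations,
    perm_statistic = cfg$perm_statistic,
    half_width_bp = cfg$half_width_bp, n_genotyped = cfg$n_genotyped,
    sex_split = cfg$sex_split, deregress = cfg$deregress, seed = cfg$seed,
    stage_seeds = stage_seeds(cfg$seed, 8),
    sim = if (!is.null(cfg$sim)) unclass(cfg$sim)[
      setdiff(names(cfg$sim), "fixed_effect_levels")] else NULL,
    fixed_effect_levels = if (!is.null(cfg$sim))
      as.list(cfg$sim$fixed_effect_levels) else NULL,
    counts = report$counts)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths <- c(paths, mp)
  invisible(paths)
}
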