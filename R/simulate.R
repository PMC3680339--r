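#' Simulation configuration
#'
#' Parameters of the synthetic herd generator. Defaults emulate the study
#' design this pipeline is built around: a composite beef-cattle herd with a
#' final genotyping cohort sired by 50 bulls (1 to 30 offspring each), a
#' lowly heritable ultrasound trait (h2 = 0.16), contemporary-group fixed
#' effects (sex, year, herd, genetic group) with age as a linear covariate,
#' and an HD-array-like SNP map scaled down to ~5,000 SNPs on 29 autosomes
#' with linkage disequilibrium decaying to mean r2 ~ 0.12 at 250 kb.
#'
#' @param n_sires number of sires of the final cohort.
#' @param offspring_per_sire_range integer pair (low, high); each sire gets a
#'   uniform draw of offspring in this range.
#' @param n_dams number of dams available to the final cohort.
#' @param n_extra_pedigree_generations generations of known ancestors above
#'   the parents of the final cohort.
#' @param n_chromosomes,snps_per_chromosome,chromosome_length_bp map shape.
#' @param founder_haplotype_pool_size haplotypes in the founder pool; the
#'   finite pool is what creates long-range LD blocks.
#' @param pool_corr_length_bp correlation length (bp) of the Markov process
#'   generating pool haplotypes; tunes how fast r2 decays with distance.
#' @param recomb_rate_per_bp Morgans per bp (default 1e-8 = 1 cM/Mb).
#' @param maf_lower_bound minimum founder minor allele frequency.
#' @param n_qtl,qtl_effect_sd planted-QTL count and raw effect-size spread
#'   (trait units per B-allele copy, before variance scaling).
#' @param qtl_variance_fraction fraction of the additive-genetic variance
#'   assigned to the planted QTL (rest is pedigree polygenic).
#' @param heritability narrow-sense h2 target.
#' @param fixed_effect_levels named counts for the contemporary-group factors.
#' @param cg_effect_sd SD of contemporary-group effects (trait units).
#' @param age_covariate_slope trait units per day of age.
#' @param missing_genotype_rate MCAR missingness applied to called dosages.
#' @param seed integer RNG seed.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_sires = 50,
                       offspring_per_sire_range = c(1L, 30L),
                       n_dams = 400,
                       n_extra_pedigree_generations = 1,
                       n_chromosomes = 29,
                       snps_per_chromosome = 170,
                       chromosome_length_bp = 10e6,
                       founder_haplotype_pool_size = 40,
                       pool_corr_length_bp = 2e5,
                       recomb_rate_per_bp = 1e-8,
                       maf_lower_bound = 0.02,
                       n_qtl = 10,
                       qtl_effect_sd = 0.1,
                       qtl_variance_fraction = 0.5,
                       heritability = 0.16,
                       fixed_effect_levels = c(sex = 2, year = 3, herd = 7,
                                               genetic_group = 2),
                       cg_effect_sd = 0.5,
                       age_covariate_slope = 0.002,
                       missing_genotype_rate = 0.005,
                       seed = 1L) {
  cfg <- list(n_sires = as.integer(n_sires),
              offspring_per_sire_range = as.integer(offspring_per_sire_range),
              n_dams = as.integer(n_dams),
              n_extra_pedigree_generations = as.integer(n_extra_pedigree_generations),
              n_chromosomes = as.integer(n_chromosomes),
              snps_per_chromosome = as.integer(snps_per_chromosome),
              chromosome_length_bp = as.double(chromosome_length_bp),
              founder_haplotype_pool_size = as.integer(founder_haplotype_pool_size),
              pool_corr_length_bp = as.double(pool_corr_length_bp),
              recomb_rate_per_bp = as.double(recomb_rate_per_bp),
              maf_lower_bound = as.double(maf_lower_bound),
              n_qtl = as.integer(n_qtl),
              qtl_effect_sd = as.double(qtl_effect_sd),
              qtl_variance_fraction = as.double(qtl_variance_fraction),
              heritability = as.double(heritability),
              fixed_effect_levels = fixed_effect_levels,
              cg_effect_sd = as.double(cg_effect_sd),
              age_covariate_slope = as.double(age_covariate_slope),
              missing_genotype_rate = as.double(missing_genotype_rate),
              seed = as.integer(seed))
  with(cfg, {
    if (n_sires < 1) stopf("n_sires must be >= 1")
    if (length(offspring_per_sire_range) != 2 ||
        offspring_per_sire_range[1] < 1 ||
        diff(offspring_per_sire_range) < 0)
      stopf("offspring_per_sire_range must be (low, high) with 1 <= low <= high")
    if (n_dams < 1) stopf("n_dams must be >= 1")
    if (heritability <= 0 || heritability >= 1)
      stopf("heritability must be in (0,1)")
    if (snps_per_chromosome < 100)
      stopf("snps_per_chromosome must be >= 100")
    if (founder_haplotype_pool_size < 2)
      stopf("founder_haplotype_pool_size must be >= 2")
    if (maf_lower_bound < 0 || maf_lower_bound >= 0.5)
      stopf("maf_lower_bound must be in [0, 0.5)")
    if (missing_genotype_rate < 0 || missing_genotype_rate >= 1)
      stopf("missing_genotype_rate must be in [0, 1)")
    if (qtl_variance_fraction < 0 || qtl_variance_fraction > 1)
      stopf("qtl_variance_fraction must be in [0, 1]")
  })
  structure(cfg, class = "sim_config")
}

#' Simulate a multi-generation pedigree
#'
#' Builds founders, `n_extra_pedigree_generations` of intermediate ancestors,
#' a sire and dam generation, and a final cohort in which each of the
#' `n_sires` sires has a uniform 1..30 (configurable) number of offspring
#' out of randomly assigned dams. Sexes are Bernoulli(0.5). The final cohort
#' is flagged in the `cohort` column.
#'
#' @param config a [sim_config()].
#' @return a [pedigree()] with extra columns `sex`, `generation`, `cohort`
#'   (logical: member of the final cohort).
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    n_parents <- config$n_sires + config$n_dams
    gens <- list()
    # ancestor generations: enough animals to supply parents
    n_prev <- 0
    prev_ids <- character(0)
    prev_sex <- character(0)
    for (g in seq_len(config$n_extra_pedigree_generations + 1)) {
      # generation sizes taper up towards the parent generation
      n_g <- if (g == config$n_extra_pedigree_generations + 1) n_parents
             else ceiling(n_parents * 0.75)
      ids <- sprintf("G%d_%04d", g, seq_len(n_g))
      if (n_prev == 0) {
        sire <- dam <- rep(NA_character_, n_g)
        sex <- rep_len(c("M", "F"), n_g)   # both sexes guaranteed
      } else {
        males <- prev_ids[prev_sex == "M"]
        females <- prev_ids[prev_sex == "F"]
        if (!length(males) || !length(females))
          stopf("a simulated generation lacks one sex; increase sizes")
        sire <- sample(males, n_g, replace = TRUE)
        dam <- sample(females, n_g, replace = TRUE)
        sex <- sample(c("M", "F"), n_g, replace = TRUE)
        if (n_g >= 2 && length(unique(sex)) == 1)
          sex[1] <- setdiff(c("M", "F"), sex[1])
      }
      gens[[g]] <- data.frame(animal = ids, sire = sire, dam = dam, sex = sex,
                              generation = g, stringsAsFactors = FALSE)
      prev_ids <- ids
      prev_sex <- sex
      n_prev <- n_g
    }
    parents <- gens[[length(gens)]]
    # force sexes in the parent generation: first n_sires male, rest female
    parents$sex <- c(rep("M", config$n_sires), rep("F", config$n_dams))
    gens[[length(gens)]] <- parents
    sires <- parents$animal[seq_len(config$n_sires)]
    dams <- parents$animal[config$n_sires + seq_len(config$n_dams)]
    lo <- config$offspring_per_sire_range[1]
    hi <- config$offspring_per_sire_range[2]
    n_off <- if (lo == hi) rep(lo, config$n_sires) else
      sample(seq(lo, hi), config$n_sires, replace = TRUE)
    off_sire <- rep(sires, times = n_off)
    off_dam <- sample(dams, sum(n_off), replace = TRUE)
    off <- data.frame(animal = sprintf("X_%04d", seq_len(sum(n_off))),
                      sire = off_sire, dam = off_dam,
                      sex = sample(c("M", "F"), sum(n_off), replace = TRUE),
                      generation = length(gens) + 1,
                      stringsAsFactors = FALSE)
    all <- rbind(do.call(rbind, gens), off)
    ped <- pedigree(all$animal, all$sire, all$dam, sex = all$sex)
    m <- match(ped$animal, all$animal)
    ped$generation <- all$generation[m]
    ped$cohort <- ped$generation == length(gens) + 1
    class(ped) <- c("pedigree", "data.frame")
    ped
  })
}

# Build the founder haplotype pool: K haplotypes x p SNPs, alleles 0/1.
# Along each chromosome a haplotype is a Markov chain: the allele at SNP j
# copies SNP j-1's source-haplotype pattern with probability
# exp(-d / pool_corr_length_bp), otherwise re-draws from the SNP frequency.
# The pool is the source of all founder LD.
make_founder_pool <- function(map, config) {
  K <- config$founder_haplotype_pool_size
  p <- nrow(map)
  freq <- stats::runif(p, config$maf_lower_bound, 1 - config$maf_lower_bound)
  H <- matrix(0L, K, p)
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    pos <- map$pos[idx]
    H[, idx[1]] <- stats::rbinom(K, 1, freq[idx[1]])
    if (length(idx) > 1) {
      for (k in 2:length(idx)) {
        j <- idx[k]
        keep <- stats::rbinom(K, 1, exp(-(pos[k] - pos[k - 1]) /
                                          config$pool_corr_length_bp))
        H[, j] <- ifelse(keep == 1, H[, idx[k - 1]],
                         stats::rbinom(K, 1, freq[j]))
      }
    }
  }
  # enforce a minimum minor-allele count within the pool
  minc <- max(1L, ceiling(config$maf_lower_bound * K))
  for (j in seq_len(p)) {
    cnt <- sum(H[, j])
    if (cnt < minc) H[sample.int(K, minc - cnt), j] <- 1L
    if (K - cnt < minc) H[sample.int(K, minc - (K - cnt)), j] <- 0L
  }
  H
}

# One gamete from parent haplotypes h1, h2 (0/1 vectors) via Poisson
# crossovers uniform along each chromosome.
make_gamete <- function(h1, h2, map_split, config) {
  out <- integer(length(h1))
  for (s in map_split) {
    idx <- s$idx
    nco <- stats::rpois(1, config$chromosome_length_bp *
                            config$recomb_rate_per_bp)
    cur <- sample(1:2, 1)
    if (nco == 0) {
      out[idx] <- if (cur == 1) h1[idx] else h2[idx]
    } else {
      bps <- sort(stats::runif(nco, 0, config$chromosome_length_bp))
      seg <- findInterval(s$pos, bps)    # segment index per SNP
      use1 <- (seg %% 2 == 0) == (cur == 1)
      out[idx] <- ifelse(use1, h1[idx], h2[idx])
    }
  }
  out
}

#' Simulate LD-structured genotypes by gene dropping
#'
#' Founders draw two haplotypes from a finite pool (the LD source);
#' non-founders inherit recombined parental gametes (Poisson crossovers,
#' uniform along the chromosome). Dosage = sum of the two haplotypes'
#' B-alleles. Founder minor allele frequencies are forced to at least
#' `maf_lower_bound` (rare SNPs have minor alleles added to founder
#' haplotype copies). Missingness is applied completely at random.
#'
#' @param ped a [pedigree()] (parents before offspring).
#' @param config a [sim_config()].
#' @param keep_haplotypes logical; attach the phased haplotypes as
#'   attributes `h1`/`h2` (used by tests).
#' @return a [genotype_matrix()] over all pedigree animals.
#' @export
simulate_genotypes <- function(ped, config, keep_haplotypes = FALSE) {
  stopifnot(inherits(ped, "pedigree"), inherits(config, "sim_config"))
  with_local_seed(config$seed + 1L, {
    p_chr <- config$snps_per_chromosome
    map <- do.call(rbind, lapply(seq_len(config$n_chromosomes), function(ch) {
      pos <- sort(sample.int(config$chromosome_length_bp, p_chr))
      data.frame(snp = sprintf("snp_%02d_%04d", ch, seq_len(p_chr)),
                 chr = as.character(ch), pos = pos,
                 a1 = "A", a2 = "B", stringsAsFactors = FALSE)
    }))
    p <- nrow(map)
    pool <- make_founder_pool(map, config)
    map_split <- lapply(unique(map$chr), function(ch) {
      idx <- which(map$chr == ch)
      list(idx = idx, pos = map$pos[idx])
    })
    n <- nrow(ped)
    H1 <- matrix(0L, n, p)
    H2 <- matrix(0L, n, p)
    pi <- parent_index(ped)
    founder_rows <- integer(0)
    for (k in seq_len(n)) {
      s <- pi$sire[k]; d <- pi$dam[k]
      if (is.na(s) && is.na(d)) {
        H1[k, ] <- pool[sample.int(nrow(pool), 1), ]
        H2[k, ] <- pool[sample.int(nrow(pool), 1), ]
        founder_rows <- c(founder_rows, k)
      } else {
        # unknown single parents get a fresh pool gamete
        H1[k, ] <- if (is.na(s)) pool[sample.int(nrow(pool), 1), ] else
          make_gamete(H1[s, ], H2[s, ], map_split, config)
        H2[k, ] <- if (is.na(d)) pool[sample.int(nrow(pool), 1), ] else
          make_gamete(H1[d, ], H2[d, ], map_split, config)
      }
    }
    # enforce founder MAF floor: add minor alleles to founder haplotypes of
    # SNPs below the bound (minimal perturbation, then re-drop is skipped:
    # descendants keep their sampled alleles, so the floor is a founder
    # guarantee only)
    if (length(founder_rows) && config$maf_lower_bound > 0) {
      nf <- length(founder_rows)
      need <- ceiling(config$maf_lower_bound * 2 * nf)
      cnt <- colSums(H1[founder_rows, , drop = FALSE]) +
        colSums(H2[founder_rows, , drop = FALSE])
      for (j in which(cnt < need)) {
        k <- need - cnt[j]
        rows <- sample(founder_rows, min(k, nf))
        H1[rows, j] <- 1L
      }
      for (j in which(2 * nf - cnt < need)) {
        k <- need - (2 * nf - cnt[j])
        rows <- sample(founder_rows, min(k, nf))
        H1[rows, j] <- 0L
        H2[rows, j] <- 0L
      }
    }
    dose <- H1 + H2
    storage.mode(dose) <- "double"
    rownames(dose) <- ped$animal
    if (config$missing_genotype_rate > 0) {
      nmiss <- stats::rbinom(1, length(dose), config$missing_genotype_rate)
      dose[sample.int(length(dose), nmiss)] <- NA_real_
    }
    gm <- genotype_matrix(dose, map)
    if (keep_haplotypes) {
      attr(gm, "h1") <- H1
      attr(gm, "h2") <- H2
    }
    gm
  })
}

#' Trait architecture with planted QTL
#'
#' Chooses `n_qtl` QTL SNPs from the genotyped panel, draws raw additive
#' effects `N(0, qtl_effect_sd^2)` and rescales them so the QTL variance
#' (computed from founder-cohort allele frequencies, sum of 2 p q a^2)
#' equals `qtl_variance_fraction * h2 * sigma2_p`. The remaining genetic
#' variance is pedigree polygenic; the residual completes `sigma2_p`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param config a [sim_config()].
#' @param sigma2_p target phenotypic variance (default 1).
#' @param mask_qtl if TRUE, QTL SNPs are recorded but intended for removal
#'   from the analyzed panel (tag-SNP experiments).
#' @return object of class `trait_architecture`: list with `qtl_snp_ids`,
#'   `qtl_effects`, `polygenic_variance`, `residual_variance`,
#'   `qtl_variance`, `sigma2_p`, `h2`, `mask_qtl`.
#' @export
trait_architecture <- function(genotypes, config, sigma2_p = 1,
                               mask_qtl = FALSE) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "sim_config"))
  with_local_seed(config$seed + 2L, {
    h2 <- config$heritability
    var_g <- h2 * sigma2_p
    var_qtl_target <- config$qtl_variance_fraction * var_g
    n_qtl <- min(config$n_qtl, ncol(genotypes$geno))
    qtl_ids <- character(0)
    effects <- numeric(0)
    if (n_qtl > 0 && var_qtl_target > 0) {
      p_b <- allele_freq(genotypes)
      informative <- which(pmin(p_b, 1 - p_b) >= 0.05)
      if (length(informative) < n_qtl) informative <- seq_along(p_b)
      pick <- informative[sample.int(length(informative), n_qtl)]
      qtl_ids <- genotypes$map$snp[pick]
      a <- stats::rnorm(n_qtl, 0, config$qtl_effect_sd)
      a[a == 0] <- config$qtl_effect_sd
      raw_var <- sum(2 * p_b[pick] * (1 - p_b[pick]) * a^2)
      effects <- a * sqrt(var_qtl_target / raw_var)
    } else {
      var_qtl_target <- 0
    }
    structure(list(qtl_snp_ids = qtl_ids, qtl_effects = effects,
                   qtl_variance = var_qtl_target,
                   polygenic_variance = max(0, var_g - var_qtl_target),
                   residual_variance = (1 - h2) * sigma2_p,
                   sigma2_p = sigma2_p, h2 = h2, mask_qtl = mask_qtl),
              class = "trait_architecture")
  })
}

#' Simulate phenotypes with the study's fixed-effect structure
#'
#' phenotype = contemporary-group effect (sex x year x herd x genetic-group
#' cell effects, N(0, cg_effect_sd^2)) + age * slope + sum of QTL dosage
#' effects + pedigree polygenic value (founders N(0, sigma2_poly),
#' offspring = parent average + Mendelian deviation scaled by parental
#' inbreeding) + residual. True breeding values (QTL + polygenic) are
#' returned for recovery tests.
#'
#' @param ped a [pedigree()] (with `sex` column, as from
#'   [simulate_pedigree()]).
#' @param genotypes a [genotype_matrix()] covering all pedigree animals.
#' @param arch a [trait_architecture()].
#' @param config a [sim_config()].
#' @param animals ids to phenotype; default all animals with both parents
#'   known.
#' @return data frame `animal`, `y`, `cg`, `sex`, `year`, `herd`,
#'   `genetic_group`, `age`, `tbv` (true breeding value), `qtl_value`,
#'   `polygenic`, with attribute `arch`.
#' @export
simulate_phenotypes <- function(ped, genotypes, arch, config,
                                animals = NULL) {
  stopifnot(inherits(ped, "pedigree"),
            inherits(genotypes, "genotype_matrix"),
            inherits(arch, "trait_architecture"),
            inherits(config, "sim_config"))
  miss_qtl <- setdiff(arch$qtl_snp_ids, genotypes$map$snp)
  if (length(miss_qtl))
    stopf("QTL SNP id(s) absent from genotype map: %s",
          paste(miss_qtl, collapse = ", "))
  with_local_seed(config$seed + 3L, {
    n <- nrow(ped)
    # QTL genetic values for everyone in the pedigree
    qtl_value <- numeric(n)
    if (length(arch$qtl_snp_ids)) {
      jq <- match(arch$qtl_snp_ids, genotypes$map$snp)
      gq <- genotypes$geno[ped$animal, jq, drop = FALSE]
      gq[is.na(gq)] <- 1  # missing calls contribute the heterozygote value
      qtl_value <- as.numeric(gq %*% arch$qtl_effects)
      qtl_value <- qtl_value - mean(qtl_value)
    }
    # pedigree polygenic values (gene-flow recursion consistent with A)
    s2u <- arch$polygenic_variance
    u <- numeric(n)
    if (s2u > 0) {
      f <- inbreeding(ped)
      pi <- parent_index(ped)
      for (k in seq_len(n)) {
        s <- pi$sire[k]; d <- pi$dam[k]
        if (is.na(s) && is.na(d)) {
          u[k] <- stats::rnorm(1, 0, sqrt(s2u))
        } else if (!is.na(s) && !is.na(d)) {
          msv <- s2u * (0.5 - 0.25 * (f[s] + f[d]))
          u[k] <- 0.5 * (u[s] + u[d]) + stats::rnorm(1, 0, sqrt(msv))
        } else {
          pknown <- if (!is.na(s)) s else d
          msv <- s2u * (0.75 - 0.25 * f[pknown])
          u[k] <- 0.5 * u[pknown] + stats::rnorm(1, 0, sqrt(msv))
        }
      }
    }
    tbv <- qtl_value + u
    # fixed effects
    fl <- config$fixed_effect_levels
    sex <- ped$sex %||% sample(c("M", "F"), n, replace = TRUE)
    sex[is.na(sex)] <- sample(c("M", "F"), sum(is.na(sex)), replace = TRUE)
    year <- sample(paste0("y", seq_len(fl[["year"]])), n, replace = TRUE)
    herd <- sample(paste0("h", seq_len(fl[["herd"]])), n, replace = TRUE)
    gg <- sample(paste0("g", seq_len(fl[["genetic_group"]])), n,
                 replace = TRUE)
    cg <- interaction(sex, year, herd, gg, drop = TRUE)
    cg_eff <- stats::rnorm(nlevels(cg), 0, config$cg_effect_sd)
    age <- round(stats::rnorm(n, 550, 30))
    e <- stats::rnorm(n, 0, sqrt(arch$residual_variance))
    y <- cg_eff[as.integer(cg)] + config$age_covariate_slope * age + tbv + e
    out <- data.frame(animal = ped$animal, y = y, cg = as.character(cg),
                      sex = sex, year = year, herd = herd,
                      genetic_group = gg, age = age, tbv = tbv,
                      qtl_value = qtl_value, polygenic = u,
                      stringsAsFactors = FALSE)
    if (is.null(animals)) {
      keep <- !is.na(ped$sire) & !is.na(ped$dam)
    } else {
      keep <- ped$animal %in% animals
    }
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "arch") <- arch
    out
  })
}

#' Select the genotyping subset
#'
#' Picks `n` animals from `candidates`, stratified by sex to the requested
#' split, preferring higher EBV accuracy, with an optional cap on per-sire
#' family contribution (greedy within sex by decreasing accuracy).
#'
#' @param candidates character vector of candidate animal ids.
#' @param ebvs a `blup_fit` or data frame with `animal` and `accuracy`.
#' @param ped a [pedigree()] with a `sex` column.
#' @param n number to select.
#' @param sex_split integer pair (males, females); must sum to `n`.
#' @param family_cap maximum offspring per sire (default unlimited).
#' @return character vector of `n` selected animal ids.
#' @export
select_genotyping_subset <- function(candidates, ebvs, ped, n,
                                     sex_split = NULL, family_cap = Inf) {
  if (inherits(ebvs, "blup_fit")) ebvs <- ebvs$ebv
  if (n > length(candidates))
    stopf("requested %d animals from %d candidates", n, length(candidates))
  m <- match(candidates, ped$animal)
  if (anyNA(m)) stopf("candidates missing from pedigree")
  sex <- ped$sex[m]
  sire <- ped$sire[m]
  acc <- ebvs$accuracy[match(candidates, ebvs$animal)]
  acc[is.na(acc)] <- 0
  if (is.null(sex_split)) {
    nm <- round(n * mean(sex == "M", na.rm = TRUE))
    sex_split <- c(nm, n - nm)
  }
  if (sum(sex_split) != n) stopf("sex_split must sum to n")
  if (sex_split[1] > sum(sex == "M", na.rm = TRUE) ||
      sex_split[2] > sum(sex == "F", na.rm = TRUE))
    stopf("infeasible sex split: need %d M / %d F, have %d M / %d F",
          sex_split[1], sex_split[2],
          sum(sex == "M", na.rm = TRUE), sum(sex == "F", na.rm = TRUE))
  # single greedy pass by decreasing accuracy, honoring both the per-sex
  # quotas and the per-sire family cap jointly
  ord <- order(-acc, candidates)
  quota <- c(M = sex_split[1], F = sex_split[2])
  fam_count <- new.env(parent = emptyenv())
  chosen <- integer(0)
  for (i in ord) {
    if (length(chosen) == n) break
    sx <- sex[i]
    if (is.na(sx) || quota[[sx]] == 0) next
    s <- sire[i]
    cnt <- if (!is.na(s)) get0(s, fam_count, ifnotfound = 0L) else 0L
    if (cnt >= family_cap) next
    chosen <- c(chosen, i)
    quota[[sx]] <- quota[[sx]] - 1L
    if (!is.na(s)) assign(s, cnt + 1L, fam_count)
  }
  if (length(chosen) < n)
    stopf("could not fill the request: family cap %s and sex split (%d, %d) leave only %d selectable animals",
          format(family_cap), sex_split[1], sex_split[2], length(chosen))
  candidates[chosen]
}
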