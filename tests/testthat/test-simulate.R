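test_that("simulated pedigrees honor the sire design and are seed-reproducible", {
  cfg <- sim_config(n_chromosomes = 3, snps_per_chromosome = 100, seed = 5)
  ped <- simulate_pedigree(cfg)
  cohort <- ped[ped$cohort, ]
  expect_gte(nrow(cohort), 50)
  expect_lte(nrow(cohort), 1500)
  sires <- unique(cohort$sire)
  expect_lte(length(sires), 50)
  expect_true(all(sires %in% ped$animal))
  # every non-founder has both parents present and earlier in the ordering
  nf <- which(!is.na(ped$sire))
  expect_true(all(match(ped$sire[nf], ped$animal) < nf))
  expect_true(all(match(ped$dam[nf], ped$animal) < nf))
  ped2 <- simulate_pedigree(cfg)
  expect_identical(as.data.frame(ped), as.data.frame(ped2))
  # degenerate single-sire single-offspring design
  cfg1 <- sim_config(n_sires = 1, offspring_per_sire_range = c(1, 1),
                     n_dams = 1, n_chromosomes = 3,
                     snps_per_chromosome = 100, seed = 2)
  expect_equal(sum(simulate_pedigree(cfg1)$cohort), 1)
  expect_error(sim_config(n_sires = 0), "n_sires")
})

test_that("gene-dropped genotypes are Mendelian-consistent", {
  cfg <- sim_config(n_sires = 4, offspring_per_sire_range = c(3, 6),
                    n_dams = 10, n_chromosomes = 3,
                    snps_per_chromosome = 100,
                    missing_genotype_rate = 0, seed = 9)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  # transmissible allele counts per parent dosage: 0 -> {0}, 1 -> {0,1}, 2 -> {1}
  lo <- function(d) ifelse(d == 2, 1, 0)
  hi <- function(d) ifelse(d == 0, 0, 1)
  for (k in which(!is.na(si) & !is.na(di))) {
    ds <- g$geno[si[k], ]; dd <- g$geno[di[k], ]; dk <- g$geno[k, ]
    expect_true(all(dk >= lo(ds) + lo(dd) & dk <= hi(ds) + hi(dd)))
  }
})

test_that("without recombination a two-haplotype pool yields only two patterns", {
  cfg <- sim_config(n_sires = 5, offspring_per_sire_range = c(2, 4),
                    n_dams = 10, n_chromosomes = 2,
                    snps_per_chromosome = 100,
                    founder_haplotype_pool_size = 2,
                    recomb_rate_per_bp = 0, maf_lower_bound = 0.2,
                    missing_genotype_rate = 0, seed = 3)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg, keep_haplotypes = TRUE)
  H <- rbind(attr(g, "h1"), attr(g, "h2"))
  for (ch in unique(g$map$chr)) {
    idx <- which(g$map$chr == ch)
    pats <- unique(apply(H[, idx, drop = FALSE], 1, paste, collapse = ""))
    expect_lte(length(pats), 2)
  }
})

test_that("founder MAF respects the configured lower bound", {
  cfg <- sim_config(n_sires = 5, offspring_per_sire_range = c(2, 4),
                    n_dams = 20, n_chromosomes = 3,
                    snps_per_chromosome = 120, maf_lower_bound = 0.05,
                    missing_genotype_rate = 0, seed = 21)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  founders <- ped$animal[is.na(ped$sire) & is.na(ped$dam)]
  fg <- g[founders, ]
  expect_true(all(maf(fg) >= 0.05 - 1e-9))
})

test_that("parent-offspring dosage correlation is near one half", {
  herd <- shared_herd()
  ped <- herd$ped
  g <- impute_median(herd$geno)
  kids <- which(ped$cohort)
  si <- match(ped$sire[kids], ped$animal)
  cors <- vapply(seq_len(ncol(g$geno)), function(j) {
    x <- g$geno[si, j]; y <- g$geno[kids, j]
    if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
    cor(x, y)
  }, numeric(1))
  expect_gt(sum(!is.na(cors)), 1000)
  expect_lt(abs(mean(cors, na.rm = TRUE) - 0.5), 0.05)
})

test_that("realized heritability lands near the target", {
  herd <- shared_herd()
  phen <- herd$phen
  expect_gt(nrow(phen), 1000)
  yr <- resid(lm(y ~ cg + age, data = phen))
  h2_real <- var(phen$tbv) / var(yr)
  expect_lt(abs(h2_real - herd$cfg$heritability), 0.05)
})

test_that("dosage covariance between relatives scales with A", {
  herd <- shared_herd()
  ped <- herd$ped
  g <- impute_median(herd$geno)
  # expected dosage correlation for a pair = a_ij / sqrt(a_ii a_jj);
  # compare mean observed SNP-wise correlation for parent-offspring (0.5)
  # and half-sib (0.25) pairs aggregated over >= 1000 SNPs
  kids <- which(ped$cohort)
  bysire <- split(kids, ped$sire[kids])
  bysire <- bysire[lengths(bysire) >= 2]
  pair <- t(vapply(bysire, function(v) v[1:2], numeric(2)))
  cors <- vapply(seq_len(ncol(g$geno)), function(j) {
    x <- g$geno[pair[, 1], j]; y <- g$geno[pair[, 2], j]
    if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
    cor(x, y)
  }, numeric(1))
  expect_lt(abs(mean(cors, na.rm = TRUE) - 0.25), 0.05)
})

test_that("null genetic architecture leaves only residual variance", {
  cfg <- sim_config(n_sires = 10, offspring_per_sire_range = c(8, 12),
                    n_dams = 50, n_chromosomes = 3,
                    snps_per_chromosome = 100,
                    missing_genotype_rate = 0, seed = 31)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  arch <- structure(list(qtl_snp_ids = character(0), qtl_effects = numeric(0),
                         qtl_variance = 0, polygenic_variance = 0,
                         residual_variance = 0.84, sigma2_p = 1,
                         h2 = cfg$heritability, mask_qtl = FALSE),
                    class = "trait_architecture")
  phen <- simulate_phenotypes(ped, g, arch, cfg)
  expect_true(all(phen$tbv == 0))
  # df-corrected residual variance (the contemporary-group factor is rich
  # relative to this small cohort)
  s2 <- summary(lm(y ~ cg + age, data = phen))$sigma^2
  expect_equal(s2, 0.84, tolerance = 0.84 * 0.25)
})

test_that("offspring phenotype regressed on mid-parent breeding value has slope 1", {
  herd <- shared_herd()
  ped <- herd$ped
  phen <- herd$phen
  m <- match(phen$animal, ped$animal)
  si <- match(ped$sire[m], ped$animal)
  di <- match(ped$dam[m], ped$animal)
  tbv_all <- setNames(rep(NA_real_, nrow(ped)), ped$animal)
  # breeding values of parents come from the truth columns of a full-herd
  # phenotype draw: reconstruct via qtl_value + polygenic of all animals
  full <- simulate_phenotypes(ped, herd$geno, herd$arch, herd$cfg,
                              animals = ped$animal)
  tbv_all[full$animal] <- full$tbv
  midp <- (tbv_all[ped$sire[m]] + tbv_all[ped$dam[m]]) / 2
  yr <- resid(lm(y ~ cg + age, data = phen))
  ok <- !is.na(midp)
  sl <- coef(lm(yr[ok] ~ midp[ok]))[2]
  expect_equal(unname(sl), 1, tolerance = 0.3)
})

test_that("phenotype simulation errors on unknown QTL ids and is deterministic", {
  cfg <- sim_config(n_sires = 3, offspring_per_sire_range = c(2, 3),
                    n_dams = 6, n_chromosomes = 3,
                    snps_per_chromosome = 100, seed = 17)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  arch <- trait_architecture(g, cfg)
  bad <- arch
  bad$qtl_snp_ids <- c(bad$qtl_snp_ids, "nonexistent_snp")
  expect_error(simulate_phenotypes(ped, g, bad, cfg), "nonexistent_snp")
  p1 <- simulate_phenotypes(ped, g, arch, cfg)
  p2 <- simulate_phenotypes(ped, g, arch, cfg)
  expect_identical(p1, p2)
})

test_that("genotyping-subset selection meets the sex split and family cap", {
  herd <- shared_herd()
  ped <- herd$ped
  fit <- list(ebv = data.frame(animal = ped$animal,
                               accuracy = runif(nrow(ped))))
  class(fit) <- "blup_fit"
  cohort <- ped$animal[ped$cohort]
  sel <- select_genotyping_subset(cohort, fit, ped, 400,
                                  sex_split = c(196, 204))
  expect_length(sel, 400)
  sx <- ped$sex[match(sel, ped$animal)]
  expect_equal(sum(sx == "M"), 196)
  expect_equal(sum(sx == "F"), 204)
  # identity selection
  small <- cohort[1:10]
  nm <- sum(ped$sex[match(small, ped$animal)] == "M")
  sel2 <- select_genotyping_subset(small, fit, ped, 10,
                                   sex_split = c(nm, 10 - nm))
  expect_setequal(sel2, small)
  # family cap of one offspring per sire
  sires <- unique(ped$sire[ped$cohort])
  one_per <- select_genotyping_subset(cohort, fit, ped, length(sires),
                                      sex_split = NULL, family_cap = 1)
  expect_equal(anyDuplicated(ped$sire[match(one_per, ped$animal)]), 0)
  expect_error(select_genotyping_subset(cohort, fit, ped, 4000),
               "candidates")
})
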