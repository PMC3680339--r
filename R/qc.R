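#' Genotype quality control
#'
#' Applies the array-QC filter chain in a fixed, documented order:
#' \enumerate{
#'   \item samples with call rate below `sample_call_rate_min`;
#'   \item SNPs with call rate below `snp_call_rate_min` or minor allele
#'     frequency below `maf_min` (MAF computed on non-missing calls of the
#'     samples surviving step 1);
#'   \item samples whose per-sample heterozygosity deviates from the cohort
#'     mean by more than `het_sd_limit` standard deviations.
#' }
#' The heterozygosity filter is per-sample by default (the conventional
#' array-QC reading); `het_on = "snp"` applies the same rule to per-SNP
#' heterozygosity instead.
#'
#' @param genotypes a [genotype_matrix()].
#' @param sample_call_rate_min,snp_call_rate_min call-rate thresholds
#'   (default 0.90): entries *below* the threshold are removed.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param het_sd_limit heterozygosity outlier limit in SD units (default 3).
#' @param het_on `"sample"` (default) or `"snp"`.
#' @return list with `genotypes` (filtered [genotype_matrix()]) and
#'   `report` (a `qc_report`: data frame of removals with columns `item`,
#'   `type`, `reason`, `value`, plus attributes `thresholds`, `n_before`,
#'   `n_after`).
#' @export
qc_filter <- function(genotypes, sample_call_rate_min = 0.90,
                      snp_call_rate_min = 0.90, maf_min = 0.01,
                      het_sd_limit = 3, het_on = c("sample", "snp")) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  het_on <- match.arg(het_on)
  g <- genotypes$geno
  if (nrow(g) == 0 || ncol(g) == 0) stopf("empty genotype matrix")
  removals <- data.frame(item = character(0), type = character(0),
                         reason = character(0), value = numeric(0),
                         stringsAsFactors = FALSE)
  note <- function(item, type, reason, value) {
    removals <<- rbind(removals,
                       data.frame(item = item, type = type, reason = reason,
                                  value = value, stringsAsFactors = FALSE))
  }
  n_before <- c(samples = nrow(g), snps = ncol(g))

  # 1. sample call rate
  scr <- rowMeans(!is.na(g))
  drop_s <- scr < sample_call_rate_min
  for (i in which(drop_s)) note(rownames(g)[i], "sample", "call_rate", scr[i])
  g <- g[!drop_s, , drop = FALSE]
  if (nrow(g) == 0) stopf("all samples removed by the call-rate filter")

  # 2. SNP call rate and MAF (recomputed after sample removal)
  ccr <- colMeans(!is.na(g))
  pfreq <- colMeans(g, na.rm = TRUE) / 2
  snp_maf <- pmin(pfreq, 1 - pfreq)
  snp_maf[is.nan(snp_maf)] <- 0
  drop_cr <- ccr < snp_call_rate_min
  drop_maf <- !drop_cr & snp_maf < maf_min   # one primary reason per removal
  for (j in which(drop_cr))
    note(colnames(g)[j], "snp", "call_rate", ccr[j])
  for (j in which(drop_maf))
    note(colnames(g)[j], "snp", "maf", snp_maf[j])
  keep_j <- !(drop_cr | drop_maf)
  g <- g[, keep_j, drop = FALSE]
  map <- genotypes$map[keep_j, , drop = FALSE]

  # 3. heterozygosity outliers
  if (het_on == "sample") {
    het <- rowMeans(g == 1, na.rm = TRUE)
    mu <- mean(het); sdv <- stats::sd(het)
    if (is.finite(sdv) && sdv > 0) {
      drop_h <- abs(het - mu) > het_sd_limit * sdv
      for (i in which(drop_h))
        note(rownames(g)[i], "sample", "heterozygosity", het[i])
      g <- g[!drop_h, , drop = FALSE]
    }
    if (nrow(g) == 0) stopf("all samples removed by the heterozygosity filter")
  } else {
    het <- colMeans(g == 1, na.rm = TRUE)
    mu <- mean(het); sdv <- stats::sd(het)
    if (is.finite(sdv) && sdv > 0) {
      drop_h <- abs(het - mu) > het_sd_limit * sdv
      for (j in which(drop_h))
        note(colnames(g)[j], "snp", "heterozygosity", het[j])
      g <- g[, !drop_h, drop = FALSE]
      map <- map[!drop_h, , drop = FALSE]
    }
  }

  report <- removals
  attr(report, "thresholds") <- list(sample_call_rate_min = sample_call_rate_min,
                                     snp_call_rate_min = snp_call_rate_min,
                                     maf_min = maf_min,
                                     het_sd_limit = het_sd_limit,
                                     het_on = het_on)
  attr(report, "n_before") <- n_before
  attr(report, "n_after") <- c(samples = nrow(g), snps = ncol(g))
  class(report) <- c("qc_report", "data.frame")
  list(genotypes = genotype_matrix(g, map), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  nb <- attr(x, "n_before"); na <- attr(x, "n_after")
  cat(sprintf("QC: samples %d -> %d, SNPs %d -> %d (%d removals)\n",
              nb["samples"], na["samples"], nb["snps"], na["snps"], nrow(x)))
  if (nrow(x)) print(table(x$type, x$reason))
  invisible(x)
}

#' Naive median imputation of missing genotypes
#'
#' Replaces every missing call with the median of that SNP's non-missing
#' dosages (the naive column-median rule). The median of an even-sized set
#' is the midpoint, so imputed dosages may be fractional (0.5 or 1.5).
#'
#' @param genotypes a [genotype_matrix()].
#' @return a [genotype_matrix()] with no missing entries.
#' @export
impute_median <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  g <- genotypes$geno
  nmiss <- colSums(is.na(g))
  if (!any(nmiss > 0)) return(genotypes)
  all_missing <- nmiss == nrow(g)
  if (any(all_missing))
    stopf("SNP(s) with no non-missing calls: %s",
          paste(utils::head(colnames(g)[all_missing], 5), collapse = ", "))
  for (j in which(nmiss > 0)) {
    g[is.na(g[, j]), j] <- stats::median(g[, j], na.rm = TRUE)
  }
  genotype_matrix(g, genotypes$map)
}
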