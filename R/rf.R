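#' Random-forest SNP importance
#'
#' Fits a regression forest of the response (typically deregressed EBVs) on
#' SNP dosages and returns a per-SNP variable-importance table. The number
#' of candidate SNPs tried at each split is `max(1, floor(mtry_fraction *
#' p))` -- 10\% of the SNPs being evaluated by default. Importance is
#' permutation importance (mean decrease in out-of-bag squared-error
#' accuracy) by default; mean decrease in impurity is available behind the
#' `importance` flag. The forest is fitted single-threaded so results are
#' deterministic under `seed`.
#'
#' @param genotypes a [genotype_matrix()] with no missing entries (run
#'   [impute_median()] first) or a plain numeric matrix plus `map`.
#' @param response numeric vector, one value per animal (row).
#' @param n_trees number of trees (default 5000).
#' @param mtry_fraction fraction of SNPs tried per split (default 0.10).
#' @param importance `"permutation"` (default) or `"impurity"`.
#' @param seed integer seed.
#' @param map SNP map when `genotypes` is a plain matrix.
#' @return object of class `importance_table`: data frame `snp`, `chr`,
#'   `importance`, with attribute `params`.
#' @export
rf_importance <- function(genotypes, response, n_trees = 5000,
                          mtry_fraction = 0.10,
                          importance = c("permutation", "impurity"),
                          seed = 1L, map = NULL) {
  importance <- match.arg(importance)
  if (inherits(genotypes, "genotype_matrix")) {
    map <- genotypes$map
    g <- genotypes$geno
  } else {
    g <- as.matrix(genotypes)
    if (ncol(g) == 0) stopf("no SNPs to evaluate")
    if (is.null(map))
      map <- data.frame(snp = colnames(g) %||% paste0("snp", seq_len(ncol(g))),
                        chr = "1", pos = seq_len(ncol(g)),
                        stringsAsFactors = FALSE)
  }
  if (ncol(g) == 0) stopf("no SNPs to evaluate")
  if (nrow(g) < 2) stopf("need at least 2 animals")
  if (anyNA(g)) stopf("genotypes contain missing values; impute first")
  if (length(response) != nrow(g))
    stopf("response length %d != %d animals", length(response), nrow(g))
  mtry <- max(1L, floor(mtry_fraction * ncol(g)))
  df <- as.data.frame(g)
  colnames(df) <- paste0("V", seq_len(ncol(g)))  # syntactic names for ranger
  fit <- ranger::ranger(x = df, y = as.numeric(response),
                        num.trees = n_trees, mtry = mtry,
                        importance = importance, seed = seed,
                        num.threads = 1)
  out <- data.frame(snp = map$snp, chr = as.character(map$chr),
                    importance = as.numeric(fit$variable.importance),
                    stringsAsFactors = FALSE)
  attr(out, "params") <- list(n_trees = n_trees,
                              mtry_fraction = mtry_fraction, mtry = mtry,
                              importance = importance, seed = seed,
                              n = nrow(g), p = ncol(g))
  class(out) <- c("importance_table", "data.frame")
  out
}
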