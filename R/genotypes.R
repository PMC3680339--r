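#' Genotype matrix container
#'
#' Animals x SNPs dosage table (0 = AA, 1 = AB, 2 = BB, NA = missing) with a
#' SNP map. The map has columns `snp`, `chr`, `pos` (1-based bp), and allele
#' labels `a1`, `a2`.
#'
#' @param dosage numeric matrix, animals in rows, SNPs in columns. Row names
#'   are animal ids; column names SNP ids (taken from `map$snp` if absent).
#' @param map data frame with columns `snp`, `chr`, `pos` (and optionally
#'   `a1`, `a2`, defaulting to "A"/"B").
#' @return object of class `genotype_matrix`: list with elements `geno`
#'   (matrix) and `map`.
#' @export
genotype_matrix <- function(dosage, map) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  stopifnot(is.data.frame(map), all(c("snp", "chr", "pos") %in% names(map)))
  if (nrow(map) != ncol(dosage))
    stopf("map has %d SNPs but dosage has %d columns", nrow(map), ncol(dosage))
  bad <- !(dosage %in% c(0, 0.5, 1, 1.5, 2) | is.na(dosage))
  if (any(bad))
    stopf("dosages must be in {0, 1, 2} (0.5 steps allowed post-imputation) or NA")
  map$snp <- as.character(map$snp)
  map$chr <- as.character(map$chr)
  map$pos <- as.integer(map$pos)
  if (is.null(map$a1)) map$a1 <- "A"
  if (is.null(map$a2)) map$a2 <- "B"
  if (anyDuplicated(map$snp)) stopf("duplicated SNP ids in map")
  colnames(dosage) <- map$snp
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("id", seq_len(nrow(dosage)))
  structure(list(geno = dosage, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d animals x %d SNPs on %d chromosome(s); %.2f%% missing\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chr)),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param i animal selector (ids, indices or logical).
#' @param j SNP selector (ids, indices or logical).
#' @param ... unused.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$geno))
  if (missing(j)) j <- seq_len(ncol(x$geno))
  if (is.character(j)) j <- match(j, x$map$snp)
  g <- x$geno[i, j, drop = FALSE]
  genotype_matrix(g, x$map[j, , drop = FALSE])
}

#' Per-SNP allele frequency of the B allele
#' @param x a [genotype_matrix()].
#' @return numeric vector of B-allele frequencies (non-missing calls).
#' @export
allele_freq <- function(x) {
  colMeans(x$geno, na.rm = TRUE) / 2
}

#' Per-SNP minor allele frequency
#' @param x a [genotype_matrix()].
#' @return numeric vector of MAF.
#' @export
maf <- function(x) {
  p <- allele_freq(x)
  pmin(p, 1 - p)
}

#' Encode allele-pair calls as 0/1/2 dosages
#'
#' Maps genotype calls (two allele letters per call, order-insensitive) to
#' additive dosages: AA -> 0, AB/BA -> 1, BB -> 2, where A and B are the
#' declared alleles of each SNP. Missing calls (NA, or either allele `"0"`)
#' stay missing.
#'
#' @param calls character matrix (animals x SNPs) of two-letter calls, e.g.
#'   `"AA"`, `"AB"`, or allele pairs separated by `/` or space.
#' @param map SNP map with columns `snp`, `chr`, `pos`, `a1`, `a2`.
#' @return a [genotype_matrix()].
#' @export
encode_genotypes <- function(calls, map) {
  calls <- as.matrix(calls)
  if (ncol(calls) != nrow(map))
    stopf("calls have %d SNPs but map has %d", ncol(calls), nrow(map))
  a1 <- as.character(map$a1 %||% rep("A", nrow(map)))
  a2 <- as.character(map$a2 %||% rep("B", nrow(map)))
  dose <- matrix(NA_real_, nrow(calls), ncol(calls))
  rownames(dose) <- rownames(calls)
  for (j in seq_len(ncol(calls))) {
    cj <- gsub("[/ ]", "", calls[, j])
    al <- cbind(substr(cj, 1, 1), substr(cj, 2, 2))
    missing_call <- is.na(cj) | al[, 1] == "0" | al[, 2] == "0" | cj == ""
    known <- c(a1[j], a2[j])
    bad <- !missing_call & (!(al[, 1] %in% known) | !(al[, 2] %in% known))
    if (any(bad)) {
      w <- which(bad)[1]
      stopf("SNP %s, animal %s: allele(s) '%s' not among declared {%s, %s}",
            map$snp[j], rownames(calls)[w] %||% w, calls[w, j], a1[j], a2[j])
    }
    dose[, j] <- ifelse(missing_call, NA_real_,
                        (al[, 1] == a2[j]) + (al[, 2] == a2[j]))
  }
  genotype_matrix(dose, map)
}
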