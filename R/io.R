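# Plain-text genotype I/O: PLINK PED/MAP and minimal GT-only VCF.

#' Read genotypes from PLINK PED/MAP text files
#'
#' The MAP file has 4 whitespace-separated columns (chr, snp id, cM, bp);
#' the PED file has 6 leading columns (family, id, father, mother, sex,
#' phenotype) followed by two allele columns per SNP (`0` = missing allele).
#' Allele labels per SNP are taken as the two distinct non-zero letters seen
#' (alphabetical -> a1, a2); monomorphic SNPs get `a2 = "B"` placeholder.
#'
#' @param ped_path,map_path file paths.
#' @return a [genotype_matrix()] with animal ids from the PED id column.
#' @export
read_plink <- function(ped_path, map_path) {
  mp <- utils::read.table(map_path, header = FALSE,
                          colClasses = c("character", "character",
                                         "numeric", "integer"))
  names(mp) <- c("chr", "snp", "cm", "pos")
  pd <- utils::read.table(ped_path, header = FALSE, colClasses = "character")
  p <- nrow(mp)
  if (ncol(pd) != 6 + 2 * p)
    stopf("PED has %d columns; expected %d for %d SNPs", ncol(pd), 6 + 2 * p, p)
  ids <- pd[[2]]
  al1 <- as.matrix(pd[, 6 + 2 * seq_len(p) - 1, drop = FALSE])
  al2 <- as.matrix(pd[, 6 + 2 * seq_len(p), drop = FALSE])
  a1 <- a2 <- character(p)
  calls <- matrix(NA_character_, length(ids), p)
  for (j in seq_len(p)) {
    obs <- c(al1[, j], al2[, j])
    alleles <- sort(setdiff(unique(obs), "0"))
    if (length(alleles) > 2)
      stopf("SNP %s has >2 alleles: %s", mp$snp[j],
            paste(alleles, collapse = ","))
    a1[j] <- if (length(alleles) >= 1) alleles[1] else "A"
    a2[j] <- if (length(alleles) == 2) alleles[2] else
      setdiff(c("A", "B"), a1[j])[1]
    calls[, j] <- paste0(al1[, j], al2[, j])
  }
  rownames(calls) <- ids
  map <- data.frame(snp = mp$snp, chr = mp$chr, pos = mp$pos,
                    a1 = a1, a2 = a2, stringsAsFactors = FALSE)
  encode_genotypes(calls, map)
}

#' Write genotypes as PLINK PED/MAP text files
#'
#' Missing dosages are written as `0 0`; non-integer (imputed) dosages are
#' not representable in PED and raise an error.
#'
#' @param x a [genotype_matrix()].
#' @param ped_path,map_path output paths.
#' @param pedigree optional [pedigree()] supplying father/mother/sex columns.
#' @return invisibly, the two paths.
#' @export
write_plink <- function(x, ped_path, map_path, pedigree = NULL) {
  g <- x$geno
  if (any(!is.na(g) & g != round(g)))
    stopf("PED cannot represent fractional (imputed) dosages")
  mp <- data.frame(chr = x$map$chr, snp = x$map$snp, cm = 0, pos = x$map$pos)
  utils::write.table(mp, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ids <- rownames(g)
  sire <- dam <- rep("0", length(ids))
  sex <- rep("0", length(ids))
  if (!is.null(pedigree)) {
    m <- match(ids, pedigree$animal)
    sire <- ifelse(is.na(m) | is.na(pedigree$sire[m]), "0", pedigree$sire[m])
    dam <- ifelse(is.na(m) | is.na(pedigree$dam[m]), "0", pedigree$dam[m])
    if (!is.null(pedigree$sex))
      sex <- ifelse(is.na(m) | is.na(pedigree$sex[m]), "0",
                    ifelse(pedigree$sex[m] == "M", "1", "2"))
  }
  p <- ncol(g)
  a1 <- x$map$a1
  a2 <- x$map$a2
  rows <- vapply(seq_along(ids), function(i) {
    d <- g[i, ]
    first <- ifelse(is.na(d), "0", ifelse(d >= 1, a2, a1))
    second <- ifelse(is.na(d), "0", ifelse(d == 2, a2, a1))
    paste(c(ids[i], ids[i], sire[i], dam[i], sex[i], "-9",
            as.vector(rbind(first, second))), collapse = " ")
  }, character(1))
  writeLines(rows, ped_path)
  invisible(c(ped_path, map_path))
}

#' Read genotypes from a VCF (GT field)
#'
#' Uses \pkg{vcfR}; biallelic records only. REF is coded as allele a1 and
#' ALT as a2, so dosage counts ALT copies.
#'
#' @param path VCF path (plain text or gzip).
#' @return a [genotype_matrix()].
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stopf("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) stopf("multi-allelic records not supported: %s",
                        paste(utils::head(fix[multi, "ID"], 3), collapse = ","))
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- apply(gt, 2, function(col) {
    a <- sub("[/|].*", "", col)
    b <- sub(".*[/|]", "", col)
    ifelse(is.na(col) | a == "." | b == ".", NA_real_,
           as.numeric(a != "0") + as.numeric(b != "0"))
  })
  dose <- t(dose)  # vcfR: rows = variants; we want animals x SNPs
  snp <- fix[, "ID"]
  snp[is.na(snp) | snp == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(snp) | snp == "."]
  map <- data.frame(snp = snp, chr = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]),
                    a1 = fix[, "REF"], a2 = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  genotype_matrix(dose, map)
}

#' Write genotypes as a minimal VCF v4.2 (GT only)
#'
#' @param x a [genotype_matrix()] with integer dosages.
#' @param path output path (plain text).
#' @return invisibly, `path`.
#' @export
write_vcf_genotypes <- function(x, path) {
  g <- x$geno
  if (any(!is.na(g) & g != round(g)))
    stopf("VCF GT cannot represent fractional (imputed) dosages")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(g)), collapse = "\t")), con)
  gtcode <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(ncol(g))) {
    d <- g[, j]
    gt <- ifelse(is.na(d), "./.", gtcode[as.character(d)])
    writeLines(paste(c(x$map$chr[j], x$map$pos[j], x$map$snp[j],
                       x$map$a1[j], x$map$a2[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read / write phenotype and dEBV tables (TSV with header)
#' @param path file path.
#' @return data frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_table_tsv
#' @param df data frame to write.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
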