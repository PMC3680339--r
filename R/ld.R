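# Pairwise genotypic LD, decay with distance, SNP windows and interval
# annotation.

#' Pairwise genotypic r-squared within a distance limit
#'
#' Composite LD from unphased dosages: for every same-chromosome SNP pair
#' within `max_distance_bp`, r2 is the squared Pearson correlation of the
#' dosage vectors. Monomorphic SNPs are skipped with a warning; pairs with
#' no complete observations are skipped and counted.
#'
#' @param genotypes a [genotype_matrix()].
#' @param max_distance_bp maximum pair distance in bp (default 1e6).
#' @return data frame (`snp1`, `snp2`, `chr`, `dist_bp`, `r2`) with
#'   attribute `n_skipped_pairs`.
#' @export
pairwise_r2 <- function(genotypes, max_distance_bp = 1e6) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  g <- genotypes$geno
  map <- genotypes$map
  mono <- apply(g, 2, function(x) stats::var(x, na.rm = TRUE)) == 0
  mono[is.na(mono)] <- TRUE
  if (any(mono)) {
    warnf("skipping %d monomorphic SNP(s)", sum(mono))
    g <- g[, !mono, drop = FALSE]
    map <- map[!mono, , drop = FALSE]
  }
  res <- list()
  skipped <- 0L
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    if (length(idx) < 2) next
    o <- idx[order(map$pos[idx])]
    pos <- map$pos[o]
    for (a in seq_len(length(o) - 1)) {
      b <- a + 1
      while (b <= length(o) && pos[b] - pos[a] <= max_distance_bp) {
        xa <- g[, o[a]]
        xb <- g[, o[b]]
        ok <- !is.na(xa) & !is.na(xb)
        if (sum(ok) >= 3 && stats::var(xa[ok]) > 0 && stats::var(xb[ok]) > 0) {
          r <- stats::cor(xa[ok], xb[ok])
          res[[length(res) + 1L]] <- data.frame(
            snp1 = map$snp[o[a]], snp2 = map$snp[o[b]], chr = ch,
            dist_bp = pos[b] - pos[a], r2 = r^2,
            stringsAsFactors = FALSE)
        } else skipped <- skipped + 1L
        b <- b + 1
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(snp1 = character(0), snp2 = character(0), chr = character(0),
               dist_bp = integer(0), r2 = numeric(0))
  rownames(out) <- NULL
  attr(out, "n_skipped_pairs") <- skipped
  out
}

#' LD decay table: mean r-squared per distance bin
#'
#' @param records output of [pairwise_r2()].
#' @param bin_width_bp bin width in bp (default 50000). Bins are
#'   `[k * width, (k + 1) * width)`.
#' @return data frame `bin_start`, `bin_end`, `mean_r2`, `n_pairs`,
#'   `cum_mean_r2` (cumulative mean over all pairs up to the bin's end,
#'   since "average r2 at a distance" can be read either way).
#' @export
ld_decay <- function(records, bin_width_bp = 50000) {
  if (!nrow(records)) stopf("no LD records")
  bin <- floor(records$dist_bp / bin_width_bp)
  agg <- stats::aggregate(records$r2, by = list(bin = bin),
                          FUN = function(x) c(mean(x), length(x)))
  out <- data.frame(bin_start = agg$bin * bin_width_bp,
                    bin_end = (agg$bin + 1) * bin_width_bp,
                    mean_r2 = agg$x[, 1], n_pairs = agg$x[, 2])
  out <- out[order(out$bin_start), , drop = FALSE]
  ord <- order(records$dist_bp)
  r2o <- records$r2[ord]
  do <- records$dist_bp[ord]
  out$cum_mean_r2 <- vapply(out$bin_end, function(e) mean(r2o[do < e]),
                            numeric(1))
  rownames(out) <- NULL
  out
}

#' Windows around query SNPs
#'
#' A window is `[max(1, pos - half_width), pos + half_width]`, 1-based
#' inclusive, clamped at the chromosome start.
#'
#' @param snps character vector of SNP ids.
#' @param map SNP map (`snp`, `chr`, `pos`).
#' @param half_width_bp half-width in bp (default 250000, i.e. 500 kb
#'   windows).
#' @return data frame `snp`, `chr`, `pos`, `start`, `end`.
#' @export
snp_windows <- function(snps, map, half_width_bp = 250000) {
  m <- match(snps, map$snp)
  if (anyNA(m))
    stopf("SNP(s) not in map: %s",
          paste(utils::head(snps[is.na(m)], 5), collapse = ", "))
  data.frame(snp = snps, chr = map$chr[m], pos = map$pos[m],
             start = pmax(1, map$pos[m] - half_width_bp),
             end = map$pos[m] + half_width_bp,
             stringsAsFactors = FALSE)
}

#' Read gene/QTL feature intervals from BED or GFF3
#'
#' BED input (0-based half-open) is converted to 1-based inclusive at the
#' boundary; GFF3 is already 1-based inclusive. Uses \pkg{rtracklayer}.
#'
#' @param path file path ending in .bed, .gff, .gff3 or .gtf.
#' @param kind feature kind label ("gene" or "QTL") attached to every row.
#' @return data frame `feature`, `kind`, `chr`, `start`, `end`, `source`.
#' @export
read_features <- function(path, kind = "gene") {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stopf("reading BED/GFF requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  nm <- if (!is.null(gr$Name)) as.character(gr$Name)
        else if (!is.null(gr$name)) as.character(gr$name)
        else if (!is.null(gr$ID)) as.character(gr$ID)
        else paste0("feature", seq_along(gr))
  data.frame(feature = nm, kind = kind,
             chr = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             source = basename(path), stringsAsFactors = FALSE)
}

#' Validate a feature-interval table
#'
#' @param features data frame `feature`, `chr`, `start`, `end` (optional
#'   `kind`, `source`).
#' @return the validated (normalized) data frame.
#' @export
validate_features <- function(features) {
  need <- c("feature", "chr", "start", "end")
  if (!all(need %in% names(features)))
    stopf("features need columns: %s", paste(need, collapse = ", "))
  bad <- which(features$start > features$end)
  if (length(bad))
    stopf("malformed interval(s) with start > end at row(s): %s",
          paste(utils::head(bad, 5), collapse = ", "))
  if (is.null(features$kind)) features$kind <- "gene"
  if (is.null(features$source)) features$source <- NA_character_
  features
}

#' Annotate windows with overlapping features
#'
#' Reports one row per (window, feature) pair whose intervals intersect by
#' at least 1 bp, using IRanges overlap machinery; chromosome labels are
#' normalized (leading "chr" stripped, case-insensitive) before comparison.
#'
#' @param windows data frame from [snp_windows()].
#' @param features data frame of feature intervals (see
#'   [validate_features()]).
#' @return data frame `snp`, `chr`, `window_start`, `window_end`, `feature`,
#'   `kind`, `feature_start`, `feature_end`, `overlap_bp`.
#' @export
annotate_windows <- function(windows, features) {
  features <- validate_features(features)
  wch <- norm_chrom(windows$chr)
  fch <- norm_chrom(features$chr)
  empty <- data.frame(snp = character(0), chr = character(0),
                      window_start = integer(0), window_end = integer(0),
                      feature = character(0), kind = character(0),
                      feature_start = integer(0), feature_end = integer(0),
                      overlap_bp = integer(0), stringsAsFactors = FALSE)
  if (!nrow(windows) || !nrow(features)) return(empty)
  qr <- GenomicRanges::GRanges(wch,
          IRanges::IRanges(windows$start, windows$end))
  sb <- GenomicRanges::GRanges(fch,
          IRanges::IRanges(features$start, features$end))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(qr, sb))
  if (!length(ov)) return(empty)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  olap <- pmin(windows$end[qi], features$end[si]) -
    pmax(windows$start[qi], features$start[si]) + 1L
  out <- data.frame(snp = windows$snp[qi], chr = windows$chr[qi],
                    window_start = windows$start[qi],
                    window_end = windows$end[qi],
                    feature = features$feature[si],
                    kind = features$kind[si],
                    feature_start = features$start[si],
                    feature_end = features$end[si],
                    overlap_bp = olap, stringsAsFactors = FALSE)
  out[order(out$snp, out$feature), , drop = FALSE]
}
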