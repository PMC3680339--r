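# Two-step top-1% SNP selection, kinship-minimizing subsamples, and the
# Common-SNP / Highest-1% candidate strategies.

new_candidate_set <- function(df, provenance) {
  rownames(df) <- NULL
  attr(df, "provenance") <- provenance
  class(df) <- c("candidate_set", "data.frame")
  df
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("Candidate set [%s]: %d SNPs on %d chromosome(s)\n",
              attr(x, "provenance") %||% "?", nrow(x),
              length(unique(x$chr))))
  invisible(x)
}

#' Keep the top fraction of SNPs by importance, per chromosome
#'
#' For each chromosome with `n_c` SNPs keeps the `max(1, floor(fraction *
#' n_c))` highest-importance SNPs. Ties are broken by higher score then
#' lexicographic SNP id.
#'
#' @param table an `importance_table` (or data frame with `snp`, `chr`,
#'   `importance`).
#' @param fraction fraction to keep, in (0, 1] (default 0.01).
#' @return a `candidate_set` data frame (`snp`, `chr`, `score`).
#' @export
select_top_fraction_by_chromosome <- function(table, fraction = 0.01) {
  check_fraction(fraction)
  stopifnot(all(c("snp", "chr", "importance") %in% names(table)))
  parts <- split(seq_len(nrow(table)), table$chr)
  keep <- unlist(lapply(parts, function(idx) {
    k <- max(1L, floor(fraction * length(idx)))
    o <- order(-table$importance[idx], table$snp[idx])
    idx[o][seq_len(k)]
  }), use.names = FALSE)
  keep <- sort(keep)
  new_candidate_set(
    data.frame(snp = table$snp[keep], chr = table$chr[keep],
               score = table$importance[keep], stringsAsFactors = FALSE),
    provenance = "stage-1")
}

#' Keep the top fraction of SNPs by importance, pooled across chromosomes
#'
#' Keeps the `max(1, floor(fraction * n))` highest-importance SNPs
#' disregarding chromosome; same tie-breaking as the per-chromosome rule.
#'
#' @inheritParams select_top_fraction_by_chromosome
#' @return a `candidate_set`.
#' @export
select_top_fraction <- function(table, fraction = 0.01) {
  check_fraction(fraction)
  k <- max(1L, floor(fraction * nrow(table)))
  o <- order(-table$importance, table$snp)
  keep <- sort(o[seq_len(k)])
  new_candidate_set(
    data.frame(snp = table$snp[keep], chr = table$chr[keep],
               score = table$importance[keep], stringsAsFactors = FALSE),
    provenance = "stage-2")
}

check_fraction <- function(fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1)
    stopf("fraction must be a single number in (0, 1]")
}

#' Two-step random-forest SNP selection
#'
#' Stage 1 fits a forest on all SNPs and keeps the highest `fraction`
#' (default 1\%) of SNPs by importance within each chromosome; stage 2
#' re-fits the forest on the stage-1 SNPs only (mtry recomputed as 10\% of
#' the reduced set) and keeps the highest `fraction` pooled across
#' chromosomes.
#'
#' @param genotypes imputed [genotype_matrix()].
#' @param response numeric response (dEBV) per animal.
#' @param fraction selection fraction per stage (default 0.01).
#' @param n_trees,mtry_fraction,importance forest parameters, see
#'   [rf_importance()].
#' @param seed integer seed (stage 2 uses `seed + 1`).
#' @return a `candidate_set` (the stage-2 set) with attributes `stage1`
#'   (stage-1 `candidate_set`) and `importance` (stage-1 table).
#' @export
two_step_select <- function(genotypes, response, fraction = 0.01,
                            n_trees = 5000, mtry_fraction = 0.10,
                            importance = "permutation", seed = 1L) {
  t1 <- rf_importance(genotypes, response, n_trees = n_trees,
                      mtry_fraction = mtry_fraction,
                      importance = importance, seed = seed)
  s1 <- select_top_fraction_by_chromosome(t1, fraction)
  g2 <- genotypes[, s1$snp]
  t2 <- rf_importance(g2, response, n_trees = n_trees,
                      mtry_fraction = mtry_fraction,
                      importance = importance, seed = seed + 1L)
  s2 <- select_top_fraction(t2, fraction)
  attr(s2, "stage1") <- s1
  attr(s2, "importance") <- t1
  s2
}

#' Build kinship-minimizing subsamples of the genotyped animals
#'
#' For each subsample: the first animal is chosen at random; each subsequent
#' animal is the unselected one with the lowest mean relationship to the
#' already-selected set, ties broken by the highest mean relationship to the
#' remaining unselected animals (most representative of the rest), then by
#' animal id; repeated until `size` animals are selected.
#'
#' @param A numerator relationship matrix (dimnames = animal ids).
#' @param genotyped character vector of genotyped animal ids (subset of
#'   `rownames(A)`).
#' @param n_subsamples number of subsamples (default 10).
#' @param size animals per subsample (default 198).
#' @param seed integer seed.
#' @return object of class `subsample_plan`: list of character vectors, with
#'   attributes `size`, `seed`.
#' @export
build_subsamples <- function(A, genotyped, n_subsamples = 10, size = 198,
                             seed = 1L) {
  genotyped <- as.character(genotyped)
  if (!all(genotyped %in% rownames(A)))
    stopf("genotyped animals missing from the relationship matrix")
  if (size > length(genotyped))
    stopf("subsample size %d exceeds %d genotyped animals",
          size, length(genotyped))
  Ag <- A[genotyped, genotyped, drop = FALSE]
  n <- length(genotyped)
  plan <- with_local_seed(seed, {
    lapply(seq_len(n_subsamples), function(rep) {
      sel <- logical(n)
      ord <- order(genotyped)           # id tie-break order
      start <- sample.int(n, 1)
      sel[start] <- TRUE
      sum_to_sel <- Ag[, start]         # running sum of A to selected set
      while (sum(sel) < size) {
        cand <- which(!sel)
        mean_sel <- sum_to_sel[cand] / sum(sel)
        best <- cand[mean_sel == min(mean_sel)]
        if (length(best) > 1) {
          # representativeness: highest mean relationship to the rest
          rest_sum <- rowSums(Ag[best, !sel, drop = FALSE]) - diag(Ag)[best]
          nrest <- sum(!sel) - 1
          mean_rest <- if (nrest > 0) rest_sum / nrest else rest_sum * 0
          best <- best[mean_rest == max(mean_rest)]
          if (length(best) > 1)
            best <- best[order(genotyped[best])][1]
        }
        sel[best] <- TRUE
        sum_to_sel <- sum_to_sel + Ag[, best]
      }
      genotyped[sel]
    })
  })
  structure(plan, size = size, seed = seed, class = "subsample_plan")
}

#' @export
print.subsample_plan <- function(x, ...) {
  cat(sprintf("Subsample plan: %d subsamples of %d animals (seed %d)\n",
              length(x), attr(x, "size"), attr(x, "seed")))
  invisible(x)
}

#' Common-SNP candidate strategy
#'
#' Combines the full-sample run with the subsample runs: keeps SNPs present
#' in the full-sample set (stage 1 by default) and in at least
#' `min_subsample_hits` of the subsample candidate sets. Output is ordered
#' by the number of supporting subsample runs, then score, then id.
#'
#' @param full_run a `candidate_set` from the full-sample analysis. When it
#'   carries a `stage1` attribute (as from [two_step_select()]) and
#'   `full_stage = "stage1"` (default), the stage-1 set is used for the
#'   membership test.
#' @param subsample_runs list of `candidate_set`s, one per subsample.
#' @param min_subsample_hits minimum supporting subsamples (default 1).
#' @param full_stage `"stage1"` or `"stage2"`: which full-run set defines
#'   membership.
#' @return a `candidate_set` with provenance `"common"` and column `hits`.
#' @export
common_snp_strategy <- function(full_run, subsample_runs,
                                min_subsample_hits = 1,
                                full_stage = c("stage1", "stage2")) {
  full_stage <- match.arg(full_stage)
  if (!length(subsample_runs)) stopf("no subsample runs supplied")
  base <- if (full_stage == "stage1" && !is.null(attr(full_run, "stage1")))
    attr(full_run, "stage1") else full_run
  if (!nrow(base)) stopf("empty full-sample candidate set")
  hits <- vapply(base$snp, function(s) {
    sum(vapply(subsample_runs, function(r) s %in% r$snp, logical(1)))
  }, integer(1))
  keep <- hits >= min_subsample_hits
  if (!any(keep))
    warnf("no SNP shared between the full run and %d+ subsample run(s)",
          min_subsample_hits)
  out <- data.frame(snp = base$snp[keep], chr = base$chr[keep],
                    score = base$score[keep], hits = hits[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$hits, -out$score, out$snp), , drop = FALSE]
  new_candidate_set(out, provenance = "common")
}
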