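# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a local RNG seed
#'
#' Evaluates `code` with the global RNG seeded at `seed`, then restores the
#' previous RNG state so callers' random streams are unaffected.
#' @noRd
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Normalize chromosome labels
#'
#' Strips a leading "chr" prefix and lower-cases, so "chr10", "Chr10" and
#' "10" compare equal across genotype maps and annotation files.
#' @param x character vector of chromosome labels.
#' @return normalized character vector.
#' @export
norm_chrom <- function(x) {
  tolower(sub("^chr", "", as.character(x), ignore.case = TRUE))
}

#' Derive per-stage seeds from a master seed
#'
#' Deterministic scheme so any pipeline stage can be re-run in isolation:
#' stage k receives `(master * 1009 + 97 * k) mod (2^31 - 1)`.
#' @param master integer master seed.
#' @param n number of stage seeds.
#' @return integer vector of length `n`.
#' @export
stage_seeds <- function(master, n) {
  master <- as.double(master)
  vapply(seq_len(n), function(k) {
    as.integer((master * 1009 + 97 * k) %% (2^31 - 1))
  }, integer(1))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
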