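#' Deregress estimated breeding values
#'
#' Turns EBVs into deregressed proofs (dEBV) usable as pseudo-phenotypes for
#' association analysis, with information weights.
#'
#' The default `"full"` mode removes the parent-average contribution: for an
#' animal with reliability \eqn{r^2} and parent-average reliability
#' \eqn{r^2_{PA} = (r^2_{sire} + r^2_{dam})/4}, a 2x2 mixed-model system in
#' the parent average and the individual's own effect is reconstructed from
#' the two reliabilities (its information contents are the unknowns), and
#' the deregressed proof is the individual's right-hand side divided by its
#' own information. When both parents are unknown the parent-average
#' equation drops out and the system reduces exactly to the `"simple"` mode,
#' `dEBV = EBV / r^2`.
#'
#' The weight for downstream weighted analyses is
#' \eqn{w = (1 - h^2) / ((c + (1 - r^2_d)/r^2_d) h^2)}, where \eqn{r^2_d} is
#' the reliability of the deregressed information and `c` the fraction of
#' genetic variance not accounted for by markers.
#'
#' @param bvs a `blup_fit` or a data frame with columns `animal`, `ebv`,
#'   `accuracy` (accuracy r, not reliability).
#' @param ped a [pedigree()] giving parent links.
#' @param h2 heritability (taken from the `blup_fit` when available).
#' @param c_frac fraction of genetic variance not explained by markers used
#'   in the weight (default 0.5).
#' @param mode `"full"` (parent-average removing, default) or `"simple"`
#'   (`EBV / r^2`).
#' @param r2_floor animals with reliability at or below this floor are
#'   flagged excluded (default 0.1).
#' @return object of class `debv_set`: data frame `animal`, `ebv`, `r2`
#'   (EBV reliability), `r2_pa`, `debv`, `r2_debv`, `w`, `excluded`.
#' @examples
#' ped <- pedigree(c("s", "d", "x"), c(NA, NA, "s"), c(NA, NA, "d"))
#' bv <- data.frame(animal = c("s", "d", "x"), ebv = c(0.2, -0.1, 1),
#'                  accuracy = c(0.8, 0.7, sqrt(0.5)))
#' deregress_ebv(bv, ped, h2 = 0.16, mode = "simple")
#' @export
deregress_ebv <- function(bvs, ped, h2 = NULL, c_frac = 0.5,
                          mode = c("full", "simple"), r2_floor = 0.1) {
  mode <- match.arg(mode)
  if (inherits(bvs, "blup_fit")) {
    h2 <- h2 %||% bvs$h2
    bvs <- bvs$ebv
  }
  if (is.null(h2)) stopf("h2 is required")
  stopifnot(inherits(ped, "pedigree"),
            all(c("animal", "ebv", "accuracy") %in% names(bvs)))
  bvs <- bvs[match(ped$animal, bvs$animal), , drop = FALSE]
  if (anyNA(bvs$animal))
    stopf("breeding values missing for some pedigree animals")
  r2 <- pmin(1, bvs$accuracy^2)
  names(r2) <- bvs$animal
  pi <- parent_index(ped)
  r2s <- ifelse(is.na(pi$sire), 0, r2[pi$sire])
  r2d <- ifelse(is.na(pi$dam), 0, r2[pi$dam])
  r2pa <- (r2s + r2d) / 4
  ebv_s <- ifelse(is.na(pi$sire), 0, bvs$ebv[pi$sire])
  ebv_d <- ifelse(is.na(pi$dam), 0, bvs$ebv[pi$dam])
  pa <- (ebv_s + ebv_d) / 2
  no_pa <- is.na(pi$sire) & is.na(pi$dam)

  lambda <- (1 - h2) / h2
  n <- nrow(bvs)
  debv <- rep(NA_real_, n)
  r2_debv <- rep(NA_real_, n)
  excluded <- r2 <= r2_floor

  for (k in seq_len(n)) {
    if (excluded[k]) next
    if (mode == "simple" || no_pa[k] || r2pa[k] <= 0) {
      debv[k] <- bvs$ebv[k] / r2[k]
      r2_debv[k] <- r2[k]
      next
    }
    # 2x2 information system: unknowns are the information contents
    # (Z'Z)_PA and (Z'Z)_i; the two reliability constraints give a
    # quadratic in the determinant of the left-hand side.
    qi <- 1 - r2[k]
    qpa <- 1 - 2 * r2pa[k]
    if (qpa <= 0) {           # parent average already fully reliable
      debv[k] <- bvs$ebv[k] / r2[k]
      r2_debv[k] <- r2[k]
      next
    }
    D <- lambda^2 * (1 + sqrt(1 + 8 * qi * qpa)) / (qi * qpa)
    a11 <- qi * D / lambda            # (Z'Z)_PA + 4 lambda
    a22 <- qpa * D / (2 * lambda)     # (Z'Z)_i  + 2 lambda
    zz_i <- a22 - 2 * lambda
    zz_pa <- a11 - 4 * lambda
    if (zz_i <= 0 || zz_pa < 0) {
      # reliabilities inconsistent with a positive-information 2x2 system;
      # fall back to the single-equation form
      debv[k] <- bvs$ebv[k] / r2[k]
      r2_debv[k] <- r2[k]
      next
    }
    y_i <- -2 * lambda * pa[k] + a22 * bvs$ebv[k]
    debv[k] <- y_i / zz_i
    r2_debv[k] <- zz_i / (zz_i + lambda)
  }
  w <- ifelse(excluded | is.na(r2_debv) | r2_debv <= 0, NA_real_,
              (1 - h2) / ((c_frac + (1 - r2_debv) / r2_debv) * h2))
  out <- data.frame(animal = bvs$animal, ebv = bvs$ebv, r2 = r2,
                    r2_pa = r2pa, debv = debv, r2_debv = r2_debv,
                    w = w, excluded = excluded, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "h2") <- h2
  attr(out, "c_frac") <- c_frac
  attr(out, "mode") <- mode
  class(out) <- c("debv_set", "data.frame")
  out
}

#' Information weight for a deregressed proof
#'
#' @param r2_debv reliability of the deregressed information.
#' @param h2 heritability.
#' @param c_frac fraction of genetic variance not explained by markers.
#' @return numeric weight(s).
#' @export
debv_weight <- function(r2_debv, h2, c_frac = 0.5) {
  (1 - h2) / ((c_frac + (1 - r2_debv) / r2_debv) * h2)
}
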