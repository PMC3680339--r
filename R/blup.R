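#' Animal-model BLUP with known variance ratio
#'
#' Solves Henderson's mixed-model equations for the model
#' `y = Xb + Zu + e`, with `u ~ N(0, A sigma2_a)` and `e ~ N(0, I sigma2_e)`,
#' where A is the pedigree numerator relationship matrix. Variance
#' components are taken as known (the paper-style workflow estimates the
#' heritability externally): either pass `sigma2_a`/`sigma2_e`, or pass `h2`
#' and a phenotypic variance (defaults to the residual variance of the
#' fixed-effects-only fit).
#'
#' Fixed-effect identifiability uses the reference-level (treatment)
#' constraint: the first level of each factor is dropped. Columns that are
#' still aliased after that raise an error naming them.
#'
#' @param phenotypes data frame with one row per record; must contain the
#'   animal id column and all model variables.
#' @param fixed one-sided formula of fixed effects, e.g. `~ cg + age`.
#' @param ped a [pedigree()] containing every phenotyped animal.
#' @param h2 heritability used to form the variance ratio (ignored when
#'   `sigma2_a` and `sigma2_e` are given).
#' @param sigma2_p phenotypic variance scale used with `h2`; default is the
#'   residual variance of `lm(y ~ X)`.
#' @param sigma2_a,sigma2_e additive and residual variances (optional,
#'   override `h2`/`sigma2_p`).
#' @param response name of the response column (default "y").
#' @param animal_col name of the animal id column (default "animal").
#' @return object of class `blup_fit`: list with `ebv` (data frame `animal`,
#'   `ebv`, `pev`, `accuracy` for every pedigree animal), `beta` (fixed
#'   effects), `sigma2_a`, `sigma2_e`, `h2`, and the assembled system
#'   (`lhs`, `rhs`) for verification.
#' @export
solve_animal_model <- function(phenotypes, fixed, ped,
                               h2 = NULL, sigma2_p = NULL,
                               sigma2_a = NULL, sigma2_e = NULL,
                               response = "y", animal_col = "animal") {
  stopifnot(inherits(ped, "pedigree"))
  if (!response %in% names(phenotypes))
    stopf("response column '%s' not found", response)
  ids <- as.character(phenotypes[[animal_col]])
  miss <- setdiff(ids, ped$animal)
  if (length(miss))
    stopf("phenotyped animals absent from pedigree: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  y <- as.numeric(phenotypes[[response]])
  X <- stats::model.matrix(fixed, data = phenotypes)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stopf("fixed-effect design is singular; aliased columns: %s",
          paste(bad, collapse = ", "))
  }
  if (is.null(sigma2_a) || is.null(sigma2_e)) {
    if (is.null(h2)) stopf("supply either h2 or sigma2_a and sigma2_e")
    if (h2 <= 0 || h2 >= 1) stopf("h2 must be in (0,1)")
    if (is.null(sigma2_p)) {
      r0 <- stats::lm.fit(X, y)$residuals
      sigma2_p <- sum(r0^2) / max(1, length(y) - qrX$rank)
    }
    sigma2_a <- h2 * sigma2_p
    sigma2_e <- (1 - h2) * sigma2_p
  }
  lambda <- sigma2_e / sigma2_a
  h2 <- sigma2_a / (sigma2_a + sigma2_e)

  nped <- nrow(ped)
  Z <- Matrix::sparseMatrix(i = seq_along(ids), j = match(ids, ped$animal),
                            x = 1, dims = c(length(ids), nped))
  Ainv <- a_inverse(ped)
  Xs <- Matrix::Matrix(X, sparse = TRUE)
  lhs <- rbind(
    cbind(Matrix::crossprod(Xs), Matrix::crossprod(Xs, Z)),
    cbind(Matrix::crossprod(Z, Xs), Matrix::crossprod(Z) + Ainv * lambda))
  rhs <- c(as.numeric(Matrix::crossprod(Xs, y)),
           as.numeric(Matrix::crossprod(Z, y)))
  Cd <- solve(as.matrix(lhs))           # dense inverse: PEV needs its diagonal
  sol <- Cd %*% rhs
  p <- ncol(X)
  beta <- stats::setNames(sol[seq_len(p)], colnames(X))
  u <- stats::setNames(sol[p + seq_len(nped)], ped$animal)
  pev <- diag(Cd)[p + seq_len(nped)] * sigma2_e
  acc <- sqrt(pmax(0, pmin(1, 1 - pev / sigma2_a)))
  structure(list(
    ebv = data.frame(animal = ped$animal, ebv = as.numeric(u),
                     pev = pev, accuracy = acc, stringsAsFactors = FALSE),
    beta = beta, sigma2_a = sigma2_a, sigma2_e = sigma2_e, h2 = h2,
    lambda = lambda, lhs = lhs, rhs = rhs, solution = as.numeric(sol)),
    class = "blup_fit")
}

#' @export
print.blup_fit <- function(x, ...) {
  cat(sprintf("Animal-model BLUP: %d animals, h2 = %.3f (lambda = %.3f)\n",
              nrow(x$ebv), x$h2, x$lambda))
  cat(sprintf("  EBV range [%.4f, %.4f], mean accuracy %.3f\n",
              min(x$ebv$ebv), max(x$ebv$ebv), mean(x$ebv$accuracy)))
  invisible(x)
}
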