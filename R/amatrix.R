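#' Numerator relationship matrix by the tabular method
#'
#' Computes the additive (numerator) relationship matrix A over all animals
#' of a pedigree with the tabular recursion: processing animals in
#' topological order, \eqn{a_{ij} = (a_{i,s(j)} + a_{i,d(j)})/2} for earlier
#' animals i, and \eqn{a_{jj} = 1 + a_{s(j),d(j)}/2}; unknown parents
#' contribute zero. The diagonal is 1 plus the inbreeding coefficient.
#'
#' @param ped a [pedigree()].
#' @return symmetric numeric matrix with animal ids as dimnames.
#' @examples
#' ped <- pedigree(c("s", "d", "x"), c(NA, NA, "s"), c(NA, NA, "d"))
#' build_a_matrix(ped)["s", "x"]  # 0.5
#' @export
build_a_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  pi <- parent_index(ped)
  si <- pi$sire
  di <- pi$dam
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (j in seq_len(n)) {
    if (j > 1L) {
      i <- seq_len(j - 1L)
      aj <- numeric(j - 1L)
      if (!is.na(si[j])) aj <- aj + 0.5 * A[i, si[j]]
      if (!is.na(di[j])) aj <- aj + 0.5 * A[i, di[j]]
      A[i, j] <- aj
      A[j, i] <- aj
    }
    A[j, j] <- 1 + if (!is.na(si[j]) && !is.na(di[j]))
      0.5 * A[si[j], di[j]] else 0
  }
  A
}

#' Inbreeding coefficients from a pedigree
#'
#' @param ped a [pedigree()].
#' @return named numeric vector F = diag(A) - 1.
#' @export
inbreeding <- function(ped) {
  diag(build_a_matrix(ped)) - 1
}

#' Inverse of the numerator relationship matrix by Henderson's rules
#'
#' Builds A^-1 directly (accounting for inbreeding) without inverting A:
#' each animal contributes alpha_i = 1/b_i to the sparse inverse, where b_i
#' is the Mendelian-sampling variance given its known parents' inbreeding.
#'
#' @param ped a [pedigree()].
#' @param f optional precomputed inbreeding coefficients (named as in `ped`);
#'   computed via [inbreeding()] when missing.
#' @return sparse symmetric [Matrix::Matrix] A^-1 with animal dimnames.
#' @export
a_inverse <- function(ped, f = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  if (is.null(f)) f <- inbreeding(ped)
  f <- f[ped$animal]
  pi <- parent_index(ped)
  si <- pi$sire
  di <- pi$dam
  ii <- jj <- integer(0)
  xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  for (k in seq_len(n)) {
    s <- si[k]; d <- di[k]
    b <- if (!is.na(s) && !is.na(d)) {
      0.5 - 0.25 * (f[s] + f[d])
    } else if (!is.na(s)) {
      0.75 - 0.25 * f[s]
    } else if (!is.na(d)) {
      0.75 - 0.25 * f[d]
    } else 1
    al <- 1 / b
    add(k, k, al)
    for (p in c(s, d)) {
      if (!is.na(p)) {
        add(k, p, -al / 2); add(p, k, -al / 2)
      }
    }
    kp <- c(s, d)[!is.na(c(s, d))]
    for (p in kp) for (q in kp) add(p, q, al / 4)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                       dimnames = list(ped$animal, ped$animal))
}
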