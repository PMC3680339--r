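#' Forward stepwise regression with sequential partial R-squared
#'
#' Classic stepwise selection on SNP dosages: at each round the candidate
#' with the smallest partial-F p-value enters if it is below `sl_entry`;
#' after each entry, any entered predictor whose p-value has risen to
#' `sl_stay` or above is removed (worst first). Iteration stops when no
#' entry or removal happens. Sequential partial R-squared values are
#' recomputed at the end by adding the surviving predictors in their entry
#' order, so they are nonnegative and sum exactly to the final model
#' R-squared. Zero-variance and (numerically) collinear candidates are
#' skipped with a warning. An intercept is always included; dosages are not
#' standardized.
#'
#' @param response numeric response vector (dEBV).
#' @param candidates numeric matrix of candidate dosage columns (named).
#' @param sl_entry,sl_stay entry/stay significance levels (default 0.15,
#'   the convention of the classic stepwise implementations).
#' @return object of class `stepwise_fit`: list with `snps` (entry order),
#'   `partial_r2` (sequential increments, fractions), `r2` (total),
#'   `adj_r2`, `coefficients`, `n`, `sl_entry`, `sl_stay`, `skipped`.
#' @export
forward_stepwise <- function(response, candidates, sl_entry = 0.15,
                             sl_stay = 0.15) {
  y <- as.numeric(response)
  X <- as.matrix(candidates)
  if (is.null(colnames(X))) colnames(X) <- paste0("snp", seq_len(ncol(X)))
  n <- length(y)
  if (nrow(X) != n) stopf("response and candidates differ in length")
  skipped <- character(0)
  zv <- apply(X, 2, stats::var) == 0
  if (any(zv)) {
    warnf("skipping zero-variance candidate(s): %s",
          paste(colnames(X)[zv], collapse = ", "))
    skipped <- colnames(X)[zv]
    X <- X[, !zv, drop = FALSE]
  }
  tss <- sum((y - mean(y))^2)
  entered <- character(0)
  avail <- colnames(X)
  repeat {
    changed <- FALSE
    # entry step
    if (length(avail) && n > length(entered) + 2) {
      pv <- vapply(avail, function(v) {
        Xm <- cbind(1, X[, entered, drop = FALSE], X[, v])
        # collinearity guard: R2 of candidate on entered predictors
        if (length(entered)) {
          base <- cbind(1, X[, entered, drop = FALSE])
          rr <- stats::lm.fit(base, X[, v])$residuals
          if (sum(rr^2) < (1e-10) * sum((X[, v] - mean(X[, v]))^2))
            return(NA_real_)
        }
        fit <- stats::lm.fit(Xm, y)
        rss1 <- sum(fit$residuals^2)
        df2 <- n - ncol(Xm)
        if (df2 <= 0) return(NA_real_)
        rss0 <- sum(stats::lm.fit(Xm[, -ncol(Xm), drop = FALSE],
                                  y)$residuals^2)
        f <- (rss0 - rss1) / (rss1 / df2)
        stats::pf(f, 1, df2, lower.tail = FALSE)
      }, numeric(1))
      coll <- is.na(pv)
      if (any(coll)) {
        warnf("skipping collinear candidate(s): %s",
              paste(avail[coll], collapse = ", "))
        skipped <- c(skipped, avail[coll])
        avail <- avail[!coll]
        pv <- pv[!coll]
      }
      if (length(pv) && min(pv) < sl_entry) {
        best <- avail[order(pv, avail)][1]   # tie-break by id
        entered <- c(entered, best)
        avail <- setdiff(avail, best)
        changed <- TRUE
      }
    }
    # removal step
    repeat {
      if (length(entered) < 1) break
      Xm <- cbind(`(Intercept)` = 1, X[, entered, drop = FALSE])
      fit <- stats::lm.fit(Xm, y)
      rss <- sum(fit$residuals^2)
      df2 <- n - ncol(Xm)
      pv_in <- vapply(entered, function(v) {
        keep <- setdiff(entered, v)
        rss0 <- sum(stats::lm.fit(cbind(1, X[, keep, drop = FALSE]),
                                  y)$residuals^2)
        f <- (rss0 - rss) / (rss / df2)
        stats::pf(f, 1, df2, lower.tail = FALSE)
      }, numeric(1))
      worst <- which(pv_in == max(pv_in))
      if (max(pv_in) >= sl_stay) {
        drop_v <- entered[worst[order(entered[worst])][1]]
        entered <- setdiff(entered, drop_v)
        avail <- c(avail, drop_v)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  # sequential partial R2 over the final model, in entry order
  partial <- numeric(length(entered))
  names(partial) <- entered
  prev_r2 <- 0
  for (k in seq_along(entered)) {
    Xm <- cbind(1, X[, entered[seq_len(k)], drop = FALSE])
    r2k <- 1 - sum(stats::lm.fit(Xm, y)$residuals^2) / tss
    partial[k] <- r2k - prev_r2
    prev_r2 <- r2k
  }
  r2 <- prev_r2
  pfin <- length(entered)
  adj <- if (n - pfin - 1 > 0) 1 - (1 - r2) * (n - 1) / (n - pfin - 1) else NA
  coefs <- if (pfin) {
    Xm <- cbind(`(Intercept)` = 1, X[, entered, drop = FALSE])
    stats::setNames(stats::lm.fit(Xm, y)$coefficients, colnames(Xm))
  } else stats::setNames(mean(y), "(Intercept)")
  structure(list(snps = entered, partial_r2 = partial, r2 = r2,
                 adj_r2 = adj, coefficients = coefs, n = n,
                 sl_entry = sl_entry, sl_stay = sl_stay, skipped = skipped),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("Stepwise fit: %d of the candidates entered; R2 = %.2f%% (n = %d)\n",
              length(x$snps), 100 * x$r2, x$n))
  if (length(x$snps))
    print(data.frame(snp = x$snps, partial_r2_pct = 100 * x$partial_r2,
                     row.names = NULL))
  invisible(x)
}

#' Permutation bias test for the stepwise model R-squared
#'
#' Shuffles the response `n_permutations` times and, for each shuffle,
#' refits the final model on the same selected SNPs, recording a model-fit
#' statistic. The default statistic is the adjusted R-squared of the full
#' fixed model, whose null mean is ~0 for any n and p (the raw R-squared
#' has null mean p/(n-1), which is not negligible at p = 21, n = 396).
#' `statistic = "stepwise"` instead re-runs the stepwise selection on the
#' shuffled response and records the resulting model R-squared.
#'
#' @param response numeric response vector.
#' @param selected numeric dosage matrix of the final-model SNPs.
#' @param n_permutations number of shuffles (default 1000).
#' @param statistic `"adjusted"` (default), `"raw"`, or `"stepwise"`.
#' @param seed integer seed.
#' @param sl_entry,sl_stay stepwise thresholds for `statistic = "stepwise"`.
#' @return object of class `permutation_summary`: list with `mean`, `sd`,
#'   `values`, `n_permutations`, `statistic`, `n`, `p`, `seed`.
#' @export
permutation_r2 <- function(response, selected, n_permutations = 1000,
                           statistic = c("adjusted", "raw", "stepwise"),
                           seed = 1L, sl_entry = 0.15, sl_stay = 0.15) {
  statistic <- match.arg(statistic)
  y <- as.numeric(response)
  X <- as.matrix(selected)
  n <- length(y)
  p <- ncol(X)
  if (n_permutations < 1) stopf("n_permutations must be >= 1")
  if (statistic != "stepwise" && p > 0 && n < p + 2)
    stopf("need at least p + 2 = %d animals, have %d", p + 2, n)
  vals <- with_local_seed(seed, {
    if (p == 0) {
      rep(0, n_permutations)
    } else if (statistic == "stepwise") {
      vapply(seq_len(n_permutations), function(i) {
        suppressWarnings(
          forward_stepwise(sample(y), X, sl_entry, sl_stay)$r2)
      }, numeric(1))
    } else {
      # fixed design: orthonormalize once, then each permutation is one
      # crossproduct
      Q <- qr.Q(qr(cbind(1, X)))
      P <- replicate(n_permutations, sample(y))
      ybar <- mean(y)
      tss <- sum((y - ybar)^2)
      fitted_ss <- colSums(crossprod(Q, P)^2) - n * ybar^2
      r2 <- fitted_ss / tss
      if (statistic == "adjusted")
        1 - (1 - r2) * (n - 1) / (n - p - 1)
      else r2
    }
  })
  structure(list(mean = mean(vals), sd = stats::sd(vals), values = vals,
                 n_permutations = n_permutations, statistic = statistic,
                 n = n, p = p, seed = seed),
            class = "permutation_summary")
}

#' @export
print.permutation_summary <- function(x, ...) {
  cat(sprintf("Permutation test (%s R2, %d shuffles, n = %d, p = %d): %.2f +/- %.2f\n",
              x$statistic, x$n_permutations, x$n, x$p, x$mean, x$sd))
  invisible(x)
}
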