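test_that("an exact predictor enters first and explains everything", {
  set.seed(1)
  X <- matrix(rbinom(50 * 3, 2, 0.4), 50, 3,
              dimnames = list(NULL, c("s1", "s2", "s3")))
  y <- X[, 2]
  fit <- forward_stepwise(y, X)
  expect_equal(fit$snps[1], "s2")
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(sum(fit$partial_r2), fit$r2, tolerance = 1e-10)
})

test_that("no candidate below the entry threshold leaves an empty model", {
  set.seed(2)
  y <- rnorm(60)
  x <- rnorm(60)
  # verify the premise: marginal p-value above the entry level
  stopifnot(summary(lm(y ~ x))$coefficients[2, 4] > 0.15)
  fit <- forward_stepwise(y, cbind(s1 = x))
  expect_length(fit$snps, 0)
  expect_equal(fit$r2, 0)
})

test_that("orthogonal predictors decompose R2 into squared simple correlations", {
  set.seed(3)
  n <- 200
  x1 <- rnorm(n)
  x2 <- resid(lm(rnorm(n) ~ x1))      # exactly orthogonal to x1
  x1 <- x1 - mean(x1)
  x2 <- x2 - mean(x2)
  y <- 0.8 * x1 + 0.4 * x2 + rnorm(n, sd = 0.6)
  fit <- forward_stepwise(y, cbind(a = x1, b = x2), sl_entry = 0.5,
                          sl_stay = 0.5)
  # oracle: closed-form OLS on the constructed data
  r2_1 <- cor(y, x1)^2
  r2_2 <- cor(y, x2)^2
  expect_setequal(fit$snps, c("a", "b"))
  expect_equal(unname(fit$partial_r2[["a"]]), r2_1, tolerance = 1e-10)
  expect_equal(unname(fit$partial_r2[["b"]]), r2_2, tolerance = 1e-10)
  expect_equal(fit$r2, r2_1 + r2_2, tolerance = 1e-10)
})

test_that("the final model is invariant to candidate ordering", {
  set.seed(4)
  n <- 150
  X <- matrix(rbinom(n * 8, 2, 0.35), n, 8,
              dimnames = list(NULL, paste0("s", 1:8)))
  y <- 0.5 * X[, 3] - 0.4 * X[, 6] + rnorm(n)
  f1 <- forward_stepwise(y, X)
  perm <- sample(8)
  f2 <- forward_stepwise(y, X[, perm])
  expect_setequal(f1$snps, f2$snps)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-12)
  expect_equal(sum(f1$partial_r2), f1$r2, tolerance = 1e-10)
  expect_true(all(f1$partial_r2 >= -1e-12))
})

test_that("raw R2 never decreases as predictors are added", {
  set.seed(5)
  n <- 80
  X <- matrix(rnorm(n * 6), n, 6)
  y <- rnorm(n)
  r2s <- vapply(1:6, function(k) {
    summary(lm(y ~ X[, 1:k, drop = FALSE]))$r.squared
  }, numeric(1))
  expect_true(all(diff(r2s) >= -1e-12))
})

test_that("zero-variance and collinear candidates are skipped with warnings", {
  set.seed(6)
  n <- 60
  x1 <- rbinom(n, 2, 0.4)
  X <- cbind(s1 = x1, s2 = rep(1, n), s3 = 2 - x1,   # s3 collinear with s1
             s4 = rbinom(n, 2, 0.4))
  y <- x1 + rnorm(n, sd = 0.5)
  expect_warning(expect_warning(fit <- forward_stepwise(y, X),
                                "zero-variance"), "collinear")
  expect_true("s2" %in% fit$skipped)
  expect_true("s3" %in% fit$skipped)
  expect_true("s1" %in% fit$snps)
})

test_that("stepwise recovers planted marker variance at large n", {
  set.seed(7)
  n <- 2000
  p_sig <- 10
  X <- matrix(rbinom(n * 30, 2, 0.3), n, 30,
              dimnames = list(NULL, paste0("s", 1:30)))
  beta <- rnorm(p_sig, 0, 1)
  gvals <- X[, 1:p_sig] %*% beta
  # scale so markers explain 40% of variance
  gvals <- gvals * sqrt(0.4 / var(as.numeric(gvals)))
  y <- as.numeric(gvals) + rnorm(n, sd = sqrt(0.6))
  planted_share <- var(as.numeric(gvals)) / var(y)
  fit <- forward_stepwise(y, X)
  expect_equal(fit$r2, planted_share, tolerance = 0.05)
})

test_that("permutation summaries match the closed-form null of R2", {
  set.seed(8)
  n <- 100; p <- 5
  X <- matrix(rbinom(n * p, 2, 0.4), n, p)
  y <- rnorm(n)
  ps <- permutation_r2(y, X, n_permutations = 2000, statistic = "raw",
                       seed = 9)
  # null R2 ~ Beta(p/2, (n-p-1)/2): mean p/(n-1), var 2p(n-p-1)/((n-1)^2(n+1))
  mu <- p / (n - 1)
  v <- 2 * p * (n - p - 1) / ((n - 1)^2 * (n + 1))
  expect_lt(abs(ps$mean - mu), 3 * sqrt(v / 2000))
  expect_lt(abs(ps$sd - sqrt(v)), 0.15 * sqrt(v))
  # adjusted statistic has null mean ~ 0
  psa <- permutation_r2(y, X, n_permutations = 2000, statistic = "adjusted",
                        seed = 9)
  expect_lt(abs(psa$mean), 3 * sqrt(v / 2000) * (n - 1) / (n - p - 1))
  # determinism under seed
  ps2 <- permutation_r2(y, X, n_permutations = 50, seed = 10)
  ps3 <- permutation_r2(y, X, n_permutations = 50, seed = 10)
  expect_identical(ps2$values, ps3$values)
})

test_that("degenerate permutation inputs behave as documented", {
  y <- rnorm(30)
  ps <- permutation_r2(y, matrix(numeric(0), 30, 0), n_permutations = 10)
  expect_true(all(ps$values == 0))
  expect_error(permutation_r2(y, matrix(rnorm(30 * 29), 30, 29)),
               "animals")
  # the stepwise-reselection mode runs and stays small under the null
  set.seed(11)
  X <- matrix(rbinom(30 * 3, 2, 0.4), 30, 3)
  pss <- permutation_r2(rnorm(30), X, n_permutations = 20,
                        statistic = "stepwise", seed = 12)
  expect_true(all(pss$values >= 0 & pss$values <= 1))
})
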