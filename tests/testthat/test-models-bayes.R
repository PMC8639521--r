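test_that("prior elicitation follows the target-variance rule", {
  set.seed(1)
  X <- matrix(rnorm(200), 20, 10)
  y <- rnorm(20)
  expect_error(elicit_prior(y, X, "BRR", R2geno = 1.2), "R2geno")

  # S = var(y) * R2 / MSx * (nu + 2): rebuild with a known MSx
  Xu <- scale(matrix(rnorm(40 * 25), 40, 25))
  msx <- sum(apply(Xu, 2, var))
  yv <- rnorm(40)
  pr <- elicit_prior(yv, Xu, "BayesA", R2geno = 0.5, nu = 5)
  expect_equal(pr$S, var(yv) * 0.5 / msx * 7)

  # S is linear in var(y): scaling y by 2 quadruples the variance and S
  pr_scaled <- elicit_prior(yv * 2, Xu, "BayesA")
  expect_equal(pr_scaled$S / pr$S, 4)

  # spike-slab correction: pi = 0.9 inflates the slab scale 10x
  prc <- elicit_prior(yv, Xu, "BayesC", pi = 0.9)
  prc0 <- elicit_prior(yv, Xu, "BayesC", pi = 0)
  expect_equal(prc$S / prc0$S, 10)
})

test_that("a degenerate all-spike prior yields mean-only predictions", {
  g <- sim_genotypes(40, 25, seed = 51)
  y <- fix_trait$y[1:40]
  pr <- elicit_prior(y, unclass(g), "BayesC", pi = 0.5)
  pr$pi <- 1
  fit <- fit_bayes(y, g, prior = pr, iters = 500, burnin = 100, thin = 2,
                   seed = 52)
  expect_true(all(fit$beta_hat == 0))
  expect_true(all(fit$inclusion_prob == 0))
  preds <- predict(fit, g)
  expect_equal(unname(preds), rep(fit$mu_hat, 40))
  expect_lt(abs(fit$mu_hat - mean(y)), 3 * sd(y) / sqrt(40))
})

test_that("chains are deterministic given a seed", {
  g <- sim_genotypes(30, 15, seed = 53)
  y <- rnorm(30)
  f1 <- fit_bayes(y, g, family = "BayesB", iters = 300, burnin = 50, seed = 9)
  f2 <- fit_bayes(y, g, family = "BayesB", iters = 300, burnin = 50, seed = 9)
  expect_identical(f1$beta_hat, f2$beta_hat)
  expect_identical(f1$residual_var_hat, f2$residual_var_hat)
  expect_error(fit_bayes(y, g, iters = 100, burnin = 100), "exceed")
  expect_error(fit_bayes(c(y[-1], NA), g, iters = 200, burnin = 50), "missing")
})

test_that("fixed-variance ridge regression is recovered by the Gibbs sampler", {
  set.seed(54)
  n <- 120; p <- 50
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X %*% rnorm(p, sd = 0.2)) + rnorm(n)
  sb2 <- 0.05; se2 <- 1
  fit <- fit_bayes(y, X, family = "BRR", iters = 20000, burnin = 2000,
                   thin = 2, seed = 55, fix_var = TRUE, sigma_beta2 = sb2,
                   sigma_e2 = se2, keep_samples = TRUE)
  Xc <- scale(X, scale = FALSE)
  ridge <- drop(solve(crossprod(Xc) + diag(se2 / sb2, p),
                      crossprod(Xc, y - mean(y))))
  z <- (unname(fit$beta_hat) - ridge) / batch_means_se(fit$beta_draws)
  # joint Monte-Carlo-error-level agreement across all coefficients
  expect_lt(sum(z^2), qchisq(0.999, df = p))
  expect_lt(max(abs(fit$beta_hat - ridge)), 0.01)
})

test_that("prediction applies training centering and validates inputs", {
  g <- sim_genotypes(30, 12, seed = 56)
  y <- rnorm(30)
  fit <- fit_bayes(y, g, family = "BRR", iters = 300, burnin = 50, seed = 57)
  expect_error(predict(fit, matrix(0, 5, 11)), "markers")
  # at-center genotypes predict exactly the intercept
  at_center <- matrix(rep(fit$centers, each = 4), nrow = 4)
  expect_equal(unname(predict(fit, at_center)), rep(fit$mu_hat, 4))
  expect_equal(predict_bayes(fit, unclass(g)), predict(fit, g))
  td <- tidy(fit)
  expect_equal(nrow(td), 12)
  expect_true(all(td$inclusion_prob >= 0 & td$inclusion_prob <= 1))
  expect_equal(glance(fit)$family, "BRR")
})
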