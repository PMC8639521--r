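#' Elicit the marker-effect variance prior from a target R-squared
#'
#' Sets the scale `S` of the scaled-inverse-chi-square prior on the
#' marker-effect variance so that the variance a priori explained by the
#' markers matches `R2geno * var(y)`. With `MSx = sum_j var(x_j)` (sum of the
#' centered marker-column variances) and prior mode `S / (nu + 2)`, that
#' gives `S = var(y) * R2geno / MSx * (nu + 2)`. Spike-slab families inflate
#' the slab scale by `1 / (1 - pi)` so the expected genomic variance is
#' preserved when only a fraction `1 - pi` of markers carry effects.
#'
#' @param y phenotype vector (training data).
#' @param X marker dosage matrix (centered internally for `MSx`).
#' @param family one of `"BRR"`, `"BayesA"`, `"BayesB"`, `"BayesC"`.
#' @param R2geno prior proportion of phenotypic variance explained by
#'   markers, in (0, 1). Default 0.5, a weakly-informative midpoint.
#' @param nu prior degrees of freedom (default 5).
#' @param pi point mass at zero for the spike-slab families (default 0.5;
#'   ignored for BRR/BayesA).
#'
#' @return A list of class `prior_spec` with `family`, `nu`, `S`, `pi`,
#'   `R2geno`.
#' @export
#' @examples
#' X <- matrix(rnorm(500), 50, 10)
#' elicit_prior(rnorm(50), X, "BayesA", R2geno = 0.5)
elicit_prior <- function(y, X, family = c("BRR", "BayesA", "BayesB", "BayesC"),
                         R2geno = 0.5, nu = 5, pi = 0.5) {
  family <- match.arg(family)
  if (!(R2geno > 0 && R2geno < 1)) {
    stop("R2geno must lie strictly between 0 and 1", call. = FALSE)
  }
  stopifnot(nu > 0, pi >= 0, pi < 1)
  msx <- sum(apply(X, 2, stats::var))
  if (msx <= 0) stop("all marker columns are constant", call. = FALSE)
  S <- stats::var(y) * R2geno / msx * (nu + 2)
  if (family %in% c("BayesB", "BayesC")) S <- S / (1 - pi)
  structure(list(family = family, nu = nu, S = S,
                 pi = if (family %in% c("BayesB", "BayesC")) pi else 0,
                 R2geno = R2geno),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("<prior_spec> %s: nu = %g, S = %.4g, pi = %g (R2geno = %g)\n",
              x$family, x$nu, x$S, x$pi, x$R2geno))
  invisible(x)
}

family_code <- function(family) {
  match(family, c("BRR", "BayesA", "BayesB", "BayesC")) - 1L
}

#' Fit a Bayesian-alphabet marker regression by Gibbs sampling
#'
#' Samples the posterior of `y = mu + X beta + e` under the chosen
#' marker-effect prior with standard conjugate updates: normal full
#' conditionals for the intercept and each effect, scaled-inverse-chi-square
#' updates for the effect variances (pooled for BRR/BayesC, per marker for
#' BayesA/BayesB), Bernoulli inclusion indicators for the spike-slab
#' families, and a scaled-inverse-chi-square update for the residual
#' variance. Returns posterior means over the post-burn-in thinned draws.
#'
#' @param y training phenotypes (no missing values).
#' @param X marker matrix (`n x p`); columns are centered internally and the
#'   centering constants are stored so new genotypes are centered identically
#'   at prediction time.
#' @param prior a [elicit_prior()] spec, or `NULL` to elicit one with the
#'   defaults (`R2geno = 0.5`, `nu = 5`).
#' @param family used only when `prior` is `NULL`.
#' @param iters,burnin,thin chain length controls (defaults 12000 / 2000 /
#'   5); `iters` must exceed `burnin`.
#' @param seed integer seed; identical settings and seed give identical
#'   chains.
#' @param fix_var if `TRUE`, the variances are frozen at `sigma_beta2` /
#'   `sigma_e2` (no variance updates) — a test mode in which the BRR
#'   posterior mean has a closed ridge-regression form.
#' @param sigma_beta2,sigma_e2 fixed variance values for `fix_var`.
#' @param keep_samples keep the thinned draws of `beta` and `mu` (for
#'   Monte-Carlo error estimation).
#'
#' @return An object of class `bayes_fit`: posterior means `mu_hat`,
#'   `beta_hat`, `residual_var_hat`, inclusion probabilities, chain metadata
#'   and centering constants.
#' @export
#' @examples
#' g <- sim_genotypes(80, 60, seed = 1)
#' tr <- sim_phenotypes(g, trait_sim_spec(h2_additive = 0.5, seed = 2))
#' fit <- fit_bayes(tr$y, g, family = "BRR", iters = 500, burnin = 100, seed = 3)
#' head(predict(fit, g))
fit_bayes <- function(y, X, prior = NULL,
                      family = c("BRR", "BayesA", "BayesB", "BayesC"),
                      iters = 12000L, burnin = 2000L, thin = 5L, seed = 1L,
                      fix_var = FALSE, sigma_beta2 = NULL, sigma_e2 = NULL,
                      keep_samples = FALSE) {
  if (anyNA(y)) stop("training phenotypes must not contain missing values", call. = FALSE)
  if (iters <= burnin) stop("iters must exceed burnin", call. = FALSE)
  X <- unclass(as_geno_or_matrix(X))
  if (nrow(X) != length(y)) stop("y and X dimensions do not match", call. = FALSE)
  centers <- colMeans(X)
  Xc <- sweep(X, 2, centers)
  if (is.null(prior)) {
    family <- match.arg(family)
    prior <- elicit_prior(y, Xc, family)
  }
  stopifnot(inherits(prior, "prior_spec"))
  # residual prior: mode at (1 - R2geno) * var(y)
  nu_e <- 5
  S_e <- stats::var(y) * (1 - prior$R2geno) * (nu_e + 2)
  vy <- stats::var(y)
  init_b2 <- if (fix_var) sigma_beta2 else prior$S / (prior$nu + 2)
  init_e2 <- if (fix_var) sigma_e2 else vy / 2
  if (fix_var && (is.null(sigma_beta2) || is.null(sigma_e2))) {
    stop("fix_var = TRUE requires sigma_beta2 and sigma_e2", call. = FALSE)
  }
  res <- withr::with_seed(as.integer(seed), {
    gibbs_bayes_cpp(as.numeric(y), Xc, family_code(prior$family),
                    prior$nu, prior$S, prior$pi, nu_e, S_e,
                    as.integer(iters), as.integer(burnin), as.integer(thin),
                    fix_var, init_b2, init_e2, keep_samples)
  })
  if (!all(is.finite(res$beta_hat)) || !is.finite(res$mu_hat)) {
    stop("Gibbs chain diverged: non-finite posterior means; check the prior scale",
         call. = FALSE)
  }
  structure(list(mu_hat = res$mu_hat,
                 beta_hat = stats::setNames(drop(res$beta_hat), colnames(X)),
                 beta_sd = drop(res$beta_sd),
                 inclusion_prob = drop(res$inclusion_prob),
                 residual_var_hat = res$residual_var_hat,
                 beta_draws = res$beta_draws, mu_draws = res$mu_draws,
                 centers = centers, prior = prior,
                 chain_meta = list(iters = iters, burnin = burnin, thin = thin,
                                   seed = as.integer(seed),
                                   n_kept = res$n_kept, fix_var = fix_var)),
            class = "bayes_fit")
}

as_geno_or_matrix <- function(x) {
  if (is_geno_matrix(x)) unclass(x) else as.matrix(x)
}

#' Predict phenotypes from a Bayesian marker regression
#'
#' Returns `mu_hat + X_new beta_hat`, centering the new genotypes with the
#' training centering constants.
#'
#' @param object a [fit_bayes()] object.
#' @param X_new new genotype matrix with the same markers as in training.
#' @param ... unused.
#' @return Numeric vector of predicted phenotypes.
#' @export
predict.bayes_fit <- function(object, X_new, ...) {
  X_new <- as_geno_or_matrix(X_new)
  if (ncol(X_new) != length(object$beta_hat)) {
    stop("X_new has a different number of markers than the training matrix",
         call. = FALSE)
  }
  Xc <- sweep(X_new, 2, object$centers)
  drop(object$mu_hat + Xc %*% object$beta_hat)
}

#' @rdname predict.bayes_fit
#' @export
predict_bayes <- function(object, X_new) predict.bayes_fit(object, X_new)

#' @export
print.bayes_fit <- function(x, ...) {
  cat(sprintf("<bayes_fit:%s> p = %d markers, %d kept draws, residual var %.4g\n",
              x$prior$family, length(x$beta_hat), x$chain_meta$n_kept,
              x$residual_var_hat))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy marker-effect estimates
#'
#' @param x a `bayes_fit` object.
#' @param ... unused.
#' @return A tibble with one row per marker: posterior mean, posterior SD
#'   and (for spike-slab families) inclusion probability.
#' @export
tidy.bayes_fit <- function(x, ...) {
  tibble::tibble(marker = names(x$beta_hat) %||% paste0("M", seq_along(x$beta_hat)),
                 estimate = unname(x$beta_hat),
                 posterior_sd = x$beta_sd,
                 inclusion_prob = x$inclusion_prob)
}

#' @export
glance.bayes_fit <- function(x, ...) {
  tibble::tibble(family = x$prior$family, p = length(x$beta_hat),
                 mu_hat = x$mu_hat, residual_var_hat = x$residual_var_hat,
                 iters = x$chain_meta$iters, burnin = x$chain_meta$burnin,
                 thin = x$chain_meta$thin, n_kept = x$chain_meta$n_kept)
}
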