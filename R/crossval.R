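#' Create a replicated k-fold partition plan
#'
#' Partitions `n` cases into `k` folds of near-equal size (sizes differ by at
#' most one), independently for each of `r` replicates. The plan is the
#' pairing device of the whole package: every model evaluated against the
#' same plan sees identical train/test splits, so per-fold accuracy
#' differences cancel the variability shared between models.
#'
#' @param n number of cases.
#' @param k folds per replicate, `2 <= k <= n`.
#' @param r replicates, `>= 1`.
#' @param seed integer seed; the same seed reproduces the assignment.
#'
#' @return An object of class `fold_plan`: an `n x r` integer matrix of fold
#'   labels with attributes `n`, `k`, `r`, `seed`.
#' @export
#' @examples
#' plan <- make_fold_plan(10, k = 5, r = 2, seed = 1)
#' table(plan[, 1])
make_fold_plan <- function(n, k, r = 1L, seed = 1L) {
  stopifnot(r >= 1)
  if (!(k >= 2 && k <= n)) {
    stop("k must satisfy 2 <= k <= n", call. = FALSE)
  }
  assignment <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(r), function(.) sample(rep_len(seq_len(k), n)), integer(n))
  })
  structure(assignment, n = as.integer(n), k = as.integer(k), r = as.integer(r),
            seed = as.integer(seed), class = c("fold_plan", "matrix", "array"))
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> n = %d, k = %d folds, r = %d replicate(s), seed = %d\n",
              attr(x, "n"), attr(x, "k"), attr(x, "r"), attr(x, "seed")))
  invisible(x)
}

#' Fold-level predictive accuracy
#'
#' The Pearson correlation between predictions and observations — the
#' standard accuracy measure in genomic prediction. It is invariant to
#' affine transformation of the predictions, unlike the mean squared error
#' (which penalises every departure and is reported alongside it in CV
#' results).
#'
#' @param pred,obs numeric vectors of equal length (at least 3).
#' @return Pearson correlation in `[-1, 1]`.
#' @export
fold_accuracy <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  if (length(pred) < 3) stop("a fold needs at least 3 cases for a correlation", call. = FALSE)
  if (anyNA(pred) || anyNA(obs)) stop("accuracy inputs must be NA-free", call. = FALSE)
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    stop("undefined accuracy: zero variance in predictions or observations",
         call. = FALSE)
  }
  stats::cor(pred, obs)
}

#' Model specifications for paired cross validation
#'
#' `spec_kernel_model()` declares a (multi-)kernel mixed model: the full
#' `n x n` kernels are sliced per fold (never rebuilt on subsets, which
#' would change the centering), fitted by REML on the training block and
#' used to predict the test block. `spec_bayes_model()` declares a
#' Bayesian-alphabet marker regression refitted by Gibbs sampling in each
#' fold. `spec_oracle_model()` declares a fixed prediction vector (e.g. the
#' true genetic values of a simulated trait) — no fitting, used for
#' calibration checks.
#'
#' @param name model label used in results and reports.
#' @param kernels a [gp_kernel()] or list of them (full data).
#' @param geno a [geno_matrix()] (full data) for marker regressions.
#' @param family,R2geno,nu,pi prior settings, see [elicit_prior()].
#' @param iters,burnin,thin,seed chain controls, see [fit_bayes()].
#' @param values fixed prediction vector over all cases (oracle).
#' @return A model spec object consumed by [run_paired_cv()].
#' @export
spec_kernel_model <- function(name, kernels) {
  if (inherits(kernels, "gp_kernel")) kernels <- list(kernels)
  stopifnot(all(vapply(kernels, inherits, TRUE, "gp_kernel")))
  structure(list(name = name, engine = "kernel", kernels = kernels),
            class = "gp_model_spec")
}

#' @rdname spec_kernel_model
#' @export
spec_bayes_model <- function(name, geno, family = "BRR", R2geno = 0.5, nu = 5,
                             pi = 0.5, iters = 12000L, burnin = 2000L,
                             thin = 5L, seed = 1L) {
  structure(list(name = name, engine = "bayes", geno = as_geno(geno),
                 family = family, R2geno = R2geno, nu = nu, pi = pi,
                 iters = iters, burnin = burnin, thin = thin, seed = seed),
            class = "gp_model_spec")
}

#' @rdname spec_kernel_model
#' @export
spec_oracle_model <- function(name, values) {
  structure(list(name = name, engine = "oracle", values = values),
            class = "gp_model_spec")
}

#' Run a paired cross validation over several models
#'
#' For every replicate and fold of the plan, trains each model on the k-1
#' training folds and predicts the held-out fold, recording the fold
#' accuracy and MSE. All models use the identical test fold — the pairing
#' invariant that the comparison machinery relies on. If any model fails on
#' a fold, that fold is dropped for all models (keeping the pairing
#' balanced) and counted in the `excluded` attribute.
#'
#' @param y phenotype vector over all cases.
#' @param models list of model specs (see [spec_kernel_model()]).
#' @param plan a [make_fold_plan()] over `length(y)` cases.
#' @return A tibble of class `cv_result` with columns `replicate`, `fold`,
#'   `model`, `accuracy`, `mse`, `n_test`; attributes carry the plan and any
#'   excluded folds.
#' @export
#' @examples
#' g <- sim_genotypes(60, 40, seed = 1)
#' tr <- sim_phenotypes(g, trait_sim_spec(h2_additive = 0.5, seed = 2))
#' plan <- make_fold_plan(60, k = 3, seed = 3)
#' cv <- run_paired_cv(tr$y, list(
#'   spec_kernel_model("GBLUP", vanraden_grm(g)),
#'   spec_oracle_model("oracle", tr$g)), plan)
#' dplyr::group_by(cv, model) |> dplyr::summarise(acc = mean(accuracy))
run_paired_cv <- function(y, models, plan) {
  stopifnot(inherits(plan, "fold_plan"), length(y) == attr(plan, "n"))
  if (inherits(models, "gp_model_spec")) models <- list(models)
  stopifnot(all(vapply(models, inherits, TRUE, "gp_model_spec")))
  nms <- vapply(models, function(m) m$name, "")
  if (anyDuplicated(nms)) stop("model names must be unique", call. = FALSE)

  rows <- list()
  excluded <- list()
  for (rep_i in seq_len(attr(plan, "r"))) {
    fold_of <- plan[, rep_i]
    for (fold_i in seq_len(attr(plan, "k"))) {
      test <- which(fold_of == fold_i)
      train <- which(fold_of != fold_i)
      fold_rows <- vector("list", length(models))
      failed <- NULL
      for (mi in seq_along(models)) {
        pred <- tryCatch(fit_predict_fold(models[[mi]], y, train, test),
                         error = function(e) e)
        if (inherits(pred, "error")) { failed <- conditionMessage(pred); break }
        acc <- tryCatch(fold_accuracy(pred, y[test]), error = function(e) e)
        if (inherits(acc, "error")) { failed <- conditionMessage(acc); break }
        fold_rows[[mi]] <- tibble::tibble(
          replicate = rep_i, fold = fold_i, model = models[[mi]]$name,
          accuracy = acc, mse = mean((pred - y[test])^2),
          n_test = length(test))
      }
      if (is.null(failed)) {
        rows <- c(rows, fold_rows)
      } else {
        excluded <- c(excluded, list(tibble::tibble(
          replicate = rep_i, fold = fold_i, reason = failed)))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "plan") <- plan
  attr(out, "models") <- nms
  attr(out, "excluded") <- if (length(excluded)) dplyr::bind_rows(excluded) else NULL
  class(out) <- c("cv_result", class(out))
  out
}

fit_predict_fold <- function(spec, y, train, test) {
  switch(spec$engine,
    oracle = spec$values[test],
    bayes = {
      M <- unclass(spec$geno)
      fit <- fit_bayes(y[train], M[train, , drop = FALSE],
                       family = spec$family, iters = spec$iters,
                       burnin = spec$burnin, thin = spec$thin,
                       seed = spec$seed)
      predict(fit, M[test, , drop = FALSE])
    },
    kernel = {
      fit <- fit_kernel_reml(y[train],
                             lapply(spec$kernels, kernel_slice, i = train))
      cross <- lapply(spec$kernels, function(k) k$matrix[test, train, drop = FALSE])
      predict_kernel(fit, cross)
    },
    stop("unknown model engine: ", spec$engine, call. = FALSE))
}

#' Rescale phenotype-scale accuracy to genetic-value accuracy
#'
#' Cross-validation accuracy is measured against phenotypes, but the
#' breeder's target is the (unobserved) genetic value; dividing by the
#' square root of the trait heritability converts between the two scales.
#' The same heritability estimate must be used for every accuracy being
#' compared, otherwise the rescaling changes model rankings.
#'
#' @param accuracy phenotype-scale accuracy (scalar or vector).
#' @param h2_hat heritability estimate in (0, 1], common to all accuracies
#'   compared.
#' @return `accuracy / sqrt(h2_hat)`.
#' @export
rescale_by_heritability <- function(accuracy, h2_hat) {
  if (!(h2_hat > 0 && h2_hat <= 1)) {
    stop("h2_hat must lie in (0, 1]", call. = FALSE)
  }
  accuracy / sqrt(h2_hat)
}

#' Selection intensity under truncation selection
#'
#' The mean of a standard normal distribution truncated to its upper `q`
#' quantile: `i_q = dnorm(qnorm(1 - q)) / q`. Strictly decreasing in the
#' selected proportion `q`.
#'
#' @param q selected proportion, in (0, 1).
#' @return Selection intensity `i_q > 0`.
#' @export
#' @examples
#' selection_intensity(0.1) # 1.7550
selection_intensity <- function(q) {
  if (any(q <= 0 | q >= 1)) stop("q must lie strictly in (0, 1)", call. = FALSE)
  stats::dnorm(stats::qnorm(1 - q)) / q
}

#' Convert accuracy to expected genetic gain per phenotypic SD
#'
#' Under truncation selection of the top fraction `q`, the expected genetic
#' gain in phenotypic standard deviations is the selection intensity times
#' the phenotype-scale accuracy: `i_q * r_ph`. The map is linear, so paired
#' accuracy differences transform to gain differences by the same factor —
#' a practically interpretable scale on which to set equivalence margins.
#'
#' @param accuracy phenotype-scale accuracy (scalar or vector).
#' @param q selected proportion, in (0, 1).
#' @return Expected gain `i_q * accuracy` in phenotypic SD units.
#' @export
#' @examples
#' to_genetic_gain(0.5, q = 0.1) # 0.8775
to_genetic_gain <- function(accuracy, q) {
  selection_intensity(q) * accuracy
}
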