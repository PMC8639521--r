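#' Fit a (multi-)kernel mixed model by REML
#'
#' Fits `y = X beta + sum_i u_i + e` with `u_i ~ N(0, K_i sigma_ui^2)` and
#' `e ~ N(0, I sigma_e^2)`. With a single kernel the restricted likelihood is
#' profiled on the kernel's spectral decomposition and maximised by a 1-D
#' search over the log variance ratio; with several kernels it is maximised
#' numerically over the log variance components (which enforces
#' nonnegativity). REML estimates are invariant to rescaling any kernel by a
#' positive constant: the component absorbs the constant and the heritability
#' estimate is unchanged.
#'
#' @param y training phenotypes; missing values are excluded (with their
#'   kernel rows/columns) rather than imputed.
#' @param kernels a [gp_kernel()] or list of them, all `n x n` over the
#'   training lines. A cached eigendecomposition ([cache_eigen()]) is reused
#'   in the single-kernel intercept-only case.
#' @param X fixed-effect design matrix; default intercept only.
#' @param varcomp optional fixed variance components
#'   `c(sigma_u1^2, ..., sigma_e^2)`; when given, no REML search is done
#'   (useful for closed-form comparisons).
#' @param compute_blups compute BLUPs and the prediction coefficients
#'   (requires one `n x n` solve); set `FALSE` when only variance components
#'   are needed.
#'
#' @return An object of class `kernel_fit` with `var_components` (one per
#'   kernel plus `sigma_e2`), `h2_hat` (the genetic share of variance, each
#'   component weighted by its kernel's mean diagonal so the estimate is
#'   invariant to kernel rescaling), fixed-effect estimates, per-kernel
#'   BLUPs, and the coefficients needed by [predict_kernel()].
#' @export
#' @examples
#' g <- sim_genotypes(150, 100, seed = 1)
#' tr <- sim_phenotypes(g, trait_sim_spec(h2_additive = 0.5, seed = 2))
#' fit <- fit_kernel_reml(tr$y, vanraden_grm(g))
#' fit$h2_hat
fit_kernel_reml <- function(y, kernels, X = NULL, varcomp = NULL,
                            compute_blups = TRUE) {
  if (inherits(kernels, "gp_kernel")) kernels <- list(kernels)
  stopifnot(length(kernels) >= 1, all(vapply(kernels, inherits, TRUE, "gp_kernel")))
  keep <- !is.na(y)
  if (!all(keep)) {
    y <- y[keep]
    kernels <- lapply(kernels, function(k) kernel_slice(k, which(keep)))
    if (!is.null(X)) X <- X[keep, , drop = FALSE]
  }
  n <- length(y)
  if (any(vapply(kernels, function(k) nrow(k$matrix), 1L) != n)) {
    stop("kernel dimensions do not match the training phenotypes", call. = FALSE)
  }
  intercept_only <- is.null(X)
  if (intercept_only) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (qr(X)$rank < ncol(X)) stop("fixed design is rank deficient", call. = FALSE)

  m <- length(kernels)
  if (!is.null(varcomp)) {
    stopifnot(length(varcomp) == m + 1, all(varcomp >= 0))
    comps <- varcomp
  } else if (m == 1L) {
    comps <- reml_single_spectral(y, kernels[[1]], X, intercept_only)
  } else {
    comps <- reml_multi_numeric(y, kernels, X)
  }
  sigma_u2 <- comps[seq_len(m)]
  sigma_e2 <- comps[m + 1]
  names(sigma_u2) <- vapply(seq_len(m), function(i) {
    nm <- kernels[[i]]$name
    if (sum(vapply(kernels, function(k) k$name, "") == nm) > 1) paste0(nm, "_", i) else nm
  }, "")

  # genetic variance on the observation scale: sigma_ui^2 * mean(diag Ki),
  # so the heritability estimate is invariant to kernel rescaling
  gvar <- sum(sigma_u2 * vapply(kernels, function(k) mean(diag(k$matrix)), 0))
  fit <- list(var_components = c(sigma_u2, sigma_e2 = sigma_e2),
              sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
              h2_hat = gvar / (gvar + sigma_e2),
              kernel_names = vapply(kernels, function(k) k$name, ""),
              training_ids = rownames(kernels[[1]]$matrix),
              n = n)
  if (compute_blups) {
    V <- Reduce(`+`, Map(function(k, s2) s2 * k$matrix, kernels, sigma_u2))
    V <- V + diag(sigma_e2, n)
    Vi <- tryCatch(chol2inv(chol(V)), error = function(e) {
      chol2inv(chol(V + diag(1e-8 * mean(diag(V)), n)))
    })
    XtVi <- crossprod(X, Vi)
    beta_hat <- drop(solve(XtVi %*% X, XtVi %*% y))
    names(beta_hat) <- colnames(X)
    alpha <- drop(Vi %*% (y - X %*% beta_hat))
    fit$fixed_hat <- beta_hat
    fit$alpha <- alpha
    fit$blups <- lapply(seq_len(m), function(i) {
      drop(sigma_u2[i] * kernels[[i]]$matrix %*% alpha)
    })
    names(fit$blups) <- names(sigma_u2)
  }
  structure(fit, class = "kernel_fit")
}

# profiled REML on the spectrum of the kernel restricted to the orthogonal
# complement of the fixed-effect design (error contrasts). Working in an
# explicit orthonormal complement keeps the decomposition exact even for
# rank-deficient kernels, whose null space would otherwise mix with the
# intercept direction.
reml_single_spectral <- function(y, kernel, X, intercept_only) {
  n <- length(y)
  q <- ncol(X)
  dec <- if (intercept_only && !is.null(kernel$eigen_c)) {
    kernel$eigen_c
  } else {
    contrast_eigen(kernel$matrix, X)
  }
  mq <- n - q
  xi <- pmax(dec$values, 0)
  eta2 <- drop(crossprod(dec$U, y))^2
  # restricted log-likelihood profiled in sigma_e^2, as a function of
  # lambda = sigma_u^2 / sigma_e^2
  rll <- function(loglam) {
    lam <- exp(loglam)
    w <- lam * xi + 1
    -mq * log(sum(eta2 / w)) - sum(log(w))
  }
  opt <- stats::optimize(rll, interval = c(-25, 25), maximum = TRUE, tol = 1e-10)
  # guard the boundaries: compare with (numerically) zero and huge ratios
  cand <- c(opt$maximum, -25, 25)
  vals <- vapply(cand, rll, 0)
  loglam <- cand[which.max(vals)]
  lam <- exp(loglam)
  w <- lam * xi + 1
  sigma_e2 <- sum(eta2 / w) / mq
  c(lam * sigma_e2, sigma_e2)
}

# eigendecomposition of Q' K Q for an orthonormal basis Q of the orthogonal
# complement of col(X); returns U = Q V (n x (n - q)) and the eigenvalues
contrast_eigen <- function(K, X) {
  n <- nrow(K)
  q <- ncol(X)
  Q <- qr.Q(qr(X), complete = TRUE)[, (q + 1):n, drop = FALSE]
  B <- crossprod(Q, K %*% Q)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(values = eig$values, U = Q %*% eig$vectors)
}

# numerical REML over log variance components for several kernels
reml_multi_numeric <- function(y, kernels, X) {
  n <- length(y)
  m <- length(kernels)
  Ks <- lapply(kernels, function(k) k$matrix)
  neg_rll <- function(theta) {
    s2 <- exp(theta)
    V <- diag(s2[m + 1], n)
    for (i in seq_len(m)) V <- V + s2[i] * Ks[[i]]
    L <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    logdetV <- 2 * sum(log(diag(L)))
    Vi_y <- backsolve(L, forwardsolve(t(L), y))
    Vi_X <- backsolve(L, forwardsolve(t(L), X))
    XtViX <- crossprod(X, Vi_X)
    XtViy <- crossprod(X, Vi_y)
    beta <- solve(XtViX, XtViy)
    quad <- sum(y * Vi_y) - sum(XtViy * beta)
    0.5 * (logdetV + determinant(XtViX, logarithm = TRUE)$modulus + quad)
  }
  vy <- stats::var(y)
  start <- log(c(rep(vy / (2 * m), m), vy / 2))
  opt <- stats::optim(start, neg_rll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  if (opt$convergence != 0) {
    opt2 <- stats::optim(opt$par, neg_rll, method = "Nelder-Mead",
                         control = list(maxit = 5000, reltol = 1e-12))
    if (opt2$value <= opt$value) opt <- opt2
  }
  exp(opt$par)
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat(sprintf("<kernel_fit> kernels: %s | h2_hat = %.3f\n",
              paste(x$kernel_names, collapse = ", "), x$h2_hat))
  print(round(x$var_components, 5))
  invisible(x)
}

#' Predict genetic values for new lines from a kernel mixed model
#'
#' Computes `u_test = sum_i sigma_ui^2 K_cross_i %*% alpha` with
#' `alpha = V^{-1}(y - X beta_hat)` cached in the fit, and adds the fixed
#' part. The cross kernels must be built with the same kernels and scaling
#' used in the fit (slices of one full-data kernel, never rebuilt on a
#' subset).
#'
#' @param fit a [fit_kernel_reml()] object fitted with
#'   `compute_blups = TRUE`.
#' @param cross_kernels list (or single matrix) of `n_test x n_train` kernel
#'   blocks, in the same order as the kernels used in the fit.
#' @param X_new optional fixed-effect design for the test lines (defaults to
#'   intercept only).
#' @return Numeric vector of predicted phenotypes for the test lines.
#' @export
predict_kernel <- function(fit, cross_kernels, X_new = NULL) {
  stopifnot(inherits(fit, "kernel_fit"))
  if (is.null(fit$alpha)) {
    stop("fit was computed with compute_blups = FALSE; refit to predict",
         call. = FALSE)
  }
  if (!is.list(cross_kernels)) cross_kernels <- list(cross_kernels)
  cross_kernels <- lapply(cross_kernels, function(k) {
    if (inherits(k, "gp_kernel")) k$matrix else as.matrix(k)
  })
  if (length(cross_kernels) != length(fit$sigma_u2)) {
    stop("number of cross kernels does not match the fit", call. = FALSE)
  }
  if (any(vapply(cross_kernels, ncol, 1L) != fit$n)) {
    stop("cross kernel blocks must have one column per training line", call. = FALSE)
  }
  nt <- nrow(cross_kernels[[1]])
  u <- rep(0, nt)
  for (i in seq_along(cross_kernels)) {
    u <- u + fit$sigma_u2[i] * drop(cross_kernels[[i]] %*% fit$alpha)
  }
  if (is.null(X_new)) X_new <- matrix(1, nt, 1)
  drop(X_new %*% fit$fixed_hat) + u
}

#' @export
tidy.kernel_fit <- function(x, ...) {
  tibble::tibble(term = names(x$var_components),
                 estimate = unname(x$var_components))
}

#' @export
glance.kernel_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_kernels = length(x$sigma_u2),
                 h2_hat = x$h2_hat, sigma_e2 = unname(x$sigma_e2))
}
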