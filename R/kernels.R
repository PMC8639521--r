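#' Kernel (genomic relationship) objects
#'
#' A kernel is a named symmetric positive-semidefinite `n x n` matrix over a
#' set of lines, used as the covariance structure of genetic values in the
#' kernel mixed models. All kernels here are defined up to a multiplicative
#' constant, which the corresponding variance component absorbs; the
#' `scaling_note` records the constant actually applied.
#'
#' @param matrix symmetric numeric matrix with line ids as dimnames.
#' @param name kernel name, e.g. `"G"`, `"EGBLUP_H"`, `"Cm"`, `"Ce"`,
#'   `"GaussianK"` or `"custom"`.
#' @param bandwidth bandwidth `h` for Gaussian kernels, `NULL` otherwise.
#' @param scaling_note free-text description of the scaling convention.
#'
#' @return An object of class `gp_kernel`.
#' @export
gp_kernel <- function(matrix, name = "custom", bandwidth = NULL,
                      scaling_note = "") {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stop("kernel matrix must be square", call. = FALSE)
  if (max(abs(matrix - t(matrix))) > 1e-8 * max(1, max(abs(matrix)))) {
    stop("kernel matrix is not symmetric", call. = FALSE)
  }
  matrix <- (matrix + t(matrix)) / 2
  if (is.null(rownames(matrix))) {
    ids <- paste0("L", seq_len(nrow(matrix)))
    dimnames(matrix) <- list(ids, ids)
  }
  structure(list(name = name, matrix = matrix, bandwidth = bandwidth,
                 scaling_note = scaling_note),
            class = "gp_kernel")
}

#' @export
print.gp_kernel <- function(x, ...) {
  cat(sprintf("<gp_kernel:%s> %d x %d%s\n", x$name, nrow(x$matrix), ncol(x$matrix),
              if (!is.null(x$bandwidth)) sprintf(", bandwidth = %.4g", x$bandwidth) else ""))
  if (nzchar(x$scaling_note)) cat("  scaling:", x$scaling_note, "\n")
  invisible(x)
}

#' @export
as.matrix.gp_kernel <- function(x, ...) x$matrix

#' @export
dim.gp_kernel <- function(x) dim(x$matrix)

#' Check positive semidefiniteness of a kernel
#'
#' A kernel passes if its smallest eigenvalue is at least
#' `-tol * largest eigenvalue` (small negative eigenvalues from floating
#' arithmetic are tolerated).
#'
#' @param kernel a [gp_kernel()] or symmetric matrix.
#' @param tol relative eigenvalue tolerance.
#' @return `TRUE`/`FALSE`.
#' @export
is_psd <- function(kernel, tol = 1e-8) {
  K <- if (inherits(kernel, "gp_kernel")) kernel$matrix else as.matrix(kernel)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol * max(abs(ev))
}

#' Slice a kernel to a subset of lines
#'
#' Extracts the `i x j` block of a kernel, keeping name, bandwidth and
#' scaling metadata. Cross-validation always slices a full-data kernel this
#' way rather than rebuilding it on a subset, which would change the
#' centering.
#'
#' @param kernel a [gp_kernel()].
#' @param i,j row/column index vectors (defaults: `j = i`).
#' @return The sliced [gp_kernel()].
#' @export
kernel_slice <- function(kernel, i, j = i) {
  gp_kernel(kernel$matrix[i, j, drop = FALSE], name = kernel$name,
            bandwidth = kernel$bandwidth, scaling_note = kernel$scaling_note)
}

#' Precompute and cache a kernel eigendecomposition
#'
#' Caches the spectral decomposition of the kernel restricted to the
#' orthogonal complement of the intercept (the error-contrast space), which
#' is what the intercept-only REML fitter profiles on. Useful when many
#' traits are fitted against the same kernel: every fit then reuses one
#' decomposition.
#'
#' @param kernel a [gp_kernel()].
#' @return The kernel with an `eigen_c` element attached.
#' @export
cache_eigen <- function(kernel) {
  if (!is.null(kernel$eigen_c)) return(kernel)
  n <- nrow(kernel$matrix)
  kernel$eigen_c <- contrast_eigen(kernel$matrix, matrix(1, n, 1))
  kernel
}

#' VanRaden additive genomic relationship matrix
#'
#' Centers the dosage matrix by twice the allele frequencies,
#' `W = M - 2 * 1 P`, and returns `G = W W' / (2 * sum(p_j (1 - p_j)))` —
#' the standard additive GRM whose diagonal averages about 1 in a panel at
#' Hardy-Weinberg proportions.
#'
#' @param geno a [geno_matrix()].
#' @return A [gp_kernel()] named `"G"`.
#' @export
#' @examples
#' g <- geno_matrix(matrix(c(0, 2), nrow = 2))
#' vanraden_grm(g)$matrix # 2x2, entries +/- 2
vanraden_grm <- function(geno) {
  geno <- as_geno(geno)
  freq <- allele_frequencies(geno)
  denom <- 2 * sum(freq * (1 - freq))
  if (denom <= 0) {
    stop("all markers are monomorphic: the additive GRM is degenerate", call. = FALSE)
  }
  W <- sweep(unclass(geno), 2, 2 * freq)
  G <- tcrossprod(W) / denom
  gp_kernel(G, name = "G",
            scaling_note = "W W' / (2 * sum p(1-p)), W = M - 2*1P")
}

#' Hadamard-square epistatic relationship matrix
#'
#' The elementwise square `H = G (*) G` of an additive GRM models pairwise
#' marker-interaction (epistatic) effects; by the Schur product theorem `H`
#' is PSD whenever `G` is.
#'
#' @param G a [gp_kernel()] (typically from [vanraden_grm()]) or symmetric
#'   matrix.
#' @return A [gp_kernel()] named `"EGBLUP_H"`.
#' @export
egblup_grm <- function(G) {
  M <- if (inherits(G, "gp_kernel")) G$matrix else as.matrix(G)
  if (nrow(M) != ncol(M)) stop("input kernel must be square", call. = FALSE)
  H <- M * M
  dimnames(H) <- dimnames(M)
  gp_kernel(H, name = "EGBLUP_H", scaling_note = "G (*) G, Hadamard square")
}

#' Categorical marker-match kernels
#'
#' Treats genotypes as categories: `Cm[i, j]` is the proportion of markers at
#' which lines i and j carry exactly the same dosage, and
#' `Ce = (Cm (*) Cm + Cm) / 2` extends the matching to marker pairs
#' (categorical epistasis). Both have unit diagonal and entries in `[0, 1]`.
#'
#' @param geno a [geno_matrix()].
#' @return A list with elements `Cm` and `Ce`, both [gp_kernel()] objects.
#' @export
categorical_kernels <- function(geno) {
  geno <- as_geno(geno)
  M <- unclass(geno)
  p <- ncol(M)
  # proportion of exactly matching dosages via indicators of the 3 categories
  Cm <- matrix(0, nrow(M), nrow(M))
  for (d in c(0, 1, 2)) {
    Ind <- (M == d) * 1
    Cm <- Cm + tcrossprod(Ind)
  }
  Cm <- Cm / p
  dimnames(Cm) <- list(rownames(M), rownames(M))
  Ce <- (Cm * Cm + Cm) / 2
  list(Cm = gp_kernel(Cm, name = "Cm", scaling_note = "match proportion over p markers"),
       Ce = gp_kernel(Ce, name = "Ce", scaling_note = "(Cm (*) Cm + Cm) / 2"))
}

#' Mean squared dosage distance between lines
#'
#' `D[i, j] = (1/p) * sum_k (M[i,k] - M[j,k])^2`, the per-marker average
#' squared dosage difference. Satisfies the identity
#' `D[i,j] = G0[i,i] + G0[j,j] - 2 G0[i,j]` with `G0 = M M' / p` (or any
#' common centering at the same scale).
#'
#' @param geno a [geno_matrix()].
#' @return A symmetric matrix of class `gp_dist` with zero diagonal.
#' @export
squared_distance <- function(geno) {
  geno <- as_geno(geno)
  M <- unclass(geno)
  p <- ncol(M)
  sq <- rowSums(M^2)
  D <- (outer(sq, rep(1, length(sq))) + outer(rep(1, length(sq)), sq) -
          2 * tcrossprod(M)) / p
  D[D < 0] <- 0 # floating underflow on the diagonal
  diag(D) <- 0
  dimnames(D) <- list(rownames(M), rownames(M))
  structure(D, class = c("gp_dist", "matrix", "array"))
}

#' Gaussian (RKHS) kernel from a distance matrix
#'
#' `K[i, j] = exp(-D[i, j] / h)` for bandwidth `h > 0`. The diagonal is 1 and
#' entries lie in `(0, 1]`; as `h` grows the kernel tends to the all-ones
#' matrix. Note the negative exponent: similarity must decay with distance
#' for the kernel to be a valid (PSD) covariance.
#'
#' @param D a [squared_distance()] matrix (or any symmetric nonnegative
#'   matrix with zero diagonal).
#' @param h bandwidth, > 0.
#' @return A [gp_kernel()] named `"GaussianK"` carrying `bandwidth = h`.
#' @export
#' @examples
#' D <- squared_distance(sim_genotypes(10, 30, seed = 1))
#' K <- gaussian_kernel(D, h = median(D[upper.tri(D)]))
gaussian_kernel <- function(D, h) {
  if (!is.numeric(h) || length(h) != 1L || h <= 0) {
    stop("bandwidth h must be a positive scalar", call. = FALSE)
  }
  D <- unclass(D)
  K <- exp(-D / h)
  gp_kernel(K, name = "GaussianK", bandwidth = h,
            scaling_note = "exp(-D/h), unit diagonal")
}

#' Default bandwidth grid for multi-kernel Gaussian models
#'
#' Rather than fixing one arbitrary bandwidth, a multi-kernel model passes
#' several Gaussian kernels at different bandwidths to the REML fitter and
#' lets the variance components weight them. The default grid is the 0.2,
#' 0.5 and 0.8 quantiles of the off-diagonal distances.
#'
#' @param D a [squared_distance()] matrix.
#' @param probs quantile levels of the off-diagonal distances.
#' @return A list of [gp_kernel()] objects, one per bandwidth.
#' @export
gaussian_kernel_list <- function(D, probs = c(0.2, 0.5, 0.8)) {
  d <- unclass(D)[upper.tri(D)]
  hs <- unique(stats::quantile(d[d > 0], probs, names = FALSE))
  lapply(hs, function(h) gaussian_kernel(D, h))
}
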