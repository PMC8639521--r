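#' Simulate a biallelic marker panel
#'
#' Draws, for each marker, an alternate-allele frequency uniformly in
#' `[maf_low, maf_high]` and then samples dosages as two independent allele
#' draws (binomial with two trials) at Hardy-Weinberg proportions. Markers are
#' independent: no linkage disequilibrium and no population structure are
#' simulated, which keeps every downstream sampling distribution analytic.
#'
#' @param n number of lines (>= 2).
#' @param p number of markers (>= 1).
#' @param maf_low,maf_high bounds of the per-marker allele frequency,
#'   `0 < maf_low <= maf_high <= 0.5`.
#' @param seed integer seed; the same seed reproduces the panel exactly.
#'
#' @return A [geno_matrix()] with `n` lines and `p` markers.
#' @export
#' @examples
#' g <- sim_genotypes(50, 20, seed = 1)
#' range(allele_frequencies(g))
sim_genotypes <- function(n, p, maf_low = 0.05, maf_high = 0.5, seed = 1L) {
  stopifnot(n >= 2, p >= 1)
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5)) {
    stop("allele frequency bounds must satisfy 0 < maf_low <= maf_high <= 0.5",
         call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    freq <- stats::runif(p, maf_low, maf_high)
    M <- matrix(stats::rbinom(n * p, size = 2L, prob = rep(freq, each = n)),
                nrow = n, ncol = p)
    geno_matrix(M)
  })
}

#' Trait architecture specification for simulation
#'
#' Describes an additive plus pairwise-epistatic genetic architecture: how
#' many markers carry additive effects, how many marker pairs carry
#' product-interaction effects, and what share of the phenotypic variance
#' each component explains.
#'
#' @param n_qtl_additive number of additive QTL (markers with nonzero
#'   effects), `<= p`.
#' @param n_pairs_epistatic number of interacting marker pairs,
#'   `<= p(p-1)/2`.
#' @param h2_additive,h2_epistatic target proportions of phenotypic variance;
#'   their sum must not exceed 1, the remainder is environmental noise.
#' @param seed integer seed for QTL placement, effect sizes and noise.
#'
#' @return A list of class `trait_sim_spec`.
#' @export
trait_sim_spec <- function(n_qtl_additive = 50L, n_pairs_epistatic = 0L,
                           h2_additive = 0.5, h2_epistatic = 0,
                           seed = 1L) {
  stopifnot(n_qtl_additive >= 0, n_pairs_epistatic >= 0,
            h2_additive >= 0, h2_epistatic >= 0)
  if (h2_additive + h2_epistatic > 1 + 1e-12) {
    stop("h2_additive + h2_epistatic must not exceed 1", call. = FALSE)
  }
  structure(list(n_qtl_additive = as.integer(n_qtl_additive),
                 n_pairs_epistatic = as.integer(n_pairs_epistatic),
                 h2_additive = h2_additive, h2_epistatic = h2_epistatic,
                 seed = as.integer(seed)),
            class = "trait_sim_spec")
}

#' Simulate phenotypes with known genetic architecture
#'
#' Builds the true genetic value as the sum of a centered additive part
#' (random standard-normal effects on frequency-centered dosages at randomly
#' placed QTL) and a centered pairwise-epistatic part (effects on products of
#' centered dosages), each rescaled so its sample variance matches its target
#' heritability share; independent normal noise is then added to bring the
#' total phenotypic variance to 1. Returning the true genetic values makes
#' parameter-recovery and oracle-accuracy tests possible downstream.
#'
#' @param geno a [geno_matrix()].
#' @param spec a [trait_sim_spec()].
#'
#' @return A list of class `sim_trait` with elements `y` (phenotypes), `g`
#'   (true genetic values), `sigma_P`, `sigma_G` (phenotypic and genetic SD),
#'   `realized_h2` (`var(g)/var(y)`), and the line identifiers.
#' @export
#' @examples
#' g <- sim_genotypes(200, 100, seed = 2)
#' tr <- sim_phenotypes(g, trait_sim_spec(h2_additive = 0.5, seed = 3))
#' tr$realized_h2
sim_phenotypes <- function(geno, spec) {
  geno <- as_geno(geno)
  stopifnot(inherits(spec, "trait_sim_spec"))
  n <- nrow(geno); p <- ncol(geno)
  if (spec$n_qtl_additive > p) stop("more additive QTL than markers", call. = FALSE)
  if (spec$n_pairs_epistatic > p * (p - 1) / 2) {
    stop("more epistatic pairs than available marker pairs", call. = FALSE)
  }
  W <- sweep(unclass(geno), 2, 2 * allele_frequencies(geno))
  withr::with_seed(spec$seed, {
    g_add <- rep(0, n)
    if (spec$h2_additive > 0 && spec$n_qtl_additive > 0) {
      qtl <- sample.int(p, spec$n_qtl_additive)
      raw <- drop(W[, qtl, drop = FALSE] %*% stats::rnorm(length(qtl)))
      g_add <- scale_to_var(raw, spec$h2_additive)
    }
    g_epi <- rep(0, n)
    if (spec$h2_epistatic > 0 && spec$n_pairs_epistatic > 0) {
      idx <- sample_marker_pairs(p, spec$n_pairs_epistatic)
      Z <- W[, idx[, 1], drop = FALSE] * W[, idx[, 2], drop = FALSE]
      raw <- drop(scale(Z, scale = FALSE) %*% stats::rnorm(nrow(idx)))
      g_epi <- scale_to_var(raw, spec$h2_epistatic)
    }
    g <- unname(g_add + g_epi)
    h2 <- spec$h2_additive + spec$h2_epistatic
    e <- if (h2 >= 1 - 1e-12) rep(0, n) else scale_to_var(stats::rnorm(n), 1 - h2)
    y <- g + e
    structure(list(y = y, g = g,
                   sigma_P = stats::sd(y), sigma_G = stats::sd(g),
                   realized_h2 = if (stats::var(y) > 0) stats::var(g) / stats::var(y) else NA_real_,
                   line_ids = rownames(geno), spec = spec),
              class = "sim_trait")
  })
}

# center and rescale a vector to an exact sample variance (0 stays 0)
scale_to_var <- function(x, v) {
  x <- x - mean(x)
  s2 <- stats::var(x)
  if (s2 <= 0) return(rep(0, length(x)))
  x * sqrt(v / s2)
}

# distinct unordered marker pairs, uniformly without replacement
sample_marker_pairs <- function(p, m) {
  total <- p * (p - 1) / 2
  sel <- if (total <= 1e6) {
    sample.int(total, m)
  } else {
    # rejection sampling for huge p: duplicates are vanishingly rare
    unique(ceiling(stats::runif(2 * m) * total))[seq_len(m)]
  }
  # map linear index to (i, j), i < j, column-major over the strict lower triangle
  j <- floor((3 + sqrt(8 * sel - 7)) / 2)
  i <- sel - (j - 1) * (j - 2) / 2
  cbind(i = as.integer(i), j = as.integer(j))
}

#' @export
print.sim_trait <- function(x, ...) {
  cat(sprintf("<sim_trait> n = %d, realized h2 = %.3f (target %.2f)\n",
              length(x$y), x$realized_h2,
              x$spec$h2_additive + x$spec$h2_epistatic))
  invisible(x)
}

#' Simulate correlated per-fold accuracy scores for two models
#'
#' Draws r-by-k bivariate-normal pairs of fold scores with the stated means,
#' a common per-fold standard deviation, and correlation `rho` between the
#' two models' scores on the same fold. This feeds the comparison machinery
#' directly (variance-reduction and power checks) without fitting any model:
#' the variance of the paired difference is `2 * sd_fold^2 * (1 - rho)`
#' against `2 * sd_fold^2` for independent scores.
#'
#' @param r replicates; @param k folds per replicate.
#' @param rho fold-score correlation between models, in `[-1, 1]`.
#' @param mean_a,mean_b mean fold score of each model.
#' @param sd_fold common per-fold score standard deviation (> 0).
#' @param seed integer seed.
#'
#' @return A tibble with columns `replicate`, `fold`, `score_a`, `score_b`.
#' @export
#' @examples
#' s <- sim_fold_scores(2, 5, rho = 0.8, seed = 1)
#' var(s$score_a - s$score_b)
sim_fold_scores <- function(r, k, rho, mean_a = 0.5, mean_b = 0.5,
                            sd_fold = 0.05, seed = 1L) {
  stopifnot(r >= 1, k >= 1)
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]", call. = FALSE)
  if (sd_fold <= 0) stop("sd_fold must be positive", call. = FALSE)
  m <- r * k
  withr::with_seed(as.integer(seed), {
    z1 <- stats::rnorm(m)
    z2 <- stats::rnorm(m)
    a <- mean_a + sd_fold * z1
    b <- mean_b + sd_fold * (rho * z1 + sqrt(1 - rho^2) * z2)
    tibble::tibble(replicate = rep(seq_len(r), each = k),
                   fold = rep(seq_len(k), times = r),
                   score_a = a, score_b = b)
  })
}
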