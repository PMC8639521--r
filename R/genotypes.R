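#' Construct a genotype dosage panel
#'
#' A genotype panel is an `n x p` integer matrix of alternate-allele dosages
#' (0, 1 or 2) with line identifiers on rows and marker identifiers on
#' columns. It is the common input of all kernel builders and of the
#' marker-regression models.
#'
#' @param M numeric matrix with entries in \{0, 1, 2\}; rows are lines,
#'   columns are markers.
#' @param line_ids character vector of unique line identifiers (defaults to
#'   existing rownames or `L1..Ln`).
#' @param marker_ids character vector of marker identifiers (defaults to
#'   existing colnames or `M1..Mp`).
#'
#' @return An object of class `geno_matrix`: the dosage matrix with
#'   `line_ids`/`marker_ids` as dimnames.
#' @export
#' @examples
#' g <- geno_matrix(matrix(c(0, 2, 1, 1), nrow = 2))
#' dim(g)
geno_matrix <- function(M, line_ids = NULL, marker_ids = NULL) {
  M <- as.matrix(M)
  if (nrow(M) < 2L) stop("a genotype panel needs at least 2 lines", call. = FALSE)
  if (ncol(M) < 1L) stop("a genotype panel needs at least 1 marker", call. = FALSE)
  if (anyNA(M) || !all(M %in% c(0, 1, 2))) {
    stop("dosages must all be 0, 1 or 2 with no missing values", call. = FALSE)
  }
  line_ids <- line_ids %||% rownames(M) %||% paste0("L", seq_len(nrow(M)))
  marker_ids <- marker_ids %||% colnames(M) %||% paste0("M", seq_len(ncol(M)))
  if (anyDuplicated(line_ids)) stop("duplicate line identifiers", call. = FALSE)
  if (length(line_ids) != nrow(M) || length(marker_ids) != ncol(M)) {
    stop("identifier lengths do not match the matrix dimensions", call. = FALSE)
  }
  storage.mode(M) <- "double"
  dimnames(M) <- list(line_ids, marker_ids)
  structure(M, class = c("geno_matrix", "matrix", "array"))
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d lines x %d markers\n", nrow(x), ncol(x)))
  af <- allele_frequencies(x)
  cat(sprintf("  allele frequency range: %.3f - %.3f\n", min(af), max(af)))
  invisible(x)
}

is_geno_matrix <- function(x) inherits(x, "geno_matrix")

as_geno <- function(x) {
  if (is_geno_matrix(x)) x else geno_matrix(x)
}

#' Alternate-allele frequencies of a panel
#'
#' The per-marker allele frequency is half the mean dosage: the proportion of
#' alternate alleles among the `2n` sampled alleles at that marker.
#' Monomorphic markers (frequency 0 or 1) are allowed here; builders that
#' cannot handle them flag them downstream.
#'
#' @param geno a [geno_matrix()] (or coercible dosage matrix).
#' @return Named numeric vector of frequencies in `[0, 1]`, one per marker.
#' @export
#' @examples
#' g <- geno_matrix(matrix(c(0, 1, 2, 1), nrow = 4))
#' allele_frequencies(g) # 0.5
allele_frequencies <- function(geno) {
  geno <- as_geno(geno)
  colMeans(unclass(geno)) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
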