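#' Read and write genotype panels
#'
#' Tabular genotypes are tab-separated text: a header row of marker ids, a
#' first column of line ids, and dosage entries in \{0, 1, 2\} ('.' for
#' missing). VCF genotypes are extracted from the GT field as
#' alternate-allele counts; multi-allelic sites are skipped (with a logged
#' count), and missing genotypes are imputed to twice the allele frequency.
#' Markers missing in more than half the lines are dropped with a warning.
#'
#' @param path file path.
#' @param format `"tabular"` (TSV) or `"vcf"`; guessed from the extension by
#'   default.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "tabular", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tabular"
  }
  if (!file.exists(path)) stop("genotype file not found: ", path, call. = FALSE)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, na.strings = ".",
                          colClasses = "character")
  M <- suppressWarnings(
    matrix(as.numeric(as.matrix(df)), nrow = nrow(df),
           dimnames = list(rownames(df), colnames(df))))
  bad <- which(!(is.na(M) | M %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("malformed dosage at data row %d (line '%s'): not in {0,1,2}",
                 bad[1, 1], rownames(M)[bad[1, 1]]), call. = FALSE)
  }
  impute_missing(M)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  biallelic <- !grepl(",", vcfR::getALT(v))
  n_skip <- sum(!biallelic)
  if (n_skip > 0) {
    message(n_skip, " multi-allelic site(s) skipped")
    v <- v[biallelic, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  # alternate-allele count from unphased or phased diploid calls
  count_alt <- function(g) {
    ifelse(is.na(g) | g %in% c("./.", ".|.", "."), NA_real_,
           vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"), 0))
  }
  alt <- matrix(count_alt(as.vector(gt)), nrow = nrow(gt),
                dimnames = dimnames(gt)) # markers x lines
  impute_missing(t(alt))
}

impute_missing <- function(M) {
  miss_frac <- colMeans(is.na(M))
  drop <- miss_frac > 0.5
  if (any(drop)) {
    warning(sum(drop), " marker(s) dropped: more than 50% missing genotypes")
    M <- M[, !drop, drop = FALSE]
  }
  n_imp <- sum(is.na(M))
  if (n_imp > 0) {
    message(n_imp, " missing genotype(s) imputed to the nearest dosage to twice the allele frequency")
    for (j in which(colSums(is.na(M)) > 0)) {
      m <- is.na(M[, j])
      M[m, j] <- round(mean(M[!m, j]))
    }
  }
  geno_matrix(M)
}

#' @rdname read_genotypes
#' @param geno a [geno_matrix()] to write.
#' @export
write_genotypes <- function(geno, path, format = c("tabular", "vcf")) {
  format <- match.arg(format)
  geno <- as_geno(geno)
  if (format == "tabular") {
    df <- data.frame(line_id = rownames(geno), unclass(geno),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write_genotypes_vcf(geno, path)
  }
  invisible(path)
}

# minimal biallelic diploid VCF (markers as rows on a dummy chromosome)
write_genotypes_vcf <- function(geno, path) {
  M <- unclass(geno)
  gt_string <- c("0/0", "0/1", "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##contig=<ID=1>",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(M)), collapse = "\t"))
  body <- vapply(seq_len(ncol(M)), function(j) {
    paste(c("1", j, colnames(M)[j], "A", "T", ".", "PASS", ".", "GT",
            gt_string[M[, j] + 1]), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read and write phenotype tables
#'
#' Two-column tab-separated text: line id and trait value ('.' for
#' missing). [write_trait()] additionally writes a sidecar
#' (`<path>.truth.tsv`) with the true genetic values and realized
#' heritability of a simulated trait.
#'
#' @param path file path.
#' @return A tibble with columns `id` and `value`.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", na.strings = ".",
                          colClasses = c("character", "numeric"))
  names(df) <- c("id", "value")
  if (anyDuplicated(df$id)) stop("duplicate line ids in phenotype file", call. = FALSE)
  tibble::as_tibble(df)
}

#' @rdname read_phenotypes
#' @param ids line identifiers; @param values trait values.
#' @export
write_phenotypes <- function(ids, values, path) {
  utils::write.table(data.frame(id = ids, value = values), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_phenotypes
#' @param trait a [sim_phenotypes()] result.
#' @export
write_trait <- function(trait, path) {
  stopifnot(inherits(trait, "sim_trait"))
  write_phenotypes(trait$line_ids, trait$y, path)
  truth <- data.frame(id = trait$line_ids, g = trait$g,
                      realized_h2 = trait$realized_h2)
  utils::write.table(truth, paste0(path, ".truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write kernels as tabular text with a JSON sidecar
#'
#' The kernel matrix is written as TSV with line ids as first row and
#' column; `<path>.json` records the kernel name, bandwidth and scaling
#' note so a round trip preserves provenance.
#'
#' @param kernel a [gp_kernel()]; @param path file path.
#' @return The kernel (read) or the path (write), invisibly.
#' @export
write_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "gp_kernel"))
  df <- data.frame(line_id = rownames(kernel$matrix), kernel$matrix,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(name = kernel$name, bandwidth = kernel$bandwidth,
               scaling_note = kernel$scaling_note)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  M <- as.matrix(df)
  if (!identical(rownames(M), colnames(M))) {
    stop("kernel file has mismatched row and column ids", call. = FALSE)
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(name = "custom", bandwidth = NULL, scaling_note = "")
  }
  gp_kernel(M, name = meta$name, bandwidth = meta$bandwidth,
            scaling_note = meta$scaling_note %||% "")
}

#' Serialize fold plans and CV results
#'
#' Fold plans round-trip through JSON (seed, shape and the full
#' assignment); CV results through tidy TSV (replicate, fold, model,
#' accuracy, mse, n_test).
#'
#' @param plan a [make_fold_plan()] object; @param path file path.
#' @export
write_fold_plan <- function(plan, path) {
  stopifnot(inherits(plan, "fold_plan"))
  obj <- list(n = attr(plan, "n"), k = attr(plan, "k"), r = attr(plan, "r"),
              seed = attr(plan, "seed"),
              assignment = lapply(seq_len(ncol(plan)), function(i) unclass(plan)[, i]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  assignment <- obj$assignment
  if (is.list(assignment)) {
    assignment <- do.call(cbind, assignment)
  } else if (is.matrix(assignment)) {
    assignment <- t(assignment) # simplified as replicates x cases
  } else {
    assignment <- matrix(assignment, ncol = obj$r)
  }
  structure(matrix(as.integer(assignment), ncol = obj$r),
            n = as.integer(obj$n), k = as.integer(obj$k), r = as.integer(obj$r),
            seed = as.integer(obj$seed),
            class = c("fold_plan", "matrix", "array"))
}

#' @rdname write_fold_plan
#' @param cv a [run_paired_cv()] result.
#' @export
write_cv_result <- function(cv, path) {
  utils::write.table(as.data.frame(cv), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_cv_result <- function(path) {
  df <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
  attr(df, "models") <- unique(df$model)
  class(df) <- c("cv_result", class(df))
  df
}

#' Serialize fitted models to JSON
#'
#' Scalars and vectors of a fit (posterior means, variance components,
#' centering constants) with a version tag; chains and kernel matrices are
#' not serialized.
#'
#' @param fit a `bayes_fit` or `kernel_fit`; @param path file path.
#' @export
write_fit <- function(fit, path) {
  obj <- if (inherits(fit, "bayes_fit")) {
    list(type = "bayes_fit", version = 1L, family = fit$prior$family,
         mu_hat = fit$mu_hat, beta_hat = unname(fit$beta_hat),
         marker_ids = names(fit$beta_hat),
         inclusion_prob = fit$inclusion_prob,
         residual_var_hat = fit$residual_var_hat, centers = unname(fit$centers),
         prior = unclass(fit$prior), chain_meta = fit$chain_meta)
  } else if (inherits(fit, "kernel_fit")) {
    list(type = "kernel_fit", version = 1L,
         kernel_names = fit$kernel_names,
         var_components = as.list(fit$var_components), h2_hat = fit$h2_hat,
         fixed_hat = as.list(fit$fixed_hat), alpha = fit$alpha,
         training_ids = fit$training_ids, n = fit$n)
  } else {
    stop("unsupported fit object", call. = FALSE)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Bundled multi-task margin-test outcomes
#'
#' A published multi-species, multi-trait comparison of a Gaussian-kernel
#' model against G-BLUP on the expected-genetic-gain scale, at low and high
#' marker-panel densities: per task the mean gain difference, its interval,
#' and whether each of the four nulls (sd, eq, noi, sup) was rejected.
#' Useful as input to [summarize_tasks()] and [report_tasks()].
#'
#' @return A tibble with columns `markers`, `species`, `trait`, `mean`,
#'   `lower`, `upper`, and logical `sd`, `eq`, `noi`, `sup`.
#' @export
gain_task_outcomes <- function() {
  path <- system.file("extdata", "gain_task_outcomes.tsv", package = "gpcv",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
}
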