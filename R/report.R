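#' All-pairs model comparison with margin tests and labels
#'
#' Runs [paired_differences()] and [run_tests()] for every ordered model
#' pair of a paired CV result, then derives the three label systems:
#' equivalence letters (maximal cliques of the pairwise-equivalence graph),
#' the superiority ranking and the non-inferiority ranking (topological
#' layering of the respective rejection digraphs). Conventional
#' "significance letters" from the statistical-difference tests are also
#' produced (models share a lowercase letter when their difference was not
#' shown statistically significant); unlike the equivalence letters, these
#' do not assert equivalence.
#'
#' For the non-inferiority ranking, mutually non-inferior pairs (both
#' directions rejected — the pair is inside the margin) carry no ordering
#' information and contribute no edge; only asymmetric non-inferiority
#' rejections order the models.
#'
#' @param cv a [run_paired_cv()] result.
#' @param margin a [margin_config()]; the margin must be on `scale`.
#' @param reference optional reference model name for the reported
#'   mean/interval columns (differences are `model - reference`).
#' @param scale,q,ci,B,seed passed to [paired_differences()].
#' @param bonferroni apply a Bonferroni correction to the test size across
#'   the all-pairs family (off by default).
#' @return An object of class `gp_comparison`: pairwise stats and outcomes,
#'   plus `labels` (model, sd letters, eq letters, noi rank, sup rank).
#' @export
compare_models <- function(cv, margin, reference = NULL,
                           scale = c("accuracy", "genetic_gain"), q = 0.1,
                           ci = c("bootstrap", "t"), B = 2000L, seed = 1L,
                           bonferroni = FALSE) {
  scale <- match.arg(scale)
  ci <- match.arg(ci)
  stopifnot(inherits(margin, "margin_config"))
  models <- attr(cv, "models") %||% unique(cv$model)
  if (!is.null(reference) && !reference %in% models) {
    stop("reference model not present in the CV result", call. = FALSE)
  }
  n_pairs <- choose(length(models), 2)
  alpha_use <- if (bonferroni) margin$alpha / n_pairs else margin$alpha
  margin_use <- margin_config(margin$delta, alpha_use)

  pairs <- utils::combn(models, 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(pr) {
    st <- paired_differences(cv, pr[1], pr[2], scale = scale, q = q,
                             level = 1 - alpha_use, ci = ci, B = B, seed = seed)
    tst <- run_tests(st, margin_use)
    rej <- stats::setNames(tst$null_rejected, tst$test)
    # reverse-direction margin tests (d -> -d): noi/sup of b over a
    st_rev <- st; st_rev$d <- -st$d; st_rev$mean_d <- -st$mean_d
    ci_rev <- t_ci_level(st_rev$mean_d, st$se_d, length(st$d) - 1, 1 - 2 * alpha_use)
    tibble::tibble(a = pr[1], b = pr[2],
                   mean_d = st$mean_d, se_d = st$se_d,
                   ci_low = st$ci_low, ci_high = st$ci_high,
                   sd = rej[["sd"]], eq = rej[["eq"]],
                   noi_ab = rej[["noi"]], sup_ab = rej[["sup"]],
                   noi_ba = ci_rev[1] > -margin_use$delta,
                   sup_ba = ci_rev[1] > margin_use$delta)
  }) |> dplyr::bind_rows()

  eq_pairs <- tibble::tibble(a = rows$a, b = rows$b, rejected = rows$eq)
  eq_letters <- equivalence_letters(models, eq_pairs)

  # sd letters: conventional compact letter display on the NON-rejection graph
  sd_pairs <- tibble::tibble(a = rows$a, b = rows$b, rejected = !rows$sd)
  sd_letters <- equivalence_letters(models, sd_pairs) |>
    dplyr::mutate(letters = tolower(.data$letters)) |>
    dplyr::rename(sd_letters = "letters")

  # superiority digraph: edge loser -> winner
  sup_edges <- dplyr::bind_rows(
    tibble::tibble(a = rows$b, b = rows$a, rejected = rows$sup_ab),
    tibble::tibble(a = rows$a, b = rows$b, rejected = rows$sup_ba))
  sup_rank <- build_ranking(models, sup_edges)

  # non-inferiority digraph: only asymmetric rejections order the models
  noi_edges <- dplyr::bind_rows(
    tibble::tibble(a = rows$b, b = rows$a, rejected = rows$noi_ab & !rows$noi_ba),
    tibble::tibble(a = rows$a, b = rows$b, rejected = rows$noi_ba & !rows$noi_ab))
  noi_rank <- build_ranking(models, noi_edges)

  labels <- eq_letters |>
    dplyr::rename(eq_letters = "letters") |>
    dplyr::left_join(sd_letters, by = "model") |>
    dplyr::left_join(dplyr::rename(noi_rank, noi_rank = "rank"), by = "model") |>
    dplyr::left_join(dplyr::rename(sup_rank, sup_rank = "rank"), by = "model") |>
    dplyr::select("model", "sd_letters", "eq_letters", "noi_rank", "sup_rank")

  structure(list(pairs = rows, labels = labels, models = models,
                 reference = reference, margin = margin, scale = scale, q = q,
                 alpha_used = alpha_use, cv = cv, ci = ci, B = B, seed = seed),
            class = "gp_comparison")
}

#' @export
print.gp_comparison <- function(x, ...) {
  cat(sprintf("<gp_comparison> %d models, margin delta = %g (alpha = %g, %s scale)\n",
              length(x$models), x$margin$delta, x$alpha_used, x$scale))
  print(report_comparison(x))
  invisible(x)
}

#' Comparison report in the standard table layout
#'
#' One row per model with the mean accuracy (or gain) difference against the
#' reference model and its interval, the conventional significance letters
#' (`sd`), the equivalence letters (`eq`) and the superiority rank (`Sup`).
#' The reference model's own difference row is zero by construction.
#'
#' @param comparison a [compare_models()] object.
#' @return A tibble with columns `model`, `mean`, `lower`, `upper`, `sd`,
#'   `eq`, `sup_rank`, ordered by mean difference.
#' @export
report_comparison <- function(comparison) {
  stopifnot(inherits(comparison, "gp_comparison"))
  x <- comparison
  ref <- x$reference %||% x$models[1]
  vs_ref <- purrr::map(setdiff(x$models, ref), function(mdl) {
    st <- paired_differences(x$cv, mdl, ref, scale = x$scale, q = x$q,
                             level = 1 - x$alpha_used, ci = x$ci, B = x$B,
                             seed = x$seed)
    tibble::tibble(model = mdl, mean = st$mean_d,
                   lower = st$ci_low, upper = st$ci_high)
  }) |> dplyr::bind_rows() |>
    dplyr::bind_rows(tibble::tibble(model = ref, mean = 0,
                                    lower = NA_real_, upper = NA_real_))
  vs_ref |>
    dplyr::left_join(x$labels, by = "model") |>
    dplyr::arrange(.data$mean) |>
    dplyr::select("model", "mean", "lower", "upper",
                  sd = "sd_letters", eq = "eq_letters", sup_rank = "sup_rank")
}

#' Multi-task report with rejection stars and proportion rows
#'
#' Formats per-task margin-test outcomes in the standard multi-task layout:
#' one row per task with its mean difference, interval and a star for each
#' rejected null, followed by one summary row per group holding rejection
#' proportions (from [summarize_tasks()]).
#'
#' @param outcomes tibble with one row per task: grouping keys, optional
#'   `mean`, `lower`, `upper` columns, and logical `sd`, `eq`, `noi`, `sup`.
#' @param grouping character vector of grouping columns for the summary
#'   rows.
#' @return A list with `tasks` (stars as `"*"`/`""`) and `proportions`.
#' @export
report_tasks <- function(outcomes, grouping = character()) {
  tests <- c("sd", "eq", "noi", "sup")
  stars <- outcomes |>
    dplyr::mutate(dplyr::across(dplyr::all_of(tests),
                                ~ ifelse(as.logical(.x), "*", "")))
  list(tasks = stars, proportions = summarize_tasks(outcomes, grouping))
}
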