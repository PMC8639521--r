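#' Paired per-fold accuracy differences between two models
#'
#' Extracts the fold-level accuracy difference `a - b` across all replicates
#' and folds of a paired CV result (both models saw identical folds), and
#' summarises it: mean, standard error, and a confidence interval (bootstrap
#' percentile by default, or the t interval). On the `genetic_gain` scale
#' every difference is multiplied by the selection intensity `i_q`.
#'
#' @param cv a [run_paired_cv()] result (or any tibble with `replicate`,
#'   `fold`, `model`, `accuracy` columns).
#' @param a,b model names present in `cv`.
#' @param scale `"accuracy"` or `"genetic_gain"`.
#' @param q selected proportion for the genetic-gain scale.
#' @param level confidence level of the reported interval.
#' @param ci `"bootstrap"` (percentile, default) or `"t"`.
#' @param B bootstrap resamples.
#' @param seed bootstrap seed.
#'
#' @return An object of class `paired_stat`: the difference vector `d`, its
#'   mean, SE and interval, plus metadata.
#' @export
paired_differences <- function(cv, a, b, scale = c("accuracy", "genetic_gain"),
                               q = 0.1, level = 0.95,
                               ci = c("bootstrap", "t"), B = 2000L, seed = 1L) {
  scale <- match.arg(scale)
  ci <- match.arg(ci)
  da <- dplyr::filter(cv, .data$model == a)
  db <- dplyr::filter(cv, .data$model == b)
  if (nrow(da) == 0 || nrow(db) == 0) {
    stop("both models must be present in the CV result", call. = FALSE)
  }
  key_a <- paste(da$replicate, da$fold)
  key_b <- paste(db$replicate, db$fold)
  if (nrow(da) != nrow(db) || !all(sort(key_a) == sort(key_b))) {
    stop("unmatched folds between the two models: pairing is broken", call. = FALSE)
  }
  db <- db[match(key_a, key_b), ]
  d <- da$accuracy - db$accuracy
  if (scale == "genetic_gain") d <- to_genetic_gain(d, q)
  new_paired_stat(d, a, b, scale = scale, q = q, level = level, ci = ci,
                  B = B, seed = seed)
}

#' Build a paired statistic from precomputed fold differences
#'
#' For fold-score differences obtained outside [run_paired_cv()] (e.g. from
#' another evaluation pipeline): summarises the difference vector exactly as
#' [paired_differences()] would.
#'
#' @param d numeric vector of per-fold differences `a - b`.
#' @param a,b model names.
#' @param scale,q,level,ci,B,seed as in [paired_differences()].
#' @return A `paired_stat` object.
#' @export
paired_stat <- function(d, a = "A", b = "B", scale = "accuracy", q = NA_real_,
                        level = 0.95, ci = c("bootstrap", "t"), B = 2000L,
                        seed = 1L) {
  stopifnot(is.numeric(d), length(d) >= 2)
  ci <- match.arg(ci)
  new_paired_stat(d, a, b, scale = scale, q = q, level = level, ci = ci,
                  B = B, seed = seed)
}

new_paired_stat <- function(d, a, b, scale = "accuracy", q = NA_real_,
                            level = 0.95, ci = "bootstrap", B = 2000L,
                            seed = 1L) {
  m <- mean(d)
  se <- stats::sd(d) / sqrt(length(d))
  stat <- structure(list(model_a = a, model_b = b, d = d, mean_d = m,
                         se_d = se, level = level, scale = scale, q = q,
                         ci_method = ci),
                    class = "paired_stat")
  iv <- if (ci == "bootstrap") {
    bootstrap_ci(stat, B = B, level = level, seed = seed)
  } else {
    t_ci(stat, level)
  }
  stat$ci_low <- iv[1]
  stat$ci_high <- iv[2]
  stat
}

t_ci <- function(stat, level) {
  n <- length(stat$d)
  if (stat$se_d == 0) return(c(stat$mean_d, stat$mean_d))
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * stat$se_d
  c(stat$mean_d - half, stat$mean_d + half)
}

#' Bootstrap percentile interval for a paired mean difference
#'
#' Nonparametric bootstrap of the fold-level differences: resamples `d` with
#' replacement `B` times and returns the percentile interval of the mean.
#' Degenerate (all-equal) difference vectors return a zero-width interval
#' with a warning.
#'
#' @param stat a [paired_differences()] object (its `d` vector is used).
#' @param B number of resamples (>= 1000 recommended).
#' @param level confidence level in (0, 1).
#' @param seed integer seed; the same seed gives the identical interval.
#' @return Length-2 numeric vector `c(lower, upper)`.
#' @export
bootstrap_ci <- function(stat, B = 2000L, level = 0.95, seed = 1L) {
  stopifnot(inherits(stat, "paired_stat"), level > 0, level < 1, B >= 1)
  d <- stat$d
  if (stats::sd(d) == 0) {
    warning("all paired differences are equal: degenerate bootstrap interval")
    return(c(d[1], d[1]))
  }
  withr::with_seed(as.integer(seed), {
    bt <- boot::boot(d, statistic = function(x, i) mean(x[i]), R = B)
    unname(stats::quantile(bt$t[, 1], c((1 - level) / 2, 1 - (1 - level) / 2)))
  })
}

#' @export
print.paired_stat <- function(x, ...) {
  cat(sprintf("<paired_stat> %s - %s (%s scale)\n", x$model_a, x$model_b, x$scale))
  cat(sprintf("  mean d = %.4f, SE = %.4f, %d%% %s CI [%.4f, %.4f], %d folds\n",
              x$mean_d, x$se_d, round(100 * x$level), x$ci_method,
              x$ci_low, x$ci_high, length(x$d)))
  invisible(x)
}

#' @export
tidy.paired_stat <- function(x, ...) {
  tibble::tibble(model_a = x$model_a, model_b = x$model_b, scale = x$scale,
                 mean_d = x$mean_d, se_d = x$se_d,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 level = x$level, n_folds = length(x$d))
}

#' Margin configuration for equivalence-style tests
#'
#' @param delta equivalence margin `>= 0`, on the same scale as the paired
#'   differences (accuracy or genetic gain). There is no default: the margin
#'   is a domain judgment the analyst must supply.
#' @param alpha test size, in (0, 0.5).
#' @return A list of class `margin_config`.
#' @export
margin_config <- function(delta, alpha = 0.05) {
  stopifnot(is.numeric(delta), length(delta) == 1, delta >= 0,
            alpha > 0, alpha < 0.5)
  structure(list(delta = delta, alpha = alpha), class = "margin_config")
}

#' Statistical-difference, equivalence, non-inferiority and superiority tests
#'
#' Tests four nulls about the mean paired difference `d` at margin `Delta`:
#' statistical difference (`sd`, H0: d = 0), equivalence (`eq`,
#' H0: |d| > Delta, via two one-sided tests), non-inferiority (`noi`,
#' H0: d < -Delta) and superiority (`sup`, H0: d < Delta). All four use the
#' same t machinery on the fold differences (df = number of folds - 1): the
#' `sd` decision is the two-sided test at level `alpha`, and the three
#' margin tests are decided by the two-sided `(1 - 2 alpha)` confidence
#' interval — equivalence when it lies inside `(-Delta, Delta)`,
#' non-inferiority when its lower bound exceeds `-Delta`, superiority when
#' its lower bound exceeds `Delta`. This construction guarantees coherence:
#' superiority implies non-inferiority, and (for `Delta > 0`) equivalence
#' excludes superiority.
#'
#' @param stat a [paired_differences()] object.
#' @param margin a [margin_config()].
#' @return A tibble of class `test_outcome` with one row per test: `test`,
#'   `null_rejected`, `p_value`, `ci_low`, `ci_high`, `ci_level`.
#' @export
run_tests <- function(stat, margin) {
  stopifnot(inherits(stat, "paired_stat"), inherits(margin, "margin_config"))
  d <- stat$d
  n <- length(d)
  m <- stat$mean_d
  se <- stat$se_d
  df <- n - 1
  delta <- margin$delta
  alpha <- margin$alpha
  degenerate <- se == 0

  p_sd <- if (degenerate) as.numeric(m == 0) else 2 * stats::pt(-abs(m / se), df)
  # one-sided p-values against the margin bounds
  p_above_lower <- if (degenerate) as.numeric(m <= -delta) else stats::pt(-(m + delta) / se, df) # H0: d <= -Delta
  p_below_upper <- if (degenerate) as.numeric(m >= delta) else stats::pt((m - delta) / se, df)   # H0: d >= Delta
  p_above_upper <- if (degenerate) as.numeric(m <= delta) else stats::pt(-(m - delta) / se, df)  # H0: d <= Delta
  p_eq <- max(p_above_lower, p_below_upper)

  # decisions via the common CI machinery
  ci_main <- t_ci_level(m, se, df, 1 - alpha)
  ci_tost <- t_ci_level(m, se, df, 1 - 2 * alpha)
  sd_rej <- if (degenerate) m != 0 else ci_main[1] > 0 || ci_main[2] < 0
  eq_rej <- ci_tost[1] > -delta && ci_tost[2] < delta
  noi_rej <- ci_tost[1] > -delta
  sup_rej <- ci_tost[1] > delta
  if (delta == 0) {
    warning("delta = 0 makes the equivalence test undecidable; eq returned not rejected")
    eq_rej <- FALSE
  }

  out <- tibble::tibble(
    test = c("sd", "eq", "noi", "sup"),
    null_rejected = c(sd_rej, eq_rej, noi_rej, sup_rej),
    p_value = c(p_sd, p_eq, p_above_lower, p_above_upper),
    ci_low = c(ci_main[1], ci_tost[1], ci_tost[1], ci_tost[1]),
    ci_high = c(ci_main[2], ci_tost[2], ci_tost[2], ci_tost[2]),
    ci_level = c(1 - alpha, rep(1 - 2 * alpha, 3)))
  attr(out, "margin") <- margin
  attr(out, "models") <- c(stat$model_a, stat$model_b)
  class(out) <- c("test_outcome", class(out))
  out
}

t_ci_level <- function(m, se, df, level) {
  if (se == 0) return(c(m, m))
  half <- stats::qt(1 - (1 - level) / 2, df) * se
  c(m - half, m + half)
}

#' Equivalence letters from pairwise equivalence tests
#'
#' Builds an undirected graph over the models with an edge wherever the
#' pairwise equivalence null was rejected (the two models were shown
#' equivalent within the margin), enumerates its maximal cliques, and
#' assigns one letter per maximal clique. A model's label is the set of
#' letters of the cliques containing it; models sharing a letter are all
#' pairwise confidently equivalent. Isolated models form their own cliques
#' and get their own letters.
#'
#' @param models character vector of model names (defines letter order).
#' @param eq_pairs data frame with columns `a`, `b`, `rejected` (logical),
#'   one row per unordered model pair.
#' @return A tibble with columns `model` and `letters` (collapsed string,
#'   e.g. `"AB"`).
#' @export
equivalence_letters <- function(models, eq_pairs) {
  g <- pair_graph(models, eq_pairs, directed = FALSE)
  cl <- igraph::max_cliques(g)
  # order cliques by the best (earliest) member in the supplied model order
  first_member <- vapply(cl, function(cc) min(match(names(cc), models)), 1)
  cl <- cl[order(first_member)]
  letters_of <- stats::setNames(vector("list", length(models)), models)
  for (i in seq_along(cl)) {
    lab <- clique_letter(i)
    for (v in names(cl[[i]])) letters_of[[v]] <- c(letters_of[[v]], lab)
  }
  tibble::tibble(model = models,
                 letters = unname(vapply(letters_of[models],
                                         function(l) paste(sort(l), collapse = ""), "")))
}

clique_letter <- function(i) {
  if (i <= 26) LETTERS[i] else paste0(LETTERS[(i - 1) %/% 26], LETTERS[(i - 1) %% 26 + 1])
}

pair_graph <- function(models, pairs, directed) {
  stopifnot(all(c("a", "b", "rejected") %in% names(pairs)))
  if (!all(pairs$a %in% models & pairs$b %in% models)) {
    stop("pairs reference unknown models", call. = FALSE)
  }
  ed <- pairs[pairs$rejected, c("a", "b"), drop = FALSE]
  igraph::graph_from_data_frame(ed, directed = directed,
                                vertices = data.frame(name = models))
}

#' Non-inferiority / superiority ranking by topological layering
#'
#' Takes the digraph whose edge `a -> b` records that model `b` was shown
#' superior (or non-inferior beyond the margin) to model `a`, verifies it is
#' acyclic, and assigns each model the ordinal `1 + length of the longest
#' directed path ending at it`. This is the consensus of all topological
#' orders: a model's ordinal exceeds another's only when a chain of
#' rejections forces it, and models incomparable in every topological order
#' share an ordinal. Cyclic rejection patterns (mutual superiority) raise an
#' inconsistency error naming the cycle.
#'
#' @param models character vector of model names.
#' @param directed_pairs data frame with columns `a`, `b`, `rejected`; a
#'   rejected row means `b` ranks above `a` (edge `a -> b`).
#' @return A tibble with columns `model` and `rank` (positive integers, no
#'   gaps in the sorted distinct set).
#' @export
build_ranking <- function(models, directed_pairs) {
  g <- pair_graph(models, directed_pairs, directed = TRUE)
  if (!igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    stop("inconsistent rejections: the comparison digraph has a cycle (e.g. through ",
         paste(unique(unlist(igraph::ends(g, cyc))), collapse = ", "), ")",
         call. = FALSE)
  }
  topo <- igraph::topo_sort(g, mode = "out")
  depth <- stats::setNames(rep(1L, length(models)), models)
  for (v in names(topo)) {
    preds <- names(igraph::neighbors(g, v, mode = "in"))
    if (length(preds)) depth[v] <- 1L + max(depth[preds])
  }
  ranks <- depth[models]
  # close gaps so ordinals are consecutive
  ranks <- match(ranks, sort(unique(ranks)))
  tibble::tibble(model = models, rank = as.integer(ranks))
}

#' Analytic power of paired vs unpaired fold-score comparisons
#'
#' For a true accuracy difference `true_d` between two models whose fold
#' scores share standard deviation `sd_fold` and correlate at `rho` across
#' folds: the paired design tests the `k` fold differences (one-sample t,
#' difference variance `2 sd_fold^2 (1 - rho)`), while the unpaired design
#' compares the two sets of `k` scores as if independent (two-sample t,
#' variance `2 sd_fold^2`, unaffected by `rho`). At `rho = 0.8` the paired
#' variance is five times smaller. Power is computed from the noncentral t
#' distribution.
#'
#' @param true_d true mean difference.
#' @param sd_fold per-fold score standard deviation (> 0).
#' @param rho fold-score correlation; `rho = 1` with `true_d != 0` gives
#'   paired power 1 (zero-variance differences).
#' @param k number of folds (>= 2).
#' @param alpha two-sided test size.
#' @return A tibble with columns `rho`, `power_paired`, `power_unpaired`
#'   (one row per value of `rho`).
#' @export
#' @examples
#' power_paired_vs_unpaired(0.02, sd_fold = 0.03, rho = 0.8, k = 10)
power_paired_vs_unpaired <- function(true_d, sd_fold, rho, k, alpha = 0.05) {
  stopifnot(sd_fold > 0, k >= 2, all(abs(rho) <= 1))
  power_p <- vapply(rho, function(r) {
    if (r >= 1) return(if (true_d != 0) 1 else alpha)
    se <- sqrt(2 * sd_fold^2 * (1 - r) / k)
    t_power(true_d / se, df = k - 1, alpha = alpha)
  }, 0)
  se_u <- sqrt(2 * sd_fold^2 / k)
  power_u <- t_power(true_d / se_u, df = 2 * k - 2, alpha = alpha)
  out <- tibble::tibble(rho = rho, power_paired = power_p,
                        power_unpaired = rep(power_u, length(rho)))
  class(out) <- c("gp_power_curve", class(out))
  out
}

# two-sided power of a t test with noncentrality ncp
t_power <- function(ncp, df, alpha) {
  crit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-crit, df, ncp = ncp) + stats::pt(crit, df, ncp = ncp, lower.tail = FALSE)
}

#' Summarise margin-test outcomes over many prediction tasks
#'
#' Given per-task results of the four tests (e.g. one task per trait and
#' panel density), computes for each group the fraction of tasks in which
#' each null was rejected — the bottom summary rows of a multi-task
#' comparison table.
#'
#' @param outcomes tibble with one row per task: logical columns `sd`, `eq`,
#'   `noi`, `sup` plus any grouping keys.
#' @param grouping character vector of grouping column names (may be empty).
#' @return A tibble with the grouping keys, `n_tasks`, and columns `sd`,
#'   `eq`, `noi`, `sup` holding rejection proportions.
#' @export
summarize_tasks <- function(outcomes, grouping = character()) {
  need <- c("sd", "eq", "noi", "sup")
  stopifnot(all(need %in% names(outcomes)))
  if (nrow(outcomes) == 0) {
    warning("no tasks to summarise")
    return(tibble::tibble())
  }
  outcomes |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(n_tasks = dplyr::n(),
                     dplyr::across(dplyr::all_of(need), ~ mean(as.logical(.x))),
                     .groups = "drop")
}
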