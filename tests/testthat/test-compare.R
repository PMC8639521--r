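cv_from_scores <- function(scores) {
  long <- tidyr::pivot_longer(scores, c("score_a", "score_b"),
                              names_to = "model", values_to = "accuracy",
                              names_prefix = "score_")
  long$mse <- 0; long$n_test <- 10
  attr(long, "models") <- c("a", "b")
  class(long) <- c("cv_result", class(long))
  long
}

test_that("paired differences carry the variance-reduction identity", {
  s <- sim_fold_scores(100, 100, rho = 0.8, sd_fold = 1, seed = 81)
  cv <- cv_from_scores(s)
  st <- paired_differences(cv, "a", "b", ci = "t")
  # var(d) = var(a) + var(b) - 2 cov(a, b), exactly
  expect_equal(stats::var(st$d),
               var(s$score_a) + var(s$score_b) - 2 * cov(s$score_a, s$score_b))
  # unpaired-to-paired variance ratio near 1 / (1 - rho) = 5
  ratio <- (var(s$score_a) + var(s$score_b)) / var(st$d)
  expect_lt(abs(ratio / 5 - 1), 0.05)

  # identical models: degenerate zero interval
  same <- cv_from_scores(sim_fold_scores(2, 5, rho = 1, seed = 82))
  st0 <- suppressWarnings(paired_differences(same, "a", "b"))
  expect_true(all(st0$d == 0))
  expect_equal(c(st0$ci_low, st0$ci_high), c(0, 0))

  # the gain scale multiplies everything by i_q
  stg <- paired_differences(cv, "a", "b", scale = "genetic_gain", q = 0.1,
                            ci = "t")
  expect_equal(stg$mean_d, st$mean_d * selection_intensity(0.1))
  expect_error(paired_differences(cv, "a", "missing"), "present")
})

test_that("bootstrap percentile intervals agree with t intervals for normal data", {
  st <- synthetic_paired_stat(0.03, 0.02, n = 50)
  bs <- bootstrap_ci(st, B = 4000, level = 0.95, seed = 83)
  tt <- gpcv:::t_ci(st, 0.95)
  expect_lt(abs((bs[2] - bs[1]) / (tt[2] - tt[1]) - 1), 0.1)
  expect_identical(bs, bootstrap_ci(st, B = 4000, level = 0.95, seed = 83))
  const <- paired_stat(rep(0.2, 10), "a", "b", ci = "t")
  expect_warning(ci <- bootstrap_ci(const, B = 100), "degenerate")
  expect_equal(ci, c(0.2, 0.2))
})

test_that("margin tests decide by interval containment", {
  # 90% CI approximately [0.02, 0.04] around mean 0.03
  half <- 0.01
  sdv <- half * sqrt(30) / qt(0.95, 29)
  st <- synthetic_paired_stat(0.03, sdv, n = 30)
  out <- run_tests(st, margin_config(0.05, alpha = 0.05))
  rej <- setNames(out$null_rejected, out$test)
  expect_true(rej[["eq"]])
  expect_true(rej[["noi"]])
  expect_false(rej[["sup"]])
  expect_true(rej[["sd"]])

  st2 <- synthetic_paired_stat(0.095, sdv, n = 30) # CI ~ [0.085, 0.105]
  rej2 <- setNames(run_tests(st2, margin_config(0.05))$null_rejected,
                   c("sd", "eq", "noi", "sup"))
  expect_true(rej2[["sup"]])
  expect_true(rej2[["noi"]])
  expect_false(rej2[["eq"]])

  expect_warning(out0 <- run_tests(st, margin_config(0)), "undecidable")
  expect_false(out0$null_rejected[out0$test == "eq"])
})

test_that("test decisions are coherent over an exhaustive grid", {
  for (m in seq(-0.12, 0.12, by = 0.03)) {
    for (sdv in c(0.005, 0.02, 0.08, 0.3)) {
      st <- synthetic_paired_stat(m, sdv, n = 20)
      for (delta in c(0.01, 0.05, 0.1)) {
        rej <- setNames(run_tests(st, margin_config(delta))$null_rejected,
                        c("sd", "eq", "noi", "sup"))
        if (rej[["sup"]]) expect_true(rej[["noi"]])
        if (rej[["eq"]]) expect_false(rej[["sup"]])
      }
    }
  }
})

test_that("the sd test attains its nominal type-I error", {
  set.seed(84)
  rejections <- replicate(2000, {
    d <- rnorm(30, 0, 0.05)
    st <- paired_stat(d, "a", "b", ci = "t")
    run_tests(st, margin_config(0.05))$null_rejected[1]
  })
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(mean(rejections) - 0.05), 2 * se)
})

test_that("equivalence letters are maximal cliques of the equivalence graph", {
  models <- c("m1", "m2", "m3")
  none <- tibble::tibble(a = c("m1", "m1", "m2"), b = c("m2", "m3", "m3"),
                         rejected = FALSE)
  lt <- equivalence_letters(models, none)
  expect_equal(sort(lt$letters), c("A", "B", "C"))
  all_eq <- dplyr::mutate(none, rejected = TRUE)
  expect_equal(unique(equivalence_letters(models, all_eq)$letters), "A")
  # overlap: m2 equivalent to both, m1 and m3 not to each other
  chain <- tibble::tibble(a = c("m1", "m1", "m2"), b = c("m2", "m3", "m3"),
                          rejected = c(TRUE, FALSE, TRUE))
  lt2 <- equivalence_letters(models, chain)
  expect_equal(lt2$letters[lt2$model == "m2"], "AB")
  # two models share a letter iff they lie in a common maximal clique
  expect_false(any(strsplit(lt2$letters[1], "")[[1]] %in%
                     strsplit(lt2$letters[3], "")[[1]]))
})

test_that("rankings layer the rejection digraph and reject cycles", {
  models <- c("x", "y", "z")
  none <- tibble::tibble(a = character(), b = character(), rejected = logical())
  expect_equal(build_ranking(models, none)$rank, c(1L, 1L, 1L))
  chain <- tibble::tibble(a = c("x", "y"), b = c("y", "z"), rejected = TRUE)
  expect_equal(build_ranking(models, chain)$rank, 1:3)
  # permutation invariance
  perm <- build_ranking(c("z", "x", "y"), chain)
  expect_equal(perm$rank[match(models, perm$model)], 1:3)
  cyc <- tibble::tibble(a = c("x", "y"), b = c("y", "x"), rejected = TRUE)
  expect_error(build_ranking(models, cyc), "cycle")
})

test_that("paired power dominates unpaired power at high fold correlation", {
  pw <- power_paired_vs_unpaired(0.02, sd_fold = 0.03,
                                 rho = c(0, 0.5, 0.8, 0.95, 1), k = 10)
  expect_equal(pw$power_paired[5], 1)
  expect_equal(length(unique(pw$power_unpaired)), 1)
  expect_true(all(diff(pw$power_paired) > 0))
  expect_gt(pw$power_paired[4], pw$power_unpaired[4])

  # Monte-Carlo oracle at a few grid points
  set.seed(85)
  for (r in c(0.4, 0.8)) {
    k <- 10; sd_fold <- 0.03; d <- 0.02
    nrep <- 1e4
    dm <- matrix(rnorm(nrep * k, mean = d, sd = sqrt(2 * sd_fold^2 * (1 - r))),
                 nrep, k)
    tstat <- rowMeans(dm) / (apply(dm, 1, sd) / sqrt(k))
    emp <- mean(abs(tstat) > qt(0.975, k - 1))
    ana <- power_paired_vs_unpaired(d, sd_fold, r, k)$power_paired
    expect_lt(abs(emp - ana), 2 * sqrt(ana * (1 - ana) / nrep) + 1e-12)
  }
})

test_that("task summaries report per-group rejection fractions", {
  all_noi <- tibble::tibble(sd = FALSE, eq = FALSE, noi = TRUE, sup = FALSE,
                            .rows = 6)
  sm <- summarize_tasks(all_noi)
  expect_equal(unlist(sm[1, c("sd", "eq", "noi", "sup")]),
               c(sd = 0, eq = 0, noi = 1, sup = 0))
  mixed <- dplyr::bind_rows(
    tibble::tibble(group = "g1", sd = TRUE, eq = c(TRUE, FALSE, FALSE, FALSE),
                   noi = TRUE, sup = FALSE),
    tibble::tibble(group = "g2", sd = FALSE, eq = c(TRUE, TRUE, FALSE, FALSE),
                   noi = TRUE, sup = TRUE))
  sm2 <- summarize_tasks(mixed, "group")
  expect_equal(sm2$eq, c(0.25, 0.5))
  expect_equal(sm2$n_tasks, c(4L, 4L))
  rt <- report_tasks(mixed, "group")
  expect_equal(rt$tasks$sup[1], "")
  expect_equal(rt$tasks$sup[5], "*")
})

test_that("the all-pairs comparison produces consistent labels end to end", {
  s <- sim_fold_scores(2, 10, rho = 0.9, mean_a = 0.55, mean_b = 0.5,
                       sd_fold = 0.02, seed = 86)
  cv <- cv_from_scores(s)
  cmp <- compare_models(cv, margin_config(0.01), reference = "b", ci = "t")
  expect_s3_class(cmp, "gp_comparison")
  tab <- report_comparison(cmp)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("model", "mean", "lower", "upper", "sd", "eq", "sup_rank")
                  %in% names(tab)))
  # a clearly better: its superiority rank must exceed b's
  expect_gt(tab$sup_rank[tab$model == "a"], tab$sup_rank[tab$model == "b"])
})

test_that("result objects have working plot and tidy methods", {
  pw <- power_paired_vs_unpaired(0.02, 0.03, rho = seq(0, 0.9, 0.1), k = 10)
  expect_s3_class(autoplot(pw), "ggplot")
  expect_s3_class(plot_power_curve(0.02, 0.03), "ggplot")
  s <- sim_fold_scores(2, 10, rho = 0.9, mean_a = 0.55, mean_b = 0.5,
                       sd_fold = 0.02, seed = 87)
  cmp <- compare_models(cv_from_scores(s), margin_config(0.02), ci = "t")
  expect_s3_class(autoplot(cmp), "ggplot")
  st <- paired_differences(cv_from_scores(s), "a", "b", ci = "t")
  td <- tidy(st)
  expect_equal(td$n_folds, 20)
  expect_true(td$ci_low <= td$mean_d && td$mean_d <= td$ci_high)
})
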