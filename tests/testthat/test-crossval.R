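test_that("fold plans partition the cases into balanced folds", {
  expect_error(make_fold_plan(5, k = 6), "2 <= k <= n")
  p1 <- make_fold_plan(10, k = 5, r = 2, seed = 1)
  expect_true(all(apply(unclass(p1), 2, function(f) all(table(f) == 2))))
  p2 <- make_fold_plan(11, k = 5, seed = 2)
  expect_equal(sort(as.vector(table(p2[, 1])), decreasing = TRUE),
               c(3, 2, 2, 2, 2))
  # every case in exactly one fold per replicate; seeded determinism
  expect_true(all(p1 %in% 1:5))
  expect_identical(unclass(make_fold_plan(10, 5, 2, seed = 1)), unclass(p1))
})

test_that("fold accuracy is an affine-invariant correlation", {
  obs <- c(1, 3, 2, 5, 4)
  expect_equal(fold_accuracy(obs, obs), 1)
  expect_equal(fold_accuracy(-obs, obs), -1)
  expect_equal(fold_accuracy(2 * obs + 7, obs), 1)
  expect_error(fold_accuracy(rep(1, 5), obs), "zero variance")
  expect_error(fold_accuracy(1:2, 1:2), "at least 3")
})

test_that("paired CV keeps identical folds across models", {
  plan <- make_fold_plan(60, k = 4, r = 2, seed = 71)
  cv <- run_paired_cv(fix_trait$y, list(
    spec_oracle_model("o1", fix_trait$g),
    spec_oracle_model("o2", fix_trait$g)), plan)
  expect_equal(nrow(cv), 2 * 4 * 2)
  wide <- tidyr::pivot_wider(cv, id_cols = c("replicate", "fold"),
                             names_from = "model", values_from = "accuracy")
  expect_equal(wide$o1, wide$o2)
  expect_true(all(cv$n_test == 15))
})

test_that("a model failing on a fold drops that fold for every model", {
  y <- fix_trait$y
  bad <- fix_trait$g
  plan <- make_fold_plan(60, k = 3, seed = 72)
  bad[plan[, 1] == 2] <- bad[which(plan[, 1] == 2)[1]] # constant on fold 2
  cv <- run_paired_cv(y, list(spec_oracle_model("good", fix_trait$g),
                              spec_oracle_model("flaky", bad)), plan)
  expect_equal(sort(unique(cv$fold)), c(1L, 3L))
  expect_equal(nrow(cv), 4) # 2 folds x 2 models
  excl <- attr(cv, "excluded")
  expect_equal(excl$fold, 2)
  expect_match(excl$reason, "zero variance")
})

test_that("an oracle predictor attains accuracy sqrt(h2)", {
  g <- sim_genotypes(600, 150, seed = 73)
  tr <- sim_phenotypes(g, trait_sim_spec(n_qtl_additive = 50,
                                         h2_additive = 0.5, seed = 74))
  plan <- make_fold_plan(600, k = 10, r = 3, seed = 75)
  cv <- run_paired_cv(tr$y, spec_oracle_model("oracle", tr$g), plan)
  mc_se <- sd(cv$accuracy) / sqrt(nrow(cv))
  expect_lt(abs(mean(cv$accuracy) - sqrt(0.5)), 3 * mc_se)
})

test_that("heritability rescaling and the gain scale are linear maps", {
  expect_error(rescale_by_heritability(0.5, 0), "h2_hat")
  expect_equal(rescale_by_heritability(0.5, 1), 0.5)
  expect_equal(rescale_by_heritability(0.5, 0.25), 1)
  acc <- c(0.2, 0.5, 0.35)
  expect_equal(order(rescale_by_heritability(acc, 0.37)), order(acc))

  expect_error(selection_intensity(0), "q must")
  expect_equal(selection_intensity(0.5), dnorm(0) / 0.5)
  expect_equal(round(selection_intensity(0.5), 4), 0.7979)
  # numeric oracle: mean of the upper-q truncated standard normal
  iq_int <- integrate(function(x) x * dnorm(x), qnorm(0.9), Inf)$value / 0.1
  expect_equal(selection_intensity(0.1), iq_int, tolerance = 1e-6)
  expect_equal(round(selection_intensity(0.1), 4), 1.755)
  grid <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(selection_intensity(grid)) < 0))

  expect_equal(to_genetic_gain(0, 0.2), 0)
  expect_equal(round(to_genetic_gain(0.5, 0.1), 4), 0.8775)
  # linearity: gain differences are i_q times accuracy differences
  expect_equal(to_genetic_gain(0.6, 0.1) - to_genetic_gain(0.45, 0.1),
               selection_intensity(0.1) * 0.15)
})
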