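test_that("genotype simulation validates bounds and is seed-reproducible", {
  expect_error(sim_genotypes(4, 3, maf_low = 1, maf_high = 1), "frequency bounds")
  expect_error(sim_genotypes(4, 3, maf_low = 0, maf_high = 0.2), "frequency bounds")
  expect_error(sim_genotypes(4, 3, maf_low = 0.3, maf_high = 0.1), "frequency bounds")
  a <- sim_genotypes(30, 20, seed = 7)
  b <- sim_genotypes(30, 20, seed = 7)
  expect_identical(unclass(a), unclass(b))
  expect_false(identical(unclass(a), unclass(sim_genotypes(30, 20, seed = 8))))
})

test_that("dosages follow the binomial sampling distribution at fixed frequency", {
  g <- sim_genotypes(100, 50, maf_low = 0.5, maf_high = 0.5, seed = 1)
  expect_true(all(unclass(g) %in% 0:2))
  # mean dosage 2 * 0.5 = 1, binomial SE sqrt(2 * 0.25 / 100)
  se <- sqrt(2 * 0.25 / 100)
  expect_true(all(abs(colMeans(unclass(g)) - 1) < 3 * se))
})

test_that("trait simulation honours degenerate variance splits", {
  g <- sim_genotypes(50, 30, seed = 2)
  pure <- sim_phenotypes(g, trait_sim_spec(n_qtl_additive = 10, h2_additive = 1,
                                           h2_epistatic = 0, seed = 3))
  expect_equal(pure$y, pure$g)
  expect_equal(pure$realized_h2, 1)
  noise <- sim_phenotypes(g, trait_sim_spec(n_qtl_additive = 10,
                                            h2_additive = 0, h2_epistatic = 0,
                                            seed = 4))
  expect_true(all(noise$g == 0))
  expect_gt(stats::var(noise$y), 0)
  expect_error(trait_sim_spec(h2_additive = 0.7, h2_epistatic = 0.5), "exceed 1")
  expect_error(sim_phenotypes(g, trait_sim_spec(n_qtl_additive = 31, seed = 1)),
               "more additive QTL")
})

test_that("realized heritability tracks the target variance split", {
  g <- sim_genotypes(1000, 200, seed = 30)
  tr <- sim_phenotypes(g, trait_sim_spec(n_qtl_additive = 50, h2_additive = 0.5,
                                         seed = 3))
  expect_gt(tr$realized_h2, 0.42)
  expect_lt(tr$realized_h2, 0.58)
  # variance bookkeeping tightens with n, including an epistatic share
  g2 <- sim_genotypes(5000, 100, seed = 31)
  tr2 <- sim_phenotypes(g2, trait_sim_spec(n_qtl_additive = 40,
                                           n_pairs_epistatic = 40,
                                           h2_additive = 0.4,
                                           h2_epistatic = 0.2, seed = 32))
  expect_lt(abs(tr2$realized_h2 - 0.6), 0.03)
  expect_equal(tr2$realized_h2, stats::var(tr2$g) / stats::var(tr2$y))
})

test_that("fold-score pairs have the requested correlation structure", {
  expect_error(sim_fold_scores(2, 5, rho = 1.2), "rho")
  expect_error(sim_fold_scores(2, 5, rho = 0.5, sd_fold = 0), "sd_fold")

  same <- sim_fold_scores(2, 5, rho = 1, mean_a = 0.5, mean_b = 0.5, seed = 5)
  expect_equal(same$score_a, same$score_b)

  s <- sim_fold_scores(100, 100, rho = 0.8, mean_a = 0.5, mean_b = 0.5,
                       sd_fold = 1, seed = 6)
  expect_equal(nrow(s), 1e4)
  # Var(a - b) = 2 sigma^2 (1 - rho) = 0.4
  expect_lt(abs(stats::var(s$score_a - s$score_b) / 0.4 - 1), 0.05)
  expect_lt(abs(stats::cor(s$score_a, s$score_b) - 0.8), 0.02)

  expect_identical(sim_fold_scores(3, 4, rho = 0.3, seed = 9),
                   sim_fold_scores(3, 4, rho = 0.3, seed = 9))
})
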