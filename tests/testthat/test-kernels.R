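test_that("allele frequencies are half the mean dosage", {
  g <- geno_matrix(matrix(c(0, 0, 0, 0,
                            2, 2, 2, 2,
                            0, 1, 2, 1), nrow = 4))
  expect_equal(unname(allele_frequencies(g)), c(0, 1, 0.5))
})

test_that("the additive GRM matches the hand-computed centered cross-product", {
  g <- geno_matrix(matrix(c(0, 2), nrow = 2))
  G <- vanraden_grm(g)
  expect_equal(unname(G$matrix), matrix(c(2, -2, -2, 2), 2))

  # identical lines give a rank <= 1 constant matrix
  gi <- geno_matrix(matrix(rep(c(0, 1, 2, 1), each = 3), nrow = 3))
  Gi <- vanraden_grm(gi)
  expect_equal(max(Gi$matrix) - min(Gi$matrix), 0)

  mono <- geno_matrix(matrix(2, nrow = 3, ncol = 2))
  expect_error(vanraden_grm(mono), "monomorphic")
})

test_that("all kernel builders return symmetric PSD matrices", {
  g <- sim_genotypes(50, 200, seed = 41)
  G <- vanraden_grm(g)
  H <- egblup_grm(G)
  cats <- categorical_kernels(g)
  K <- gaussian_kernel(squared_distance(g), h = 2)
  for (k in list(G, H, cats$Cm, cats$Ce, K)) {
    expect_lt(max(abs(k$matrix - t(k$matrix))), 1e-12)
    expect_true(is_psd(k))
    expect_true(all(diag(k$matrix) > 0))
  }
  expect_true(all(cats$Cm$matrix >= 0 & cats$Cm$matrix <= 1))
  expect_true(all(cats$Ce$matrix >= 0 & cats$Ce$matrix <= 1))
  expect_true(all(K$matrix > 0 & K$matrix <= 1))
})

test_that("the epistatic kernel is the Hadamard square", {
  expect_equal(unname(egblup_grm(matrix(c(2, -2, -2, 2), 2))$matrix),
               matrix(4, 2, 2))
  expect_equal(unname(egblup_grm(diag(3))$matrix), diag(3))
  expect_error(egblup_grm(matrix(1, 2, 3)), "square")
})

test_that("categorical kernels count exact genotype matches", {
  # lines 1,2 identical; line 3 matches them at exactly half the markers
  g <- geno_matrix(matrix(c(0, 0, 2,
                            1, 1, 1,
                            2, 2, 0,
                            1, 1, 1), nrow = 3))
  cats <- categorical_kernels(g)
  expect_equal(unname(diag(cats$Cm$matrix)), rep(1, 3))
  expect_equal(unname(diag(cats$Ce$matrix)), rep(1, 3))
  expect_equal(cats$Cm$matrix[1, 2], 1)
  expect_equal(cats$Ce$matrix[1, 2], 1)
  expect_equal(cats$Cm$matrix[1, 3], 0.5)
  expect_equal(cats$Ce$matrix[1, 3], (0.25 + 0.5) / 2)
})

test_that("squared distances satisfy the cross-product identity", {
  g <- geno_matrix(rbind(rep(0, 5), rep(2, 5)))
  D <- squared_distance(g)
  expect_equal(unname(unclass(D)), matrix(c(0, 4, 4, 0), 2))

  gr <- sim_genotypes(30, 60, seed = 42)
  D2 <- unclass(squared_distance(gr))
  expect_true(all(diag(D2) == 0))
  G0 <- tcrossprod(unclass(gr)) / ncol(gr)
  ident <- outer(diag(G0), rep(1, 30)) + outer(rep(1, 30), diag(G0)) - 2 * G0
  expect_lt(max(abs(D2 - ident)), 1e-10)
})

test_that("the Gaussian kernel decays with distance and respects limits", {
  expect_error(gaussian_kernel(matrix(0, 2, 2), h = 0), "positive")
  D <- matrix(c(0, 4, 4, 0), 2)
  K <- gaussian_kernel(D, h = 4)
  expect_equal(unname(diag(K$matrix)), c(1, 1))
  expect_equal(K$matrix[1, 2], exp(-1))
  Kinf <- gaussian_kernel(D, h = 1e9)
  expect_lt(max(abs(Kinf$matrix - 1)), 1e-6)

  hs <- vapply(gaussian_kernel_list(squared_distance(fix_panel)),
               function(k) k$bandwidth, 0)
  expect_true(all(diff(hs) > 0))
})

test_that("rescaling a kernel leaves CV accuracies unchanged", {
  K5 <- gp_kernel(5 * fix_G$matrix, name = "G")
  plan <- make_fold_plan(60, k = 3, seed = 43)
  cv1 <- run_paired_cv(fix_trait$y, spec_kernel_model("a", fix_G), plan)
  cv2 <- run_paired_cv(fix_trait$y, spec_kernel_model("a", K5), plan)
  expect_equal(cv1$accuracy, cv2$accuracy, tolerance = 1e-6)
})
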