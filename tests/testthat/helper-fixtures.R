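# shared small fixtures, built once per test run

fix_panel <- sim_genotypes(60, 40, seed = 101)
fix_trait <- sim_phenotypes(fix_panel, trait_sim_spec(n_qtl_additive = 20,
                                                      h2_additive = 0.5,
                                                      seed = 102))
fix_G <- vanraden_grm(fix_panel)

# construct a paired_stat with an exact sample mean and sd (n points),
# so the t machinery lands on a prescribed interval
synthetic_paired_stat <- function(mean_d, sd_d, n = 30, a = "A", b = "B") {
  base <- stats::qnorm(seq_len(n) / (n + 1))
  d <- mean_d + sd_d * (base - mean(base)) / stats::sd(base)
  paired_stat(d, a, b, ci = "t")
}

# batch-means Monte-Carlo standard error of column means of a draws matrix
batch_means_se <- function(draws, n_batches = 40) {
  n <- nrow(draws)
  batch <- rep(seq_len(n_batches), each = ceiling(n / n_batches))[seq_len(n)]
  bm <- apply(draws, 2, function(x) tapply(x, batch, mean))
  apply(bm, 2, stats::sd) / sqrt(n_batches)
}
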