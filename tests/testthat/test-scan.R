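test_that("the 1D scan nails a noiseless causal locus and matches an lm oracle", {
  cfg <- sim_config(n_accessions = 50, n_snps = 8, n_subpops = 1,
                    divergence = 0, seed = 23)
  panel <- simulate_genotypes(cfg)
  coded <- code_genotypes(panel, recode_major = FALSE)
  # noiseless y = x_A: perfect fit, p at the numerical floor
  g <- coded$xA[, 2]
  ph <- toy_pheno(g)
  s <- scan_1d(coded, ph, 2)
  expect_gt(s$statistic, 1e6)
  expect_lt(s$p, 1e-12)

  # independent oracle: lm with environment blocks, joint (a, d) F-test
  arch <- trait_architecture(main = data.frame(locus = 2, a = 0.8, d = 0.3),
                             residual_sd = 1)
  ph2 <- simulate_phenotypes(panel, arch, n_envs = 3, n_reps = 2, seed = 3)
  s2 <- scan_1d(coded, ph2, 2)
  acc <- match(ph2$accession, rownames(panel$codes))
  df <- data.frame(y = ph2$value, env = factor(ph2$env),
                   xA = coded$xA[acc, 2], xD = coded$xD[acc, 2])
  f0 <- stats::lm(y ~ env, df)
  f1 <- stats::lm(y ~ env + xA + xD, df)
  an <- stats::anova(f0, f1)
  expect_equal(s2$statistic, an$F[2], tolerance = 1e-8)
  expect_equal(s2$p, an$`Pr(>F)`[2], tolerance = 1e-8)
  mono <- suppressWarnings(
    code_genotypes(toy_panel(cbind(rep(2, 50), rbinom(50, 2, 0.5))),
                   recode_major = FALSE))
  expect_error(scan_1d(mono, toy_pheno(stats::rnorm(50)), 1),
               "monomorphic")
})

test_that("1D scan holds its pointwise type-I error under the null", {
  set.seed(31)
  n <- 200; m <- 1000
  codes <- matrix(rbinom(n * m, 2, 0.4), nrow = n)
  panel <- toy_panel(codes, chrom = rep("chr1", m),
                     pos = seq(1e4, by = 1e4, length.out = m))
  coded <- code_genotypes(panel, recode_major = FALSE)
  ph <- toy_pheno(stats::rnorm(n), seed = 5)
  scan <- scan_genome_1d(coded, ph)
  rate <- mean(scan$p < 0.05)
  expect_lt(abs(rate - 0.05), 0.02)
  expect_true(all(scan$p > 0 & scan$p <= 1))
  expect_true(all(scan$neg_log10_p >= 0))
})

test_that("the 2D scan matches an lm oracle and holds its null level", {
  cfg <- sim_config(n_accessions = 200, n_snps = 40, n_subpops = 1,
                    divergence = 0, seed = 37, mean_gap_bp = 500000)
  panel <- simulate_genotypes(cfg)
  coded <- code_genotypes(panel, recode_major = FALSE)
  arch <- trait_architecture(main = data.frame(locus = c(5, 20),
                                               a = c(0.5, -0.4),
                                               d = c(0.2, 0.1)),
                             residual_sd = 1)
  ph <- simulate_phenotypes(panel, arch, n_envs = 2, n_reps = 2, seed = 7)
  s <- scan_2d(coded, ph, 5, 20)
  acc <- match(ph$accession, rownames(panel$codes))
  pc <- pair_columns(coded, 5, 20)
  df <- data.frame(y = ph$value, env = factor(ph$env),
                   a1 = coded$xA[acc, 5], d1 = coded$xD[acc, 5],
                   a2 = coded$xA[acc, 20], d2 = coded$xD[acc, 20],
                   pc[acc, , drop = FALSE])
  f0 <- stats::lm(y ~ env + a1 + d1 + a2 + d2, df)
  f1 <- stats::lm(y ~ env + a1 + d1 + a2 + d2 + aa + ad + da + dd, df)
  an <- stats::anova(f0, f1)
  expect_equal(s$statistic, an$F[2], tolerance = 1e-8)
  expect_equal(s$p, an$`Pr(>F)`[2], tolerance = 1e-8)

  # additive-only truth: epistasis rejections near the nominal level
  pvals <- vapply(1:150, function(i) {
    set.seed(100 + i)
    arch_i <- trait_architecture(main = data.frame(locus = 1, a = 0.5,
                                                   d = 0),
                                 residual_sd = 1)
    ph_i <- simulate_phenotypes(panel, arch_i, n_envs = 1, n_reps = 1,
                                seed = 200 + i)
    scan_2d(coded, ph_i, sample(2:40, 1), 1)$p
  }, 0)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.045)
})

test_that("planted epistasis is detected at the permutation threshold", {
  hits <- vapply(1:20, function(s) {
    cfg <- sim_config(n_accessions = 400, n_snps = 20, n_subpops = 1,
                      divergence = 0, seed = 400 + s, mean_gap_bp = 500000)
    panel <- simulate_genotypes(cfg)
    coded <- code_genotypes(panel, recode_major = FALSE)
    arch <- trait_architecture(
      epistasis = data.frame(locus_i = 4, locus_j = 12, aa = 0, ad = 0,
                             da = 0, dd = 2),
      residual_sd = 0.5)
    ph <- simulate_phenotypes(panel, arch, n_envs = 1, n_reps = 1,
                              seed = 500 + s)
    prs <- t(utils::combn(seq(2, 20, by = 2), 2))
    thr <- permutation_threshold(coded, ph, "2d", pairs = prs,
                                 n_perm = 150, seed = 600 + s)
    obs <- scan_2d(coded, ph, 4, 12)$statistic
    obs > thr$threshold
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("permutation thresholds dominate pointwise ones and are seeded", {
  cfg <- sim_config(n_accessions = 100, n_snps = 30, n_subpops = 1,
                    divergence = 0, seed = 43)
  panel <- simulate_genotypes(cfg)
  coded <- code_genotypes(panel, recode_major = FALSE)
  ph <- simulate_phenotypes(panel,
                            trait_architecture(mu = 1, residual_sd = 1),
                            n_envs = 2, n_reps = 2, seed = 9)
  poly <- which(apply(coded$xA, 2, stats::var) > 0)
  thr_family <- permutation_threshold(coded, ph, "1d", loci = poly,
                                      n_perm = 200, seed = 1)
  thr_single <- permutation_threshold(coded, ph, "1d", loci = poly[1],
                                      n_perm = 200, seed = 1)
  expect_gte(thr_family$threshold, thr_single$threshold)
  thr_again <- permutation_threshold(coded, ph, "1d", loci = poly,
                                     n_perm = 200, seed = 1)
  expect_identical(thr_family$threshold, thr_again$threshold)
  expect_identical(thr_family$max_stats, thr_again$max_stats)
  expect_error(permutation_threshold(coded, ph, "1d", loci = poly,
                                     n_perm = 50), "n_perm")
})
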