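test_that("genotype simulation is seeded, respects the design shape and the MAF floor", {
  cfg <- sim_config(n_accessions = 316, n_snps = 4000, n_chromosomes = 5,
                    n_envs = 3, seed = 11)
  panel <- simulate_genotypes(cfg)
  expect_equal(nrow(panel$codes), 316)
  expect_equal(ncol(panel$codes), 4000)
  expect_true(all(maf(panel) >= 0.01))
  expect_true(all(panel$codes %in% 0:2))
  # positions strictly increasing within chromosome
  for (ch in unique(panel$snps$chrom))
    expect_true(all(diff(panel$snps$pos[panel$snps$chrom == ch]) > 0))

  cfg_small <- sim_config(n_accessions = 40, n_snps = 50, n_subpops = 1,
                          divergence = 0, seed = 7)
  p1 <- simulate_genotypes(cfg_small)
  p2 <- simulate_genotypes(cfg_small)
  expect_identical(p1$codes, p2$codes)
  expect_identical(p1$snps, p2$snps)

  expect_error(sim_config(n_subpops = 3), "n_subpops")
  expect_error(sim_config(maf_min = 0.6), "maf_min")
})

test_that("subpopulation divergence matches the Hudson Fst estimator", {
  cfg <- sim_config(n_accessions = 2000, n_snps = 300, n_chromosomes = 3,
                    n_subpops = 2, divergence = 0.2, seed = 21,
                    mean_gap_bp = 500000)
  panel <- simulate_genotypes(cfg)
  sp <- panel$subpop
  # Hudson estimator, ratio of averages over SNPs (independent oracle)
  p1 <- colMeans(panel$codes[sp == 1, ]) / 2
  p2 <- colMeans(panel$codes[sp == 2, ]) / 2
  n1 <- 2 * sum(sp == 1); n2 <- 2 * sum(sp == 2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fst <- sum(num) / sum(den)
  expect_lt(abs(fst - 0.2), 0.05)
})

test_that("phenotypes follow the model exactly in degenerate settings", {
  codes <- matrix(c(2, 1, 0, 2, 0, 1), nrow = 3)
  panel <- toy_panel(codes)
  # all effects and sds zero -> phenotype is exactly mu
  arch0 <- trait_architecture(mu = 7)
  ph0 <- simulate_phenotypes(panel, arch0, n_envs = 2, n_reps = 2, seed = 1)
  expect_true(all(ph0$value == 7))
  # single additive QTS: coefficient coding x_A = 1, 0, -1
  arch1 <- trait_architecture(mu = 0,
                              main = data.frame(locus = 1, a = 1, d = 0))
  ph1 <- simulate_phenotypes(panel, arch1, n_envs = 1, n_reps = 1, seed = 1)
  expect_equal(ph1$value[match(paste0("acc", 1:3), ph1$accession)],
               c(1, 0, -1))
  # missing genotype at an architecture locus is an error
  panel_na <- panel; panel_na$codes[1, 1] <- NA
  expect_error(simulate_phenotypes(panel_na, arch1, 1, 1, 1), "missing")
})

test_that("regression on the coded design recovers planted effects to machine precision", {
  cfg <- sim_config(n_accessions = 200, n_snps = 30, n_chromosomes = 3,
                    n_subpops = 1, divergence = 0, seed = 31)
  panel <- simulate_genotypes(cfg)
  arch <- trait_architecture(
    mu = 3, main = data.frame(locus = c(4, 18), a = c(1.5, -0.7),
                              d = c(0.4, 0.9)),
    epistasis = data.frame(locus_i = 4, locus_j = 18,
                           aa = 0.8, ad = -0.3, da = 0.2, dd = 1.1))
  ph <- simulate_phenotypes(panel, arch, n_envs = 1, n_reps = 1, seed = 5)
  coded <- code_genotypes(panel, recode_major = FALSE)
  X <- cbind(coded$xA[, c(4, 18)], coded$xD[, c(4, 18)],
             pair_columns(coded, 4, 18))
  y <- ph$value[match(rownames(panel$codes), ph$accession)]
  b <- stats::coef(stats::lm(y ~ X))
  expect_equal(unname(b),
               c(3, 1.5, -0.7, 0.4, 0.9, 0.8, -0.3, 0.2, 1.1),
               tolerance = 1e-10)
})

test_that("empirical phenotypic variance matches the planted decomposition", {
  cfg <- sim_config(n_accessions = 5000, n_snps = 20, n_chromosomes = 4,
                    n_subpops = 1, divergence = 0, seed = 41)
  panel <- simulate_genotypes(cfg)
  arch <- trait_architecture(
    mu = 10, main = data.frame(locus = c(2, 12), a = c(1, 0.6),
                               d = c(0.5, 0)),
    residual_sd = 1)
  ph <- simulate_phenotypes(panel, arch, n_envs = 1, n_reps = 1, seed = 3)
  tt <- true_heritabilities(panel, arch)
  expect_lt(abs(stats::var(ph$value) - tt$V_P) / tt$V_P, 0.05)
  # ANOVA-style check: model SS fraction agrees with planted genetic h2
  coded <- code_genotypes(panel, recode_major = FALSE)
  y <- ph$value[match(rownames(panel$codes), ph$accession)]
  fit <- stats::lm(y ~ coded$xA[, 2] + coded$xD[, 2] + coded$xA[, 12])
  r2 <- summary(fit)$r.squared * 100
  expect_lt(abs(r2 - tt$h2_total), 2.5)
})

test_that("architecture-implied heritabilities match hand computation and are additive", {
  codes <- matrix(rep(c(2, 1, 0), times = c(79, 158, 79)), ncol = 1)
  panel <- toy_panel(codes)
  # Var(x_A) = 0.5 for counts (79, 158, 79); residual tuned so V_P = 10
  arch <- trait_architecture(main = data.frame(locus = 1, a = 1, d = 0),
                             residual_sd = sqrt(9.5))
  tt <- true_heritabilities(panel, arch)
  expect_equal(unname(tt$aggregates["A"]), 5, tolerance = 1e-10)
  expect_equal(tt$V_P, 10, tolerance = 1e-10)
  expect_equal(tt$h2_total, sum(tt$aggregates), tolerance = 1e-12)
  # zero-effect architecture
  tt0 <- true_heritabilities(panel, trait_architecture(residual_sd = 1))
  expect_true(all(tt0$aggregates == 0))
  expect_equal(tt0$h2_total, 0)
})

test_that("panel degradation hits its target rates and is seeded", {
  cfg <- sim_config(n_accessions = 200, n_snps = 500, n_subpops = 1,
                    divergence = 0, seed = 51)
  panel <- simulate_genotypes(cfg)
  expect_identical(degrade_panel(panel, 0, 0, seed = 1)$codes, panel$codes)
  d1 <- degrade_panel(panel, missing_rate = 0.3, seed = 2)
  expect_lt(abs(mean(is.na(d1$codes)) - 0.3), 0.01)
  d2 <- degrade_panel(panel, missing_rate = 0.3, seed = 2)
  expect_identical(d1$codes, d2$codes)
  # heterozygote inflation touches only homozygotes
  d3 <- degrade_panel(panel, het_inflation = 0.5, seed = 3)
  was_het <- panel$codes == 1L
  expect_true(all(d3$codes[was_het] == 1L))
  extra_het <- mean(d3$codes == 1L) - mean(was_het)
  expect_gt(extra_het, 0.3 * mean(panel$codes != 1L))
  expect_error(degrade_panel(panel, missing_rate = 1.2), "rates")
})
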