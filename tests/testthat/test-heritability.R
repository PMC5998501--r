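test_that("aggregation reproduces the protein partition and its epistatic share", {
  eff <- data.frame(
    class = c("a", "d", "aa", "ad", "da", "dd"),
    h2 = c(12.51, 15.74, 1.72, 21.18, 10.85, 31.43))
  rep_all <- aggregate_heritability(eff)
  expect_equal(rep_all$h2_total, 93.43, tolerance = 1e-9)
  epi <- aggregate_heritability(eff[eff$class %in% c("aa", "ad", "da",
                                                     "dd"), ])
  expect_equal(epi$h2_total, 65.18, tolerance = 1e-9)
  empty <- aggregate_heritability(data.frame(class = character(),
                                             h2 = numeric()))
  expect_true(all(empty$aggregates == 0))
  expect_equal(empty$h2_total, 0)
  expect_error(aggregate_heritability(data.frame(class = "bogus", h2 = 1)),
               "unknown")
})

test_that("per-effect heritability matches hand computation and recovers planted values", {
  # genotype counts (79, 158, 79): Var(x_A) = 0.5; a = 1, V_P = 10 -> 5%
  x <- rep(c(1, 0, -1), times = c(79, 158, 79))
  expect_equal(effect_heritability(1, x, 10), 5)
  expect_equal(effect_heritability(0, x, 10), 0)
  expect_error(effect_heritability(1, x, 0), "V_P")

  # planted h2_a = 20% at n = 2000, estimated effect via least squares
  set.seed(91)
  n <- 2000
  codes <- rbinom(n, 2, 0.5)
  xA <- codes - 1
  a_true <- 1
  v_res <- a_true^2 * stats::var(xA) * (1 / 0.2 - 1)
  y <- a_true * xA + stats::rnorm(n, 0, sqrt(v_res))
  a_hat <- stats::coef(stats::lm(y ~ xA))[2]
  h2_hat <- effect_heritability(a_hat, xA, stats::var(y))
  expect_lt(abs(h2_hat - 20), 3)
})

test_that("architecture heritabilities are invariant to affine trait rescaling", {
  cfg <- sim_config(n_accessions = 150, n_snps = 10, n_subpops = 1,
                    divergence = 0, seed = 97)
  panel <- simulate_genotypes(cfg)
  arch <- trait_architecture(mu = 4,
                             main = data.frame(locus = 3, a = 1, d = 0.4),
                             gxe_sds = c(ae = 0.5), residual_sd = 1)
  arch_scaled <- trait_architecture(mu = 4 * 3 + 7,
                                    main = data.frame(locus = 3, a = 3,
                                                      d = 1.2),
                                    gxe_sds = c(ae = 1.5), residual_sd = 3)
  t1 <- true_heritabilities(panel, arch)
  t2 <- true_heritabilities(panel, arch_scaled)
  expect_equal(t1$aggregates, t2$aggregates, tolerance = 1e-10)
  expect_equal(t1$h2_total, t2$h2_total, tolerance = 1e-10)
})

test_that("genotypic correlations reflect shared and disjoint genetic control", {
  set.seed(101)
  n <- 2000
  codes <- matrix(rbinom(4 * n, 2, 0.5), ncol = 4)
  panel <- toy_panel(codes)
  ids <- panel$snps$id
  m_a <- toy_model(effect_rows(list(class = "a", term = ids[1],
                                    estimate = 1),
                               list(class = "d", term = ids[1],
                                    estimate = 0.5)),
                   snps = panel$snps)
  # proportional effects: r_g exactly 1; negated: exactly -1
  m_b <- toy_model(effect_rows(list(class = "a", term = ids[1],
                                    estimate = 2),
                               list(class = "d", term = ids[1],
                                    estimate = 1)),
                   snps = panel$snps)
  m_c <- toy_model(effect_rows(list(class = "a", term = ids[1],
                                    estimate = -2),
                               list(class = "d", term = ids[1],
                                    estimate = -1)),
                   snps = panel$snps)
  expect_equal(genotypic_correlation(m_a, m_b, panel), 1)
  expect_equal(genotypic_correlation(m_a, m_c, panel), -1)
  # disjoint QTS sets on independent loci: near zero
  m_d <- toy_model(effect_rows(list(class = "a", term = ids[3],
                                    estimate = 1)),
                   snps = panel$snps)
  expect_lt(abs(genotypic_correlation(m_a, m_d, panel)), 0.1)
  # one pleiotropic QTS with opposite-sign additive effects: negative
  m_e <- toy_model(effect_rows(list(class = "a", term = ids[1],
                                    estimate = -1.5),
                               list(class = "a", term = ids[4],
                                    estimate = 0.2)),
                   snps = panel$snps)
  expect_lt(genotypic_correlation(m_a, m_e, panel), 0)
})

test_that("marginal and joint partitions agree for orthogonal effects", {
  # mid-frequency loci: E[x_A] ~ 0, so within-locus a-d covariance and
  # between-locus covariances vanish and the two conventions coincide
  set.seed(103)
  panel <- toy_panel(matrix(rbinom(400 * 4, 2, 0.5), ncol = 4),
                     chrom = paste0("chr", 1:4), pos = rep(1e5, 4))
  arch <- trait_architecture(main = data.frame(locus = c(2, 4),
                                               a = c(1, -0.8),
                                               d = c(0, 0)),
                             residual_sd = 1)
  ph <- simulate_phenotypes(panel, arch, n_envs = 1, n_reps = 1, seed = 4)
  m <- fit_qts_model(panel, ph, qts = c(2, 4), n_iter = 1500, burn_in = 300,
                     seed = 5, recode_major = FALSE, include_gxe = FALSE)
  h_marg <- heritability(m)
  h_joint <- heritability(m, method = "joint")
  # loci on distinct chromosomes: realized column correlation is O(n^-1/2),
  # so the two conventions differ only by small cross-covariance terms
  expect_lt(abs(h_marg$aggregates["A"] - h_joint$aggregates["A"]), 6)
  expect_lt(abs(h_marg$h2_total - h_joint$h2_total), 6)
  expect_lte(h_joint$h2_total, 100)
})
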