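make_qc_toy <- function() {
  # 10 accessions x 10 SNPs, exactly one violation of each rule:
  # SNP1 depth too high, SNP2+SNP3 adjacent (< 5 bp), SNP4 call rate 0.5,
  # SNP5 heterozygosity 0.4, SNP6 monomorphic (MAF 0), SNP7-10 clean
  clean <- rep(c(2, 0), times = c(6, 4))        # maf 0.4, het 0
  codes <- sapply(1:10, function(j) clean)
  codes[, 5] <- rep(c(1, 2), times = c(4, 6))   # het 0.4
  codes[, 6] <- rep(2, 10)                      # monomorphic
  codes[1:5, 4] <- NA                           # call rate 0.5
  pos <- c(100, 200, 203, 300, 400, 500, 600, 700, 800, 900)
  depth <- c(7000, rep(1000, 9))
  toy_panel(codes, pos = pos, depth = depth)
}

test_that("SNP filters remove exactly the hand-enumerated violators", {
  panel <- make_qc_toy()
  res <- apply_snp_filters(panel, qc_config())
  expect_equal(ncol(res$panel$codes), 4)
  expect_equal(res$panel$snps$pos, c(600, 700, 800, 900))
  rep_counts <- stats::setNames(res$report$n_removed, res$report$rule)
  expect_equal(unname(rep_counts[c("depth", "adjacent", "call_rate",
                                   "heterozygosity", "maf", "survivors")]),
               c(1, 2, 1, 1, 1, 4))
  # idempotence
  res2 <- apply_snp_filters(res$panel, qc_config())
  expect_identical(res2$panel$codes, res$panel$codes)
  expect_equal(sum(res2$report$n_removed[res2$report$rule != "survivors"]), 0)
})

test_that("a clean panel passes unchanged and bad configs are rejected", {
  clean <- toy_panel(sapply(1:5, function(j) rep(c(2, 0), c(6, 4))),
                     depth = rep(1000, 5))
  res <- apply_snp_filters(clean, qc_config())
  expect_identical(res$panel$codes, clean$codes)
  expect_equal(sum(res$report$n_removed[res$report$rule != "survivors"]), 0)
  # without depth metadata the depth rule is skipped with a warning
  no_depth <- toy_panel(sapply(1:5, function(j) rep(c(2, 0), c(6, 4))))
  expect_warning(apply_snp_filters(no_depth, qc_config()), "depth")
  expect_error(qc_config(call_rate_min = 0), "call_rate_min")
  expect_error(qc_config(maf_min = 0.7), "maf_min")
  expect_error(apply_snp_filters(subset_snps(clean, integer(0))), "empty")
})

test_that("pairwise r2 matches hand computation and is symmetric", {
  g1 <- c(0, 0, 1, 2); g2 <- c(0, 1, 1, 2)
  panel <- toy_panel(cbind(g1, g2, g1, 2 - g1))
  expect_equal(pairwise_r2(panel, 1, 3), 1)          # identical vectors
  expect_equal(pairwise_r2(panel, 1, 4), 1)          # g vs 2 - g
  # hand Pearson: r = cov / (sd1 sd2) computed from first principles
  m1 <- mean(g1); m2 <- mean(g2)
  r_hand <- sum((g1 - m1) * (g2 - m2)) /
    sqrt(sum((g1 - m1)^2) * sum((g2 - m2)^2))
  expect_equal(pairwise_r2(panel, 1, 2), r_hand^2)
  expect_equal(pairwise_r2(panel, 1, 2), pairwise_r2(panel, 2, 1))
  mono <- toy_panel(cbind(g1, rep(2, 4)))
  expect_error(pairwise_r2(mono, 1, 2), "variance")
})

test_that("LD pruning matches a brute-force implementation of the greedy rule", {
  cfg <- sim_config(n_accessions = 150, n_snps = 100, n_chromosomes = 2,
                    n_subpops = 1, divergence = 0, seed = 13,
                    ld_block_bp = 200000, mean_gap_bp = 20000)
  panel <- simulate_genotypes(cfg)
  pruned <- ld_prune(panel, window_snps = 50, r2_max = 0.1)
  # independent oracle: plain double loop per chromosome over retained set
  keep <- character(0)
  for (ch in unique(panel$snps$chrom)) {
    idx <- which(panel$snps$chrom == ch)
    retained <- integer(0)
    for (j in idx) {
      win <- retained[retained > length(retained) - 50]
      win <- utils::tail(retained, 50)
      ok <- TRUE
      for (k in win) {
        r2 <- stats::cor(panel$codes[, k], panel$codes[, j])^2
        if (!is.na(r2) && r2 > 0.1) { ok <- FALSE; break }
      }
      if (ok) retained <- c(retained, j)
    }
    keep <- c(keep, panel$snps$id[retained])
  }
  expect_identical(pruned$snps$id, keep)
  # no retained pair within the window exceeds the cap (direct assertion)
  for (ch in unique(pruned$snps$chrom)) {
    idx <- which(pruned$snps$chrom == ch)
    for (a in seq_along(idx))
      for (b in seq_len(min(a - 1, 50)))
        expect_lte(pairwise_r2(pruned, idx[a - b], idx[a]), 0.1)
  }
})

test_that("duplicate SNPs are pruned and independent SNPs are kept", {
  set.seed(3)
  g <- matrix(sample(0:2, 300, replace = TRUE), nrow = 30)
  panel <- toy_panel(cbind(g[, 1], g[, 1], g[, 2:10]),
                     pos = seq(1e5, by = 1e5, length.out = 11))
  pruned <- ld_prune(panel)
  expect_false(panel$snps$id[2] %in% pruned$snps$id)
  # mutually independent SNPs (all r2 far below the cap) pass unchanged
  set.seed(9)
  ind <- toy_panel(matrix(rbinom(500 * 8, 2, 0.5), nrow = 500))
  expect_identical(ld_prune(ind)$snps$id, ind$snps$id)
})

test_that("LD decay recovers the simulated half-decay scale", {
  cfg <- sim_config(n_accessions = 200, n_snps = 400, n_chromosomes = 1,
                    n_subpops = 1, divergence = 0, seed = 11,
                    ld_block_bp = 160000, mean_gap_bp = 10000)
  panel <- simulate_genotypes(cfg)
  ld <- ld_decay(panel, max_dist = 600000, bin_width = 10000)
  expect_true(all(ld$pairs$r2 >= 0 & ld$pairs$r2 <= 1))
  expect_true(all(is.finite(ld$curve$mean_r2)))
  expect_gt(ld$half_decay_bp, 160000 / 1.5)
  expect_lt(ld$half_decay_bp, 160000 * 1.5)
})

test_that("a free-recombination panel shows no decay structure", {
  set.seed(5)
  codes <- matrix(rbinom(100 * 80, 2, 0.4), nrow = 100)
  panel <- toy_panel(codes, pos = seq(5e3, by = 5e3, length.out = 80))
  ld <- ld_decay(panel, max_dist = 200000, bin_width = 20000)
  # curve flat at the sampling baseline: half-decay resolution-limited
  expect_lte(ld$half_decay_bp, ld$curve$mid[2])
  expect_lt(max(ld$curve$mean_r2), 0.1)
})
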