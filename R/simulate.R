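#' Simulation configuration for a synthetic germplasm panel
#'
#' Defaults emulate the study design the package targets: a panel of 316
#' tetraploid cotton accessions split into two subpopulations, biallelic
#' SNPs with MAF >= 0.01, linkage disequilibrium with an r-squared
#' half-decay distance around 160 kb, and phenotypes observed in 3
#' environments x 3 replicates.
#'
#' @param n_accessions number of accessions.
#' @param n_snps total number of SNPs (split near-evenly over chromosomes).
#' @param n_chromosomes number of chromosomes.
#' @param n_subpops 1 or 2 subpopulations.
#' @param divergence subpopulation allele-frequency divergence in \[0, 1):
#'   the Balding-Nichols F parameter, equal in expectation to the Hudson
#'   Fst between the two subpopulations.
#' @param maf_min minimum empirical minor allele frequency, in (0, 0.5).
#' @param ld_block_bp LD scale in bp: the distance at which mean pairwise
#'   r-squared halves.
#' @param mean_gap_bp mean physical spacing between adjacent SNPs.
#' @param n_envs,n_reps environments and replicates of the phenotyping
#'   design.
#' @param seed integer RNG seed; every simulation operation is fully
#'   reproducible given the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_accessions = 316, n_snps = 1000,
                       n_chromosomes = 5, n_subpops = 2, divergence = 0.1,
                       maf_min = 0.01, ld_block_bp = 160000,
                       mean_gap_bp = 10000, n_envs = 3, n_reps = 3,
                       seed = 1) {
  if (!n_subpops %in% c(1L, 2L)) stop("n_subpops must be 1 or 2")
  if (maf_min <= 0 || maf_min >= 0.5) stop("maf_min must be in (0, 0.5)")
  if (divergence < 0 || divergence >= 1) stop("divergence must be in [0, 1)")
  if (any(c(n_accessions, n_snps, n_chromosomes, n_envs, n_reps) < 1))
    stop("all counts must be >= 1")
  structure(list(n_accessions = n_accessions, n_snps = n_snps,
                 n_chromosomes = n_chromosomes, n_subpops = n_subpops,
                 divergence = divergence, maf_min = maf_min,
                 ld_block_bp = ld_block_bp, mean_gap_bp = mean_gap_bp,
                 n_envs = n_envs, n_reps = n_reps, seed = seed),
            class = "sim_config")
}

#' Simulate a genotype panel
#'
#' Haplotypes are generated by a Gaussian-copula autoregression along each
#' chromosome (latent correlation `exp(-d * log(2) / (2 * ld_block_bp))`
#' between sites `d` bp apart, so pairwise r-squared halves at
#' `ld_block_bp`) and thresholded at the subpopulation allele frequency,
#' giving Hardy-Weinberg genotypes within subpopulation. With two
#' subpopulations, per-SNP frequencies are drawn from the Balding-Nichols
#' beta distribution around a shared ancestral frequency. SNPs whose
#' empirical MAF falls below `maf_min` have the haplotypes nearest the
#' frequency threshold flipped, deterministically, until the floor holds.
#'
#' @param config a [sim_config()].
#' @return A [genotype_panel()] with subpopulation labels and random
#'   major/minor allele nucleotides.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  N <- config$n_accessions
  m <- config$n_snps
  n_hap <- 2L * N

  # chromosome assignment and positions
  chrom_sizes <- diff(round(seq(0, m, length.out = config$n_chromosomes + 1)))
  chrom <- rep(paste0("chr", seq_len(config$n_chromosomes)), chrom_sizes)
  pos <- unlist(lapply(chrom_sizes, function(mc) {
    cumsum(1L + stats::rgeom(mc, 1 / config$mean_gap_bp))
  }), use.names = FALSE)

  # subpopulations and per-SNP allele frequencies
  subpop <- rep(seq_len(config$n_subpops), length.out = N)
  p_anc <- stats::runif(m, 0.1, 0.9)
  freq <- matrix(p_anc, nrow = config$n_subpops, ncol = m, byrow = TRUE)
  if (config$n_subpops == 2L && config$divergence > 0) {
    Fst <- config$divergence
    shape <- (1 - Fst) / Fst
    for (s in 1:2)
      freq[s, ] <- stats::rbeta(m, p_anc * shape, (1 - p_anc) * shape)
    # keep frequencies away from fixation so the MAF floor stays mild
    freq <- pmin(pmax(freq, 0.02), 0.98)
  }

  # latent AR(1) field per chromosome, shared decay rate across haplotypes
  Z <- matrix(stats::rnorm(n_hap * m), nrow = n_hap, ncol = m)
  rate <- log(2) / (2 * config$ld_block_bp)
  start <- cumsum(c(1, chrom_sizes[-length(chrom_sizes)]))
  for (ci in seq_along(chrom_sizes)) {
    idx <- seq(start[ci], length.out = chrom_sizes[ci])
    if (length(idx) < 2) next
    rho <- exp(-diff(pos[idx]) * rate)
    for (k in 2:length(idx)) {
      j <- idx[k]
      Z[, j] <- rho[k - 1] * Z[, j - 1] + sqrt(1 - rho[k - 1]^2) * Z[, j]
    }
  }

  hap_subpop <- rep(subpop, each = 2L)
  thr <- stats::qnorm(t(freq)[, hap_subpop, drop = FALSE])  # m x n_hap
  alleles <- (t(Z) < thr) * 1L                              # m x n_hap, 1 = Q

  # deterministic MAF floor: flip haplotypes closest to their threshold
  c_min <- ceiling(config$maf_min * n_hap)
  for (j in seq_len(m)) {
    cnt_q <- sum(alleles[j, ])
    cnt <- min(cnt_q, n_hap - cnt_q)
    if (cnt >= c_min) next
    need <- c_min - cnt
    delta <- t(Z)[j, ] - thr[j, ]
    if (cnt_q <= n_hap - cnt_q) {   # Q allele is minor: flip nearest non-Q
      cand <- which(alleles[j, ] == 0L)
      flip <- cand[order(delta[cand])[seq_len(need)]]
      alleles[j, flip] <- 1L
    } else {                        # non-Q minor: flip nearest Q
      cand <- which(alleles[j, ] == 1L)
      flip <- cand[order(-delta[cand])[seq_len(need)]]
      alleles[j, flip] <- 0L
    }
  }

  codes <- t(alleles[, seq(1, n_hap, by = 2), drop = FALSE] +
               alleles[, seq(2, n_hap, by = 2), drop = FALSE])
  rownames(codes) <- paste0("acc", seq_len(N))

  nt <- c("A", "C", "G", "T")
  major <- sample(nt, m, replace = TRUE)
  minor <- vapply(major, function(a) sample(setdiff(nt, a), 1), "")

  genotype_panel(codes, chrom = chrom, pos = pos,
                 accessions = rownames(codes), major = major, minor = minor,
                 subpop = if (config$n_subpops > 1) subpop)
}

#' Trait architecture
#'
#' The genetic architecture that drives [simulate_phenotypes()]: population
#' mean, per-locus additive/dominance effects, digenic epistatic effects,
#' and the standard deviations of the random environment, gene-environment
#' interaction and residual components (all in trait units).
#'
#' @param mu population mean.
#' @param main `NULL` or data frame with columns `locus`, `a`, `d`.
#' @param epistasis `NULL` or data frame with columns `locus_i`, `locus_j`
#'   (`locus_i < locus_j`), `aa`, `ad`, `da`, `dd`.
#' @param env_sd standard deviation of the random environment main effect.
#' @param gxe_sds named vector giving per-class interaction standard
#'   deviations for classes `ae`, `de`, `aae`, `ade`, `dae`, `dde`
#'   (missing classes default to 0).
#' @param residual_sd residual standard deviation.
#' @return A list of class `trait_architecture`.
#' @export
trait_architecture <- function(mu = 0, main = NULL, epistasis = NULL,
                               env_sd = 0, gxe_sds = NULL, residual_sd = 0) {
  gxe <- c(ae = 0, de = 0, aae = 0, ade = 0, dae = 0, dde = 0)
  if (!is.null(gxe_sds)) {
    bad <- setdiff(names(gxe_sds), names(gxe))
    if (length(bad)) stop("unknown GxE class: ", paste(bad, collapse = ", "))
    gxe[names(gxe_sds)] <- gxe_sds
  }
  if (any(c(env_sd, gxe, residual_sd) < 0)) stop("all sds must be >= 0")
  if (!is.null(main)) {
    stopifnot(all(c("locus", "a", "d") %in% names(main)))
    if (anyDuplicated(main$locus))
      stop("a locus may appear in at most one main-effect entry")
  }
  if (!is.null(epistasis)) {
    stopifnot(all(c("locus_i", "locus_j", "aa", "ad", "da", "dd") %in%
                    names(epistasis)))
    if (any(epistasis$locus_i >= epistasis$locus_j))
      stop("epistasis requires locus_i < locus_j")
  }
  structure(list(mu = mu, main = main, epistasis = epistasis,
                 env_sd = env_sd, gxe_sds = gxe, residual_sd = residual_sd),
            class = "trait_architecture")
}

arch_loci <- function(arch) {
  unique(c(arch$main$locus, arch$epistasis$locus_i, arch$epistasis$locus_j))
}

# realized genetic values per accession (mu excluded); Q is the counted
# allele (x_A = code - 1), so planted signs are interpretable directly
arch_genetic_values <- function(panel, arch) {
  coded <- code_genotypes(panel, recode_major = FALSE)
  g <- numeric(nrow(panel$codes))
  if (!is.null(arch$main))
    for (r in seq_len(nrow(arch$main))) {
      i <- arch$main$locus[r]
      g <- g + arch$main$a[r] * coded$xA[, i] + arch$main$d[r] * coded$xD[, i]
    }
  if (!is.null(arch$epistasis))
    for (r in seq_len(nrow(arch$epistasis))) {
      pc <- pair_columns(coded, arch$epistasis$locus_i[r],
                         arch$epistasis$locus_j[r])
      g <- g + pc %*% c(arch$epistasis$aa[r], arch$epistasis$ad[r],
                        arch$epistasis$da[r], arch$epistasis$dd[r])
    }
  drop(g)
}

# coefficient columns for the GxE classes, as a list class -> matrix with
# one column per planted effect of that class
arch_gxe_columns <- function(panel, arch) {
  coded <- code_genotypes(panel, recode_major = FALSE)
  out <- list(ae = NULL, de = NULL, aae = NULL, ade = NULL,
              dae = NULL, dde = NULL)
  if (!is.null(arch$main)) {
    out$ae <- coded$xA[, arch$main$locus, drop = FALSE]
    out$de <- coded$xD[, arch$main$locus, drop = FALSE]
  }
  if (!is.null(arch$epistasis)) {
    pcs <- lapply(seq_len(nrow(arch$epistasis)), function(r)
      pair_columns(coded, arch$epistasis$locus_i[r],
                   arch$epistasis$locus_j[r]))
    for (cl in c("aa", "ad", "da", "dd"))
      out[[paste0(cl, "e")]] <-
        do.call(cbind, lapply(pcs, function(p) p[, cl]))
  }
  out
}

#' Simulate phenotypes from a trait architecture
#'
#' Generates observations under the full genetic model: the phenotype of
#' accession k in environment h is the sum of the population mean, the
#' fixed genetic value (main + epistatic effects with coefficient coding
#' x_A = 1/0/-1, x_D = 0/1/0 and their products), a random environment
#' effect e_h drawn once per environment, random gene-environment
#' interaction effects drawn once per (effect, environment) and multiplied
#' by the matching coefficients, and an observation-level residual.
#'
#' @param panel a [genotype_panel()] with no missing codes at architecture
#'   loci.
#' @param arch a [trait_architecture()].
#' @param n_envs,n_reps design dimensions.
#' @param seed integer RNG seed.
#' @param trait trait name recorded in the output table.
#' @return A [phenotype_table()].
#' @export
simulate_phenotypes <- function(panel, arch, n_envs = 3, n_reps = 3,
                                seed = 1, trait = "trait") {
  loci <- arch_loci(arch)
  if (length(loci) && anyNA(panel$codes[, loci]))
    stop("architecture references a locus with missing genotypes")
  N <- nrow(panel$codes)
  set.seed(seed)
  g <- arch_genetic_values(panel, arch)
  e_h <- stats::rnorm(n_envs, 0, arch$env_sd)
  gxe_cols <- arch_gxe_columns(panel, arch)
  gxe_kh <- matrix(0, nrow = N, ncol = n_envs)
  for (cl in names(gxe_cols)) {
    X <- gxe_cols[[cl]]
    if (is.null(X) || ncol(X) == 0 || arch$gxe_sds[[cl]] == 0) next
    u <- matrix(stats::rnorm(ncol(X) * n_envs, 0, arch$gxe_sds[[cl]]),
                nrow = ncol(X), ncol = n_envs)
    gxe_kh <- gxe_kh + X %*% u
  }
  acc <- rownames(panel$codes)
  grid <- expand.grid(rep = seq_len(n_reps), env = seq_len(n_envs),
                      k = seq_len(N))
  eps <- stats::rnorm(nrow(grid), 0, arch$residual_sd)
  y <- arch$mu + g[grid$k] + e_h[grid$env] +
    gxe_kh[cbind(grid$k, grid$env)] + eps
  phenotype_table(acc[grid$k], grid$env, grid$rep, trait, y)
}

#' Heritabilities implied by a trait architecture
#'
#' Computes, from the planted effects and the realized genotype
#' frequencies, the per-effect and per-class heritabilities that
#' [simulate_phenotypes()] data embody, using the same variance formulas as
#' [effect_heritability()]: a fixed effect of size b on coefficient column
#' x contributes `b^2 * var(x)`, and a GxE class with per-class standard
#' deviation s contributes `s^2 * mean(x^2)` per planted effect. The
#' phenotypic variance V_P is the sum of all components plus the residual
#' variance; the environment main effect is excluded throughout.
#'
#' @param panel,arch as in [simulate_phenotypes()].
#' @return A `heritability_report` (see [aggregate_heritability()]).
#' @export
true_heritabilities <- function(panel, arch) {
  loci <- arch_loci(arch)
  if (length(loci) && anyNA(panel$codes[, loci]))
    stop("architecture references a locus with missing genotypes")
  coded <- code_genotypes(panel, recode_major = FALSE)
  pvar <- function(x) mean((x - mean(x))^2)
  terms <- character(); classes <- character(); vars <- numeric()
  add_term <- function(term, cl, v) {
    terms <<- c(terms, term); classes <<- c(classes, cl)
    vars <<- c(vars, v)
  }
  ids <- coded$snps$id
  if (!is.null(arch$main))
    for (r in seq_len(nrow(arch$main))) {
      i <- arch$main$locus[r]
      add_term(ids[i], "a", arch$main$a[r]^2 * pvar(coded$xA[, i]))
      add_term(ids[i], "d", arch$main$d[r]^2 * pvar(coded$xD[, i]))
    }
  if (!is.null(arch$epistasis))
    for (r in seq_len(nrow(arch$epistasis))) {
      i <- arch$epistasis$locus_i[r]; j <- arch$epistasis$locus_j[r]
      pc <- pair_columns(coded, i, j)
      pair_id <- paste(ids[i], ids[j], sep = " & ")
      for (cl in c("aa", "ad", "da", "dd"))
        add_term(pair_id, cl, arch$epistasis[[cl]][r]^2 * pvar(pc[, cl]))
    }
  gxe_cols <- arch_gxe_columns(panel, arch)
  for (cl in names(gxe_cols)) {
    X <- gxe_cols[[cl]]
    if (is.null(X) || ncol(X) == 0) next
    s2 <- arch$gxe_sds[[cl]]^2
    labs <- if (cl %in% c("ae", "de")) ids[arch$main$locus] else
      paste(ids[arch$epistasis$locus_i], ids[arch$epistasis$locus_j],
            sep = " & ")
    for (q in seq_len(ncol(X)))
      add_term(labs[q], cl, s2 * mean(X[, q]^2))
  }
  V_P <- sum(vars) + arch$residual_sd^2
  eff <- data.frame(term = terms, class = classes,
                    h2 = if (length(vars)) 100 * vars / V_P else numeric(0),
                    stringsAsFactors = FALSE)
  heritability_report(eff, V_P = V_P)
}

#' Degrade a genotype panel
#'
#' Introduces missingness and inflated heterozygosity for testing quality
#' control: each entry is set missing with probability `missing_rate`, and
#' each remaining homozygote entry is converted to a heterozygote with
#' probability `het_inflation`.
#'
#' @param panel a [genotype_panel()].
#' @param missing_rate,het_inflation probabilities in \[0, 1\].
#' @param seed integer RNG seed.
#' @return A degraded [genotype_panel()].
#' @export
degrade_panel <- function(panel, missing_rate = 0, het_inflation = 0,
                          seed = 1) {
  if (missing_rate < 0 || missing_rate > 1 ||
      het_inflation < 0 || het_inflation > 1)
    stop("rates must be in [0, 1]")
  codes <- panel$codes
  set.seed(seed)
  if (missing_rate > 0)
    codes[stats::runif(length(codes)) < missing_rate] <- NA_integer_
  if (het_inflation > 0) {
    hom <- which(!is.na(codes) & codes != 1L)
    conv <- hom[stats::runif(length(hom)) < het_inflation]
    codes[conv] <- 1L
  }
  out <- panel
  out$codes <- codes
  out
}
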