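#' Bonferroni-adjusted per-test threshold
#'
#' @param alpha experiment-wise significance level in (0, 1).
#' @param m number of tests (>= 1).
#' @return The per-test threshold `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  alpha / m
}

#' Chi-square test of genotype frequencies between subpopulations
#'
#' Post-hoc stratification check at a detected QTS: Pearson chi-square on
#' the 2 x k table of genotype counts (QQ / Qq / qq) between two
#' subpopulations, with empty genotype columns dropped and the degrees of
#' freedom adjusted accordingly. No continuity correction is applied. An
#' allele-level 2 x 2 variant is available.
#'
#' @param panel a [genotype_panel()] with exactly two subpopulation labels
#'   (or labels passed via `subpop`).
#' @param snp SNP id or index.
#' @param subpop optional vector of subpopulation labels overriding the
#'   panel's.
#' @param level `"genotype"` (2 x 3 table) or `"allele"` (2 x 2 table of
#'   allele counts).
#' @param bonferroni_m when given, the result's `significant` flag uses
#'   the Bonferroni threshold `0.05 / bonferroni_m`.
#' @return A list of class `subpop_test`: `snp`, `table`, `statistic`,
#'   `df`, `p`, `significant`, `threshold`.
#' @export
subpop_genotype_chisq <- function(panel, snp, subpop = NULL,
                                  level = c("genotype", "allele"),
                                  bonferroni_m = NULL) {
  level <- match.arg(level)
  if (is.null(subpop)) subpop <- panel$subpop
  if (is.null(subpop)) stop("no subpopulation labels available")
  labs <- unique(subpop[!is.na(subpop)])
  if (length(labs) != 2) stop("exactly two subpopulations required")
  j <- if (is.character(snp)) match(snp, panel$snps$id) else snp
  g <- panel$codes[, j]
  ok <- !is.na(g) & !is.na(subpop)
  if (any(tapply(ok, subpop, sum) == 0))
    stop("a subpopulation has zero non-missing calls at this SNP")
  g <- g[ok]; sp <- subpop[ok]
  if (level == "genotype") {
    tab <- table(factor(sp, levels = labs),
                 factor(g, levels = c(2, 1, 0),
                        labels = c("QQ", "Qq", "qq")))
  } else {
    q_counts <- tapply(g, factor(sp, levels = labs), sum)
    n_counts <- tapply(rep(2, length(g)), factor(sp, levels = labs), sum)
    tab <- cbind(Q = q_counts, q = n_counts - q_counts)
  }
  tab <- tab[, colSums(tab) > 0, drop = FALSE]   # drop empty columns
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  if (df < 1) {
    stat <- 0; p <- 1
  } else {
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - expd)^2 / expd)
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
  }
  thr <- if (!is.null(bonferroni_m)) bonferroni_threshold(0.05, bonferroni_m)
  structure(list(snp = panel$snps$id[j], table = tab, statistic = stat,
                 df = df, p = p,
                 significant = if (!is.null(thr)) p < thr,
                 threshold = thr),
            class = "subpop_test")
}

#' @export
print.subpop_test <- function(x, ...) {
  cat(sprintf("Subpopulation genotype-frequency test at %s: X2 = %.3f on %d df, p = %.3g\n",
              x$snp, x$statistic, x$df, x$p))
  if (!is.null(x$significant))
    cat(sprintf("  %s at Bonferroni threshold %.3g\n",
                if (x$significant) "significant" else "not significant",
                x$threshold))
  invisible(x)
}

#' Run the stratification check over a set of SNPs
#'
#' @param panel a [genotype_panel()] with two subpopulations.
#' @param snps SNP ids or indices (default all).
#' @param bonferroni_m number of tests for the Bonferroni flag (defaults
#'   to the number of SNPs tested).
#' @param ... passed to [subpop_genotype_chisq()].
#' @return Data frame with one row per SNP: `snp`, `statistic`, `df`,
#'   `p`, `significant`.
#' @export
subpop_scan <- function(panel, snps = NULL, bonferroni_m = NULL, ...) {
  if (is.null(snps)) snps <- seq_len(ncol(panel$codes))
  if (is.null(bonferroni_m)) bonferroni_m <- length(snps)
  rows <- lapply(snps, function(s) {
    r <- subpop_genotype_chisq(panel, s, bonferroni_m = bonferroni_m, ...)
    data.frame(snp = r$snp, statistic = r$statistic, df = r$df, p = r$p,
               significant = r$significant, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
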