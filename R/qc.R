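#' SNP quality-control configuration
#'
#' Thresholds for [apply_snp_filters()]. A SNP is removed when its total
#' sequencing depth exceeds `depth_max` or falls below `depth_min` (only
#' when depth metadata is present), when it lies closer than
#' `min_adjacent_bp` to an adjacent SNP (both members of the offending
#' adjacency are removed), when its call rate is below `call_rate_min`,
#' when its heterozygote proportion exceeds `het_max`, or when its minor
#' allele frequency is below `maf_min`.
#'
#' @param depth_max,depth_min total-depth bounds in reads.
#' @param min_adjacent_bp minimum distance between adjacent SNPs in bp.
#' @param call_rate_min minimum call rate in (0, 1].
#' @param het_max maximum heterozygote proportion in (0, 1].
#' @param maf_min minimum minor allele frequency in (0, 0.5).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(depth_max = 6500, depth_min = 60, min_adjacent_bp = 5,
                      call_rate_min = 0.70, het_max = 0.30, maf_min = 0.01) {
  if (call_rate_min <= 0 || call_rate_min > 1)
    stop("call_rate_min must be in (0, 1]")
  if (het_max <= 0 || het_max > 1) stop("het_max must be in (0, 1]")
  if (maf_min <= 0 || maf_min >= 0.5) stop("maf_min must be in (0, 0.5)")
  structure(as.list(environment()), class = "qc_config")
}

#' Apply SNP quality-control filters
#'
#' Removes every SNP violating any rule of the [qc_config()] and reports
#' removal counts per rule. A SNP violating several rules counts under each
#' of them. The depth rule is applied only when the panel carries depth
#' metadata; otherwise it is skipped with a warning. Filtering is
#' idempotent.
#'
#' @param panel a nonempty [genotype_panel()].
#' @param qc a [qc_config()].
#' @return A list with `panel` (survivors) and `report` (data frame with
#'   columns `rule` and `n_removed`, final row `survivors`).
#' @export
apply_snp_filters <- function(panel, qc = qc_config()) {
  m <- ncol(panel$codes)
  if (m == 0) stop("empty panel")
  viol <- list()

  if (!is.null(panel$depth)) {
    viol$depth <- panel$depth > qc$depth_max | panel$depth < qc$depth_min
  } else {
    viol$depth <- rep(FALSE, m)
    warning("no depth metadata: depth rule skipped")
  }

  adj <- rep(FALSE, m)
  for (ch in unique(panel$snps$chrom)) {
    idx <- which(panel$snps$chrom == ch)
    if (length(idx) < 2) next
    close_pair <- diff(panel$snps$pos[idx]) < qc$min_adjacent_bp
    # both members of an offending adjacency are removed
    adj[idx[which(close_pair)]] <- TRUE
    adj[idx[which(close_pair) + 1L]] <- TRUE
  }
  viol$adjacent <- adj

  viol$call_rate <- colMeans(!is.na(panel$codes)) < qc$call_rate_min
  het <- colMeans(panel$codes == 1L, na.rm = TRUE)
  viol$heterozygosity <- !is.na(het) & het > qc$het_max
  mafs <- maf(panel)
  viol$maf <- is.na(mafs) | mafs < qc$maf_min

  drop <- Reduce(`|`, viol)
  report <- data.frame(
    rule = c(names(viol), "survivors"),
    n_removed = c(vapply(viol, sum, 0L), sum(!drop)),
    stringsAsFactors = FALSE
  )
  list(panel = subset_snps(panel, !drop), report = report)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of the 0/1/2 genotype code vectors of two
#' SNPs over pairwise-complete accessions.
#'
#' @param panel a [genotype_panel()].
#' @param i,j SNP indices or ids.
#' @return r-squared in \[0, 1\].
#' @export
pairwise_r2 <- function(panel, i, j) {
  if (is.character(i)) i <- match(i, panel$snps$id)
  if (is.character(j)) j <- match(j, panel$snps$id)
  gi <- panel$codes[, i]; gj <- panel$codes[, j]
  ok <- !is.na(gi) & !is.na(gj)
  if (sum(ok) < 2) stop("fewer than 2 pairwise-complete accessions")
  if (stats::var(gi[ok]) == 0 || stats::var(gj[ok]) == 0)
    stop("zero variance at one of the loci: r2 undefined")
  stats::cor(gi[ok], gj[ok])^2
}

#' LD pruning in a sliding SNP window
#'
#' Greedy left-to-right pass per chromosome: a SNP is dropped when its
#' r-squared with any retained SNP among the preceding `window_snps`
#' retained SNPs exceeds `r2_max`. Output order is preserved. Monomorphic
#' SNPs (undefined r-squared) are retained and do not constrain others.
#'
#' @param panel a [genotype_panel()], sorted by chromosome and position.
#' @param window_snps window size in retained SNPs (default 50).
#' @param r2_max maximum tolerated r-squared (default 0.1).
#' @return The pruned [genotype_panel()].
#' @export
ld_prune <- function(panel, window_snps = 50, r2_max = 0.1) {
  if (window_snps < 1) stop("window_snps must be >= 1")
  keep <- logical(ncol(panel$codes))
  for (ch in unique(panel$snps$chrom)) {
    idx <- which(panel$snps$chrom == ch)
    retained <- integer(0)
    for (j in idx) {
      window <- utils::tail(retained, window_snps)
      drop_j <- FALSE
      for (k in window) {
        r2 <- tryCatch(pairwise_r2(panel, k, j), error = function(e) NA)
        if (!is.na(r2) && r2 > r2_max) { drop_j <- TRUE; break }
      }
      if (!drop_j) retained <- c(retained, j)
    }
    keep[retained] <- TRUE
  }
  subset_snps(panel, keep)
}

#' LD decay curve and half-decay distance
#'
#' Bins intra-chromosomal pairwise r-squared by physical distance and
#' reports the mean per bin. The half-decay distance is the smallest bin
#' midpoint at which the binned mean r-squared falls to half the maximum
#' binned mean; when the curve never falls that far (no LD structure at
#' the sampled resolution) the first bin midpoint is returned.
#'
#' @param panel a [genotype_panel()] with >= 2 SNPs on some chromosome.
#' @param max_dist maximum pair distance in bp.
#' @param bin_width distance bin width in bp (default 5000).
#' @return A list of class `ld_result`: `pairs` (data frame `snp_i`,
#'   `snp_j`, `distance`, `r2`), `curve` (data frame `bin_start`,
#'   `bin_end`, `mid`, `mean_r2`, `n_pairs`) and `half_decay_bp`.
#' @export
ld_decay <- function(panel, max_dist = 500000, bin_width = 5000) {
  recs <- list()
  for (ch in unique(panel$snps$chrom)) {
    idx <- which(panel$snps$chrom == ch)
    if (length(idx) < 2) next
    p <- panel$snps$pos[idx]
    for (a in seq_len(length(idx) - 1)) {
      b <- which(p > p[a] & p - p[a] <= max_dist)
      b <- b[b > a]
      if (!length(b)) next
      r2 <- vapply(idx[b], function(j)
        tryCatch(pairwise_r2(panel, idx[a], j), error = function(e) NA_real_),
        0)
      recs[[length(recs) + 1L]] <- data.frame(
        snp_i = panel$snps$id[idx[a]], snp_j = panel$snps$id[idx[b]],
        distance = p[b] - p[a], r2 = r2, stringsAsFactors = FALSE)
    }
  }
  if (!length(recs)) stop("no intra-chromosomal pairs within max_dist")
  pairs <- do.call(rbind, recs)
  pairs <- pairs[!is.na(pairs$r2), ]
  bin <- pmin(floor(pairs$distance / bin_width), ceiling(max_dist / bin_width) - 1)
  agg <- stats::aggregate(pairs$r2, by = list(bin = bin),
                          FUN = function(v) c(mean(v), length(v)))
  curve <- data.frame(bin_start = agg$bin * bin_width,
                      bin_end = (agg$bin + 1) * bin_width,
                      mid = (agg$bin + 0.5) * bin_width,
                      mean_r2 = agg$x[, 1], n_pairs = agg$x[, 2])
  half <- max(curve$mean_r2) / 2
  below <- which(curve$mean_r2 <= half)
  half_decay_bp <- if (length(below)) curve$mid[min(below)] else curve$mid[1]
  structure(list(pairs = pairs, curve = curve, half_decay_bp = half_decay_bp),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat("LD decay over", nrow(x$pairs), "pairs in", nrow(x$curve),
      "bins; half-decay at", x$half_decay_bp, "bp\n")
  invisible(x)
}

#' Write QC and LD summaries as TSV
#'
#' @param report the filter report from [apply_snp_filters()].
#' @param ld an `ld_result` from [ld_decay()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_filter_report_tsv <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_filter_report_tsv
#' @export
write_ld_curve_tsv <- function(ld, path) {
  utils::write.table(ld$curve[, c("bin_start", "bin_end", "mean_r2",
                                  "n_pairs")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
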