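#' GMDR screening configuration
#'
#' @param max_order highest interaction order scanned (1, 2 or 3).
#' @param cv_folds cross-validation folds (>= 2).
#' @param top_k number of SNPs retained per strategy.
#' @param beam_width number of top marginal SNPs seeding higher-order
#'   combinations on large panels; panels with at most `beam_width` SNPs
#'   are scanned exhaustively.
#' @param seed integer RNG seed for fold assignment.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(max_order = 3, cv_folds = 10, top_k = 1000,
                          beam_width = 25, seed = 1) {
  if (!max_order %in% 1:3) stop("max_order must be 1, 2 or 3")
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  if (top_k < 1) stop("top_k must be >= 1")
  structure(as.list(environment()), class = "screen_config")
}

#' GMDR per-observation scores
#'
#' For a quantitative trait the GMDR score is the residual of the
#' phenotype under the null model: the grand mean, or environment-
#' stratified means when the environment covariate is included. Scores
#' sum to zero (exactly zero within each environment when stratified).
#'
#' @param pheno a [phenotype_table()] restricted to one trait.
#' @param include_env_covariate include the environment as a covariate.
#' @return Numeric score vector aligned with the rows of `pheno`.
#' @export
gmdr_scores <- function(pheno, include_env_covariate = FALSE) {
  if (nrow(pheno) < 2) stop("need >= 2 observations")
  if (length(unique(pheno$trait)) > 1)
    stop("scores are computed per trait; filter the table first")
  y <- pheno$value
  if (stats::var(y) == 0) warning("all-identical phenotypes: zero-variance trait")
  if (include_env_covariate) {
    y - stats::ave(y, pheno$env)
  } else {
    y - mean(y)
  }
}

#' Evaluate a multilocus genotype combination by cross-validation
#'
#' Accessions are binned into multilocus genotype cells; a cell is labeled
#' high-risk when its mean training score exceeds 0, else low-risk (empty
#' training cells default to low). The testing statistic is the balanced
#' accuracy of sign(score) against the cell label on held-out folds,
#' averaged over folds; cross-validation consistency counts folds with
#' testing accuracy above chance (0.5).
#'
#' @param panel a [genotype_panel()].
#' @param scores per-observation scores from [gmdr_scores()].
#' @param pheno the matching [phenotype_table()] (supplies the
#'   accession of each observation).
#' @param loci distinct SNP indices or ids, at most the scan order.
#' @param cv_folds number of folds.
#' @param seed integer RNG seed for the fold split.
#' @return A list with `statistic` (mean balanced testing accuracy),
#'   `fold_stats` and `consistency`.
#' @export
gmdr_evaluate <- function(panel, scores, pheno, loci, cv_folds = 10,
                          seed = 1) {
  loci <- vapply(loci, function(l)
    if (is.character(l)) match(l, panel$snps$id) else as.integer(l), 0L)
  if (anyDuplicated(loci)) stop("loci must be distinct")
  acc_of_obs <- match(pheno$accession, rownames(panel$codes))
  geno <- panel$codes[, loci, drop = FALSE]
  cell_of_acc <- apply(geno, 1, paste, collapse = "/")
  cell <- cell_of_acc[acc_of_obs]

  set.seed(seed)
  n_acc <- nrow(panel$codes)
  fold_of_acc <- sample(rep(seq_len(cv_folds), length.out = n_acc))
  fold <- fold_of_acc[acc_of_obs]

  fold_stats <- vapply(seq_len(cv_folds), function(f) {
    tr <- fold != f; te <- !tr
    if (!any(te) || !any(tr)) return(NA_real_)
    cm <- tapply(scores[tr], cell[tr], mean)
    high_cells <- names(cm)[cm > 0]          # empty cells default to low
    pred_high <- cell[te] %in% high_cells
    truth_high <- scores[te] > 0
    sens <- if (any(truth_high)) mean(pred_high[truth_high]) else NA
    spec <- if (any(!truth_high)) mean(!pred_high[!truth_high]) else NA
    mean(c(sens, spec), na.rm = TRUE)
  }, 0)
  stat <- mean(fold_stats, na.rm = TRUE)
  if (is.nan(stat)) stat <- 0.5
  list(statistic = stat, fold_stats = fold_stats,
       consistency = sum(fold_stats > 0.5, na.rm = TRUE))
}

#' GMDR prescreening of candidate SNPs
#'
#' Stage-one filter for the association pipeline: evaluates genotype
#' combinations up to `max_order` (exhaustively when the panel has at most
#' `beam_width` SNPs, otherwise seeding higher orders with the top
#' marginal SNPs), ranks SNPs by support (membership in the
#' best-scoring combinations, ties broken by best statistic), and retains
#' `top_k` per strategy. With `strategy = "both"` (the default) the screen
#' is run once ignoring the environment and once including it as a
#' covariate, and the union of the two retained sets is returned.
#'
#' @param panel a QC'd [genotype_panel()].
#' @param pheno a [phenotype_table()] for one trait.
#' @param config a [screen_config()].
#' @param strategy `"both"`, `"no_env"` or `"env_covariate"`.
#' @return A list of class `candidate_set`: `trait`, `snps` (data frame
#'   `snp_id`, `support`, `best_statistic`, `strategy`), `retained`
#'   (character vector, union over strategies).
#' @export
gmdr_screen <- function(panel, pheno, config = screen_config(),
                        strategy = c("both", "no_env", "env_covariate")) {
  strategy <- match.arg(strategy)
  trait <- unique(pheno$trait)
  if (length(trait) != 1) stop("one trait at a time")
  m <- ncol(panel$codes)
  if (config$top_k > m)
    warning("top_k exceeds SNP count; retaining all SNPs")

  run_one <- function(include_env) {
    scores <- gmdr_scores(pheno, include_env)
    marg <- vapply(seq_len(m), function(j)
      gmdr_evaluate(panel, scores, pheno, j, config$cv_folds,
                    config$seed)$statistic, 0)
    combos <- as.list(seq_len(m))
    stats_all <- marg
    if (config$max_order >= 2) {
      seed_snps <- if (m <= config$beam_width) seq_len(m) else
        order(marg, decreasing = TRUE)[seq_len(config$beam_width)]
      for (ord in 2:config$max_order) {
        sets <- utils::combn(sort(seed_snps), ord, simplify = FALSE)
        st <- vapply(sets, function(s)
          gmdr_evaluate(panel, scores, pheno, s, config$cv_folds,
                        config$seed)$statistic, 0)
        combos <- c(combos, sets)
        stats_all <- c(stats_all, st)
      }
    }
    # support: membership count among the best-scoring combinations
    n_best <- min(length(combos), max(config$top_k, 20L))
    best <- order(stats_all, decreasing = TRUE)[seq_len(n_best)]
    support <- tabulate(unlist(combos[best]), nbins = m)
    best_stat <- vapply(seq_len(m), function(j)
      max(stats_all[vapply(combos, function(s) j %in% s, TRUE)]), 0)
    rank <- order(-support, -best_stat, seq_len(m))
    retained <- rank[seq_len(min(config$top_k, m))]
    data.frame(snp_id = panel$snps$id[retained],
               support = support[retained],
               best_statistic = best_stat[retained],
               strategy = if (include_env) "env_covariate" else "no_env",
               stringsAsFactors = FALSE)
  }

  runs <- switch(strategy,
                 both = list(run_one(FALSE), run_one(TRUE)),
                 no_env = list(run_one(FALSE)),
                 env_covariate = list(run_one(TRUE)))
  snps <- do.call(rbind, runs)
  structure(list(trait = trait, snps = snps,
                 retained = unique(snps$snp_id)),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("GMDR candidate set for trait", x$trait, "-", length(x$retained),
      "SNPs retained over", length(unique(x$snps$strategy)), "strategy(ies)\n")
  invisible(x)
}

#' Write a candidate set as TSV
#'
#' @param cs a `candidate_set` from [gmdr_screen()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_candidate_set_tsv <- function(cs, path) {
  out <- cbind(trait = cs$trait, cs$snps)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
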