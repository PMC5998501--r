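#' Per-effect table of a fitted QTS model
#'
#' Flattens a [fit_qts_model()] fit into the field's customary effect
#' table: one row per significant-effect entry with the QTS (or QTS pair),
#' chromosome, major/minor alleles, effect type (a, d, aa, ad, da, dd and
#' the per-environment interaction types ae1, de2, aae3, ...), predicted
#' effect, -log10 p and percent heritability.
#'
#' @param model a `qts_model`.
#' @param min_neg_log10_p keep only effects with -log10 p above this
#'   value (fixed effects; interaction rows are kept when their class
#'   variance contributes nonzero heritability). Default `NULL` keeps all.
#' @return Data frame with columns `trait`, `qts`, `chrom`, `alleles`,
#'   `effect_type`, `effect`, `neg_log10_p`, `h2`.
#' @export
effect_table <- function(model, min_neg_log10_p = NULL) {
  h2 <- heritability(model)
  ct <- model$coef_table
  gen <- ct[ct$class != "mu", , drop = FALSE]
  ann <- function(term) {
    parts <- strsplit(term, " & ", fixed = TRUE)[[1]]
    rows <- match(parts, model$snps$id)
    list(chrom = paste(model$snps$chrom[rows], collapse = " & "),
         alleles = paste(paste0(model$snps$major[rows], "/",
                                model$snps$minor[rows]), collapse = " & "))
  }
  fixed_rows <- lapply(seq_len(nrow(gen)), function(r) {
    a <- ann(gen$term[r])
    data.frame(trait = model$trait, qts = gen$term[r], chrom = a$chrom,
               alleles = a$alleles, effect_type = gen$class[r],
               effect = gen$estimate[r], neg_log10_p = gen$neg_log10_p[r],
               h2 = h2$effects$h2[match(paste0(gen$class[r], gen$term[r]),
                                        paste0(h2$effects$class,
                                               h2$effects$term))],
               stringsAsFactors = FALSE)
  })
  ge <- model$gxe_effects
  gxe_rows <- lapply(seq_len(nrow(ge)), function(r) {
    a <- ann(ge$term[r])
    data.frame(trait = model$trait, qts = ge$term[r], chrom = a$chrom,
               alleles = a$alleles,
               effect_type = paste0(ge$class[r], ge$env[r]),
               effect = ge$estimate[r], neg_log10_p = NA_real_,
               h2 = NA_real_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(fixed_rows, gxe_rows))
  if (is.null(out))
    out <- data.frame(trait = character(), qts = character(),
                      chrom = character(), alleles = character(),
                      effect_type = character(), effect = numeric(),
                      neg_log10_p = numeric(), h2 = numeric())
  if (!is.null(min_neg_log10_p))
    out <- out[is.na(out$neg_log10_p) |
                 out$neg_log10_p > min_neg_log10_p, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' QTS network edge list
#'
#' Builds the node/edge structure of the QTS interaction network from a
#' per-effect table (a fitted model's [effect_table()] or an equivalent
#' data frame): nodes are QTSs flagged by the effect classes they express,
#' edges are epistatic pairs annotated with their epistasis classes and
#' whether an epistasis-by-environment interaction is present.
#'
#' @param effects data frame with columns `qts` (pair rows contain
#'   `" & "`) and `effect_type`.
#' @return A list of class `qts_network` with data frames `nodes` (`id`,
#'   `additive`, `dominance`, `gxe`) and `edges` (`qts_i`, `qts_j`,
#'   `classes`, `gxe`).
#' @export
qts_network <- function(effects) {
  is_pair <- grepl(" & ", effects$qts, fixed = TRUE)
  singles <- effects[!is_pair, , drop = FALSE]
  pairs <- effects[is_pair, , drop = FALSE]
  node_ids <- unique(c(singles$qts,
                       unlist(strsplit(pairs$qts, " & ", fixed = TRUE))))
  nodes <- data.frame(
    id = node_ids,
    additive = vapply(node_ids, function(id)
      any(singles$qts == id & grepl("^a", singles$effect_type)), TRUE),
    dominance = vapply(node_ids, function(id)
      any(singles$qts == id & grepl("^d", singles$effect_type)), TRUE),
    gxe = vapply(node_ids, function(id)
      any(singles$qts == id & grepl("e[0-9]*$", singles$effect_type)), TRUE),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (nrow(pairs)) {
    sp <- split(pairs, pairs$qts)
    edges <- do.call(rbind, lapply(sp, function(df) {
      members <- strsplit(df$qts[1], " & ", fixed = TRUE)[[1]]
      data.frame(qts_i = members[1], qts_j = members[2],
                 classes = paste(sort(unique(df$effect_type)),
                                 collapse = ","),
                 gxe = any(grepl("e[0-9]+$", df$effect_type)),
                 stringsAsFactors = FALSE)
    }))
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(qts_i = character(), qts_j = character(),
                        classes = character(), gxe = logical())
  }
  structure(list(nodes = nodes, edges = edges), class = "qts_network")
}

#' @export
print.qts_network <- function(x, ...) {
  cat("QTS network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Write model reports
#'
#' Emits the standard report files for a fitted model: the per-effect
#' table, the heritability partition, the superior-genotype designs and
#' the QTS network edge list (TSV and JSON).
#'
#' @param model a `qts_model`.
#' @param out_dir output directory (created if absent).
#' @param designs optional named list of `design_result` objects.
#' @return Named character vector of the files written, invisibly.
#' @export
write_reports <- function(model, out_dir, designs = NULL) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  eff <- effect_table(model)
  files <- c(effects = file.path(out_dir, "effects.tsv"),
             heritability = file.path(out_dir, "heritability.tsv"),
             edges = file.path(out_dir, "network_edges.tsv"),
             network = file.path(out_dir, "network.json"))
  utils::write.table(eff, files["effects"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_heritability_tsv(heritability(model), files["heritability"])
  net <- qts_network(eff)
  utils::write.table(net$edges, files["edges"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(nodes = net$nodes, edges = net$edges),
                       files["network"], auto_unbox = TRUE, digits = NA)
  if (!is.null(designs)) {
    files <- c(files, designs = file.path(out_dir, "designs.tsv"))
    write_design_tsv(designs, files["designs"], trait = model$trait)
  }
  invisible(files)
}

#' Run the full association pipeline
#'
#' Orchestrates the stages end to end for one trait: SNP quality control,
#' optional GMDR prescreening, the 1D genome scan with its permutation
#' threshold, the 2D scan over candidate pairs with its permutation
#' threshold, the full-model Gibbs fit on the significant QTSs and pairs,
#' the heritability partition, and superior-genotype design. Every stage's
#' seed derives from the global seed; rerunning with the same inputs and
#' seed reproduces all outputs exactly.
#'
#' @param panel a [genotype_panel()] or a path to a panel TSV.
#' @param pheno a [phenotype_table()] or a path to a phenotype TSV.
#' @param qc a [qc_config()], or `NULL` to skip filtering.
#' @param screen a [screen_config()], or `NULL` to skip GMDR prescreening.
#' @param n_perm,alpha permutation-threshold settings.
#' @param n_iter,burn_in Gibbs sampler settings.
#' @param max_pair_candidates the 2D scan enumerates pairs among at least
#'   this many top-ranked 1D loci (all significant loci always included).
#' @param thin_r2 significant loci in LD above this r-squared with a
#'   stronger hit are collapsed onto the peak locus before the 2D scan
#'   and the full-model fit.
#' @param design_objective `"max"`, `"min"`, or `NULL` to skip designs.
#' @param seed global integer seed.
#' @param out_dir when given, reports are written there.
#' @return A list of class `qts_pipeline` with all stage outputs and a
#'   `manifest` recording inputs, seeds and stage summaries.
#' @export
run_qts_pipeline <- function(panel, pheno, qc = qc_config(), screen = NULL,
                             n_perm = 1000, alpha = 0.05, n_iter = 20000,
                             burn_in = 2000, max_pair_candidates = 15,
                             thin_r2 = 0.5,
                             design_objective = "max", seed = 1,
                             out_dir = NULL) {
  if (is.character(panel)) {
    if (!file.exists(panel)) stop("genotype file not found: ", panel)
    panel <- read_panel_tsv(panel)
  }
  if (is.character(pheno)) {
    if (!file.exists(pheno)) stop("phenotype file not found: ", pheno)
    pheno <- read_phenotypes_tsv(pheno)
  }
  trait <- unique(pheno$trait)
  if (length(trait) != 1) stop("one trait at a time; filter the table")
  manifest <- list(seed = seed, trait = trait,
                   n_accessions = nrow(panel$codes),
                   n_snps_input = ncol(panel$codes))

  # stage: QC
  if (!is.null(qc)) {
    qcres <- apply_snp_filters(panel, qc)
    panel <- qcres$panel
    manifest$qc <- qcres$report
  }
  manifest$n_snps_qc <- ncol(panel$codes)

  # stage: GMDR prescreen
  candidates <- panel$snps$id
  screen_result <- NULL
  if (!is.null(screen)) {
    screen$seed <- seed + 1L
    screen_result <- gmdr_screen(panel, pheno, screen)
    candidates <- screen_result$retained
    manifest$n_snps_screened <- length(candidates)
  }

  coded <- code_genotypes(panel)
  cand_idx <- match(candidates, coded$snps$id)
  poly <- cand_idx[apply(coded$xA[, cand_idx, drop = FALSE], 2,
                         function(v) stats::var(v, na.rm = TRUE) > 0)]

  # stage: 1D scan + threshold
  scan1 <- scan_genome_1d(coded, pheno, loci = poly)
  thr1 <- permutation_threshold(coded, pheno, family = "1d", loci = poly,
                                n_perm = n_perm, alpha = alpha,
                                seed = seed + 2L)
  sig1 <- scan1$locus[scan1$statistic > thr1$threshold]
  manifest$threshold_1d <- thr1$threshold
  manifest$n_significant_1d <- length(sig1)

  # thin correlated hits: keep the strongest locus per LD cluster so the
  # full model carries one representative QTS per association peak
  if (length(sig1) > 1) {
    ord <- sig1[order(-scan1$statistic[match(sig1, scan1$locus)])]
    kept <- character(0)
    for (l in ord) {
      r2 <- vapply(kept, function(k)
        tryCatch(pairwise_r2(panel, k, l), error = function(e) 0), 0)
      if (!length(r2) || max(r2) <= thin_r2) kept <- c(kept, l)
    }
    sig1 <- kept
  }
  manifest$n_significant_thinned <- length(sig1)

  # stage: 2D scan + threshold over pairs of top candidates (LD-thinned)
  top <- scan1$locus[order(-scan1$statistic)]
  pool <- sig1
  for (l in top) {
    if (length(pool) >= max(length(sig1), max_pair_candidates)) break
    if (l %in% pool) next
    r2 <- vapply(pool, function(k)
      tryCatch(pairwise_r2(panel, k, l), error = function(e) 0), 0)
    if (!length(r2) || max(r2) <= thin_r2) pool <- c(pool, l)
  }
  sig_pairs <- NULL
  scan2 <- NULL
  if (length(pool) >= 2) {
    prs <- t(utils::combn(pool, 2))
    scan2 <- scan_genome_2d(coded, pheno, prs)
    thr2 <- permutation_threshold(coded, pheno, family = "2d", pairs = prs,
                                  n_perm = n_perm, alpha = alpha,
                                  seed = seed + 3L)
    keep <- !is.na(scan2$statistic) & scan2$statistic > thr2$threshold
    if (any(keep)) {
      parts <- strsplit(scan2$locus[keep], " & ", fixed = TRUE)
      sig_pairs <- do.call(rbind, parts)
    }
    manifest$threshold_2d <- thr2$threshold
    manifest$n_significant_2d <- sum(keep)
  }

  # stage: full-model fit
  model <- fit_qts_model(coded, pheno, qts = sig1, pairs = sig_pairs,
                         n_iter = n_iter, burn_in = burn_in,
                         seed = seed + 4L)
  herit <- heritability(model)

  # stage: design
  designs <- NULL
  if (!is.null(design_objective) &&
      any(model$coef_table$class != "mu")) {
    designs <- list(
      GSL = design_superior(model, design_target("GSL", design_objective)),
      GSH = design_superior(model, design_target("GSH", design_objective)))
    if (model$n_env >= 2 && nrow(model$gxe_effects))
      for (h in seq_len(model$n_env)) {
        designs[[paste0("SL", h)]] <- design_superior(
          model, design_target("SL", design_objective, environment = h))
        designs[[paste0("SH", h)]] <- design_superior(
          model, design_target("SH", design_objective, environment = h))
      }
  }

  files <- NULL
  if (!is.null(out_dir)) {
    files <- write_reports(model, out_dir, designs)
    manifest$files <- files
  }
  structure(list(panel = panel, scan_1d = scan1, scan_2d = scan2,
                 screen = screen_result, significant_qts = sig1,
                 significant_pairs = sig_pairs, model = model,
                 heritability = herit, designs = designs,
                 manifest = manifest),
            class = "qts_pipeline")
}

#' @export
print.qts_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("QTS pipeline run for trait", m$trait, "\n")
  cat(sprintf("  %d accessions; SNPs: %d input -> %d after QC%s\n",
              m$n_accessions, m$n_snps_input, m$n_snps_qc,
              if (!is.null(m$n_snps_screened))
                paste0(" -> ", m$n_snps_screened, " screened") else ""))
  cat(sprintf("  1D: %d significant at F* = %.3f", m$n_significant_1d,
              m$threshold_1d))
  if (!is.null(m$threshold_2d))
    cat(sprintf("; 2D: %d significant at F* = %.3f", m$n_significant_2d,
                m$threshold_2d))
  cat("\n")
  invisible(x)
}
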