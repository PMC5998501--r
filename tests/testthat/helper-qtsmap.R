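# shared builders for deterministic toy objects

# panel from an accession x SNP code matrix, positions 1e5 apart on chr1
toy_panel <- function(codes, chrom = NULL, pos = NULL, ...) {
  codes <- as.matrix(codes)
  m <- ncol(codes)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq(1e5, by = 1e5, length.out = m)
  genotype_panel(codes, chrom = chrom, pos = pos, ...)
}

# balanced phenotype table from per-accession genetic values
toy_pheno <- function(g, n_envs = 1, n_reps = 1, trait = "trait",
                      env_effects = rep(0, n_envs), noise_sd = 0,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- length(g)
  grid <- expand.grid(rep = seq_len(n_reps), env = seq_len(n_envs),
                      k = seq_len(N))
  y <- g[grid$k] + env_effects[grid$env] +
    if (noise_sd > 0) stats::rnorm(nrow(grid), 0, noise_sd) else 0
  phenotype_table(paste0("acc", grid$k), grid$env, grid$rep, trait, y)
}

# hand-assembled qts_model carrying just what predict/design/heritability
# methods read; effects: data.frame(name, class, term, estimate);
# gxe: data.frame(name, class, term, env, estimate) or NULL
toy_model <- function(effects, gxe = NULL, snps = NULL, n_env = 3,
                      trait = "trait") {
  loci <- unique(unlist(strsplit(effects$term[effects$class != "mu"],
                                 " & ", fixed = TRUE)))
  if (is.null(snps))
    snps <- data.frame(id = loci, chrom = "chr1",
                       pos = seq_along(loci), major = NA_character_,
                       minor = NA_character_, stringsAsFactors = FALSE)
  pair_rows <- grepl(" & ", effects$term, fixed = TRUE)
  pairs <- if (any(pair_rows)) {
    parts <- unique(effects$term[pair_rows])
    sp <- strsplit(parts, " & ", fixed = TRUE)
    data.frame(id_i = vapply(sp, `[`, "", 1), id_j = vapply(sp, `[`, "", 2),
               stringsAsFactors = FALSE)
  }
  ct <- data.frame(name = effects$name, class = effects$class,
                   term = effects$term, estimate = effects$estimate,
                   sd = 0.1, ci_lower = effects$estimate - 0.2,
                   ci_upper = effects$estimate + 0.2, neg_log10_p = 8,
                   stringsAsFactors = FALSE)
  gxe_df <- if (is.null(gxe))
    data.frame(name = character(), class = character(), term = character(),
               env = integer(), estimate = numeric()) else gxe
  structure(list(trait = trait, coef_table = ct,
                 varcomp = data.frame(component = c("env", "residual"),
                                      estimate = c(0, 1)),
                 gxe_effects = gxe_df,
                 env_effects = data.frame(env = seq_len(n_env),
                                          estimate = rep(0, n_env)),
                 snps = snps,
                 flipped = stats::setNames(rep(FALSE, nrow(snps)), snps$id),
                 pairs = pairs, dropped = list(), diagnostics = list(rhat = 1),
                 n_env = n_env, n_obs = 0),
            class = "qts_model")
}

# rows of a main+epistasis effect list -> the coef_table rows toy_model wants
effect_rows <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(name = paste0(r$class, ":", r$term), class = r$class,
               term = r$term, estimate = r$estimate,
               stringsAsFactors = FALSE)))
}

# independent evaluator of a genotype assignment against an effect table:
# written from the model definition, not from the package internals
oracle_genetic_value <- function(codes, effects, gxe = NULL, env = NULL) {
  xA <- codes - 1
  xD <- as.integer(codes == 1)
  names(xA) <- names(xD) <- names(codes)
  total <- 0
  eval_row <- function(class, term, est) {
    p <- strsplit(term, " & ", fixed = TRUE)[[1]]
    coefv <- switch(class,
                    a = xA[p[1]], d = xD[p[1]],
                    aa = xA[p[1]] * xA[p[2]], ad = xA[p[1]] * xD[p[2]],
                    da = xD[p[1]] * xA[p[2]], dd = xD[p[1]] * xD[p[2]],
                    ae = xA[p[1]], de = xD[p[1]],
                    aae = xA[p[1]] * xA[p[2]], ade = xA[p[1]] * xD[p[2]],
                    dae = xD[p[1]] * xA[p[2]], dde = xD[p[1]] * xD[p[2]])
    est * coefv
  }
  for (r in seq_len(nrow(effects)))
    if (effects$class[r] != "mu")
      total <- total + eval_row(effects$class[r], effects$term[r],
                                effects$estimate[r])
  if (!is.null(env) && !is.null(gxe)) {
    ge <- gxe[gxe$env == env, , drop = FALSE]
    for (r in seq_len(nrow(ge)))
      total <- total + eval_row(ge$class[r], ge$term[r], ge$estimate[r])
  }
  unname(total)
}
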