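#' Internal normalization of chromatogram peak areas
#'
#' Expresses each fatty-acid peak area as a percentage of the total peak
#' area: `X_i = A_i * 100 / sum(A)`. The output sums to 100 and is
#' invariant under positive rescaling of all areas.
#'
#' @param areas named numeric vector of non-negative peak areas with at
#'   least one positive entry.
#' @return Named numeric vector of percentages, order preserved.
#' @export
internal_normalization <- function(areas) {
  if (any(areas < 0)) stop("peak areas must be >= 0")
  total <- sum(areas)
  if (total <= 0) stop("all-zero peak areas")
  areas * 100 / total
}

#' Replicate agreement check
#'
#' Two replicate measurements agree when their absolute difference is less
#' than 10% of their arithmetic mean. The check is advisory: it flags, it
#' does not drop.
#'
#' @param v1,v2 finite replicate values.
#' @param tol relative tolerance (default 0.10).
#' @return A list with `pass` (logical) and `reason`.
#' @export
replicate_qc <- function(v1, v2, tol = 0.10) {
  if (!is.finite(v1) || !is.finite(v2)) stop("values must be finite")
  m <- (v1 + v2) / 2
  d <- abs(v1 - v2)
  if (m <= 0 && d > 0)
    return(list(pass = FALSE, reason = "non-positive mean with nonzero difference"))
  list(pass = d < tol * m || d == 0, reason = NA_character_)
}

#' Build a trait matrix from a phenotype table
#'
#' Averages replicates per (accession, environment, trait); at the pooled
#' level the per-environment means are further averaged over environments.
#' Missing (accession, environment) combinations are flagged.
#'
#' @param pheno a [phenotype_table()].
#' @param level `"per-environment"` or `"pooled"`.
#' @return A list of class `trait_matrix`: `values` (accession x trait
#'   matrix at the pooled level, or a list of such matrices per
#'   environment), `level`, and `missing` (data frame of absent
#'   combinations, if any).
#' @export
build_trait_matrix <- function(pheno, level = c("pooled", "per-environment")) {
  level <- match.arg(level)
  if (!nrow(pheno)) stop("empty phenotype table")
  key <- paste(pheno$accession, pheno$env, pheno$rep, pheno$trait)
  if (anyDuplicated(key)) stop("duplicate (accession, env, rep, trait) rows")
  envmeans <- stats::aggregate(value ~ accession + env + trait,
                               data = as.data.frame(pheno), FUN = mean)
  accs <- sort(unique(pheno$accession))
  traits <- sort(unique(pheno$trait))
  envs <- sort(unique(pheno$env))
  full <- expand.grid(accession = accs, env = envs, trait = traits,
                      stringsAsFactors = FALSE)
  have <- paste(envmeans$accession, envmeans$env, envmeans$trait)
  missing <- full[!paste(full$accession, full$env, full$trait) %in% have, ]
  to_matrix <- function(df) {
    m <- matrix(NA_real_, length(accs), length(traits),
                dimnames = list(accs, traits))
    m[cbind(match(df$accession, accs), match(df$trait, traits))] <- df$value
    m
  }
  if (level == "per-environment") {
    values <- lapply(envs, function(h) to_matrix(envmeans[envmeans$env == h, ]))
    names(values) <- paste0("env", envs)
  } else {
    pooled <- stats::aggregate(value ~ accession + trait, data = envmeans,
                               FUN = mean)
    values <- to_matrix(pooled)
  }
  structure(list(values = values, level = level,
                 missing = if (nrow(missing)) missing),
            class = "trait_matrix")
}

#' Phenotypic correlation between two traits
#'
#' Pearson correlation of accession-level values (replicates averaged; at
#' the default pooled level, also averaged over environments).
#'
#' @param tm a `trait_matrix` from [build_trait_matrix()] at the pooled
#'   level, or a [phenotype_table()] (pooled internally).
#' @param trait_a,trait_b trait names.
#' @return Pearson correlation r_p in \[-1, 1\].
#' @export
phenotypic_correlation <- function(tm, trait_a, trait_b) {
  if (inherits(tm, "phenotype_table")) tm <- build_trait_matrix(tm, "pooled")
  if (tm$level != "pooled")
    stop("phenotypic_correlation requires a pooled trait matrix")
  v <- tm$values
  a <- v[, trait_a]; b <- v[, trait_b]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) stop("need >= 3 accessions with both traits")
  if (stats::var(a[ok]) == 0 || stats::var(b[ok]) == 0)
    stop("zero variance in one of the traits")
  stats::cor(a[ok], b[ok])
}

#' Read a chromatogram table and normalize it
#'
#' Input TSV has columns `accession`, `rep`, then one peak-area column per
#' fatty acid. Each row is internally normalized to percentages.
#'
#' @param path TSV file path.
#' @return Data frame with the same layout, areas replaced by percentages.
#' @export
read_chromatograms_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  acids <- setdiff(names(df), c("accession", "rep"))
  for (r in seq_len(nrow(df)))
    df[r, acids] <- as.list(internal_normalization(unlist(df[r, acids])))
  df
}
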