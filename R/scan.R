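# Alignment of phenotype observations with coded genotypes ------------------

obs_align <- function(coded, pheno) {
  acc_idx <- match(pheno$accession, coded$accessions)
  if (anyNA(acc_idx)) stop("phenotype table names accessions absent from panel")
  list(y = pheno$value, env = pheno$env, acc = acc_idx,
       n_env = length(unique(pheno$env)))
}

env_center <- function(v, env) v - stats::ave(v, env)

# locus columns expanded to observations, mean-imputed at missing codes
obs_locus_cols <- function(coded, al, locus) {
  i <- locus_index(coded, locus)
  xA <- coded$xA[, i]; xD <- coded$xD[, i]
  if (anyNA(xA)) xA[is.na(xA)] <- mean(xA, na.rm = TRUE)
  if (anyNA(xD)) xD[is.na(xD)] <- mean(xD, na.rm = TRUE)
  cbind(a = xA[al$acc], d = xD[al$acc])
}

drop_constant <- function(X) {
  keep <- apply(X, 2, function(v) stats::var(v) > 0)
  X[, keep, drop = FALSE]
}

# F-test of adding block E to a model already containing env blocks and an
# optional nuisance block N, all computed on env-centered data
block_f_test <- function(yc, env, N, E, n_env) {
  n <- length(yc)
  rss0 <- sum(yc^2)
  qN <- 0
  if (!is.null(N) && ncol(N) > 0) {
    qrN <- qr(N)
    qN <- qrN$rank
    QN <- qr.Q(qrN)[, seq_len(qN), drop = FALSE]
    yc <- yc - QN %*% crossprod(QN, yc)
    E <- E - QN %*% crossprod(QN, E)
  }
  qrE <- qr(E)
  qE <- qrE$rank
  if (qE == 0) return(list(F = NA_real_, df1 = 0, df2 = NA, p = NA_real_))
  QE <- qr.Q(qrE)[, seq_len(qE), drop = FALSE]
  proj <- drop(crossprod(QE, yc))
  ssE <- sum(proj^2)
  rss1 <- sum(yc^2) - ssE
  df2 <- n - n_env - qN - qE
  Fv <- (ssE / qE) / (rss1 / df2)
  list(F = Fv, df1 = qE, df2 = df2,
       p = stats::pf(Fv, qE, df2, lower.tail = FALSE))
}

#' One-dimensional genome scan at a locus
#'
#' Fits the single-locus submodel with the environment absorbed as fixed
#' blocks and returns the joint F-type statistic for the additive and
#' dominance effects (a, d); with two or more environments the
#' gene-environment interaction (ae, de) is additionally tested by a
#' variance-ratio F on the interaction columns.
#'
#' @param coded a [code_genotypes()] result.
#' @param pheno a [phenotype_table()] for one trait.
#' @param locus SNP index or id (must be polymorphic).
#' @return A one-row data frame: `locus`, `statistic`, `df1`, `df2`, `p`,
#'   `neg_log10_p`, `classes` (effect classes actually tested),
#'   `statistic_gxe`, `p_gxe`.
#' @export
scan_1d <- function(coded, pheno, locus) {
  al <- obs_align(coded, pheno)
  X <- obs_locus_cols(coded, al, locus)
  Xc <- drop_constant(env_center_mat(X, al$env))
  if (ncol(Xc) == 0) stop("monomorphic locus: nothing to test")
  yc <- env_center(al$y, al$env)
  main <- block_f_test(yc, al$env, NULL, Xc, al$n_env)

  stat_gxe <- NA_real_; p_gxe <- NA_real_
  if (al$n_env >= 2) {
    G <- gxe_interaction_cols(X, al$env)
    Gc <- drop_constant(env_center_mat(G, al$env))
    if (ncol(Gc) > 0) {
      gx <- block_f_test(yc, al$env, Xc, Gc, al$n_env)
      stat_gxe <- gx$F; p_gxe <- gx$p
    }
  }
  id <- coded$snps$id[locus_index(coded, locus)]
  data.frame(locus = id, statistic = main$F, df1 = main$df1, df2 = main$df2,
             p = main$p, neg_log10_p = -log10(main$p),
             classes = paste(colnames(Xc), collapse = ","),
             statistic_gxe = stat_gxe, p_gxe = p_gxe,
             stringsAsFactors = FALSE)
}

env_center_mat <- function(X, env) {
  apply(X, 2, env_center, env = env)
}

# interaction columns of each x-column with environment contrasts (env 2..H)
gxe_interaction_cols <- function(X, env) {
  H <- sort(unique(env))
  cols <- list()
  for (j in seq_len(ncol(X)))
    for (h in H[-1])
      cols[[paste0(colnames(X)[j], "e", h)]] <- X[, j] * (env == h)
  do.call(cbind, cols)
}

#' Two-dimensional genome scan at a locus pair
#'
#' Fits the two-locus submodel (environment blocks, both loci's a and d
#' effects) and returns the joint F test of the four digenic epistasis
#' terms aa, ad, da, dd; degenerate epistasis columns (empty two-locus
#' cells) are dropped and recorded. With two or more environments the
#' epistasis-by-environment interaction is additionally tested.
#'
#' @param coded a [code_genotypes()] result.
#' @param pheno a [phenotype_table()] for one trait.
#' @param locus_i,locus_j distinct polymorphic loci.
#' @return A one-row data frame analogous to [scan_1d()].
#' @export
scan_2d <- function(coded, pheno, locus_i, locus_j) {
  i <- locus_index(coded, locus_i); j <- locus_index(coded, locus_j)
  if (i == j) stop("loci must be distinct")
  al <- obs_align(coded, pheno)
  Xi <- obs_locus_cols(coded, al, i); Xj <- obs_locus_cols(coded, al, j)
  M <- cbind(a_i = Xi[, 1], d_i = Xi[, 2], a_j = Xj[, 1], d_j = Xj[, 2])
  E <- cbind(aa = Xi[, 1] * Xj[, 1], ad = Xi[, 1] * Xj[, 2],
             da = Xi[, 2] * Xj[, 1], dd = Xi[, 2] * Xj[, 2])
  Mc <- drop_constant(env_center_mat(M, al$env))
  Ec <- drop_constant(env_center_mat(E, al$env))
  if (ncol(Ec) == 0) stop("all epistasis columns degenerate for this pair")
  yc <- env_center(al$y, al$env)
  ep <- block_f_test(yc, al$env, Mc, Ec, al$n_env)

  stat_gxe <- NA_real_; p_gxe <- NA_real_
  if (al$n_env >= 2) {
    G <- gxe_interaction_cols(E, al$env)
    Gc <- drop_constant(env_center_mat(G, al$env))
    if (ncol(Gc) > 0) {
      gx <- block_f_test(yc, al$env, cbind(Mc, Ec), Gc, al$n_env)
      stat_gxe <- gx$F; p_gxe <- gx$p
    }
  }
  data.frame(locus = paste(coded$snps$id[i], coded$snps$id[j], sep = " & "),
             statistic = ep$F, df1 = ep$df1, df2 = ep$df2, p = ep$p,
             neg_log10_p = -log10(ep$p),
             classes = paste(colnames(Ec), collapse = ","),
             statistic_gxe = stat_gxe, p_gxe = p_gxe,
             stringsAsFactors = FALSE)
}

#' Scan every locus (or locus pair) of a panel
#'
#' @param coded a [code_genotypes()] result.
#' @param pheno a [phenotype_table()] for one trait.
#' @param loci locus indices/ids to scan (default: all polymorphic loci).
#' @param pairs for the 2D scan, a two-column matrix (or data frame) of
#'   locus indices/ids.
#' @return A `scan_result` data frame, one row per locus or pair.
#' @export
scan_genome_1d <- function(coded, pheno, loci = NULL) {
  if (is.null(loci)) {
    poly <- which(apply(coded$xA, 2,
                        function(v) stats::var(v, na.rm = TRUE) > 0))
    loci <- poly
  }
  out <- do.call(rbind, lapply(loci, function(l) scan_1d(coded, pheno, l)))
  class(out) <- c("scan_result", "data.frame")
  out
}

#' @rdname scan_genome_1d
#' @export
scan_genome_2d <- function(coded, pheno, pairs) {
  pairs <- as.matrix(pairs)
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r)
    tryCatch(scan_2d(coded, pheno, pairs[r, 1], pairs[r, 2]),
             error = function(e) NULL)))
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Permutation-based experiment-wise threshold
#'
#' Permutes the accession-to-phenotype assignment within each environment
#' (replicates follow their accession, so the environment main effect is
#' preserved), recomputes the scan's F statistics for the whole family on
#' each permutation, records the familywise maximum, and returns its
#' (1 - alpha) empirical quantile. Requires a design in which every
#' accession is observed in every (environment, replicate) combination.
#'
#' @param coded a [code_genotypes()] result.
#' @param pheno a [phenotype_table()] for one trait.
#' @param family `"1d"` or `"2d"`.
#' @param loci loci scanned in the 1D family (default all polymorphic).
#' @param pairs two-column matrix of loci for the 2D family.
#' @param n_perm number of permutations (>= 100).
#' @param alpha experiment-wise significance level.
#' @param seed integer RNG seed.
#' @return A list of class `perm_threshold`: `threshold`, `max_stats`
#'   (length `n_perm`), `observed` (per-member observed F), `family`,
#'   `alpha`, `n_perm`.
#' @export
permutation_threshold <- function(coded, pheno, family = c("1d", "2d"),
                                  loci = NULL, pairs = NULL, n_perm = 1000,
                                  alpha = 0.05, seed = 1) {
  family <- match.arg(family)
  if (n_perm < 100) stop("n_perm must be >= 100")
  al <- obs_align(coded, pheno)
  n <- length(al$y)
  yc <- env_center(al$y, al$env)

  # test blocks: orthonormal bases for nuisance (beyond env) and tested part
  if (family == "1d") {
    if (is.null(loci))
      loci <- which(apply(coded$xA, 2,
                          function(v) stats::var(v, na.rm = TRUE) > 0))
    members <- lapply(loci, function(l) {
      Xc <- drop_constant(env_center_mat(obs_locus_cols(coded, al, l), al$env))
      if (ncol(Xc) == 0) return(NULL)
      list(N = NULL, E = Xc)
    })
  } else {
    if (is.null(pairs)) stop("2d family requires pairs")
    pairs <- as.matrix(pairs)
    members <- lapply(seq_len(nrow(pairs)), function(r) {
      i <- locus_index(coded, pairs[r, 1]); j <- locus_index(coded, pairs[r, 2])
      Xi <- obs_locus_cols(coded, al, i); Xj <- obs_locus_cols(coded, al, j)
      Mc <- drop_constant(env_center_mat(
        cbind(Xi, Xj), al$env))
      Ec <- drop_constant(env_center_mat(
        cbind(Xi[, 1] * Xj[, 1], Xi[, 1] * Xj[, 2],
              Xi[, 2] * Xj[, 1], Xi[, 2] * Xj[, 2]), al$env))
      if (ncol(Ec) == 0) return(NULL)
      list(N = Mc, E = Ec)
    })
  }
  members <- Filter(Negate(is.null), members)
  if (!length(members)) stop("empty test family")

  proj <- lapply(members, function(mb) {
    qN <- 0; QN <- NULL
    E <- mb$E
    if (!is.null(mb$N) && ncol(mb$N) > 0) {
      qrN <- qr(mb$N); qN <- qrN$rank
      QN <- qr.Q(qrN)[, seq_len(qN), drop = FALSE]
      E <- E - QN %*% crossprod(QN, E)
    }
    qrE <- qr(E); qE <- qrE$rank
    QE <- qr.Q(qrE)[, seq_len(qE), drop = FALSE]
    list(QN = QN, qN = qN, QE = QE, qE = qE,
         df2 = n - al$n_env - qN - qE)
  })

  # permutation matrix: accession-level shuffles within environment
  set.seed(seed)
  key <- paste(al$acc, al$env, sep = "/")
  perm_orders <- matrix(0L, nrow = n, ncol = n_perm)
  accs <- sort(unique(al$acc))
  envs <- sort(unique(al$env))
  obs_by <- split(seq_len(n), list(acc = al$acc, env = al$env), drop = FALSE)
  # verify balance for the accession-level shuffle
  sizes <- lengths(split(seq_len(n), paste(al$acc, al$env)))
  balanced <- length(unique(sizes)) == 1 &&
    length(sizes) == length(accs) * length(envs)
  if (!balanced)
    stop("permutation threshold requires a balanced accession x environment design")
  idx_tab <- lapply(envs, function(h) {
    lapply(accs, function(k) which(al$acc == k & al$env == h))
  })
  for (p in seq_len(n_perm)) {
    ord <- integer(n)
    for (hi in seq_along(envs)) {
      pi_h <- sample(length(accs))
      for (ki in seq_along(accs))
        ord[idx_tab[[hi]][[ki]]] <- idx_tab[[hi]][[pi_h[ki]]]
    }
    perm_orders[, p] <- ord
  }
  Yperm <- matrix(yc[perm_orders], nrow = n, ncol = n_perm)
  rss0 <- sum(yc^2)

  member_f <- function(pr, Y) {
    ssN <- if (pr$qN > 0) colSums(crossprod(pr$QN, Y)^2) else 0
    ssE <- colSums(crossprod(pr$QE, Y)^2)
    (ssE / pr$qE) / ((rss0 - ssN - ssE) / pr$df2)
  }
  Fmat <- vapply(proj, member_f, numeric(n_perm), Y = Yperm)
  max_stats <- if (length(proj) == 1) as.numeric(Fmat) else
    apply(Fmat, 1, max)
  observed <- vapply(proj, function(pr)
    member_f(pr, matrix(yc, ncol = 1)), 0)
  structure(list(threshold = stats::quantile(max_stats, 1 - alpha,
                                             names = FALSE, type = 1),
                 max_stats = max_stats, observed = observed,
                 family = family, alpha = alpha, n_perm = n_perm),
            class = "perm_threshold")
}

#' @export
print.perm_threshold <- function(x, ...) {
  cat(sprintf("%s-family permutation threshold (alpha = %g, %d perms): F* = %.3f\n",
              x$family, x$alpha, x$n_perm, x$threshold))
  invisible(x)
}

#' Write a scan result as TSV
#'
#' @param scan a `scan_result` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
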