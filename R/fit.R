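#' Fit the full QTS model by Gibbs sampling
#'
#' Estimates the full genetic model for a set of selected quantitative
#' trait SNPs (QTSs) and QTS pairs: additive and dominance main effects and
#' the four digenic epistasis classes (aa, ad, da, dd) as fixed effects,
#' with the environment main effect and every gene-environment interaction
#' class (ae, de, aae, ade, dae, dde) as random effects, plus an
#' observation-level residual. Fixed effects carry flat priors; variance
#' components carry weak inverse-gamma priors. Point estimates are
#' posterior means; per-effect significance is summarized as a Wald
#' -log10 p from the posterior mean/sd ratio against a standard normal.
#'
#' Degenerate or collinear design columns are dropped and logged.
#' Observations from accessions with missing genotypes at any selected
#' locus are dropped and logged. Convergence is checked by split-chain
#' potential scale reduction on the fixed effects.
#'
#' @param panel a [genotype_panel()] (or a [code_genotypes()] result).
#' @param pheno a [phenotype_table()] for one trait.
#' @param qts character vector of SNP ids (or integer indices) with main
#'   effects in the model.
#' @param pairs two-column matrix/data frame of SNP ids (or indices) whose
#'   epistatic effects enter the model; pair loci automatically contribute
#'   main-effect columns as well.
#' @param n_iter total Gibbs iterations (default 20000).
#' @param burn_in burn-in iterations discarded (default 2000).
#' @param seed integer RNG seed.
#' @param include_gxe fit random gene-environment interaction effects
#'   (requires >= 2 environments).
#' @param recode_major designate the major allele as Q before coding.
#' @return An object of class `qts_model`; see [summary.qts_model()].
#'   Components include `coef_table` (per-effect posterior summaries),
#'   `varcomp` (environment, per-effect GxE and residual variances),
#'   `gxe_effects` (posterior means of the per-environment interaction
#'   effects), `env_effects`, `dropped` (log of dropped columns and
#'   observations), and `diagnostics` (split-chain R-hat).
#' @export
fit_qts_model <- function(panel, pheno, qts = character(), pairs = NULL,
                          n_iter = 20000, burn_in = 2000, seed = 1,
                          include_gxe = TRUE, recode_major = TRUE) {
  coded <- if (inherits(panel, "coded_genotypes")) panel else
    code_genotypes(panel, recode_major = recode_major)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  trait <- unique(pheno$trait)
  if (length(trait) != 1) stop("one trait at a time")

  qts_idx <- vapply(qts, locus_index, 0L, coded = coded)
  if (!is.null(pairs)) {
    pairs <- as.matrix(pairs)
    pair_idx <- cbind(vapply(pairs[, 1], locus_index, 0L, coded = coded),
                      vapply(pairs[, 2], locus_index, 0L, coded = coded))
  } else pair_idx <- matrix(0L, 0, 2)
  main_idx <- sort(unique(c(qts_idx, as.integer(pair_idx))))

  dropped <- list(columns = character(), observations = 0L)

  # drop observations with missing genotypes at selected loci
  if (length(main_idx)) {
    bad_acc <- rowSums(is.na(coded$xA[, main_idx, drop = FALSE])) > 0
    if (any(bad_acc)) {
      keep_obs <- !(pheno$accession %in% coded$accessions[bad_acc])
      dropped$observations <- sum(!keep_obs)
      pheno <- pheno[keep_obs, , drop = FALSE]
    }
  }
  al <- obs_align(coded, pheno)
  n <- length(al$y)
  H <- al$n_env
  env <- al$env

  # fixed design ------------------------------------------------------------
  ids <- coded$snps$id
  Xl <- list(mu = rep(1, n))
  meta <- data.frame(name = "mu", class = "mu", term = "(intercept)",
                     stringsAsFactors = FALSE)
  add_col <- function(v, name, cl, term) {
    if (stats::var(v) == 0) {
      dropped$columns <<- c(dropped$columns, name)
      return(invisible())
    }
    Xl[[name]] <<- v
    meta <<- rbind(meta, data.frame(name = name, class = cl, term = term,
                                    stringsAsFactors = FALSE))
  }
  for (i in main_idx) {
    xa <- coded$xA[al$acc, i]; xd <- coded$xD[al$acc, i]
    add_col(xa, paste0("a:", ids[i]), "a", ids[i])
    add_col(xd, paste0("d:", ids[i]), "d", ids[i])
  }
  if (nrow(pair_idx))
    for (r in seq_len(nrow(pair_idx))) {
      i <- pair_idx[r, 1]; j <- pair_idx[r, 2]
      pc <- pair_columns(coded, i, j)[al$acc, , drop = FALSE]
      pid <- paste(ids[i], ids[j], sep = " & ")
      for (cl in colnames(pc))
        add_col(pc[, cl], paste0(cl, ":", pid), cl, pid)
    }
  X <- do.call(cbind, Xl)
  colnames(X) <- meta$name

  # collinearity: drop pivoted-out columns
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- qrX$pivot[-seq_len(qrX$rank)]
    dropped$columns <- c(dropped$columns, colnames(X)[drop_cols])
    X <- X[, -drop_cols, drop = FALSE]
    meta <- meta[meta$name %in% colnames(X), , drop = FALSE]
  }
  p <- ncol(X)

  # random GxE structure: one variance per genetic column, effects per env
  gxe_cols <- if (include_gxe && H >= 2) which(meta$class != "mu") else integer(0)
  n_g <- length(gxe_cols)

  # Gibbs sampler -----------------------------------------------------------
  set.seed(seed)
  XtX <- crossprod(X)
  Rch <- chol(XtX)
  # weak inverse-gamma priors (Jeffreys-like shape); with only a few
  # environments the variance components rest on H draws each, so the
  # heritability summaries use the realized second moment of the sampled
  # interaction effects rather than these weakly-identified components
  a0 <- 0.5; b0 <- 1e-6
  y <- al$y
  beta <- qr.coef(qrX, y)[colnames(X)]
  beta[is.na(beta)] <- 0
  e_h <- rep(0, H)
  U <- matrix(0, nrow = max(n_g, 1), ncol = H)
  s2_e <- max(stats::var(y) * 0.1, 1e-8)
  s2_g <- rep(max(stats::var(y) * 0.05, 1e-8), max(n_g, 1))
  s2_eps <- max(stats::var(y - X %*% beta) , 1e-8)
  env_n <- tabulate(env, H)

  zsq <- if (n_g) vapply(gxe_cols, function(j)
    rowsum(X[, j]^2, env)[, 1], numeric(H)) else NULL  # H x n_g

  eta_rand <- e_h[env]
  resid <- drop(y - X %*% beta - eta_rand)

  n_keep <- n_iter - burn_in
  Bdraws <- matrix(0, n_keep, p, dimnames = list(NULL, colnames(X)))
  Vdraws <- matrix(0, n_keep, 2 + n_g)
  colnames(Vdraws) <- c("env", "residual",
                        if (n_g) paste0(meta$class[gxe_cols], "e:",
                                        meta$term[gxe_cols]))
  Usum <- matrix(0, max(n_g, 1), H)
  U2sum <- matrix(0, max(n_g, 1), H)
  esum <- numeric(H)
  e2sum <- 0

  for (it in seq_len(n_iter)) {
    # fixed block
    target <- drop(y - eta_rand)
    mvec <- backsolve(Rch, forwardsolve(t(Rch), crossprod(X, target)))
    beta <- drop(mvec + sqrt(s2_eps) * backsolve(Rch, stats::rnorm(p)))
    resid <- target - drop(X %*% beta)

    # environment main effect (random, shared variance)
    resid <- resid + e_h[env]
    s_h <- rowsum(resid, env)[, 1]
    prec <- env_n / s2_eps + 1 / s2_e
    e_h <- s_h / s2_eps / prec + stats::rnorm(H) / sqrt(prec)
    resid <- resid - e_h[env]

    # GxE scalar effects, one genetic column at a time across environments
    if (n_g) {
      for (g in seq_len(n_g)) {
        z <- X[, gxe_cols[g]]
        u_old <- U[g, ]
        resid <- resid + z * u_old[env]
        s_hg <- rowsum(z * resid, env)[, 1]
        prec <- zsq[, g] / s2_eps + 1 / s2_g[g]
        u_new <- s_hg / s2_eps / prec + stats::rnorm(H) / sqrt(prec)
        U[g, ] <- u_new
        resid <- resid - z * u_new[env]
      }
    }

    # recentering sweeps: the fixed intercept is flat against the mean of
    # the environment effects, and each fixed genetic effect is flat
    # against the mean of its per-environment interaction effects; sample
    # the shift along each flat direction to keep the chain mixing
    if ("mu" %in% colnames(X)) {
      delta <- stats::rnorm(1, mean(e_h), sqrt(s2_e / H))
      beta[colnames(X) == "mu"] <- beta[colnames(X) == "mu"] + delta
      e_h <- e_h - delta
    }
    if (n_g) {
      delta_g <- stats::rnorm(n_g, rowMeans(U), sqrt(s2_g / H))
      beta[gxe_cols] <- beta[gxe_cols] + delta_g
      U <- U - delta_g
    }

    # variances
    s2_e <- 1 / stats::rgamma(1, a0 + H / 2, b0 + sum(e_h^2) / 2)
    if (n_g)
      s2_g <- 1 / stats::rgamma(n_g, a0 + H / 2, b0 + rowSums(U^2) / 2)
    s2_eps <- 1 / stats::rgamma(1, a0 + n / 2, b0 + sum(resid^2) / 2)

    eta_rand <- e_h[env]
    if (n_g)
      for (g in seq_len(n_g))
        eta_rand <- eta_rand + X[, gxe_cols[g]] * U[g, env]

    if (it > burn_in) {
      k <- it - burn_in
      Bdraws[k, ] <- beta
      Vdraws[k, ] <- c(s2_e, s2_eps, if (n_g) s2_g)
      Usum <- Usum + U
      U2sum <- U2sum + U^2
      esum <- esum + e_h
      e2sum <- e2sum + mean(e_h^2)
    }
  }

  # summaries ----------------------------------------------------------------
  est <- colMeans(Bdraws)
  sds <- apply(Bdraws, 2, stats::sd)
  ci <- apply(Bdraws, 2, stats::quantile, probs = c(0.025, 0.975))
  z <- est / pmax(sds, .Machine$double.eps)
  neg_log10_p <- -(log(2) + stats::pnorm(-abs(z), log.p = TRUE)) / log(10)
  coef_table <- cbind(meta,
                      data.frame(estimate = est, sd = sds,
                                 ci_lower = ci[1, ], ci_upper = ci[2, ],
                                 neg_log10_p = neg_log10_p,
                                 row.names = NULL))
  vmeans <- colMeans(Vdraws)
  # realized variance per component: posterior mean of the average squared
  # effect, robust to the weak variance prior when H is small
  realized <- c(env = mean(e2sum / n_keep),
                residual = unname(vmeans["residual"]),
                if (n_g) rowMeans(U2sum / n_keep))
  varcomp <- data.frame(component = colnames(Vdraws), estimate = vmeans,
                        realized = unname(realized),
                        stringsAsFactors = FALSE, row.names = NULL)
  Umean <- Usum / n_keep
  gxe_effects <- if (n_g) data.frame(
    name = rep(paste0(meta$class[gxe_cols], "e:", meta$term[gxe_cols]),
               times = H),
    class = rep(paste0(meta$class[gxe_cols], "e"), times = H),
    term = rep(meta$term[gxe_cols], times = H),
    env = rep(seq_len(H), each = n_g),
    estimate = as.vector(Umean), stringsAsFactors = FALSE
  ) else data.frame(name = character(), class = character(),
                    term = character(), env = integer(),
                    estimate = numeric())

  # split-chain potential scale reduction on fixed effects
  rhat <- apply(Bdraws, 2, split_rhat)
  if (any(rhat > 1.1, na.rm = TRUE))
    warning("possible non-convergence: max split R-hat = ",
            round(max(rhat, na.rm = TRUE), 3))

  fitted_vals <- drop(X %*% est)
  e_mean <- esum / n_keep
  eta <- fitted_vals + e_mean[env]
  if (n_g)
    for (g in seq_len(n_g))
      eta <- eta + X[, gxe_cols[g]] * Umean[g, env]

  V_P <- mean((env_center(y, env))^2) * n / max(n - 1, 1)

  structure(list(
    trait = trait, coef_table = coef_table, varcomp = varcomp,
    gxe_effects = gxe_effects,
    env_effects = data.frame(env = seq_len(H), estimate = e_mean),
    snps = coded$snps[main_idx, , drop = FALSE],
    flipped = stats::setNames(coded$flipped[main_idx], ids[main_idx]),
    pairs = if (nrow(pair_idx))
      data.frame(id_i = ids[pair_idx[, 1]], id_j = ids[pair_idx[, 2]],
                 stringsAsFactors = FALSE),
    dropped = dropped, diagnostics = list(rhat = rhat),
    draws = list(beta = Bdraws, varcomp = Vdraws),
    X = X, y = y, env = env, fitted = eta, V_P = V_P,
    n_iter = n_iter, burn_in = burn_in, seed = seed,
    n_obs = n, n_env = H
  ), class = "qts_model")
}

split_rhat <- function(x) {
  n <- length(x)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  chains <- list(x[seq_len(half)], x[(n - half + 1):n])
  means <- vapply(chains, mean, 0)
  vars <- vapply(chains, stats::var, 0)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' @export
print.qts_model <- function(x, ...) {
  cat("Full QTS model for trait", x$trait, "\n")
  cat(sprintf("  %d observations, %d environments, %d fixed effects, seed %d\n",
              x$n_obs, x$n_env, nrow(x$coef_table), x$seed))
  cat(sprintf("  Gibbs: %d iterations (%d burn-in); max split R-hat %.3f\n",
              x$n_iter, x$burn_in, max(x$diagnostics$rhat, na.rm = TRUE)))
  invisible(x)
}

#' Summarize a fitted QTS model
#'
#' @param object a `qts_model`.
#' @param ... unused.
#' @return The model's coefficient table, variance components and
#'   heritability partition, printed and returned invisibly.
#' @export
summary.qts_model <- function(object, ...) {
  out <- list(coef = object$coef_table, varcomp = object$varcomp,
              heritability = heritability(object))
  cat("Fixed genetic effects (posterior means):\n")
  print(out$coef[, c("name", "estimate", "sd", "ci_lower", "ci_upper",
                     "neg_log10_p")], digits = 3, row.names = FALSE)
  cat("\nVariance components:\n")
  print(out$varcomp, digits = 3, row.names = FALSE)
  cat("\n")
  print(out$heritability)
  invisible(out)
}

#' @export
coef.qts_model <- function(object, ...) {
  stats::setNames(object$coef_table$estimate, object$coef_table$name)
}

#' @export
fitted.qts_model <- function(object, ...) object$fitted

#' @export
residuals.qts_model <- function(object, ...) object$y - object$fitted

#' Predict genetic values from a fitted QTS model
#'
#' Computes the pure genetic value (fixed main + epistatic effects; the
#' population mean and environment main effect are excluded) for each
#' accession of a panel, optionally adding the predicted gene-environment
#' interaction effects of one environment.
#'
#' @param object a `qts_model`.
#' @param panel a [genotype_panel()]; defaults to the accessions the model
#'   was fitted on (via its stored design).
#' @param environment `NULL` for the environment-independent value, or an
#'   environment id whose predicted GxE effects are added.
#' @param ... unused.
#' @return Named numeric vector of genetic values.
#' @export
predict.qts_model <- function(object, panel = NULL, environment = NULL, ...) {
  if (!is.null(environment) && !environment %in% seq_len(object$n_env))
    stop("unknown environment: ", environment)
  ct <- object$coef_table
  gen <- ct[ct$class != "mu", , drop = FALSE]
  if (is.null(panel)) {
    obs_g <- drop(object$X[, gen$name, drop = FALSE] %*% gen$estimate)
    if (!is.null(environment)) {
      ge <- object$gxe_effects[object$gxe_effects$env == environment, ]
      for (r in seq_len(nrow(ge))) {
        base_name <- sub("e:", ":", ge$name[r], fixed = TRUE)
        if (base_name %in% colnames(object$X))
          obs_g <- obs_g + object$X[, base_name] * ge$estimate[r]
      }
    }
    # one value per accession: observations within accession share genotype
    return(obs_g)
  }
  loci <- gen_model_loci(object)
  missing_loci <- setdiff(loci, colnames(panel$codes))
  if (length(missing_loci))
    stop("panel lacks model loci: ", paste(missing_loci, collapse = ", "))
  assign_codes <- panel$codes[, loci, drop = FALSE]
  # translate panel codes into the model's Q-allele counting
  flip <- names(object$flipped)[object$flipped]
  flip <- intersect(flip, loci)
  if (length(flip))
    assign_codes[, flip] <- 2L - assign_codes[, flip]
  apply(assign_codes, 1, function(codes)
    genetic_value(stats::setNames(as.integer(codes), loci),
                  object, environment = environment))
}

gen_model_loci <- function(object) {
  unique(unlist(strsplit(
    object$coef_table$term[object$coef_table$class != "mu"], " & ",
    fixed = TRUE)))
}

#' Simulate phenotypes from a fitted QTS model
#'
#' Draws new observation sets from the fitted parameters: fixed effects at
#' their posterior means, environment and gene-environment effects redrawn
#' from their estimated variance components, and residuals from the
#' estimated residual variance.
#'
#' @param object a `qts_model`.
#' @param nsim number of simulated datasets.
#' @param seed integer RNG seed.
#' @param ... unused.
#' @return A list of `nsim` numeric vectors aligned with the model's
#'   observations.
#' @export
simulate.qts_model <- function(object, nsim = 1, seed = 1, ...) {
  set.seed(seed)
  vc <- stats::setNames(object$varcomp$estimate, object$varcomp$component)
  X <- object$X
  fixed <- drop(X %*% object$coef_table$estimate)
  gxe_names <- setdiff(names(vc), c("env", "residual"))
  H <- object$n_env
  lapply(seq_len(nsim), function(s) {
    y <- fixed + stats::rnorm(H, 0, sqrt(vc["env"]))[object$env]
    for (nm in gxe_names) {
      base_name <- sub("e:", ":", nm, fixed = TRUE)
      u <- stats::rnorm(H, 0, sqrt(vc[nm]))
      y <- y + X[, base_name] * u[object$env]
    }
    y + stats::rnorm(length(y), 0, sqrt(vc["residual"]))
  })
}

#' Plot fixed-effect estimates of a fitted QTS model
#'
#' Dot-and-interval plot of the posterior means and 95% credible
#' intervals of all fixed genetic effects.
#'
#' @param x a `qts_model`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.qts_model <- function(x, ...) {
  ct <- x$coef_table[x$coef_table$class != "mu", , drop = FALSE]
  if (!nrow(ct)) {
    warning("no genetic effects to plot")
    return(invisible())
  }
  k <- seq_len(nrow(ct))
  graphics::plot(ct$estimate, k, xlim = range(ct$ci_lower, ct$ci_upper),
                 pch = 19, yaxt = "n", xlab = "effect (trait units)",
                 ylab = "", main = paste("QTS effects:", x$trait), ...)
  graphics::segments(ct$ci_lower, k, ct$ci_upper, k)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::axis(2, at = k, labels = ct$name, las = 2, cex.axis = 0.7)
  invisible(x)
}
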