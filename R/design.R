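#' Design target for superior-genotype prediction
#'
#' The four design schemes: GSL / GSH are the general superior homozygous
#' line / hybrid (environment-independent, main + epistatic effects only);
#' SL / SH are their environment-specific counterparts, which add the
#' predicted gene-environment interaction effects of one environment.
#' Line designs (GSL, SL) restrict every locus to the homozygotes QQ/qq;
#' hybrid designs (GSH, SH) also allow Qq.
#'
#' @param mode one of `"GSL"`, `"GSH"`, `"SL"`, `"SH"`.
#' @param objective `"max"` or `"min"`.
#' @param environment environment id, required for SL/SH and forbidden for
#'   GSL/GSH.
#' @return A list of class `design_target`.
#' @export
design_target <- function(mode = c("GSL", "GSH", "SL", "SH"),
                          objective = c("max", "min"),
                          environment = NULL) {
  mode <- match.arg(mode)
  objective <- match.arg(objective)
  env_specific <- mode %in% c("SL", "SH")
  if (env_specific && is.null(environment))
    stop(mode, " requires an environment id")
  if (!env_specific && !is.null(environment))
    stop(mode, " is environment-independent; drop the environment id")
  structure(list(mode = mode, objective = objective,
                 environment = environment,
                 allowed = if (mode %in% c("GSL", "SL")) c(2L, 0L)
                           else c(2L, 1L, 0L)),
            class = "design_target")
}

#' Genetic value of a multilocus genotype assignment
#'
#' Sums the model's fixed main effects times their coefficients and
#' epistatic effects times the coefficient products for a complete
#' assignment of genotypes to the model's QTSs; with an environment id,
#' the predicted gene-environment interaction effects of that environment
#' are added. The population mean is excluded (pure genetic value).
#'
#' @param assignment named vector over the model's loci: Q-allele counts
#'   (2 = QQ, 1 = Qq, 0 = qq) or genotype strings `"QQ"`, `"Qq"`, `"qq"`.
#' @param model a `qts_model`.
#' @param environment `NULL` or an environment id.
#' @param include_epistasis_gxe add epistasis-by-environment predicted
#'   effects (only relevant with an environment id).
#' @return Genetic value in trait units.
#' @export
genetic_value <- function(assignment, model, environment = NULL,
                          include_epistasis_gxe = TRUE) {
  if (!is.null(environment) && !environment %in% seq_len(model$n_env))
    stop("unknown environment: ", environment)
  codes <- parse_assignment(assignment)
  loci <- gen_model_loci(model)
  if (!all(loci %in% names(codes)))
    stop("incomplete assignment: missing ",
         paste(setdiff(loci, names(codes)), collapse = ", "))
  xA <- codes - 1; xD <- (codes == 1) * 1
  coef_of <- function(cl, term) {
    parts <- strsplit(term, " & ", fixed = TRUE)[[1]]
    switch(cl,
           a = xA[term], d = xD[term],
           aa = xA[parts[1]] * xA[parts[2]],
           ad = xA[parts[1]] * xD[parts[2]],
           da = xD[parts[1]] * xA[parts[2]],
           dd = xD[parts[1]] * xD[parts[2]])
  }
  ct <- model$coef_table
  gen <- ct[ct$class != "mu", , drop = FALSE]
  val <- 0
  for (r in seq_len(nrow(gen)))
    val <- val + gen$estimate[r] * coef_of(gen$class[r], gen$term[r])
  if (!is.null(environment) && nrow(model$gxe_effects)) {
    ge <- model$gxe_effects[model$gxe_effects$env == environment, ,
                            drop = FALSE]
    if (!include_epistasis_gxe)
      ge <- ge[ge$class %in% c("ae", "de"), , drop = FALSE]
    for (r in seq_len(nrow(ge))) {
      base_cl <- sub("e$", "", ge$class[r])
      val <- val + ge$estimate[r] * coef_of(base_cl, ge$term[r])
    }
  }
  unname(val)
}

parse_assignment <- function(assignment) {
  if (is.character(assignment)) {
    map <- c(QQ = 2L, Qq = 1L, qQ = 1L, qq = 0L)
    codes <- map[assignment]
    if (anyNA(codes)) stop("genotypes must be QQ, Qq or qq")
    names(codes) <- names(assignment)
  } else codes <- assignment
  if (is.null(names(codes))) stop("assignment must be named by SNP id")
  if (!all(codes %in% c(0L, 1L, 2L))) stop("codes must be 0, 1 or 2")
  codes
}

#' Predict the superior genotype for a design target
#'
#' Finds the exact optimum of the genetic value over the allowed per-locus
#' genotype space: loci are partitioned into connected components of the
#' epistasis graph; isolated loci are optimized independently and each
#' component is solved by exhaustive enumeration over allowed genotype
#' combinations. Ties are broken lexicographically (QQ < Qq < qq, loci in
#' model order).
#'
#' @param model a `qts_model`.
#' @param target a [design_target()].
#' @return A list of class `design_result`: `assignment` (Q-allele counts
#'   per QTS), `genotype_labels` (allele-pair strings built from the
#'   major/minor metadata, e.g. `"AA"`, `"AG"`), `value`, and
#'   `values_by_env` (per-environment values including predicted GxE
#'   effects, when the model has any).
#' @export
design_superior <- function(model, target) {
  stopifnot(inherits(model, "qts_model"), inherits(target, "design_target"))
  loci <- gen_model_loci(model)
  if (!length(loci)) stop("model has no genetic effects")
  env <- target$environment

  # epistasis graph components (union-find over model pairs)
  parent <- stats::setNames(seq_along(loci), loci)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (!is.null(model$pairs) && nrow(model$pairs))
    for (r in seq_len(nrow(model$pairs))) {
      ri <- find(match(model$pairs$id_i[r], loci))
      rj <- find(match(model$pairs$id_j[r], loci))
      if (ri != rj) parent[ri] <- rj
    }
  comp <- vapply(seq_along(loci), function(i) find(i), 0L)
  comp_sizes <- table(comp)
  if (any(comp_sizes > 20))
    stop("an epistasis component has more than 20 loci; exhaustive design ",
         "enumeration refused - split the model or prune the component")

  sign <- if (target$objective == "max") 1 else -1
  # genotype preference order for tie-breaking: QQ < Qq < qq
  pref <- intersect(c(2L, 1L, 0L), target$allowed)

  assignment <- stats::setNames(rep(NA_integer_, length(loci)), loci)
  for (cp in unique(comp)) {
    members <- loci[comp == cp]
    assignment[members] <- solve_component(members, model, env, pref, sign)
  }
  value <- genetic_value(assignment, model, environment = env)
  values_by_env <- if (nrow(model$gxe_effects))
    vapply(seq_len(model$n_env), function(h)
      genetic_value(assignment, model, environment = h), 0)
  structure(list(mode = target$mode, objective = target$objective,
                 environment = env, assignment = assignment,
                 genotype_labels = genotype_labels(assignment, model),
                 value = value, values_by_env = values_by_env),
            class = "design_result")
}

# exact optimum over one epistasis component: chunked vectorized
# enumeration of the allowed genotype combinations in lexicographic order
# (QQ < Qq < qq), first optimum kept on ties
solve_component <- function(members, model, env, pref, sign) {
  k <- length(members)
  # effect rows touching only this component, pre-parsed
  rows <- list()
  add_rows <- function(df, cls, est) {
    for (r in seq_len(nrow(df))) {
      parts <- strsplit(df$term[r], " & ", fixed = TRUE)[[1]]
      if (!all(parts %in% members)) next
      rows[[length(rows) + 1L]] <<- list(
        class = cls[r], i = match(parts[1], members),
        j = if (length(parts) > 1) match(parts[2], members) else NA_integer_,
        est = est[r])
    }
  }
  gen <- model$coef_table[model$coef_table$class != "mu", , drop = FALSE]
  add_rows(gen, gen$class, gen$estimate)
  if (!is.null(env) && nrow(model$gxe_effects)) {
    ge <- model$gxe_effects[model$gxe_effects$env == env, , drop = FALSE]
    add_rows(ge, sub("e$", "", ge$class), ge$estimate)
  }

  n_comb <- length(pref)^k
  chunk <- 100000L
  best_val <- -Inf; best_codes <- NULL
  start <- 0L
  base <- length(pref)
  while (start < n_comb) {
    nn <- min(chunk, n_comb - start)
    idx <- start + seq_len(nn) - 1L
    # digit expansion, first member most significant -> lexicographic order
    G <- matrix(0L, nn, k)
    rem <- idx
    for (c in k:1) {
      G[, c] <- pref[rem %% base + 1L]
      rem <- rem %/% base
    }
    xA <- G - 1L; xD <- (G == 1L) * 1L
    val <- numeric(nn)
    for (rw in rows) {
      coefv <- switch(rw$class,
                      a = xA[, rw$i], d = xD[, rw$i],
                      aa = xA[, rw$i] * xA[, rw$j],
                      ad = xA[, rw$i] * xD[, rw$j],
                      da = xD[, rw$i] * xA[, rw$j],
                      dd = xD[, rw$i] * xD[, rw$j])
      val <- val + rw$est * coefv
    }
    m <- which.max(sign * val)
    if (sign * val[m] > best_val) {
      best_val <- sign * val[m]
      best_codes <- G[m, ]
    }
    start <- start + nn
  }
  stats::setNames(best_codes, members)
}

genotype_labels <- function(assignment, model) {
  vapply(names(assignment), function(l) {
    row <- match(l, model$snps$id)
    maj <- model$snps$major[row]; mnr <- model$snps$minor[row]
    if (is.na(maj) || is.na(mnr))
      return(c("qq", "Qq", "QQ")[assignment[l] + 1L])
    switch(as.character(assignment[l]),
           "2" = paste0(maj, maj), "1" = paste0(maj, mnr),
           "0" = paste0(mnr, mnr))
  }, "")
}

#' @export
print.design_result <- function(x, ...) {
  env_lab <- if (is.null(x$environment)) "" else
    paste0(" (environment ", x$environment, ")")
  cat(sprintf("%s design, objective %s%s: value %.4g\n", x$mode,
              x$objective, env_lab, x$value))
  cat("  ", paste(names(x$assignment), x$genotype_labels, sep = "=",
                  collapse = "  "), "\n")
  invisible(x)
}

#' Pleiotropy conflict report
#'
#' For every QTS appearing in at least two trait models, lists the
#' per-trait optimal genotype under each trait's design target and flags
#' QTSs whose optima disagree between traits.
#'
#' @param models named list (trait -> `qts_model`) with >= 2 traits.
#' @param targets named list (trait -> [design_target()]); defaults to
#'   the general superior line maximization for every trait.
#' @return Data frame with columns `qts`, `trait`, `genotype`, `code`,
#'   `conflict`.
#' @export
pleiotropy_conflict_report <- function(models, targets = NULL) {
  if (length(models) < 2) stop("need >= 2 trait models")
  traits <- names(models)
  if (is.null(targets))
    targets <- stats::setNames(
      replicate(length(models), design_target("GSL", "max"),
                simplify = FALSE), traits)
  designs <- lapply(traits, function(tr)
    design_superior(models[[tr]], targets[[tr]]))
  names(designs) <- traits
  rows <- do.call(rbind, lapply(traits, function(tr) {
    d <- designs[[tr]]
    data.frame(qts = names(d$assignment), trait = tr,
               genotype = d$genotype_labels, code = unname(d$assignment),
               stringsAsFactors = FALSE)
  }))
  shared <- names(which(table(unique(rows[, c("qts", "trait")])$qts) >= 2))
  rows <- rows[rows$qts %in% shared, , drop = FALSE]
  conflict_qts <- vapply(split(rows$code, rows$qts),
                         function(v) length(unique(v)) > 1, TRUE)
  rows$conflict <- conflict_qts[rows$qts]
  rownames(rows) <- NULL
  rows[order(rows$qts, rows$trait), ]
}

#' Write design results as TSV
#'
#' One row per QTS with the GSL/GSH assignments and, when environment-
#' specific designs are supplied, SL/SH columns per environment.
#'
#' @param designs named list of `design_result` objects (names like
#'   `"GSL"`, `"SL1"`, `"SH2"`, ...).
#' @param path output file path.
#' @param trait trait name recorded in the table.
#' @return `path`, invisibly.
#' @export
write_design_tsv <- function(designs, path, trait = "") {
  loci <- names(designs[[1]]$assignment)
  out <- data.frame(qts = loci, trait = trait, stringsAsFactors = FALSE)
  for (nm in names(designs))
    out[[nm]] <- designs[[nm]]$genotype_labels[loci]
  out$objective <- designs[[1]]$objective
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
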