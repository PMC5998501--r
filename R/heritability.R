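h2_classes <- c("a", "d", "aa", "ad", "da", "dd",
                "ae", "de", "aae", "ade", "dae", "dde")
h2_class_agg <- toupper(h2_classes)

#' Heritability report
#'
#' Per-effect heritabilities (percent of phenotypic variance) with their
#' class aggregates and the total broad-sense heritability. The class
#' aggregate equals the sum of its member effects and the total equals the
#' sum of the class aggregates.
#'
#' @param effects data frame with columns `term`, `class` (one of a, d,
#'   aa, ad, da, dd, ae, de, aae, ade, dae, dde) and `h2` (percent).
#' @param V_P phenotypic variance used as the denominator (optional,
#'   recorded for provenance).
#' @return A list of class `heritability_report` with `effects`,
#'   `aggregates` (named numeric over classes A...DDE), `h2_total`, `V_P`.
#' @export
heritability_report <- function(effects, V_P = NA_real_) {
  stopifnot(all(c("term", "class", "h2") %in% names(effects)))
  unknown <- setdiff(unique(effects$class), h2_classes)
  if (length(unknown))
    stop("unknown effect class: ", paste(unknown, collapse = ", "))
  if (any(effects$h2 < 0)) stop("heritabilities must be >= 0")
  agg <- vapply(h2_classes, function(cl)
    sum(effects$h2[effects$class == cl]), 0)
  names(agg) <- h2_class_agg
  structure(list(effects = effects, aggregates = agg,
                 h2_total = sum(agg), V_P = V_P),
            class = "heritability_report")
}

#' @export
print.heritability_report <- function(x, ...) {
  cat("Heritability partition (% of phenotypic variance):\n")
  nz <- x$aggregates[x$aggregates > 0]
  if (length(nz)) {
    for (nm in names(nz)) cat(sprintf("  h2_%-4s %6.2f\n", nm, nz[nm]))
  } else cat("  (no genetic components)\n")
  cat(sprintf("  h2_T   %6.2f\n", x$h2_total))
  invisible(x)
}

#' Heritability of a single effect
#'
#' For a fixed genetic effect of size `value` on coefficient column `x`,
#' the contribution to phenotypic variance is `value^2 * var(x)`
#' (population variance, equal accession weights); for a random
#' gene-environment class with estimated variance component `value`, it is
#' `value * mean(x^2)`. Both are reported as percentages of `V_P`.
#'
#' @param value effect estimate (fixed) or variance component (random).
#' @param x coefficient column over accessions.
#' @param V_P phenotypic variance (> 0).
#' @param random `TRUE` for a random (GxE) variance component.
#' @return h-squared in percent.
#' @export
effect_heritability <- function(value, x, V_P, random = FALSE) {
  if (V_P <= 0) stop("V_P must be > 0")
  v <- if (random) value * mean(x^2) else value^2 * mean((x - mean(x))^2)
  100 * v / V_P
}

#' Aggregate per-effect heritabilities
#'
#' Sums per-effect heritabilities into class aggregates and the total
#' broad-sense heritability h2_T.
#'
#' @param effects a `heritability_report`, or a data frame with columns
#'   `class` and `h2` (a `term` column is added when absent).
#' @return A `heritability_report`.
#' @export
aggregate_heritability <- function(effects) {
  if (inherits(effects, "heritability_report")) effects <- effects$effects
  effects <- as.data.frame(effects)
  if (!"term" %in% names(effects))
    effects$term <- if (nrow(effects))
      paste0("effect", seq_len(nrow(effects))) else character(0)
  heritability_report(effects[, c("term", "class", "h2")])
}

#' Heritability partition of a fitted QTS model
#'
#' Applies [effect_heritability()] to every fixed genetic effect and every
#' gene-environment variance component of a [fit_qts_model()] fit, with
#' V_P the variance of the environment-centered phenotypes (the
#' environment main effect is excluded from the denominator).
#'
#' With `method = "marginal"` (the convention of the field's effect
#' tables) each effect contributes its own variance and aggregates are
#' sums, which ignores covariances between non-orthogonal coefficient
#' columns — correlated QTSs can then double-count, and h2_T may exceed
#' 100. `method = "joint"` computes each fixed class's aggregate as the
#' variance of the class's summed contribution and h2_T from the total
#' genetic prediction, so covariances are accounted for.
#'
#' @param model a `qts_model`.
#' @param V_P override the phenotypic variance denominator.
#' @param method `"marginal"` or `"joint"` (fixed-effect covariances).
#' @return A `heritability_report`.
#' @export
heritability <- function(model, V_P = NULL, method = c("marginal", "joint")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "qts_model"))
  if (is.null(V_P)) V_P <- model$V_P
  ct <- model$coef_table
  gen <- ct[ct$class != "mu", , drop = FALSE]
  effs <- lapply(seq_len(nrow(gen)), function(r) {
    data.frame(term = gen$term[r], class = gen$class[r],
               h2 = effect_heritability(gen$estimate[r],
                                        model$X[, gen$name[r]], V_P),
               stringsAsFactors = FALSE)
  })
  vc <- model$varcomp[!model$varcomp$component %in% c("env", "residual"), ,
                      drop = FALSE]
  # the realized (posterior mean squared effect) variance is the robust
  # summary of a GxE component estimated from only a few environments
  vc_val <- if ("realized" %in% names(vc)) vc$realized else vc$estimate
  effs_r <- lapply(seq_len(nrow(vc)), function(r) {
    nm <- vc$component[r]
    cl <- sub(":.*$", "", nm)
    base_name <- sub("e:", ":", nm, fixed = TRUE)
    data.frame(term = sub("^[^:]*:", "", nm), class = cl,
               h2 = effect_heritability(vc_val[r],
                                        model$X[, base_name], V_P,
                                        random = TRUE),
               stringsAsFactors = FALSE)
  })
  effects <- do.call(rbind, c(effs, effs_r))
  if (is.null(effects))
    effects <- data.frame(term = character(), class = character(),
                          h2 = numeric())
  rep_marginal <- heritability_report(effects, V_P = V_P)
  if (method == "marginal") return(rep_marginal)

  # joint: class aggregates from the variance of summed contributions
  pvar <- function(v) mean((v - mean(v))^2)
  agg <- rep_marginal$aggregates
  total_fixed <- 0
  for (cl in c("a", "d", "aa", "ad", "da", "dd")) {
    rows <- gen[gen$class == cl, , drop = FALSE]
    contrib <- if (nrow(rows))
      drop(model$X[, rows$name, drop = FALSE] %*% rows$estimate) else 0
    agg[toupper(cl)] <- 100 * pvar(contrib) / V_P
    total_fixed <- total_fixed + contrib
  }
  gxe_total <- sum(agg[c("AE", "DE", "AAE", "ADE", "DAE", "DDE")])
  structure(list(effects = effects, aggregates = agg,
                 h2_total = 100 * pvar(total_fixed) / V_P + gxe_total,
                 V_P = V_P),
            class = "heritability_report")
}

#' Genotypic correlation between two fitted traits
#'
#' Pearson correlation, across accessions, of the total predicted genetic
#' values (main plus epistatic effects, no environment terms) of two QTS
#' models fitted on the same panel.
#'
#' @param model_a,model_b `qts_model` objects.
#' @param panel the shared [genotype_panel()].
#' @return r_g in \[-1, 1\].
#' @export
genotypic_correlation <- function(model_a, model_b, panel) {
  ga <- predict(model_a, panel)
  gb <- predict(model_b, panel)
  if (stats::var(ga) == 0 || stats::var(gb) == 0)
    stop("zero genetic variance in one of the traits")
  stats::cor(ga, gb)
}

#' Reference heritability partition for seven cottonseed traits
#'
#' Published class-level broad-sense heritability estimates (percent) for
#' cottonseed protein, oil and five fatty acids from a multi-environment
#' association study, shipped as a plain-text fixture. Used in examples
#' and for validating the aggregation identities (each trait's h2_T equals
#' the sum of its class components).
#'
#' @return Data frame with columns `trait`, the class aggregates `A`,
#'   `D`, `AA`, `AD`, `DA`, `DD`, `AE`, `DE`, `AAE`, `ADE` (NA where the
#'   class was not detected) and `T` (total).
#' @export
cottonseed_reference_classes <- function() {
  utils::read.table(system.file("extdata", "cottonseed_h2_classes.tsv",
                                package = "qtsmap"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Reference per-effect QTS table for cottonseed traits
#'
#' Published per-effect estimates (predicted effect, -log10 p and percent
#' heritability) for the significant QTSs of seven cottonseed traits,
#' shipped as a plain-text fixture; `qts` holds `"chrom_pos"` ids, with
#' `" & "` separating the members of an epistatic pair.
#'
#' @return Data frame with columns `trait`, `qts`, `chrom`, `alleles`,
#'   `effect_type`, `effect`, `neg_log10_p`, `h2`.
#' @export
cottonseed_reference_effects <- function() {
  utils::read.table(system.file("extdata", "cottonseed_qts_effects.tsv",
                                package = "qtsmap"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a heritability report as TSV
#'
#' @param report a `heritability_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_heritability_tsv <- function(report, path) {
  agg <- data.frame(term = "(all)", class = names(report$aggregates),
                    h2 = unname(report$aggregates))
  out <- rbind(report$effects,
               agg[agg$h2 > 0 | agg$class == "A", ],
               data.frame(term = "(all)", class = "T",
                          h2 = report$h2_total))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
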