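#' Genetic-effect coefficient coding
#'
#' Converts 0/1/2 genotype codes into the coefficient columns of the full
#' genetic model: for each locus the additive coefficient
#' \eqn{x_A = 1, 0, -1} for QQ, Qq, qq and the dominance coefficient
#' \eqn{x_D = 0, 1, 0}, where Q is the designated (major) allele. Digenic
#' epistasis coefficients are the elementwise products
#' \eqn{x_{AA} = x_{A_i} x_{A_j}}, \eqn{x_{AD} = x_{A_i} x_{D_j}},
#' \eqn{x_{DA} = x_{D_i} x_{A_j}}, \eqn{x_{DD} = x_{D_i} x_{D_j}}; the
#' environment-interaction coefficients equal the matching x-coefficients.
#'
#' Panels are recoded so that Q is the major allele: columns whose Q-allele
#' frequency falls below 0.5 are flipped (codes mapped 0 <-> 2) before
#' coding, so effect signs are relative to the major-allele homozygote.
#'
#' @param panel a [genotype_panel()].
#' @param recode_major if `TRUE` (default), designate the major allele as Q.
#' @return An object of class `coded_genotypes`: list with matrices `xA`
#'   and `xD` (accessions x loci), the SNP metadata, and a record of which
#'   columns were flipped. Monomorphic loci are coded (with a warning) but
#'   carry no information.
#' @export
code_genotypes <- function(panel, recode_major = TRUE) {
  codes <- panel$codes
  snps <- panel$snps
  flipped <- rep(FALSE, ncol(codes))
  if (recode_major) {
    f <- colMeans(codes, na.rm = TRUE) / 2
    flipped <- !is.na(f) & f < 0.5
    if (any(flipped)) {
      codes[, flipped] <- 2L - codes[, flipped]
      maj <- snps$major[flipped]
      snps$major[flipped] <- snps$minor[flipped]
      snps$minor[flipped] <- maj
    }
  }
  mono <- apply(codes, 2, function(g) length(unique(g[!is.na(g)])) < 2)
  if (any(mono))
    warning(sum(mono), " monomorphic locus/loci: coding defined but uninformative")
  xA <- codes - 1
  xD <- (codes == 1L) * 1
  structure(list(xA = xA, xD = xD, snps = snps, flipped = flipped,
                 accessions = rownames(panel$codes)),
            class = "coded_genotypes")
}

#' @export
print.coded_genotypes <- function(x, ...) {
  cat("Coded genotypes:", nrow(x$xA), "accessions x", ncol(x$xA), "loci;",
      sum(x$flipped), "column(s) flipped to major-allele coding\n")
  invisible(x)
}

#' Epistasis coefficient columns for a locus pair
#'
#' @param coded a [code_genotypes()] result.
#' @param i,j locus indices or SNP ids, `i != j`.
#' @return A 4-column matrix with columns `aa`, `ad`, `da`, `dd`.
#' @export
pair_columns <- function(coded, i, j) {
  i <- locus_index(coded, i); j <- locus_index(coded, j)
  if (i == j) stop("epistasis requires two distinct loci")
  cbind(aa = coded$xA[, i] * coded$xA[, j],
        ad = coded$xA[, i] * coded$xD[, j],
        da = coded$xD[, i] * coded$xA[, j],
        dd = coded$xD[, i] * coded$xD[, j])
}

locus_index <- function(coded, i) {
  if (is.character(i)) {
    k <- match(i, coded$snps$id)
    if (is.na(k)) stop("unknown SNP id: ", i)
    k
  } else as.integer(i)
}
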