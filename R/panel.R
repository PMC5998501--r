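#' Genotype panel
#'
#' Container for a biallelic SNP panel: an accession-by-SNP matrix of
#' genotype codes counting copies of the designated Q allele (0, 1, 2, or
#' `NA` for missing), together with per-SNP chromosome/position metadata and
#' optional sequencing depth and subpopulation labels.
#'
#' SNP identifiers follow the `<chromosome>_<position>` convention
#' (e.g. `"A3_115443958"`); positions are 1-based and strictly increasing
#' within a chromosome.
#'
#' @param codes integer matrix, accessions in rows, SNPs in columns; entries
#'   in \{0, 1, 2, `NA`\}.
#' @param chrom character vector of chromosome names, one per SNP.
#' @param pos integer vector of 1-based physical positions, one per SNP.
#' @param accessions character vector of accession identifiers; defaults to
#'   `acc1 ... accN`.
#' @param major,minor optional character vectors of major/minor allele
#'   nucleotides per SNP (used to render genotype labels such as `"AG"`).
#' @param depth optional numeric vector of total sequencing depth per SNP.
#' @param subpop optional vector of subpopulation labels per accession.
#' @return An object of class `genotype_panel` with elements `codes`,
#'   `snps` (data frame: `id`, `chrom`, `pos`, `major`, `minor`), `depth`
#'   and `subpop`.
#' @export
genotype_panel <- function(codes, chrom, pos, accessions = NULL,
                           major = NULL, minor = NULL,
                           depth = NULL, subpop = NULL) {
  codes <- as.matrix(codes)
  m <- ncol(codes)
  n <- nrow(codes)
  pos <- as.integer(pos)
  if (length(chrom) != m || length(pos) != m)
    stop("chrom/pos must have one entry per SNP column")
  bad <- !(codes %in% c(0L, 1L, 2L) | is.na(codes))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  if (is.null(accessions)) accessions <- paste0("acc", seq_len(n))
  if (is.null(major)) major <- rep(NA_character_, m)
  if (is.null(minor)) minor <- rep(NA_character_, m)
  snps <- data.frame(
    id = paste(chrom, pos, sep = "_"),
    chrom = as.character(chrom), pos = as.integer(pos),
    major = as.character(major), minor = as.character(minor),
    stringsAsFactors = FALSE
  )
  # positions must be strictly increasing within each chromosome
  for (ch in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  if (!is.null(depth) && length(depth) != m)
    stop("depth must have one entry per SNP")
  if (!is.null(subpop) && length(subpop) != n)
    stop("subpop must have one label per accession")
  rownames(codes) <- accessions
  colnames(codes) <- snps$id
  structure(
    list(codes = codes, snps = snps, depth = depth, subpop = subpop),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("Genotype panel:", nrow(x$codes), "accessions x", ncol(x$codes),
      "SNPs on", length(unique(x$snps$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$codes))
  cat(sprintf("  missing rate %.3f", miss))
  if (!is.null(x$subpop))
    cat(";  subpopulations:", paste(names(table(x$subpop)),
                                    table(x$subpop), collapse = ", "))
  cat("\n")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$codes)

n_accessions <- function(panel) nrow(panel$codes)
n_snps <- function(panel) ncol(panel$codes)

#' Subset a genotype panel by SNP index
#'
#' @param panel a [genotype_panel()].
#' @param keep integer or logical index of SNP columns to retain.
#' @return A `genotype_panel` with the selected SNPs (accession set,
#'   subpopulation labels and, where present, depth metadata preserved).
#' @export
subset_snps <- function(panel, keep) {
  genotype_panel(
    panel$codes[, keep, drop = FALSE],
    chrom = panel$snps$chrom[keep], pos = panel$snps$pos[keep],
    accessions = rownames(panel$codes),
    major = panel$snps$major[keep], minor = panel$snps$minor[keep],
    depth = if (!is.null(panel$depth)) panel$depth[keep],
    subpop = panel$subpop
  )
}

#' Minor allele frequency per SNP
#'
#' Empirical frequency of the less common allele, computed over non-missing
#' codes (codes count Q-allele copies).
#'
#' @param panel a [genotype_panel()].
#' @return Numeric vector of MAF values, one per SNP.
#' @export
maf <- function(panel) {
  f <- colMeans(panel$codes, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Read/write a genotype panel as a TSV matrix
#'
#' The dialect has one row per SNP with columns `chrom`, `pos`, `id`,
#' optionally `depth`, then one 0/1/2/NA column per accession.
#'
#' @param panel a [genotype_panel()].
#' @param path file path.
#' @return `read_panel_tsv` returns a `genotype_panel`; `write_panel_tsv`
#'   returns `path` invisibly.
#' @export
write_panel_tsv <- function(panel, path) {
  df <- data.frame(chrom = panel$snps$chrom, pos = panel$snps$pos,
                   id = panel$snps$id, stringsAsFactors = FALSE)
  if (!is.null(panel$depth)) df$depth <- panel$depth
  geno <- t(panel$codes)
  colnames(geno) <- rownames(panel$codes)
  utils::write.table(cbind(df, geno), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- intersect(c("chrom", "pos", "id", "depth"), names(df))
  acc <- setdiff(names(df), meta_cols)
  codes <- t(as.matrix(df[, acc, drop = FALSE]))
  genotype_panel(codes, chrom = df$chrom, pos = df$pos, accessions = acc,
                 depth = if ("depth" %in% meta_cols) df$depth)
}

#' Write a genotype panel as a minimal biallelic VCF
#'
#' Emits a VCFv4.2 file with GT fields only. Code 2 (two Q = major alleles)
#' is written as `0/0` with REF = major allele, code 1 as `0/1`, code 0 as
#' `1/1`, and missing as `./.`. SNPs without allele metadata use `A`/`T`.
#'
#' @param panel a [genotype_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(panel$codes)),
                     collapse = "\t")), con)
  ref <- ifelse(is.na(panel$snps$major), "A", panel$snps$major)
  alt <- ifelse(is.na(panel$snps$minor), "T", panel$snps$minor)
  gt_map <- c("1/1", "0/1", "0/0")  # codes 0,1,2
  for (j in seq_len(ncol(panel$codes))) {
    g <- panel$codes[, j]
    gt <- ifelse(is.na(g), "./.", gt_map[g + 1L])
    writeLines(paste(c(panel$snps$chrom[j], panel$snps$pos[j],
                       panel$snps$id[j], ref[j], alt[j], ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a biallelic VCF into a genotype panel
#'
#' Uses vcfR when available, otherwise a plain-text fallback for
#' GT-only VCFs such as those produced by [write_panel_vcf()]. Codes count
#' REF (= major) allele copies.
#'
#' @param path VCF file path.
#' @return A [genotype_panel()].
#' @export
read_panel_vcf <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    count_ref <- function(s) {
      ifelse(is.na(s) | s %in% c("./.", ".|."), NA_integer_,
             2L - (as.integer(substr(s, 1, 1)) + as.integer(substr(s, 3, 3))))
    }
    codes <- t(apply(gt, 2, count_ref))
    if (ncol(v@gt) - 1L == 1L) codes <- matrix(codes, nrow = 1)
    fix <- vcfR::getFIX(v)
    genotype_panel(codes, chrom = fix[, "CHROM"],
                   pos = as.integer(fix[, "POS"]),
                   accessions = colnames(v@gt)[-1],
                   major = fix[, "REF"], minor = fix[, "ALT"])
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "##")]
    header <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
    body <- strsplit(lines[-1], "\t")
    fields <- do.call(rbind, body)
    acc <- header[-(1:9)]
    gt <- fields[, -(1:9), drop = FALSE]
    gt <- substr(gt, 1, 3)
    codes <- matrix(NA_integer_, nrow = length(acc), ncol = nrow(fields))
    for (j in seq_len(nrow(fields))) {
      s <- gt[j, ]
      ok <- !(s %in% c("./.", ".|."))
      codes[ok, j] <- 2L - (as.integer(substr(s[ok], 1, 1)) +
                              as.integer(substr(s[ok], 3, 3)))
    }
    genotype_panel(codes, chrom = fields[, 1], pos = as.integer(fields[, 2]),
                   accessions = acc, major = fields[, 4], minor = fields[, 5])
  }
}

#' Phenotype table constructor and I/O
#'
#' A phenotype table is a long-format data frame with columns `accession`,
#' `env` (environment id, numbered consecutively from 1), `rep` (replicate
#' id), `trait` and `value`. Each (accession, env, rep) combination appears
#' at most once per trait.
#'
#' @param accession,env,rep,trait,value column vectors of equal length.
#' @return A data frame of class `phenotype_table`.
#' @export
phenotype_table <- function(accession, env, rep, trait, value) {
  df <- data.frame(accession = as.character(accession),
                   env = as.integer(env), rep = as.integer(rep),
                   trait = as.character(trait), value = as.numeric(value),
                   stringsAsFactors = FALSE)
  key <- paste(df$accession, df$env, df$rep, df$trait)
  if (anyDuplicated(key))
    stop("duplicate (accession, env, rep, trait) rows in phenotype table")
  envs <- sort(unique(df$env))
  if (!identical(envs, seq_along(envs)))
    stop("environments must be numbered consecutively from 1")
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' @rdname phenotype_table
#' @param path file path for TSV serialization.
#' @export
write_phenotypes_tsv <- function(pheno, path) {
  utils::write.table(as.data.frame(pheno), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname phenotype_table
#' @param pheno a `phenotype_table`.
#' @export
read_phenotypes_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  phenotype_table(df$accession, df$env, df$rep, df$trait, df$value)
}
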