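# Plain-text readers/writers for the pipeline's tabular interfaces.

#' Read and write count tables, catalogs and profiles as TSV
#'
#' Count tables and species profiles are written with samples in rows and
#' a leading `sample` column; the catalog is written as-is. All files are
#' tab-separated with a one-line header.
#'
#' @param x matrix or data.frame to write.
#' @param path file path.
#' @return readers return a matrix (counts/profile) or data.frame
#'   (catalog); writers return the path invisibly.
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(sample = rownames(x), as.data.frame(x),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample
  m
}

#' @rdname write_count_table
#' @export
write_catalog <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_catalog <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Export a species profile as sparse triplet TSV
#'
#' BIOM-compatible sparse representation: one `sample`, `species`,
#' `abundance` row per non-zero cell.
#'
#' @param profile species profile matrix (percent).
#' @param path file path.
#' @export
write_profile_triplets <- function(profile, path) {
  nz <- which(profile > 0, arr.ind = TRUE)
  df <- data.frame(sample = rownames(profile)[nz[, 1]],
                   species = colnames(profile)[nz[, 2]],
                   abundance = profile[nz])
  df <- df[order(df$sample, df$species), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Genotype dosage TSV and minimal VCF writers
#'
#' The TSV has samples in rows (leading `sample` column) and SNPs in
#' columns. The VCF writer emits a minimal VCFv4.2 file with GT-only
#' genotypes (dosage 0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`), one record per
#' SNP.
#'
#' @param genotypes n x m dosage matrix.
#' @param snp_info data.frame with `snp`, `chr`, `bp`, `ea`, `nea`
#'   (effect allele written as ALT).
#' @param path file path.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  write_count_table(genotypes, path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  read_count_table(path)
}

#' @rdname write_genotypes_tsv
#' @export
write_vcf <- function(genotypes, snp_info, path) {
  ids <- rownames(genotypes) %||% sprintf("S%d", seq_len(nrow(genotypes)))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", ids), collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  idx <- match(colnames(genotypes), snp_info$snp)
  body <- vapply(seq_len(ncol(genotypes)), function(j) {
    i <- idx[j]
    paste(c(snp_info$chr[i], snp_info$bp[i], snp_info$snp[i],
            snp_info$nea[i], snp_info$ea[i], ".", "PASS", ".", "GT",
            gt_code[genotypes[, j] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read and write GWAS summary statistics TSV
#'
#' The dialect uses the column order `SNP, CHR, BP, EA, NEA, EAF, BETA,
#' SE, P, N`; the reader accepts the same and returns lower-case column
#' names as used throughout the package.
#'
#' @param records GWAS records data.frame (as from [gwas_linear()]).
#' @param path file path.
#' @export
write_sumstats <- function(records, path) {
  out <- data.frame(SNP = records$snp, CHR = records$chr,
                    BP = records$bp, EA = records$ea, NEA = records$nea,
                    EAF = records$eaf, BETA = records$beta,
                    SE = records$se, P = records$p, N = records$n)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  stats::setNames(df[, c("snp", "chr", "bp", "ea", "nea", "eaf", "beta",
                         "se", "p", "n")],
                  c("snp", "chr", "bp", "ea", "nea", "eaf", "beta", "se",
                    "p", "n"))
}

#' Read and write a simulation configuration
#'
#' Serialized as YAML key-value pairs mirroring the [sim_config()]
#' arguments; `effect_table` is stored as a list of records.
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$effect_table)) {
    x$effect_table <- lapply(seq_len(nrow(x$effect_table)), function(i) {
      as.list(x$effect_table[i, ])
    })
  }
  x$plate <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$effect_table)) {
    x$effect_table <- do.call(rbind, lapply(x$effect_table, as.data.frame))
  }
  if (!is.null(x$maf_range)) x$maf_range <- as.numeric(x$maf_range)
  do.call(sim_config, x)
}
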