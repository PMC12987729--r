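# Species quantification from signature-gene read counts.
#
# The quantification model: within a species and sample, the read count of
# signature gene g is negative binomial with mean proportional to its
# effective length and size (dispersion) parameter log2(effective length).
# Genes whose observed count falls outside the central 99% of that
# distribution are treated as cross-mapping/outlier artifacts and excluded
# before abundance estimation.

#' Classify paired-end alignment records against the gene catalog
#'
#' Applies the unique/multi/unmapped read-pair classification used to build
#' the gene count table. An individual read is uniquely mapped when its
#' mapping quality is at least 20, it aligned with at least 95% identity
#' over at least 100 bp, and at most 10 of its bases failed to align.
#' Reads meeting the identity/length/unaligned criteria but not the MAPQ
#' threshold are multi-mapped; all other reads are unmapped. A pair is
#' counted as uniquely mapped to a gene if either read is unique (read one
#' wins when both are unique to different genes), multi-mapped if neither
#' read is unique but at least one is multi-mapped, and unmapped otherwise.
#'
#' @param records data.frame with one row per read pair and columns
#'   `mapq1`, `identity1`, `aligned1`, `unaligned1`, `gene1` and the same
#'   five fields suffixed `2`. `gene*` may be `NA` for unaligned reads;
#'   identities are fractions in `[0, 1]`, lengths are base pairs.
#' @return list with `pairs`, a data.frame of per-pair `label`
#'   (`"unique"`, `"multi"` or `"unmapped"`) and `gene` (the counted gene or
#'   `NA`), and `counts`, a named integer vector of unique read-pair counts
#'   per gene.
#' @export
classify_read_pairs <- function(records) {
  records <- as.data.frame(records)
  need <- as.vector(outer(c("mapq", "identity", "aligned", "unaligned",
                            "gene"), 1:2, paste0))
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stopf("records missing columns: %s", paste(miss, collapse = ", "))
  }

  read_status <- function(mapq, identity, aligned, unaligned) {
    crit <- !is.na(identity) & identity >= 0.95 & aligned >= 100 &
      unaligned <= 10
    ifelse(crit & mapq >= 20, "unique", ifelse(crit, "multi", "unmapped"))
  }
  s1 <- read_status(records$mapq1, records$identity1, records$aligned1,
                    records$unaligned1)
  s2 <- read_status(records$mapq2, records$identity2, records$aligned2,
                    records$unaligned2)

  label <- ifelse(s1 == "unique" | s2 == "unique", "unique",
                  ifelse(s1 == "multi" | s2 == "multi", "multi", "unmapped"))
  gene <- ifelse(s1 == "unique", records$gene1,
                 ifelse(s2 == "unique", records$gene2, NA_character_))
  gene[label != "unique"] <- NA_character_

  counts <- table(gene[!is.na(gene)])
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(pairs = data.frame(label = label, gene = gene,
                          stringsAsFactors = FALSE),
       counts = counts)
}

#' Negative-binomial admissibility bounds for signature genes
#'
#' Given the total signature-gene read count of a species in one sample,
#' computes for each gene the expected count (proportional to effective
#' length), the central 99% quantile bounds (0.5% to 99.5%, inclusive) of
#' the negative binomial distribution with that mean and size
#' `log2(effective length)`, and the probability of observing a non-zero
#' count.
#'
#' @param effective_lengths numeric vector of effective gene lengths (bp,
#'   each >= 1). Lengths below 2 would give a size below 1; these are
#'   clamped to size 1 and counted in the `clamped` attribute.
#' @param total_count total signature-gene read count for the species in
#'   the sample (>= 0).
#' @return data.frame with columns `mean`, `size`, `lower`, `upper`,
#'   `p_nonzero`; attribute `clamped` gives the number of size-clamped
#'   genes.
#' @export
nb_gene_bounds <- function(effective_lengths, total_count) {
  if (any(effective_lengths < 1)) stopf("effective lengths must be >= 1")
  check_number(total_count, "total_count", lower = 0)
  L <- as.numeric(effective_lengths)
  mu <- total_count * L / sum(L)
  size <- log2(L)
  clamped <- sum(size < 1)
  size <- pmax(size, 1)
  if (total_count == 0) {
    out <- data.frame(mean = mu, size = size, lower = 0, upper = 0,
                      p_nonzero = 0)
  } else {
    out <- data.frame(
      mean = mu, size = size,
      lower = stats::qnbinom(0.005, size = size, mu = mu),
      upper = stats::qnbinom(0.995, size = size, mu = mu),
      p_nonzero = 1 - stats::dnbinom(0, size = size, mu = mu))
  }
  attr(out, "clamped") <- clamped
  out
}

# Quantify one species in one sample. Returns list(abundance, flag) where
# abundance is on the count-per-effective-bp scale (pre-normalization).
quantify_species_sample <- function(cnt, leff) {
  if (length(cnt) == 0) return(list(abundance = 0, flag = "no_genes"))
  total <- sum(cnt)
  if (total == 0) return(list(abundance = 0, flag = "observed_zero"))
  b <- nb_gene_bounds(leff, total)

  considered <- rep(TRUE, length(cnt))
  # Zero-ignoring rule: with >=50 non-zero genes and >=99% of genes
  # expected non-zero under the model, zero-count genes are dropped.
  if (sum(cnt > 0) >= 50 && mean(b$p_nonzero) >= 0.99) {
    considered <- cnt > 0
  }
  within <- cnt >= b$lower & cnt <= b$upper
  admitted <- considered & within
  nz_within <- considered & within & cnt > 0

  if (sum(nz_within) < 5) {
    return(list(abundance = 0, flag = "zeroed_lt5"))
  }
  if (sum(nz_within) / sum(considered) < 0.66) {
    lc <- cnt / leff
    if (stats::median(lc) > 0) {
      return(list(abundance = stats::median(lc[cnt > 0]),
                  flag = "median_fallback"))
    }
    return(list(abundance = 0, flag = "zeroed_lt66"))
  }
  list(abundance = mean(cnt[admitted] / leff[admitted]), flag = "ok")
}

#' Estimate species relative abundances from a gene count table
#'
#' Implements the signature-gene quantification rules in order: (1) the
#' zero-ignoring rule (zero-count genes are dropped when at least 50
#' signature genes are non-zero and at least 99% of genes are expected
#' non-zero given the species total); (2) the negative-binomial 99%
#' quantile filter from [nb_gene_bounds()]; (3) abundance as the mean
#' length-normalized count over admitted genes; (4) abundance zero when
#' fewer than five non-zero genes lie within the quantile bounds; (5) when
#' fewer than 66% of considered genes have non-zero counts within bounds
#' the species is zeroed unless the median length-corrected abundance over
#' its signature genes is non-zero, in which case the median over non-zero
#' genes is used; (6) sample-wise normalization so species abundances sum
#' to 100%.
#'
#' @param counts integer matrix, samples in rows, genes in columns; column
#'   names must be gene ids present in `catalog`.
#' @param catalog gene catalog data.frame as produced by
#'   [generate_catalog()] (columns `gene_id`, `species`, `length`,
#'   `effective_length`, `signature`, `ko`). Only signature genes are used.
#' @return numeric matrix samples x species of relative abundances in
#'   percent (rows sum to 100, or 0 for empty samples), with a character
#'   attribute matrix `flag` recording which rule produced each cell
#'   (`"ok"`, `"observed_zero"`, `"zeroed_lt5"`, `"zeroed_lt66"`,
#'   `"median_fallback"`, `"no_genes"`).
#' @export
estimate_abundances <- function(counts, catalog) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stopf("counts must have gene column names")
  sig <- catalog[catalog$signature, , drop = FALSE]
  species <- sort(unique(catalog$species))
  n <- nrow(counts)
  raw <- matrix(0, n, length(species),
                dimnames = list(rownames(counts), species))
  flag <- matrix("no_genes", n, length(species),
                 dimnames = dimnames(raw))
  for (sp in species) {
    genes <- sig$gene_id[sig$species == sp]
    genes <- genes[genes %in% colnames(counts)]
    if (length(genes) == 0) {
      warning(sprintf("species %s has no signature genes in the count table",
                      sp), call. = FALSE)
      next
    }
    leff <- sig$effective_length[match(genes, sig$gene_id)]
    sub <- counts[, genes, drop = FALSE]
    for (s in seq_len(n)) {
      q <- quantify_species_sample(as.numeric(sub[s, ]), leff)
      raw[s, sp] <- q$abundance
      flag[s, sp] <- q$flag
    }
  }
  tot <- rowSums(raw)
  prof <- raw
  nz <- tot > 0
  prof[nz, ] <- 100 * raw[nz, , drop = FALSE] / tot[nz]
  attr(prof, "flag") <- flag
  class(prof) <- c("species_profile", class(prof))
  prof
}

#' Rarefy a count table and re-estimate abundances
#'
#' Draws a fixed number of signature-gene read units per sample without
#' replacement (multivariate hypergeometric subsampling of the per-gene
#' count multiset), then re-runs [estimate_abundances()] on the rarefied
#' table. Samples with fewer total signature-gene counts than `target` are
#' excluded and reported in the `excluded` attribute.
#'
#' @param counts samples x genes count matrix.
#' @param catalog gene catalog; only signature genes are subsampled.
#' @param target number of signature-gene counts to draw per sample
#'   (default 164245, the rarefaction depth used for alpha-diversity).
#' @param seed integer seed; rarefaction is deterministic given the seed.
#' @return species profile as in [estimate_abundances()], with attributes
#'   `excluded` (character vector of dropped sample names) and
#'   `rarefied_counts` (the subsampled signature-gene count matrix).
#' @export
rarefy_profile <- function(counts, catalog, target = 164245, seed = 1) {
  check_number(target, "target", lower = 1)
  counts <- as.matrix(counts)
  sig_genes <- intersect(colnames(counts),
                         catalog$gene_id[catalog$signature])
  sub <- counts[, sig_genes, drop = FALSE]
  totals <- rowSums(sub)
  keep <- totals >= target
  excluded <- rownames(sub)[!keep]
  rare <- with_seed(seed, {
    out <- sub[keep, , drop = FALSE]
    for (s in seq_len(nrow(out))) {
      cnt <- out[s, ]
      if (sum(cnt) == target) next
      # expand the count multiset and subsample without replacement
      units <- rep.int(seq_along(cnt), cnt)
      drawn <- sample(units, target, replace = FALSE)
      out[s, ] <- tabulate(drawn, nbins = length(cnt))
    }
    out
  })
  prof <- estimate_abundances(rare, catalog)
  attr(prof, "excluded") <- excluded
  attr(prof, "rarefied_counts") <- rare
  prof
}

#' Alpha diversity of a species profile
#'
#' Shannon index (natural log) and richness per sample, computed from
#' relative abundances.
#'
#' @param profile species profile matrix in percent (rows sum to 100 or 0).
#' @return data.frame with columns `sample`, `shannon` (nats), `richness`.
#' @export
alpha_diversity <- function(profile) {
  p <- as.matrix(profile) / 100
  shannon <- apply(p, 1, function(row) {
    row <- row[row > 0]
    if (length(row) == 0) return(0)
    -sum(row * log(row))
  })
  data.frame(sample = rownames(p) %||% as.character(seq_len(nrow(p))),
             shannon = unname(shannon),
             richness = unname(rowSums(p > 0)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' KEGG orthology functional profile
#'
#' Per-sample proportion of total length-normalized gene abundance carried
#' by genes annotated to each KO. All catalog genes contribute to the
#' denominator; unannotated genes dilute the KO proportions, so per-sample
#' KO sums are at most 1.
#'
#' @param counts samples x genes count matrix.
#' @param catalog gene catalog with `ko` column (`NA` for unannotated
#'   genes).
#' @return samples x KO matrix of proportions in `[0, 1]`.
#' @export
ko_profile <- function(counts, catalog) {
  counts <- as.matrix(counts)
  idx <- match(colnames(counts), catalog$gene_id)
  if (anyNA(idx)) stopf("count table contains genes absent from the catalog")
  ab <- sweep(counts, 2, catalog$effective_length[idx], "/")
  total <- rowSums(ab)
  kos <- sort(unique(stats::na.omit(catalog$ko[idx])))
  out <- matrix(0, nrow(counts), length(kos),
                dimnames = list(rownames(counts), kos))
  for (k in kos) {
    cols <- which(!is.na(catalog$ko[idx]) & catalog$ko[idx] == k)
    out[, k] <- rowSums(ab[, cols, drop = FALSE])
  }
  nz <- total > 0
  out[nz, ] <- out[nz, , drop = FALSE] / total[nz]
  out
}

#' Prevalence filter for downstream association analysis
#'
#' Keeps traits (species or modules) present — abundance strictly positive —
#' in at least `min_prevalence` of samples.
#'
#' @param profile samples x traits abundance matrix.
#' @param min_prevalence minimum fraction of samples with non-zero
#'   abundance (default 0.30).
#' @return the filtered matrix.
#' @export
prevalence_filter <- function(profile, min_prevalence = 0.30) {
  keep <- colMeans(as.matrix(profile) > 0) >= min_prevalence
  profile[, keep, drop = FALSE]
}
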