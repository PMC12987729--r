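# Shared small fixtures, built once per test run.

small_cfg <- function(seed = 101, ...) {
  sim_config(seed = seed, n_samples = 40, n_species = 8,
             genes_per_species = 80, depth = 4e4, outlier_gene_rate = 0,
             n_snps = 30, ...)
}

small_cohort <- local({
  coh <- NULL
  function() {
    if (is.null(coh)) coh <<- simulate_cohort(small_cfg())
    coh
  }
})

# one alignment-record row builder
rec <- function(mapq1 = 30, id1 = 0.99, len1 = 140, un1 = 0,
                gene1 = "gA", mapq2 = 30, id2 = 0.99, len2 = 140,
                un2 = 0, gene2 = "gB") {
  data.frame(mapq1 = mapq1, identity1 = id1, aligned1 = len1,
             unaligned1 = un1, gene1 = gene1, mapq2 = mapq2,
             identity2 = id2, aligned2 = len2, unaligned2 = un2,
             gene2 = gene2, stringsAsFactors = FALSE)
}

# minimal catalog for hand-built count tables: one row per gene
toy_catalog <- function(species, lengths, kos = NA_character_,
                        signature = TRUE) {
  n <- length(lengths)
  data.frame(gene_id = sprintf("%s_g%02d", species, seq_len(n)),
             species = species, length = lengths,
             effective_length = pmax(lengths - 99, 1),
             prevalence = 1, unique = TRUE,
             signature = rep_len(signature, n),
             ko = rep_len(kos, n), stringsAsFactors = FALSE)
}
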