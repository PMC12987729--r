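# Synthetic cohort generator with known ground truth.
#
# The generative model mirrors the statistical assumptions of the
# quantification and association methods: species compositions are
# heavy-tailed log-normal on a latent log-abundance scale; per-gene read
# counts are negative binomial with mean proportional to composition times
# effective gene length; genotypes are biallelic in Hardy-Weinberg
# equilibrium with optional copy-with-mutation LD blocks; genetic and
# BMI-like causal effects act additively on the latent log scale before
# closure (renormalization to proportions).

#' Simulation configuration
#'
#' Collects and validates every tunable of the synthetic cohort
#' generator. Effect sizes in `effect_table` and `bmi_effects` are
#' expressed in within-sample latent-log standard deviation units per
#' allele (respectively per BMI s.d.), so that — up to the closure
#' attenuation discussed in the vignette — they are approximately the
#' betas recovered on the IRNT scale downstream.
#'
#' @param seed integer RNG seed; a fixed seed makes every generator
#'   byte-identical.
#' @param n_samples,n_species,n_snps cohort dimensions.
#' @param genes_per_species pangenome genes generated per species.
#' @param depth expected signature-gene read pairs per sample.
#' @param outlier_gene_rate fraction of gene-sample cells inflated.
#' @param outlier_fold multiplicative count inflation for outlier cells
#'   (> 1).
#' @param maf_range interval in (0, 0.5] for block minor allele
#'   frequencies.
#' @param ld_block_size SNPs per LD block (1 = independent SNPs).
#' @param ld_mut within-block copy-mutation rate (adjacent-SNP allele
#'   correlation is `1 - ld_mut`).
#' @param effect_table data.frame (`snp`, `species`, `beta`) of planted
#'   per-allele SNP effects, or NULL.
#' @param bmi_effects numeric vector (length `n_species`) of causal
#'   effects of the BMI-like trait on species, or NULL.
#' @param bmi_instruments list(`n`, `beta`): the first `n` SNPs receive
#'   per-allele effects `beta` (scalar or vector recycled to `n`, in BMI
#'   s.d. units) on the BMI-like trait, providing genetic instruments for
#'   Mendelian randomization. Varied magnitudes (as observed for real
#'   complex-trait instruments) are needed for MR-Egger to be identified.
#' @param disease_model list(`species`, `intercept`, `slope`): binary
#'   disease sampled from `plogis(intercept + slope * z)` where `z` is the
#'   standardized abundance of the named species, or NULL.
#' @param comp_meanlog_sd between-species spread of mean log abundances.
#' @param comp_sdlog within-sample (between-subject) latent log-abundance
#'   standard deviation.
#' @param n_kos,n_modules size of the generated KO pool and KEGG module
#'   set.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_samples = 500, n_species = 50,
                       genes_per_species = 100, depth = 1e5,
                       outlier_gene_rate = 0.005, outlier_fold = 50,
                       maf_range = c(0.05, 0.5), n_snps = 200,
                       ld_block_size = 1, ld_mut = 0.1,
                       effect_table = NULL, bmi_effects = NULL,
                       bmi_instruments = list(n = 0, beta = 0),
                       disease_model = NULL,
                       comp_meanlog_sd = 1.5, comp_sdlog = 1.0,
                       n_kos = 5 * n_species, n_modules = 20) {
  check_number(seed, "seed", 0, .Machine$integer.max)
  check_number(n_samples, "n_samples", 1)
  check_number(n_species, "n_species", 1)
  check_number(genes_per_species, "genes_per_species", 1)
  check_number(depth, "depth", 0)
  check_number(outlier_gene_rate, "outlier_gene_rate", 0, 1)
  check_number(outlier_fold, "outlier_fold", 1)
  check_number(n_snps, "n_snps", 1)
  check_number(ld_block_size, "ld_block_size", 1)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stopf("maf_range must be an interval within (0, 0.5]")
  }
  if (!is.null(bmi_effects) && length(bmi_effects) != n_species) {
    stopf("bmi_effects must have one entry per species")
  }
  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              n_species = as.integer(n_species),
              genes_per_species = as.integer(genes_per_species),
              depth = depth, outlier_gene_rate = outlier_gene_rate,
              outlier_fold = outlier_fold, maf_range = maf_range,
              n_snps = as.integer(n_snps),
              ld_block_size = as.integer(ld_block_size), ld_mut = ld_mut,
              effect_table = effect_table, bmi_effects = bmi_effects,
              bmi_instruments = bmi_instruments,
              disease_model = disease_model,
              comp_meanlog_sd = comp_meanlog_sd, comp_sdlog = comp_sdlog,
              n_kos = as.integer(n_kos), n_modules = as.integer(n_modules))
  class(cfg) <- "sim_config"
  cfg
}

species_ids <- function(n) sprintf("sp%03d", seq_len(n))
snp_ids <- function(n) sprintf("rs%05d", seq_len(n))

#' Generate a gene catalog and KEGG module definitions
#'
#' Per species, draws `genes_per_species` pangenome genes with log-normal
#' lengths, MAG prevalences and a uniqueness flag, then applies
#' [select_signature_genes()] (core prevalence >= 60%, 200 bp to 20 kb,
#' unique, capped at 250). Genes receive at most one KO label from a
#' species-biased KO pool, and `n_modules` module definitions are built
#' over that pool.
#'
#' @param config a [sim_config()].
#' @return list with `catalog` (data.frame `gene_id`, `species`, `length`,
#'   `effective_length`, `prevalence`, `unique`, `signature`, `ko`) and
#'   `modules` (list of [kegg_module()]).
#' @export
generate_catalog <- function(config) {
  with_seed(derive_seed(config$seed, "catalog"), {
    sp <- species_ids(config$n_species)
    kos <- sprintf("K%05d", seq_len(config$n_kos))
    rows <- lapply(seq_along(sp), function(k) {
      g <- config$genes_per_species
      len <- round(stats::rlnorm(g, meanlog = log(1000), sdlog = 0.8))
      len <- pmax(len, 120)
      data.frame(
        gene_id = sprintf("%s_g%04d", sp[k], seq_len(g)),
        species = sp[k],
        length = len,
        # most pangenome genes are core (high MAG prevalence), with a
        # minority of accessory genes below the 60% core threshold
        prevalence = round(1 - stats::rbeta(g, 1, 4) * 0.7, 3),
        unique = stats::runif(g) < 0.95,
        stringsAsFactors = FALSE)
    })
    catalog <- do.call(rbind, rows)
    catalog$effective_length <- pmax(catalog$length - 100 + 1, 1)
    catalog$signature <- FALSE
    for (k in sp) {
      sub <- catalog[catalog$species == k, ]
      sel <- select_signature_genes(
        sub[, c("gene_id", "length", "prevalence", "unique")])
      catalog$signature[catalog$gene_id %in% sel$gene_id] <- TRUE
    }
    # KO labels: each species draws from a mostly-private slice of the
    # pool so that module associations differ between species
    catalog$ko <- NA_character_
    per_sp <- max(1L, config$n_kos %/% config$n_species)
    for (k in seq_along(sp)) {
      idx <- which(catalog$species == sp[k])
      own <- kos[((k - 1L) * per_sp) %% config$n_kos + seq_len(per_sp)]
      lab <- stats::runif(length(idx)) < 0.6
      catalog$ko[idx[lab]] <- sample(c(own, sample(kos, per_sp)),
                                     sum(lab), replace = TRUE)
    }
    modules <- lapply(seq_len(config$n_modules), function(m) {
      n_paths <- sample(1:2, 1)
      paths <- lapply(seq_len(n_paths), function(p) {
        n_steps <- sample(2:6, 1)
        lapply(seq_len(n_steps), function(s) {
          sample(kos, sample(1:2, 1))
        })
      })
      kegg_module(sprintf("M%05d", m), paths)
    })
    list(catalog = catalog, modules = modules)
  })
}

#' Generate genotypes, covariates and the BMI-like trait
#'
#' Biallelic dosages in Hardy-Weinberg equilibrium; within an LD block all
#' SNPs share one allele frequency and haplotypes are copied with
#' per-locus mutation rate `ld_mut`, so adjacent-SNP allele correlation is
#' `1 - ld_mut` and decays geometrically. Covariates are age
#' (uniform 20-80), sex (Bernoulli 0.5) and library plate (8 levels);
#' each has a small fixed effect on the BMI-like trait so covariate
#' adjustment is non-trivial. The first `bmi_instruments$n` SNPs add
#' `bmi_instruments$beta` per allele to standardized BMI.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (n x m dosage matrix), `snp_info`
#'   (data.frame `snp`, `chr`, `bp`, `ea`, `nea`, `maf`, `block`) and
#'   `traits` (data.frame `sample`, `age`, `sex`, `plate`, `bmi`).
#' @export
generate_genotypes_and_traits <- function(config) {
  with_seed(derive_seed(config$seed, "genotypes"), {
    n <- config$n_samples
    m <- config$n_snps
    bs <- config$ld_block_size
    block <- ((seq_len(m) - 1L) %/% bs) + 1L
    maf_block <- stats::runif(max(block), config$maf_range[1],
                              config$maf_range[2])
    hap <- function() {
      H <- matrix(0L, n, m)
      for (j in seq_len(m)) {
        p <- maf_block[block[j]]
        fresh <- stats::rbinom(n, 1, p)
        if (j > 1 && block[j] == block[j - 1]) {
          copy <- stats::runif(n) >= config$ld_mut
          H[, j] <- ifelse(copy, H[, j - 1], fresh)
        } else {
          H[, j] <- fresh
        }
      }
      H
    }
    G <- hap() + hap()
    colnames(G) <- snp_ids(m)
    rownames(G) <- sprintf("S%05d", seq_len(n))
    snp_info <- data.frame(snp = colnames(G), chr = 1L,
                           bp = seq_len(m) * 5000L, ea = "A", nea = "G",
                           maf = maf_block[block], block = block,
                           stringsAsFactors = FALSE)
    age <- stats::runif(n, 20, 80)
    sex <- stats::rbinom(n, 1, 0.5)
    plate <- sample(factor(sprintf("P%d", 1:8)), n, replace = TRUE)
    plate_eff <- stats::rnorm(8, 0, 0.1)[as.integer(plate)]
    bmi_gen <- 0
    bi <- config$bmi_instruments
    if (bi$n > 0) {
      bmi_gen <- G[, seq_len(bi$n), drop = FALSE] %*%
        rep(bi$beta, length.out = bi$n)
    }
    bmi <- as.numeric(0.01 * (age - 50) + 0.2 * sex + plate_eff +
                        bmi_gen + stats::rnorm(n))
    list(genotypes = G, snp_info = snp_info,
         traits = data.frame(sample = rownames(G), age = age, sex = sex,
                             plate = plate, bmi = bmi,
                             stringsAsFactors = FALSE))
  })
}

#' Generate ground-truth species compositions
#'
#' Latent log abundance of species k in sample s is
#' `mu_k + sd * eps + sd * (planted SNP effects + BMI effect)`, with
#' `eps ~ N(0, 1)`; compositions are the softmax of the latents (closure),
#' so rows are non-negative and sum to one.
#'
#' @param config a [sim_config()].
#' @param genotypes dosage matrix from [generate_genotypes_and_traits()].
#' @param bmi BMI-like trait vector (standardized internally).
#' @return list of class `ground_truth` with `compositions` (n x
#'   n_species, rows summing to 1), `effect_table`, `bmi_effects`.
#' @export
generate_truth <- function(config, genotypes, bmi = NULL) {
  sp <- species_ids(config$n_species)
  et <- config$effect_table
  if (!is.null(et)) {
    bad_snp <- setdiff(et$snp, colnames(genotypes))
    bad_sp <- setdiff(et$species, sp)
    if (length(bad_snp) || length(bad_sp)) {
      stopf("effect_table references unknown snp/species: %s",
            paste(c(bad_snp, bad_sp), collapse = ", "))
    }
  }
  with_seed(derive_seed(config$seed, "truth"), {
    n <- config$n_samples
    mu <- stats::rnorm(config$n_species, 0, config$comp_meanlog_sd)
    latent <- matrix(stats::rnorm(n * config$n_species, 0,
                                  config$comp_sdlog),
                     n, config$n_species)
    latent <- sweep(latent, 2, mu, "+")
    if (!is.null(et)) {
      for (i in seq_len(nrow(et))) {
        k <- match(et$species[i], sp)
        latent[, k] <- latent[, k] +
          config$comp_sdlog * et$beta[i] * genotypes[, et$snp[i]]
      }
    }
    if (!is.null(config$bmi_effects)) {
      z <- as.numeric(scale(bmi))
      latent <- latent + config$comp_sdlog *
        (z %*% t(config$bmi_effects))
    }
    ex <- exp(latent)
    comp <- ex / rowSums(ex)
    dimnames(comp) <- list(rownames(genotypes), sp)
    structure(list(compositions = comp, effect_table = et,
                   bmi_effects = config$bmi_effects),
              class = "ground_truth")
  })
}

#' Generate the binary disease outcome
#'
#' Disease status is Bernoulli with
#' `plogis(intercept + slope * z)` where `z` is the standardized (IRNT)
#' true abundance of the configured species.
#'
#' @param config a [sim_config()] with a `disease_model`.
#' @param truth a [generate_truth()] result.
#' @return integer 0/1 vector.
#' @export
generate_disease <- function(config, truth) {
  dm <- config$disease_model
  if (is.null(dm)) stopf("config has no disease_model")
  if (!dm$species %in% colnames(truth$compositions)) {
    stopf("disease_model references unknown species %s", dm$species)
  }
  with_seed(derive_seed(config$seed, "disease"), {
    z <- irnt(truth$compositions[, dm$species])
    stats::rbinom(length(z), 1, stats::plogis(dm$intercept + dm$slope * z))
  })
}

#' Generate a gene count table from compositions
#'
#' The count of gene g in sample s is negative binomial with mean
#' `depth * w / sum(w)` where `w = composition(s, species(g)) *
#' effective_length(g)` and size `log2(effective_length)` (clamped at 1),
#' matching the profiler's assumed model. A fraction `outlier_gene_rate`
#' of gene-sample cells is then inflated `outlier_fold`-fold to emulate
#' cross-mapping artifacts. Only signature genes receive counts.
#'
#' @param catalog catalog data.frame from [generate_catalog()].
#' @param truth a [generate_truth()] result with species matching the
#'   catalog.
#' @param config a [sim_config()].
#' @return samples x signature-genes integer matrix with an `outliers`
#'   attribute (logical matrix of inflated cells).
#' @export
generate_counts <- function(catalog, truth, config) {
  if (config$depth < 0) stopf("depth must be >= 0")
  sig <- catalog[catalog$signature, , drop = FALSE]
  if (!all(sig$species %in% colnames(truth$compositions))) {
    stopf("catalog and truth species sets differ")
  }
  with_seed(derive_seed(config$seed, "counts"), {
    n <- nrow(truth$compositions)
    g <- nrow(sig)
    leff <- sig$effective_length
    size <- pmax(log2(leff), 1)
    comp <- truth$compositions[, sig$species, drop = FALSE]
    w <- sweep(comp, 2, leff, "*")
    mu <- config$depth * w / rowSums(w)
    counts <- matrix(stats::rnbinom(n * g, size = rep(size, each = n),
                                    mu = as.numeric(mu)), n, g)
    out_mask <- matrix(stats::runif(n * g) < config$outlier_gene_rate,
                       n, g)
    counts[out_mask] <- counts[out_mask] * config$outlier_fold
    dimnames(counts) <- list(rownames(truth$compositions), sig$gene_id)
    dimnames(out_mask) <- dimnames(counts)
    attr(counts, "outliers") <- out_mask
    counts
  })
}

#' Simulate a full cohort
#'
#' Orchestrates catalog, genotypes/traits, ground-truth compositions,
#' counts and (if configured) the disease outcome into one object.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort` with elements `config`, `catalog`,
#'   `modules`, `genotypes`, `snp_info`, `traits`, `truth`, `counts`.
#' @export
simulate_cohort <- function(config) {
  cat_mod <- generate_catalog(config)
  gt <- generate_genotypes_and_traits(config)
  truth <- generate_truth(config, gt$genotypes, gt$traits$bmi)
  counts <- generate_counts(cat_mod$catalog, truth, config)
  traits <- gt$traits
  if (!is.null(config$disease_model)) {
    traits$disease <- generate_disease(config, truth)
  }
  structure(list(config = config, catalog = cat_mod$catalog,
                 modules = cat_mod$modules, genotypes = gt$genotypes,
                 snp_info = gt$snp_info, traits = traits, truth = truth,
                 counts = counts),
            class = "sim_cohort")
}

#' Simulate paired discovery and replication cohorts
#'
#' Two cohorts sharing the planted effect table (and all other
#' configuration) but with disjoint sample ids and independent noise.
#'
#' @param config a [sim_config()]; `n_samples` sizes the discovery
#'   cohort.
#' @param n_replication replication cohort size (default: same).
#' @return list with `discovery` and `replication` [simulate_cohort()]
#'   objects.
#' @export
generate_cohort_pair <- function(config, n_replication = config$n_samples) {
  check_number(n_replication, "n_replication", 1)
  disc <- simulate_cohort(config)
  cfg_rep <- config
  cfg_rep$n_samples <- as.integer(n_replication)
  cfg_rep$seed <- derive_seed(config$seed, "replication")
  rep_ <- simulate_cohort(cfg_rep)
  relabel <- function(coh, prefix) {
    ids <- sprintf("%s%05d", prefix, seq_len(nrow(coh$genotypes)))
    rownames(coh$genotypes) <- ids
    rownames(coh$truth$compositions) <- ids
    rownames(coh$counts) <- ids
    coh$traits$sample <- ids
    coh
  }
  list(discovery = relabel(disc, "D"), replication = relabel(rep_, "R"))
}

#' Generate a colocalization panel
#'
#' Simulates one genomic region with LD-block genotypes and two
#' quantitative traits, then computes per-variant regression summary
#' statistics for each trait on the raw data. In `shared` mode both
#' traits are driven by the same causal variant; in `distinct` mode by
#' two different variants (in different LD blocks when possible); in
#' `null` mode neither trait has a causal variant.
#'
#' @param mode `"shared"`, `"distinct"` or `"null"`.
#' @param config a [sim_config()]; `n_snps` (>= 10) sets the region size.
#' @param beta per-allele causal effect size in trait s.d. units
#'   (default 0.5, a strong signal).
#' @return list with `stats1`, `stats2` (summary data.frames with `snp`,
#'   `beta`, `se`, `p`, `n`), `ld` (variant correlation matrix),
#'   `causal1`, `causal2` (causal variant ids or NA).
#' @export
generate_coloc_panel <- function(mode = c("shared", "distinct", "null"),
                                 config, beta = 0.5) {
  mode <- match.arg(mode)
  if (config$n_snps < 10) stopf("coloc panel needs >= 10 variants")
  gt <- generate_genotypes_and_traits(config)
  G <- gt$genotypes
  m <- ncol(G)
  with_seed(derive_seed(config$seed, paste0("coloc_", mode)), {
    idx1 <- idx2 <- NA_integer_
    if (mode != "null") {
      idx1 <- sample(m, 1)
      idx2 <- if (mode == "shared") idx1 else {
        other <- which(gt$snp_info$block != gt$snp_info$block[idx1])
        if (length(other) == 0) other <- setdiff(seq_len(m), idx1)
        sample(other, 1)
      }
    }
    n <- nrow(G)
    y1 <- stats::rnorm(n) + if (is.na(idx1)) 0 else beta * G[, idx1]
    y2 <- stats::rnorm(n) + if (is.na(idx2)) 0 else beta * G[, idx2]
    X <- matrix(1, n, 1)
    mk_stats <- function(y) {
      fit <- ols_scan(G, y, X)
      data.frame(snp = colnames(G), beta = fit$beta, se = fit$se,
                 p = fit$p, n = n, stringsAsFactors = FALSE)
    }
    list(stats1 = mk_stats(y1), stats2 = mk_stats(y2),
         ld = stats::cor(G),
         causal1 = if (is.na(idx1)) NA_character_ else colnames(G)[idx1],
         causal2 = if (is.na(idx2)) NA_character_ else colnames(G)[idx2])
  })
}
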