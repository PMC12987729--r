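# Species quantification: read-pair classification, NB quantile filter,
# abundance rules, rarefaction, diversity, KO profiles.

test_that("read-pair classification follows the stated predicate on the boundary grid", {
  # independent oracle: direct evaluation of the written rule
  read_oracle <- function(mapq, id, len, un) {
    crit <- id >= 0.95 && len >= 100 && un <= 10
    if (crit && mapq >= 20) "unique" else if (crit) "multi" else "unmapped"
  }
  grid <- expand.grid(mapq = c(19, 20), id = c(0.949, 0.95),
                      len = c(99, 100), un = c(10, 11))
  recs <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    rec(mapq1 = g$mapq, id1 = g$id, len1 = g$len, un1 = g$un,
        mapq2 = 0, id2 = 0, len2 = 0, un2 = 100, gene2 = NA)
  }))
  got <- classify_read_pairs(recs)$pairs
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    r1 <- read_oracle(g$mapq, g$id, g$len, g$un)
    expect_equal(got$label[i], if (r1 == "unique") "unique" else
      if (r1 == "multi") "multi" else "unmapped",
      info = paste(unlist(g), collapse = "/"))
  }
})

test_that("pair-level counting rules: read one wins, multi and unmapped combine", {
  # both unique to different genes -> read one's gene counted
  r <- classify_read_pairs(rec(gene1 = "gA", gene2 = "gB"))
  expect_equal(r$pairs$label, "unique")
  expect_equal(r$counts, c(gA = 1L))
  # read 2 unique only
  r2 <- classify_read_pairs(rec(mapq1 = 5, gene1 = "gA", gene2 = "gB"))
  expect_equal(r2$counts, c(gB = 1L))
  # neither unique, one multi
  r3 <- classify_read_pairs(rec(mapq1 = 5, mapq2 = 1, id2 = 0.5))
  expect_equal(r3$pairs$label, "multi")
  expect_equal(length(r3$counts), 0)
  # both unmapped
  r4 <- classify_read_pairs(rec(id1 = 0.5, id2 = 0.5))
  expect_equal(r4$pairs$label, "unmapped")
})

test_that("NB bounds match a brute-force CDF oracle and degenerate cleanly", {
  # mu = 10, r = 10: gene of effective length 2^10 among equals
  L <- rep(1024, 4)
  b <- nb_gene_bounds(L, 40)
  expect_true(all(b$mean == 10), TRUE)
  # oracle: iterate the pmf until the cumulative crosses the targets
  cdf_oracle <- function(mu, size, q) {
    x <- 0
    acc <- stats::dnbinom(0, size = size, mu = mu)
    while (acc < q) {
      x <- x + 1
      acc <- acc + stats::dnbinom(x, size = size, mu = mu)
    }
    x
  }
  expect_equal(b$lower[1], cdf_oracle(10, 10, 0.005))
  expect_equal(b$upper[1], cdf_oracle(10, 10, 0.995))
  expect_equal(b$p_nonzero[1], 1 - dnbinom(0, size = 10, mu = 10))
  # equal lengths -> identical bounds
  expect_equal(length(unique(b$lower)), 1)
  expect_equal(length(unique(b$upper)), 1)
  # zero total -> degenerate bounds
  b0 <- nb_gene_bounds(L, 0)
  expect_true(all(b0$lower == 0 & b0$upper == 0 & b0$p_nonzero == 0))
  # short genes clamp the size parameter
  expect_equal(attr(nb_gene_bounds(c(1.5, 1024), 10), "clamped"), 1)
})

test_that("abundance rules: all-zero, fewer-than-five, and 66% median fallback", {
  # spA: 12 signature genes; spB carries reads so normalization works
  cat2 <- rbind(toy_catalog("spA", rep(600, 12)),
                toy_catalog("spB", rep(600, 10)))
  leff <- 600 - 99
  base <- matrix(0, 1, 22, dimnames = list("s1", cat2$gene_id))
  base[1, 13:22] <- 50
  # all signature genes zero -> abundance 0
  p0 <- estimate_abundances(base, cat2)
  expect_equal(unname(p0[1, "spA"]), 0)
  expect_equal(attr(p0, "flag")[1, "spA"], "observed_zero")
  expect_equal(unname(p0[1, "spB"]), 100)
  # a count of 6 on k of 12 genes stays inside the NB bounds by design
  for (k in 4:6) {
    b <- nb_gene_bounds(rep(leff, 12), 6 * k)
    expect_true(all(6 >= b$lower[1] & 6 <= b$upper[1]))
  }
  # exactly 4 non-zero in-bounds genes -> zeroed by the <5 rule
  m4 <- base
  m4[1, 1:4] <- 6
  p4 <- estimate_abundances(m4, cat2)
  expect_equal(unname(p4[1, "spA"]), 0)
  expect_equal(attr(p4, "flag")[1, "spA"], "zeroed_lt5")
  # 5 non-zero of 12 -> 42% < 66% and the median over 12 genes (7 zeros)
  # is zero -> zeroed by the 66% rule
  m5 <- base
  m5[1, 1:5] <- 6
  p5 <- estimate_abundances(m5, cat2)
  expect_equal(unname(p5[1, "spA"]), 0)
  expect_equal(attr(p5, "flag")[1, "spA"], "zeroed_lt66")
  # 6 non-zero of 12 -> 50% < 66% but the median is positive -> median
  # of non-zero length-corrected abundances is used
  m6 <- base
  m6[1, 1:6] <- 6
  p6 <- estimate_abundances(m6, cat2)
  expect_equal(attr(p6, "flag")[1, "spA"], "median_fallback")
  raw_a <- stats::median(rep(6 / leff, 6))
  raw_b <- mean(rep(50 / leff, 10))
  expect_equal(unname(p6[1, "spA"]), 100 * raw_a / (raw_a + raw_b))
})

test_that("profile rows are conserved at 100 and recovery tracks the truth", {
  coh <- small_cohort()
  prof <- estimate_abundances(coh$counts, coh$catalog)
  expect_true(all(abs(rowSums(prof) - 100) < 1e-6))
  tc <- coh$truth$compositions[, colnames(prof)]
  err <- abs(prof / 100 - tc)
  # moderate depth, small panel: absolute tracking of the truth
  expect_lt(max(err), 0.05)
})

test_that("quantile filter admits >= 97% of genes under the model with no outliers", {
  coh <- small_cohort()
  sig <- coh$catalog[coh$catalog$signature, ]
  fracs <- c()
  for (sp in unique(sig$species)) {
    genes <- sig$gene_id[sig$species == sp]
    leff <- sig$effective_length[match(genes, sig$gene_id)]
    for (s in seq_len(10)) {
      cnt <- coh$counts[s, genes]
      if (sum(cnt) == 0) next
      b <- nb_gene_bounds(leff, sum(cnt))
      fracs <- c(fracs, mean(cnt >= b$lower & cnt <= b$upper))
    }
  }
  expect_gte(mean(fracs), 0.97)
  # equivalently, under no contamination the filter removes < 2% of genes
  expect_lt(1 - mean(fracs), 0.02)
})

test_that("quantile filter confers outlier robustness that the naive mean lacks", {
  coh <- small_cohort()
  sig <- coh$catalog[coh$catalog$signature, ]
  sp <- names(sort(colMeans(coh$truth$compositions), decreasing = TRUE))[2]
  genes <- sig$gene_id[sig$species == sp]
  clean <- coh$counts
  dirty <- clean
  set.seed(9)
  hit <- sample(genes, ceiling(0.05 * length(genes)))
  dirty[, hit] <- dirty[, hit] * 50
  p_clean <- estimate_abundances(clean, coh$catalog)
  p_dirty <- estimate_abundances(dirty, coh$catalog)
  rel <- abs(p_dirty[, sp] - p_clean[, sp]) / p_clean[, sp]
  expect_lt(stats::median(rel), 0.15)
  # naive unfiltered length-normalized mean fails the same property
  naive <- function(counts) {
    raw <- sapply(sort(unique(sig$species)), function(k) {
      g <- sig$gene_id[sig$species == k]
      rowMeans(sweep(counts[, g, drop = FALSE], 2,
                     sig$effective_length[match(g, sig$gene_id)], "/"))
    })
    100 * raw / rowSums(raw)
  }
  n_rel <- abs(naive(dirty)[, sp] - naive(clean)[, sp]) / naive(clean)[, sp]
  expect_gt(stats::median(n_rel), 0.15)
})

test_that("rarefaction: identity at full depth, monotone richness, hypergeometric mean", {
  coh <- small_cohort()
  sig_genes <- coh$catalog$gene_id[coh$catalog$signature]
  sub <- coh$counts[1:5, intersect(colnames(coh$counts), sig_genes)]
  full_tot <- min(rowSums(sub))
  # target = sample total leaves that sample's counts unchanged
  r_full <- rarefy_profile(coh$counts[which.min(rowSums(coh$counts[, sig_genes])), ,
                                      drop = FALSE],
                           coh$catalog,
                           target = min(rowSums(coh$counts[, sig_genes])),
                           seed = 4)
  expect_identical(attr(r_full, "rarefied_counts")[1, ],
                   coh$counts[which.min(rowSums(coh$counts[, sig_genes])),
                              colnames(attr(r_full, "rarefied_counts"))])
  # rarefied richness never exceeds full richness
  target <- floor(full_tot / 2)
  r <- rarefy_profile(coh$counts, coh$catalog, target = target, seed = 4)
  full_prof <- estimate_abundances(coh$counts, coh$catalog)
  kept <- setdiff(rownames(coh$counts), attr(r, "excluded"))
  expect_true(all(alpha_diversity(r[kept, ])$richness <=
                    alpha_diversity(full_prof[kept, ])$richness))
  # determinism
  r2 <- rarefy_profile(coh$counts, coh$catalog, target = target, seed = 4)
  expect_identical(attr(r, "rarefied_counts"), attr(r2, "rarefied_counts"))
  # undersampled samples are excluded, not errors
  r3 <- rarefy_profile(coh$counts, coh$catalog,
                       target = max(rowSums(coh$counts[, sig_genes])) + 1,
                       seed = 1)
  expect_equal(sort(attr(r3, "excluded")), sort(rownames(coh$counts)))
})

test_that("rarefied per-gene counts match the hypergeometric expectation", {
  cat1 <- toy_catalog("spA", c(300, 500, 900))
  counts <- matrix(c(10L, 15L, 25L), 1, 3,
                   dimnames = list("s1", cat1$gene_id))
  target <- 20
  draws <- sapply(1:1000, function(i) {
    attr(rarefy_profile(counts, cat1, target = target, seed = i),
         "rarefied_counts")[1, ]
  })
  expected <- target * c(10, 15, 25) / 50
  mc_se <- apply(draws, 1, stats::sd) / sqrt(1000)
  expect_true(all(abs(rowMeans(draws) - expected) < 3 * mc_se + 1e-9))
  expect_true(all(colSums(draws) == target))
})

test_that("alpha diversity matches closed forms and the vegan oracle", {
  one <- matrix(c(100, 0), 1, 2, dimnames = list("s", c("a", "b")))
  expect_equal(alpha_diversity(one)$shannon, 0)
  expect_equal(alpha_diversity(one)$richness, 1)
  unif <- matrix(rep(12.5, 8), 1, 8,
                 dimnames = list("s", letters[1:8]))
  expect_equal(alpha_diversity(unif)$shannon, log(8), tolerance = 1e-12)
  # random profile vs direct summation and vegan::diversity
  set.seed(2)
  p <- matrix(stats::rgamma(50, 0.5), 5, 10)
  p <- 100 * p / rowSums(p)
  rownames(p) <- paste0("s", 1:5)
  ad <- alpha_diversity(p)
  direct <- apply(p / 100, 1, function(r) -sum(r[r > 0] * log(r[r > 0])))
  expect_equal(ad$shannon, unname(direct), tolerance = 1e-12)
  skip_if_not_installed("vegan")
  expect_equal(ad$shannon, unname(vegan::diversity(p / 100)),
               tolerance = 1e-10)
  # empty sample
  expect_equal(alpha_diversity(matrix(0, 1, 3))$shannon, 0)
})

test_that("KO profile proportions follow the hand-computed toy and sum rules", {
  cat3 <- toy_catalog("spA", c(199, 299, 399), kos = c("KA", "KA", "KB"))
  counts <- matrix(c(10, 20, 30), 1, 3,
                   dimnames = list("s1", cat3$gene_id))
  kp <- ko_profile(counts, cat3)
  expect_equal(unname(kp[1, "KA"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(kp[1, "KB"]), 1 / 3, tolerance = 1e-12)
  # unannotated genes dilute: drop KB annotation
  cat3$ko[3] <- NA
  kp2 <- ko_profile(counts, cat3)
  expect_equal(unname(kp2[1, "KA"]), 2 / 3, tolerance = 1e-12)
  expect_lt(sum(kp2[1, ]), 1)
  # all-zero sample -> all-zero row
  kp3 <- ko_profile(counts * 0, cat3)
  expect_true(all(kp3 == 0))
})

test_that("prevalence filter keeps traits present in at least 30% of samples", {
  m <- cbind(common = c(1, 2, 3, 0), rare = c(0, 0, 0, 1))
  expect_equal(colnames(prevalence_filter(m, 0.30)), "common")
  expect_equal(ncol(prevalence_filter(m, 0.25)), 2)
})
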