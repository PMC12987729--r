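# IRNT, GWAS scan, interaction, meta-analysis, thresholds, logistic and
# partial Spearman.

test_that("IRNT produces standard-normal Blom scores and preserves order", {
  set.seed(1)
  x <- rnorm(500)
  z <- irnt(x)
  expect_lt(abs(mean(z)), 0.01)
  expect_true(sd(z) > 0.95 && sd(z) < 1.05)
  expect_identical(order(x), order(z))
  # n = 3 distinct values: hand-computed Blom quantiles
  z3 <- irnt(c(5, 1, 3))
  hand <- qnorm((c(3, 1, 2) - 3 / 8) / (3 + 1 / 4))
  expect_equal(z3, hand, tolerance = 1e-12)
  expect_equal(qnorm(0.1923), hand[2], tolerance = 1e-3)
  # ties get average ranks
  expect_equal(irnt(c(1, 1, 2))[1], irnt(c(1, 1, 2))[2])
  expect_error(irnt(c(2, 2, 2)), "constant")
  expect_error(irnt(c(1, 2)), "3 finite")
})

test_that("gwas_linear equals the normal-equation OLS oracle", {
  set.seed(4)
  n <- 12
  G <- cbind(s1 = sample(0:2, n, TRUE), s2 = sample(0:2, n, TRUE))
  y <- rnorm(n)
  cov <- data.frame(age = runif(n))
  res <- gwas_linear(G, y, cov, maf_min = 0)
  for (j in 1:2) {
    sm <- summary(stats::lm(y ~ G[, j] + cov$age))$coefficients
    expect_equal(res$beta[j], unname(sm[2, 1]), tolerance = 1e-10)
    expect_equal(res$se[j], unname(sm[2, 2]), tolerance = 1e-10)
    expect_equal(res$p[j], unname(sm[2, 4]), tolerance = 1e-10)
  }
})

test_that("gwas_linear filters by MAF, rejects collinearity, annotates SNPs", {
  set.seed(5)
  n <- 300
  G <- cbind(common = rbinom(n, 2, 0.3), rare = rbinom(n, 2, 0.004))
  y <- rnorm(n)
  res <- gwas_linear(G, y)
  expect_equal(res$snp, "common")
  info <- data.frame(snp = "common", chr = 9L, bp = 136146597L,
                     ea = "T", nea = "C")
  res2 <- gwas_linear(G, y, snp_info = info)
  expect_equal(res2$bp, 136146597L)
  bad_cov <- data.frame(a = seq_len(n), b = 2 * seq_len(n))
  expect_error(gwas_linear(G, y, bad_cov), "collinear.*b")
})

test_that("allele-orientation invariance: flipping dosage negates beta, keeps p", {
  set.seed(6)
  n <- 500
  G <- cbind(snp = rbinom(n, 2, 0.25))
  y <- 0.2 * G[, 1] + rnorm(n)
  a <- gwas_linear(G, y)
  b <- gwas_linear(cbind(snp = 2 - G[, 1]), y)
  expect_equal(b$beta, -a$beta, tolerance = 1e-12)
  expect_equal(b$eaf, 1 - a$eaf, tolerance = 1e-12)
  expect_equal(b$p, a$p, tolerance = 1e-12)
})

test_that("multi-trait scan equals per-trait gwas_linear", {
  set.seed(7)
  n <- 400
  G <- sapply(1:6, function(i) rbinom(n, 2, 0.3))
  colnames(G) <- paste0("s", 1:6)
  Y <- cbind(t1 = rnorm(n), t2 = rnorm(n) + 0.1 * G[, 2])
  cov <- data.frame(age = runif(n))
  sc <- gwas_scan_traits(G, Y, cov)
  for (t in 1:2) {
    single <- gwas_linear(G, Y[, t], cov)
    expect_equal(unname(sc$beta[, t]), single$beta, tolerance = 1e-12)
    expect_equal(unname(sc$se[, t]), single$se, tolerance = 1e-12)
    expect_equal(unname(sc$p[, t]), single$p, tolerance = 1e-12)
  }
})

test_that("conditioning on the index SNP removes its own signal", {
  set.seed(8)
  n <- 1200
  G <- sapply(1:4, function(i) rbinom(n, 2, 0.4))
  colnames(G) <- paste0("s", 1:4)
  y <- 0.3 * G[, 1] + rnorm(n)
  res <- gwas_linear(G, y, condition_on = "s1")
  self <- res[res$snp == "s1", ]
  expect_equal(self$beta, 0)
  expect_equal(self$p, 1)
  # the conditional scan finds the two planted independent signals
  y2 <- 0.4 * G[, 1] + 0.3 * G[, 3] + rnorm(n)
  info <- data.frame(snp = colnames(G), chr = 1L,
                     bp = c(100L, 200L, 300L, 400L), ea = "A", nea = "G")
  sc <- conditional_scan(G, y2, NULL, index_snp = "s1", snp_info = info,
                         entry_threshold = 1e-4, window = 1000)
  expect_setequal(sc$snp, c("s1", "s3"))
})

test_that("interaction test matches the full-design OLS oracle and recovers effects", {
  set.seed(9)
  n <- 2000
  g1 <- rbinom(n, 2, 0.3)
  g2 <- rbinom(n, 2, 0.4)
  y <- 0.1 * g1 - 0.05 * g2 + 0.15 * g1 * g2 + rnorm(n)
  it <- interaction_test(g1, g2, y)
  sm <- summary(stats::lm(y ~ g1 + g2 + g1:g2))$coefficients
  expect_equal(it$beta, unname(sm["g1:g2", 1]), tolerance = 1e-10)
  expect_equal(it$se, unname(sm["g1:g2", 2]), tolerance = 1e-10)
  expect_lt(abs(it$beta - 0.15) / it$se, 2)
  # additive generative model: interaction p is uniform over replicates
  ps <- replicate(120, {
    yy <- 0.2 * g1[1:300] + 0.2 * g2[1:300] + rnorm(300)
    interaction_test(g1[1:300], g2[1:300], yy)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("IVW meta-analysis reproduces the published pooled effects", {
  # discovery + replication rows pooled at 2 d.p.
  m1 <- meta_analyze(beta = c(-0.14, -0.10), se = c(0.02, 0.01))
  expect_equal(round(m1$beta, 2), -0.11)
  m2 <- meta_analyze(beta = c(-0.16, -0.12), se = c(0.02, 0.01))
  expect_equal(round(m2$beta, 2), -0.13)
  m3 <- meta_analyze(beta = c(-0.08, -0.06), se = c(0.01, 0.01))
  expect_equal(round(m3$beta, 2), -0.07)
  # two identical studies: same beta, se / sqrt(2)
  mi <- meta_analyze(beta = c(0.2, 0.2), se = c(0.05, 0.05))
  expect_equal(mi$beta, 0.2)
  expect_equal(mi$se, 0.05 / sqrt(2))
  # pooled SE never exceeds the smallest component SE
  expect_lte(m1$se, 0.01)
  # fixed-effect algebra matches metafor
  skip_if_not_installed("metafor")
  rf <- metafor::rma(yi = c(-0.14, -0.10), sei = c(0.02, 0.01),
                     method = "FE")
  expect_equal(m1$beta, as.numeric(rf$beta), tolerance = 1e-10)
  expect_equal(m1$se, rf$se, tolerance = 1e-10)
})

test_that("sample-size-weighted meta combines signed z-scores; IVW refuses mixed scales", {
  p <- c(1e-4, 1e-3)
  n <- c(1000, 4000)
  dir <- c(1, -1)
  m <- meta_analyze(p = p, n = n, direction = dir, method = "sample_size")
  zi <- sign(dir) * qnorm(p / 2, lower.tail = FALSE)
  z_hand <- sum(zi * sqrt(n)) / sqrt(sum(n))
  expect_equal(m$z, z_hand, tolerance = 1e-12)
  expect_equal(m$p, 2 * pnorm(-abs(z_hand)), tolerance = 1e-12)
  expect_true(is.na(m$beta))
  expect_error(meta_analyze(beta = c(1, 1), se = c(1, 1),
                            mixed_scale = TRUE), "sample_size")
})

test_that("effective tests: Li-Ji on exactly uncorrelated traits gives m, thresholds print as published", {
  set.seed(10)
  # principal-component scores are exactly uncorrelated
  pc <- stats::prcomp(matrix(rnorm(600), 100, 6))$x
  expect_equal(effective_tests(pc)$m_eff, 6, tolerance = 1e-8)
  # perfectly duplicated traits halve the effective number
  dup <- cbind(pc[, 1], pc[, 1], pc[, 2], pc[, 2])
  expect_equal(effective_tests(dup)$m_eff, 2, tolerance = 1e-8)
  expect_equal(signif(study_threshold(391), 2), 1.3e-10)
  expect_equal(signif(study_threshold(102), 2), 4.9e-10)
  expect_equal(signif(study_threshold(546), 2), 9.2e-11)
  expect_equal(signif(bonferroni_threshold(13), 2), 3.8e-3)
  expect_equal(bonferroni_threshold(8), 6.25e-3)
})

test_that("replication decisions require concordance and the Bonferroni threshold", {
  disc <- list(beta = 0.09, p = 4.3e-12)
  # concordant but p = 7.4e-2 above 0.05/13 -> not replicated
  r1 <- replication_decision(disc, list(beta = 0.02, p = 7.4e-2), 13)
  expect_false(r1$replicated)
  expect_true(r1$concordant)
  # strong but discordant -> not replicated
  r2 <- replication_decision(disc, list(beta = -0.10, p = 1e-20), 13)
  expect_false(r2$replicated)
  # concordant and below threshold -> replicated
  r3 <- replication_decision(disc, list(beta = 0.10, p = 8.5e-17), 13)
  expect_true(r3$replicated)
  # zero replication effect counts as discordant
  expect_false(replication_decision(disc, list(beta = 0, p = 1e-5),
                                    13)$replicated)
})

test_that("logistic association matches the contingency oracle and recovers planted log-OR", {
  # 2x2 binarized toy: OR = ad/bc
  x <- rep(c(0, 1), times = c(60, 40))
  y <- c(rep(c(0, 1), times = c(45, 15)), rep(c(0, 1), times = c(20, 20)))
  fit <- logistic_assoc(x, y)
  expect_equal(fit$or, (45 * 20) / (15 * 20), tolerance = 1e-6)
  # planted log-OR recovered within 2 SE
  set.seed(11)
  n <- 4000
  z <- rnorm(n)
  yy <- rbinom(n, 1, plogis(-1.5 - 0.6 * z))
  f2 <- logistic_assoc(z, yy)
  expect_lt(abs(f2$beta + 0.6) / f2$se, 2)
  # separation errors with a diagnostic
  expect_error(logistic_assoc(c(1, 2, 3, 4), c(0, 0, 1, 1)), "separation")
  expect_error(logistic_assoc(z, rep(1, n)), "classes")
})

test_that("null logistic CI coverage is near nominal", {
  set.seed(12)
  cover <- replicate(1000, {
    x <- rnorm(400)
    y <- rbinom(400, 1, 0.3)
    f <- logistic_assoc(x, y)
    f$ci_low <= 1 && f$ci_high >= 1
  })
  expect_gte(mean(cover), 0.93)
})

test_that("partial Spearman reduces to plain Spearman and handles covariates", {
  set.seed(13)
  x <- rnorm(80)
  y <- rnorm(80)
  ps <- partial_spearman(x, y)
  expect_equal(ps$rho, cor(x, y, method = "spearman"), tolerance = 1e-10)
  # strictly monotone relation -> rho 1
  expect_equal(partial_spearman(x, exp(x))$rho, 1, tolerance = 1e-12)
  # removing a shared covariate kills an induced correlation
  z <- rnorm(200)
  a <- z + rnorm(200, sd = 0.4)
  b <- z + rnorm(200, sd = 0.4)
  raw <- partial_spearman(a, b)
  adj <- partial_spearman(a, b, covariates = data.frame(z = z))
  expect_gt(raw$rho, 0.5)
  expect_lt(abs(adj$rho), 0.25)
  expect_error(partial_spearman(rep(1, 80), y), "constant")
})
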