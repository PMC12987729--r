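# Covariate-adjusted association testing and meta-analysis.

#' Inverse rank-normal transformation
#'
#' Maps values to standard-normal scores through their ranks using the
#' Blom offset: `qnorm((rank - 3/8) / (n + 1/4))`. Ties receive the
#' average rank.
#'
#' @param values numeric vector with at least three finite values.
#' @return numeric vector of normal scores (NA preserved).
#' @export
irnt <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < 3) stopf("irnt needs at least 3 finite values")
  if (length(unique(values[ok])) == 1) {
    stopf("irnt: input is constant and cannot be rank-transformed")
  }
  out <- rep(NA_real_, length(values))
  r <- rank(values[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - 3 / 8) / (sum(ok) + 1 / 4))
  out
}

# Internal single-trait scan shared by gwas_linear / interaction_test.
# Residualizes trait and dosages on the nuisance design (Frisch-Waugh),
# giving coefficients/SEs identical to the full OLS fit.
ols_scan <- function(G, y, X) {
  n <- length(y)
  yr <- residualize(y, X)
  Gr <- residualize(G, X)
  gtg <- colSums(Gr^2)
  gty <- as.numeric(crossprod(Gr, yr))
  # a dosage column absorbed by the design (e.g. conditioning on the SNP
  # itself) has no residual variance left to test
  degenerate <- gtg < .Machine$double.eps^0.5 * n
  gtg[degenerate] <- Inf
  beta <- gty / gtg
  beta[degenerate] <- 0
  df <- n - ncol(X) - 1L
  rss <- sum(yr^2) - beta^2 * gtg
  rss[degenerate] <- sum(yr^2)
  se <- sqrt(pmax(rss, 0) / df / gtg)
  se[degenerate] <- Inf
  stat <- beta / se
  stat[degenerate] <- 0
  # two-sided p: normal approximation for large n, t below that
  p <- if (n >= 1000) 2 * stats::pnorm(-abs(stat)) else
    2 * stats::pt(-abs(stat), df)
  list(beta = beta, se = se, p = p, df = df)
}

#' Single-variant GWAS by covariate-adjusted linear regression
#'
#' Per-SNP ordinary least squares of a (typically inverse rank-normal
#' transformed) trait on allele dosage plus covariates, under an additive
#' genetic model. Variants with minor allele frequency below `maf_min`
#' are excluded. Optional conditioning SNPs are added to the covariate
#' design (the stepwise conditional scan).
#'
#' @param genotypes n x m dosage matrix (values 0/1/2) with SNP column
#'   names.
#' @param trait numeric trait vector of length n (transform upstream with
#'   [irnt()] for abundance traits).
#' @param covariates optional data.frame/matrix of covariates; factors are
#'   expanded to dummies.
#' @param condition_on optional character vector of SNP ids whose dosages
#'   are added as covariates.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param snp_info optional data.frame with columns `snp`, `chr`, `bp`,
#'   `ea`, `nea` used to annotate the output.
#' @return data.frame of GWAS records: `snp`, `chr`, `bp`, `ea`, `nea`,
#'   `eaf`, `beta` (per effect allele), `se`, `p` (two-sided), `n`.
#' @export
gwas_linear <- function(genotypes, trait, covariates = NULL,
                        condition_on = NULL, maf_min = 0.01,
                        snp_info = NULL) {
  G <- as.matrix(genotypes)
  n <- nrow(G)
  if (length(trait) != n) stopf("trait length does not match genotypes")
  X <- design_matrix(covariates, n)
  if (!is.null(condition_on)) {
    bad <- setdiff(condition_on, colnames(G))
    if (length(bad) > 0) stopf("unknown conditioning SNPs: %s",
                               paste(bad, collapse = ", "))
    X <- cbind(X, G[, condition_on, drop = FALSE])
  }
  if (n <= ncol(X) + 2) stopf("too few samples for the design")
  eaf <- colMeans(G) / 2
  keep <- pmin(eaf, 1 - eaf) >= maf_min
  Gk <- G[, keep, drop = FALSE]
  fit <- ols_scan(Gk, trait, X)
  snp <- colnames(Gk)
  info_idx <- if (!is.null(snp_info)) match(snp, snp_info$snp) else
    rep(NA_integer_, length(snp))
  pick <- function(col, default) {
    if (!is.null(snp_info) && col %in% names(snp_info)) {
      snp_info[[col]][info_idx]
    } else rep(default, length(snp))
  }
  data.frame(snp = snp,
             chr = pick("chr", NA_integer_),
             bp = pick("bp", NA_integer_),
             ea = pick("ea", "A"),
             nea = pick("nea", "G"),
             eaf = unname(eaf[keep]),
             beta = unname(fit$beta), se = unname(fit$se),
             p = unname(fit$p), n = n,
             stringsAsFactors = FALSE)
}

#' Multi-trait GWAS scan
#'
#' Runs the [gwas_linear()] model for every column of a trait matrix at
#' once (shared genotypes, covariates and sample set), as used for the
#' hundreds of species/module traits of a microbiome GWAS. Estimates are
#' identical to per-trait [gwas_linear()] calls.
#'
#' @inheritParams gwas_linear
#' @param traits n x T numeric matrix of (transformed) traits.
#' @return list with `beta`, `se`, `p` (m x T matrices, SNPs in rows),
#'   `eaf`, `n`.
#' @export
gwas_scan_traits <- function(genotypes, traits, covariates = NULL,
                             maf_min = 0.01) {
  G <- as.matrix(genotypes)
  Y <- as.matrix(traits)
  n <- nrow(G)
  if (nrow(Y) != n) stopf("traits rows do not match genotypes")
  X <- design_matrix(covariates, n)
  eaf <- colMeans(G) / 2
  keep <- pmin(eaf, 1 - eaf) >= maf_min
  Gr <- residualize(G[, keep, drop = FALSE], X)
  Yr <- residualize(Y, X)
  gtg <- colSums(Gr^2)
  B <- crossprod(Gr, Yr) / gtg
  df <- n - ncol(X) - 1L
  yty <- colSums(Yr^2)
  rss <- pmax(sweep(-B^2 * gtg, 2, yty, "+"), 0)
  SE <- sqrt(rss / df / gtg)
  Z <- B / SE
  P <- if (n >= 1000) 2 * stats::pnorm(-abs(Z)) else
    2 * stats::pt(-abs(Z), df)
  dimnames(B) <- dimnames(SE) <- dimnames(P) <-
    list(colnames(G)[keep], colnames(Y))
  list(beta = B, se = SE, p = P, eaf = eaf[keep], n = n)
}

#' Stepwise conditional scan within a locus
#'
#' Starting from the index SNP of a locus (index SNP plus/minus `window`
#' bp), repeatedly adds the current index variant as a covariate and
#' rescans the locus, stopping when no remaining SNP passes
#' `entry_threshold`.
#'
#' @inheritParams gwas_linear
#' @param index_snp SNP id anchoring the locus.
#' @param entry_threshold p-value required for a new independent signal
#'   (default 5e-8).
#' @param window half-width of the locus in bp (default 5e5).
#' @return data.frame of independent signals (one row per step, columns as
#'   [gwas_linear()] plus `step`).
#' @export
conditional_scan <- function(genotypes, trait, covariates, index_snp,
                             snp_info, entry_threshold = 5e-8,
                             window = 5e5, maf_min = 0.01) {
  anchor <- snp_info[snp_info$snp == index_snp, ]
  if (nrow(anchor) != 1) stopf("index SNP %s not found", index_snp)
  locus <- snp_info$snp[snp_info$chr == anchor$chr &
                          abs(snp_info$bp - anchor$bp) <= window]
  locus <- intersect(locus, colnames(genotypes))
  signals <- character(0)
  out <- NULL
  repeat {
    res <- gwas_linear(genotypes[, locus, drop = FALSE], trait, covariates,
                       condition_on = if (length(signals)) signals else NULL,
                       maf_min = maf_min, snp_info = snp_info)
    res <- res[!res$snp %in% signals, , drop = FALSE]
    if (nrow(res) == 0 || min(res$p) >= entry_threshold) break
    hit <- res[which.min(res$p), , drop = FALSE]
    hit$step <- length(signals) + 1L
    out <- rbind(out, hit)
    signals <- c(signals, hit$snp)
  }
  out
}

#' SNP x SNP interaction test
#'
#' OLS of the trait on both dosages, covariates and the dosage product;
#' the reported statistic is the product-term coefficient.
#'
#' @param snp1,snp2 dosage vectors.
#' @inheritParams gwas_linear
#' @return one-row data.frame with `beta`, `se`, `p` for the interaction
#'   term (plus the main-effect estimates as attributes-free columns
#'   `beta1`, `beta2`).
#' @export
interaction_test <- function(snp1, snp2, trait, covariates = NULL) {
  n <- length(trait)
  X <- cbind(design_matrix(covariates, n), snp1 = snp1, snp2 = snp2)
  fit <- ols_scan(cbind(inter = snp1 * snp2), trait, X)
  main <- ols_scan(cbind(snp1, snp2), trait, design_matrix(covariates, n))
  data.frame(beta = fit$beta, se = fit$se, p = fit$p,
             beta1 = main$beta[1], beta2 = main$beta[2])
}

#' METAL-style meta-analysis of summary statistics
#'
#' Fixed-effect inverse-variance weighted (IVW) meta-analysis of
#' effect/standard-error pairs, or sample-size-weighted meta-analysis of
#' signed z-scores (required when component studies report effects on
#' different trait scales, e.g. a cohort analyzed on a centered log-ratio
#' instead of the inverse rank-normal scale — IVW is refused for such
#' mixed-scale input).
#'
#' @param beta,se numeric vectors of per-study effects and standard errors
#'   (IVW method).
#' @param p,n,direction per-study p-values, sample sizes and effect signs
#'   (+1/-1) for the sample-size method.
#' @param method `"ivw"` (fixed-effect inverse-variance) or
#'   `"sample_size"`.
#' @param mixed_scale logical; set `TRUE` when study effects are on
#'   different trait scales. IVW then errors, directing to the
#'   sample-size method.
#' @return data.frame with `beta` (NA for the sample-size method), `se`,
#'   `z`, `p`, `method`, `k`.
#' @export
meta_analyze <- function(beta = NULL, se = NULL, p = NULL, n = NULL,
                         direction = NULL,
                         method = c("ivw", "sample_size"),
                         mixed_scale = FALSE) {
  method <- match.arg(method)
  if (method == "ivw") {
    if (mixed_scale) {
      stopf(paste("IVW meta-analysis is invalid for mixed-scale effects;",
                  "use method = \"sample_size\""))
    }
    if (length(beta) < 2 || length(beta) != length(se)) {
      stopf("ivw needs k >= 2 matched beta/se")
    }
    if (any(se <= 0)) stopf("standard errors must be positive")
    w <- 1 / se^2
    pooled <- sum(w * beta) / sum(w)
    pooled_se <- sqrt(1 / sum(w))
    z <- pooled / pooled_se
    data.frame(beta = pooled, se = pooled_se, z = z,
               p = 2 * stats::pnorm(-abs(z)), method = "ivw",
               k = length(beta), stringsAsFactors = FALSE)
  } else {
    if (length(p) < 2 || length(p) != length(n) ||
        length(p) != length(direction)) {
      stopf("sample_size method needs k >= 2 matched p/n/direction")
    }
    if (any(n <= 0)) stopf("sample sizes must be positive")
    zi <- sign(direction) * stats::qnorm(p / 2, lower.tail = FALSE)
    z <- sum(zi * sqrt(n)) / sqrt(sum(n))
    data.frame(beta = NA_real_, se = NA_real_, z = z,
               p = 2 * stats::pnorm(-abs(z)), method = "sample_size",
               k = length(p), stringsAsFactors = FALSE)
  }
}

#' Effective number of independent tests (Li-Ji eigenvalue method)
#'
#' Estimates the effective number of independent traits from the
#' eigenvalues of the trait correlation matrix:
#' `M_eff = sum over eigenvalues of [1(lambda >= 1) + (lambda - floor(lambda))]`.
#' Negative eigenvalues from rank-deficient inputs are floored at zero.
#'
#' @param traits samples x traits numeric matrix.
#' @return list with `m_eff` and the eigenvalues.
#' @export
effective_tests <- function(traits) {
  traits <- as.matrix(traits)
  if (ncol(traits) < 2 || nrow(traits) < 3) {
    stopf("effective_tests needs >= 2 traits and >= 3 samples")
  }
  ev <- eigen(stats::cor(traits), symmetric = TRUE, only.values = TRUE)$values
  # floor() below is discontinuous at integers; strip floating-point
  # noise so exactly degenerate spectra are scored stably
  ev <- round(pmax(ev, 0), 10)
  m_eff <- sum((ev >= 1) + (ev - floor(ev)))
  list(m_eff = m_eff, eigenvalues = ev)
}

#' Multiple-testing thresholds
#'
#' Study-wide significance threshold `alpha / M_eff` given an effective
#' number of tests (which may come from [effective_tests()] or be supplied
#' directly, e.g. 391 for species traits and 102 for KEGG modules), and a
#' plain Bonferroni helper `alpha / k`.
#'
#' @param m_eff effective number of tests.
#' @param alpha genome-wide significance level (default 5e-8).
#' @return the adjusted threshold.
#' @export
study_threshold <- function(m_eff, alpha = 5e-8) {
  check_number(m_eff, "m_eff", lower = 1)
  alpha / m_eff
}

#' @rdname study_threshold
#' @param k number of comparisons.
#' @export
bonferroni_threshold <- function(k, alpha = 0.05) {
  check_number(k, "k", lower = 1)
  alpha / k
}

#' Replication decision for a discovery signal
#'
#' A signal replicates when the replication effect has the same sign as
#' the discovery effect and the replication p-value is below the
#' Bonferroni threshold `0.05 / k_comparisons`. A zero replication effect
#' is treated as discordant.
#'
#' @param discovery,replication one-row GWAS records (or lists) with
#'   `beta` and `p` fields.
#' @param k_comparisons number of signals taken to replication.
#' @return list with `replicated`, `concordant`, `threshold`.
#' @export
replication_decision <- function(discovery, replication, k_comparisons) {
  thr <- bonferroni_threshold(k_comparisons)
  concordant <- sign(discovery$beta) == sign(replication$beta) &&
    replication$beta != 0
  list(replicated = concordant && replication$p < thr,
       concordant = concordant, threshold = thr)
}

#' Logistic association of a binary outcome with an exposure
#'
#' Maximum-likelihood logistic regression of the outcome on the exposure
#' and covariates; reports the odds ratio per unit of exposure (per s.d.
#' if the exposure is standardized upstream) with a Wald 95% CI.
#'
#' @param exposure numeric vector.
#' @param outcome binary 0/1 vector with both classes present.
#' @param covariates optional covariates.
#' @return data.frame with `or`, `ci_low`, `ci_high`, `beta`, `se`, `p`.
#' @export
logistic_assoc <- function(exposure, outcome, covariates = NULL) {
  if (length(unique(outcome)) != 2) stopf("outcome must have both classes")
  df <- data.frame(.y = outcome, .x = exposure)
  X <- design_matrix(covariates, length(outcome))
  df <- cbind(df, as.data.frame(X[, -1, drop = FALSE]))
  fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                     family = stats::binomial()))
  probs <- stats::fitted(fit)
  if (!fit$converged || any(probs > 1 - 1e-8) || any(probs < 1e-8)) {
    if (max(probs) > 1 - 1e-8 || min(probs) < 1e-8) {
      stopf(paste("perfect or quasi-perfect separation detected:",
                  "fitted probabilities reached 0 or 1"))
    }
  }
  cf <- summary(fit)$coefficients[".x", ]
  beta <- cf[["Estimate"]]
  se <- cf[["Std. Error"]]
  data.frame(or = exp(beta),
             ci_low = exp(beta - 1.96 * se),
             ci_high = exp(beta + 1.96 * se),
             beta = beta, se = se, p = cf[["Pr(>|z|)"]])
}

#' Partial Spearman rank correlation
#'
#' Rank-transforms both variables, residualizes the ranks on the
#' covariates, and reports the Pearson correlation of the residuals with a
#' t-based two-sided p-value on `n - 2 - (number of covariate columns)`
#' degrees of freedom. With no covariates this equals the ordinary
#' Spearman correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates optional covariates.
#' @return data.frame with `rho`, `p`, `n`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stopf("constant input has no rank correlation")
  }
  X <- design_matrix(covariates, n)
  if (n <= ncol(X) + 3) stopf("too few observations")
  rx <- residualize(rank(x), X)
  ry <- residualize(rank(y), X)
  rho <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - 2 - (ncol(X) - 1)
  tt <- rho * sqrt(df / (1 - rho^2))
  data.frame(rho = rho, p = 2 * stats::pt(-abs(tt), df), n = n)
}
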