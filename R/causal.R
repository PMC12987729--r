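# Two-sample Mendelian randomization and Bayesian colocalization.

#' Harmonize exposure and outcome summary statistics
#'
#' Joins two summary-statistic tables on SNP id, flips the outcome effect
#' (beta negated, EAF complemented) where the outcome's effect allele is
#' the exposure's other allele, drops strand-ambiguous (A/T, C/G) SNPs and
#' SNPs whose alleles cannot be reconciled, and counts what was dropped.
#'
#' @param exposure,outcome GWAS summary data.frames with columns `snp`,
#'   `ea`, `nea`, `eaf`, `beta`, `se`, `p`, `n`.
#' @return data.frame with exposure columns suffixed `_exp` and harmonized
#'   outcome columns suffixed `_out`; attributes `n_flipped`,
#'   `n_ambiguous`, `n_incompatible`.
#' @export
harmonize_sumstats <- function(exposure, outcome) {
  m <- merge(exposure, outcome, by = "snp", suffixes = c("_exp", "_out"))
  pal <- function(a, b) paste0(a, b) %in% c("AT", "TA", "CG", "GC")
  ambiguous <- pal(m$ea_exp, m$nea_exp)
  same <- m$ea_out == m$ea_exp & m$nea_out == m$nea_exp
  flipped <- m$ea_out == m$nea_exp & m$nea_out == m$ea_exp
  incompatible <- !same & !flipped
  keep <- !ambiguous & !incompatible
  out <- m[keep, , drop = FALSE]
  fl <- flipped[keep]
  out$beta_out[fl] <- -out$beta_out[fl]
  out$eaf_out[fl] <- 1 - out$eaf_out[fl]
  out$ea_out[fl] <- out$ea_exp[fl]
  out$nea_out[fl] <- out$nea_exp[fl]
  attr(out, "n_flipped") <- sum(fl)
  attr(out, "n_ambiguous") <- sum(ambiguous)
  attr(out, "n_incompatible") <- sum(incompatible & !ambiguous)
  out
}

#' Select genetic instruments from exposure summary statistics
#'
#' Filters to variants with MAF above 1% and exposure p below 5e-8, then
#' greedily prunes for independence in ascending p order, dropping any
#' variant whose squared genotype correlation with an already retained
#' variant is 0.01 or more. Per-instrument variance explained is
#' `R2 = 2 p (1-p) beta^2 / var(trait)` and `F = R2 (n-2) / (1-R2)`.
#'
#' @param exposure_stats GWAS summary data.frame (`snp`, `eaf`, `beta`,
#'   `se`, `p`, `n`).
#' @param genotype_panel n x m dosage matrix (column names covering the
#'   candidate SNPs) used for LD pruning.
#' @param p_threshold,maf_min,r2_max selection rules (defaults 5e-8, 0.01,
#'   0.01).
#' @param trait_var variance of the exposure trait (1 for an IRNT trait).
#' @return data.frame of retained instruments with `r2` and `f_stat`
#'   columns; zero rows when nothing passes.
#' @export
select_instruments <- function(exposure_stats, genotype_panel,
                               p_threshold = 5e-8, maf_min = 0.01,
                               r2_max = 0.01, trait_var = 1) {
  st <- exposure_stats
  maf <- pmin(st$eaf, 1 - st$eaf)
  st <- st[maf > maf_min & st$p < p_threshold &
             st$snp %in% colnames(genotype_panel), , drop = FALSE]
  st <- st[order(st$p), , drop = FALSE]
  retained <- character(0)
  for (s in st$snp) {
    if (length(retained) == 0) {
      retained <- s
      next
    }
    r2 <- stats::cor(genotype_panel[, s],
                     genotype_panel[, retained, drop = FALSE])^2
    if (all(r2 < r2_max)) retained <- c(retained, s)
  }
  out <- st[match(retained, st$snp), , drop = FALSE]
  p <- out$eaf
  out$r2 <- 2 * p * (1 - p) * out$beta^2 / trait_var
  out$f_stat <- out$r2 * (out$n - 2) / (1 - out$r2)
  rownames(out) <- NULL
  out
}

# weighted median of ratio estimates (standard MR weighted-median)
weighted_median <- function(b, w) {
  ord <- order(b)
  b <- b[ord]
  w <- w[ord] / sum(w)
  cs <- cumsum(w) - w / 2
  below <- max(which(cs < 0.5))
  b[below] + (b[below + 1] - b[below]) *
    (0.5 - cs[below]) / (cs[below + 1] - cs[below])
}

#' Two-sample Mendelian randomization estimate
#'
#' Combines per-instrument exposure and outcome effects. Methods:
#' `wald` (single-instrument ratio with first-order delta standard
#' error), `ivw` (weighted regression of outcome on exposure effects
#' through the origin, weights `se_out^-2`; `auto` inflates the fixed-
#' effect SE by `max(1, sqrt(Q/(k-1)))` when Cochran's Q is heterogeneous
#' at p < 0.05), `egger` (adds an intercept as a directional-pleiotropy
#' test; instruments are oriented to positive exposure effects first) and
#' `weighted_median` (weighted median of the ratio estimates with a
#' bootstrap SE).
#'
#' @param instruments data.frame with columns `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out` (one row per instrument), e.g. from
#'   [harmonize_sumstats()].
#' @param method one of `"auto"`, `"wald"`, `"ivw"`, `"egger"`,
#'   `"weighted_median"`. `"auto"` uses the Wald ratio for one instrument
#'   and Q-dependent fixed/random IVW otherwise.
#' @param n_boot bootstrap resamples for the weighted-median SE.
#' @param seed seed for the bootstrap.
#' @return data.frame of class `mr_result` with `method`, `estimate`,
#'   `se`, `p`, `k`, `q`, `q_p` and (Egger) `intercept`, `intercept_se`,
#'   `intercept_p`.
#' @export
mr_estimate <- function(instruments,
                        method = c("auto", "wald", "ivw", "egger",
                                   "weighted_median"),
                        n_boot = 1000, seed = 1) {
  method <- match.arg(method)
  k <- nrow(instruments)
  if (k < 1) stopf("no instruments supplied")
  bx <- instruments$beta_exp
  sx <- instruments$se_exp
  by <- instruments$beta_out
  sy <- instruments$se_out
  if (method == "auto") method <- if (k == 1) "wald" else "ivw"

  res <- function(method, estimate, se, k, q = NA_real_, q_p = NA_real_,
                  intercept = NA_real_, intercept_se = NA_real_,
                  intercept_p = NA_real_) {
    structure(data.frame(method = method, estimate = estimate, se = se,
                         p = 2 * stats::pnorm(-abs(estimate / se)),
                         k = k, q = q, q_p = q_p, intercept = intercept,
                         intercept_se = intercept_se,
                         intercept_p = intercept_p,
                         stringsAsFactors = FALSE),
              class = c("mr_result", "data.frame"))
  }

  if (method == "wald") {
    if (k != 1) stopf("wald ratio requires exactly 1 instrument, got %d", k)
    est <- by / bx
    se <- sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
    return(res("wald", est, se, 1L))
  }
  if (method == "ivw") {
    w <- 1 / sy^2
    est <- sum(bx * by * w) / sum(bx^2 * w)
    se_fixed <- sqrt(1 / sum(bx^2 * w))
    if (k == 1) {
      # degenerate single-instrument case: the IVW point estimate reduces
      # to the Wald ratio
      return(res("ivw-fixed", est, se_fixed, 1L))
    }
    ratio <- by / bx
    q <- sum((bx / sy)^2 * (ratio - est)^2)
    q_p <- stats::pchisq(q, df = k - 1, lower.tail = FALSE)
    se <- if (q_p < 0.05) se_fixed * max(1, sqrt(q / (k - 1))) else se_fixed
    meth <- if (q_p < 0.05) "ivw-random" else "ivw-fixed"
    return(res(meth, est, se, k, q, q_p))
  }
  if (method == "egger") {
    if (k < 3) stopf("egger requires k >= 3 instruments")
    flip <- sign(bx)
    bx2 <- bx * flip
    by2 <- by * flip
    w <- 1 / sy^2
    fit <- stats::lm(by2 ~ bx2, weights = w)
    sm <- summary(fit)$coefficients
    return(res("egger", sm["bx2", 1], sm["bx2", 2], k,
               intercept = sm["(Intercept)", 1],
               intercept_se = sm["(Intercept)", 2],
               intercept_p = 2 * stats::pnorm(-abs(sm["(Intercept)", 1] /
                                                     sm["(Intercept)", 2]))))
  }
  # weighted median
  if (k < 3) stopf("weighted_median requires k >= 3 instruments")
  ratio <- by / bx
  w <- 1 / (sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  est <- weighted_median(ratio, w)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bxs <- stats::rnorm(k, bx, sx)
      bys <- stats::rnorm(k, by, sy)
      rs <- bys / bxs
      ws <- 1 / (sy^2 / bxs^2 + bys^2 * sx^2 / bxs^4)
      weighted_median(rs, ws)
    }, numeric(1))
  })
  res("weighted_median", est, stats::sd(boot), k)
}

#' Many-trait MR screen for one exposure
#'
#' Runs the Q-dependent fixed/random-effect IVW estimator of
#' [mr_estimate()] for one exposure against many outcome traits at once
#' (e.g. a BMI-like exposure against every species), vectorized over
#' traits; per-trait results are identical to [mr_estimate()] with
#' `method = "auto"` for k >= 2.
#'
#' @param beta_exp,se_exp length-k instrument effects on the exposure.
#' @param beta_out,se_out k x T matrices of instrument effects on each
#'   outcome trait.
#' @return data.frame with one row per trait: `estimate`, `se`, `p`,
#'   `q`, `q_p`, `method`.
#' @export
mr_screen <- function(beta_exp, se_exp, beta_out, se_out) {
  bx <- as.numeric(beta_exp)
  k <- length(bx)
  beta_out <- as.matrix(beta_out)
  se_out <- as.matrix(se_out)
  if (nrow(beta_out) != k) stopf("beta_out must have one row per instrument")
  if (k < 2) stopf("mr_screen requires k >= 2 instruments")
  w <- 1 / se_out^2
  denom <- colSums(bx^2 * w)
  est <- colSums(bx * beta_out * w) / denom
  se_fixed <- sqrt(1 / denom)
  ratio <- beta_out / bx
  q <- colSums((bx / se_out)^2 *
                 (ratio - rep(est, each = k))^2)
  q_p <- stats::pchisq(q, df = k - 1, lower.tail = FALSE)
  infl <- ifelse(q_p < 0.05, pmax(1, sqrt(q / (k - 1))), 1)
  se <- se_fixed * infl
  data.frame(trait = colnames(beta_out) %||%
               as.character(seq_along(est)),
             estimate = est, se = se,
             p = 2 * stats::pnorm(-abs(est / se)),
             q = q, q_p = q_p,
             method = ifelse(q_p < 0.05, "ivw-random", "ivw-fixed"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summary statistics for a many-trait MR screen
#'
#' For a screen of one exposure against many traits: counts nominally
#' significant MR p-values, compares the count with the `alpha * n`
#' expectation by a 1-df observed/expected chi-square (both cells) and an
#' exact binomial test, and correlates the observational betas with the
#' MR betas (Pearson, two-sided p).
#'
#' @param obs_betas numeric vector of observational association betas,
#'   one per trait.
#' @param mr_betas,mr_ps matched MR estimates and p-values.
#' @param alpha nominal significance level (default 0.05).
#' @return data.frame with `n_traits`, `n_nominal`, `expected`,
#'   `chisq`, `chisq_p`, `binom_p`, `pearson_r`, `pearson_p`.
#' @export
mr_screen_summary <- function(obs_betas, mr_betas, mr_ps, alpha = 0.05) {
  n <- length(mr_ps)
  if (n == 0) stopf("no traits in screen")
  if (length(obs_betas) != n || length(mr_betas) != n) {
    stopf("trait lists differ in length")
  }
  observed <- sum(mr_ps < alpha)
  expected <- alpha * n
  chisq <- (observed - expected)^2 / expected +
    ((n - observed) - (n - expected))^2 / (n - expected)
  ct <- stats::cor.test(obs_betas, mr_betas)
  data.frame(n_traits = n, n_nominal = observed, expected = expected,
             chisq = chisq,
             chisq_p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
             binom_p = stats::binom.test(observed, n, alpha)$p.value,
             pearson_r = unname(ct$estimate), pearson_p = ct$p.value)
}

# Wakefield log approximate Bayes factor for one variant
wakefield_labf <- function(beta, se, sd_prior) {
  v <- se^2
  w <- sd_prior^2
  r <- w / (w + v)
  0.5 * (log(1 - r) + r * (beta / se)^2)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Approximate-Bayes-factor colocalization
#'
#' Single-causal-variant colocalization of two traits over a shared
#' variant set. Per-variant Wakefield approximate Bayes factors are
#' computed from (beta, se) with prior effect SD 0.15 for quantitative and
#' 0.2 for binary traits, combined into the five hypothesis sums (H0: no
#' association; H1/H2: only trait 1/2; H3: two distinct causal variants;
#' H4: one shared causal variant) with per-variant priors `p1`, `p2`,
#' `p12`, and normalized into posterior probabilities.
#'
#' @param stats1,stats2 data.frames with columns `snp`, `beta`, `se` (and
#'   matching `snp` sets).
#' @param p1,p2,p12 prior probabilities that a variant is causal for
#'   trait 1 only, trait 2 only, or both (defaults 1e-4, 1e-4, 1e-5).
#' @param type1,type2 `"quant"` or `"binary"`, selecting the prior effect
#'   SD per trait.
#' @return data.frame of class `coloc_result` with `pp0`..`pp4`,
#'   `n_variants`, and the priors.
#' @export
coloc_abf <- function(stats1, stats2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      type1 = c("quant", "binary"),
                      type2 = c("quant", "binary")) {
  type1 <- match.arg(type1)
  type2 <- match.arg(type2)
  if (!setequal(stats1$snp, stats2$snp)) {
    d1 <- setdiff(stats1$snp, stats2$snp)
    d2 <- setdiff(stats2$snp, stats1$snp)
    stopf("variant sets differ (only in stats1: %s; only in stats2: %s)",
          paste(utils::head(d1, 5), collapse = ","),
          paste(utils::head(d2, 5), collapse = ","))
  }
  if (nrow(stats1) < 10) stopf("coloc needs >= 10 variants")
  stats2 <- stats2[match(stats1$snp, stats2$snp), , drop = FALSE]
  sd1 <- if (type1 == "quant") 0.15 else 0.2
  sd2 <- if (type2 == "quant") 0.15 else 0.2
  l1 <- wakefield_labf(stats1$beta, stats1$se, sd1)
  l2 <- wakefield_labf(stats2$beta, stats2$se, sd2)

  s1 <- logsumexp(l1)                 # log sum BF1
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)           # log sum BF1*BF2 (shared variant)
  # H3: different variants; sum over i != j = sum_i sum_j - sum_i==j
  s3 <- log(pmax(exp(s1 + s2 - s12), 1) - 1) + s12

  lh <- c(h0 = 0,
          h1 = log(p1) + s1,
          h2 = log(p2) + s2,
          h3 = log(p1) + log(p2) + s3,
          h4 = log(p12) + s12)
  pp <- exp(lh - logsumexp(lh))
  structure(data.frame(pp0 = pp[1], pp1 = pp[2], pp2 = pp[3],
                       pp3 = pp[4], pp4 = pp[5],
                       n_variants = nrow(stats1),
                       p1 = p1, p2 = p2, p12 = p12),
            class = c("coloc_result", "data.frame"))
}
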