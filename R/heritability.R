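# GRM construction and single-component REML heritability.

#' Genetic relationship matrix (GRM)
#'
#' Standard allele-frequency-scaled estimator:
#' `A_jk = (1/m) * sum_i (x_ij - 2 p_i) (x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' over the m polymorphic SNPs. Monomorphic SNPs are excluded and counted.
#'
#' @param genotypes n x m dosage matrix.
#' @return list of class `grm` with `A` (n x n symmetric matrix), `m`
#'   (SNPs used), `excluded` (monomorphic SNPs dropped) and `ids`.
#' @export
compute_grm <- function(genotypes) {
  G <- as.matrix(genotypes)
  p <- colMeans(G) / 2
  poly <- p > 0 & p < 1
  excluded <- sum(!poly)
  G <- G[, poly, drop = FALSE]
  p <- p[poly]
  if (ncol(G) < 2) stopf("need at least 2 polymorphic SNPs")
  W <- sweep(sweep(G, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
  A <- tcrossprod(W) / ncol(G)
  structure(list(A = A, m = ncol(G), excluded = excluded,
                 ids = rownames(G) %||% as.character(seq_len(nrow(G)))),
            class = "grm")
}

#' Drop one of each closely related pair
#'
#' Greedy pruner over GRM off-diagonals: while any pair exceeds the
#' relatedness threshold, removes the member of the worst pair with the
#' larger number of over-threshold partners.
#'
#' @param grm a [compute_grm()] result.
#' @param threshold maximum allowed off-diagonal relatedness (default
#'   0.05).
#' @return character vector of retained sample ids.
#' @export
prune_related <- function(grm, threshold = 0.05) {
  A <- grm$A
  diag(A) <- 0
  keep <- rep(TRUE, nrow(A))
  repeat {
    B <- abs(A[keep, keep, drop = FALSE])
    if (all(B <= threshold)) break
    deg <- rowSums(B > threshold)
    drop_local <- which.max(deg)
    keep[which(keep)[drop_local]] <- FALSE
  }
  grm$ids[keep]
}

# Shared eigen-rotated REML machinery. Given eigenvalues lam and rotated
# yt, Xt, returns restricted log-likelihood pieces at (vg, ve).
reml_pieces <- function(vg, ve, lam, yt, Xt) {
  d <- vg * lam + ve
  dinv <- 1 / d
  DX <- Xt * dinv
  XtVX <- crossprod(Xt, DX)
  cholX <- chol(XtVX)
  aux <- backsolve(cholX, forwardsolve(t(cholX), crossprod(DX, yt)))
  Py <- dinv * yt - DX %*% aux
  Py <- as.numeric(Py)
  # trace of P * diag(m) for m = lam (A) and m = 1 (I)
  tr_pm <- function(m) {
    S <- crossprod(DX, m * DX)
    sum(dinv * m) - sum(diag(backsolve(cholX,
                                       forwardsolve(t(cholX), S))))
  }
  ll <- -0.5 * (sum(log(d)) + 2 * sum(log(diag(cholX))) +
                  sum(yt * Py))
  list(Py = Py, tr_a = tr_pm(lam), tr_i = tr_pm(1), ll = ll,
       dinv = dinv, DX = DX, cholX = cholX)
}

# P %*% v in the rotated space given pieces
apply_p <- function(pieces, v) {
  aux <- backsolve(pieces$cholX,
                   forwardsolve(t(pieces$cholX),
                                crossprod(pieces$DX, v)))
  as.numeric(pieces$dinv * v - pieces$DX %*% aux)
}

#' REML SNP heritability (single GRM, average-information algorithm)
#'
#' Fits `y = X beta + g + e` with `Var(g) = A Vg`, `Var(e) = I Ve` by
#' restricted maximum likelihood using average-information updates with an
#' EM fallback when an AI step fails or leaves the parameter space.
#' Variance components are constrained to be non-negative (floored at
#' 1e-6 of the phenotypic variance, the usual GREML convention), standard
#' errors come from the inverse AI matrix at convergence, and the
#' heritability SE uses the delta method.
#'
#' @param grm a [compute_grm()] result.
#' @param trait numeric trait vector (IRNT-transform abundance traits
#'   upstream).
#' @param covariates optional covariates (intercept always included).
#' @param max_iter maximum REML iterations (default 100).
#' @param tol convergence tolerance on the restricted log-likelihood
#'   (default 1e-6).
#' @return list of class `h2_result` with `vg`, `ve`, `vp`, `h2`, `se_vg`,
#'   `se_ve`, `se_h2`, `loglik`, `converged`, `iterations`.
#' @export
reml_h2 <- function(grm, trait, covariates = NULL, max_iter = 100,
                    tol = 1e-6) {
  A <- grm$A
  n <- length(trait)
  if (nrow(A) != n) stopf("trait length does not match GRM")
  X <- design_matrix(covariates, n)
  eg <- eigen(A, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  yt <- as.numeric(crossprod(eg$vectors, trait))
  Xt <- crossprod(eg$vectors, X)

  vp0 <- stats::var(trait)
  floor_v <- 1e-6 * vp0
  vg <- ve <- vp0 / 2
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  ai <- matrix(NA_real_, 2, 2)
  while (iter < max_iter) {
    iter <- iter + 1
    pc <- reml_pieces(vg, ve, lam, yt, Xt)
    ug <- lam * pc$Py
    ue <- pc$Py
    ypapy <- sum(ug * pc$Py)          # y' P A P y  (A diagonal = lam)
    ypipy <- sum(ue * pc$Py)          # y' P P y
    grad <- -0.5 * c(pc$tr_a - ypapy, pc$tr_i - ypipy)
    pug <- apply_p(pc, ug)
    pue <- apply_p(pc, ue)
    ai <- 0.5 * matrix(c(sum(ug * pug), sum(ug * pue),
                         sum(ue * pug), sum(ue * pue)), 2, 2)
    step <- tryCatch(solve(ai, grad), error = function(e) NULL)
    new <- NULL
    if (!is.null(step) && all(is.finite(step))) {
      # constrained AI update: components driven negative are clamped to
      # the floor (boundary estimate) rather than rejected
      cand <- pmax(c(vg, ve) + step, floor_v)
      ll_cand <- tryCatch(reml_pieces(cand[1], cand[2], lam, yt, Xt)$ll,
                          error = function(e) -Inf)
      if (is.finite(ll_cand) && ll_cand >= ll_old - 1e-8) new <- cand
    }
    if (is.null(new)) {
      # EM fallback, robust but slow
      new <- pmax(c(vg + vg^2 * (ypapy - pc$tr_a) / n,
                    ve + ve^2 * (ypipy - pc$tr_i) / n), floor_v)
    }
    vg <- new[1]
    ve <- new[2]
    pc2 <- reml_pieces(vg, ve, lam, yt, Xt)
    if (abs(pc2$ll - ll_old) < tol) {
      converged <- TRUE
      ll_old <- pc2$ll
      break
    }
    ll_old <- pc2$ll
  }
  vcv <- tryCatch(solve(ai), error = function(e) matrix(NA_real_, 2, 2))
  vp <- vg + ve
  h2 <- vg / vp
  dh <- c(ve, -vg) / vp^2
  se_h2 <- sqrt(max(0, drop(t(dh) %*% vcv %*% dh)))
  structure(list(vg = vg, ve = ve, vp = vp, h2 = h2,
                 se_vg = sqrt(max(0, vcv[1, 1])),
                 se_ve = sqrt(max(0, vcv[2, 2])),
                 se_h2 = se_h2, loglik = ll_old,
                 converged = converged, iterations = iter),
            class = "h2_result")
}

#' @export
print.h2_result <- function(x, ...) {
  cat(sprintf("GREML h2 = %.4f (SE %.4f)  Vg = %.4f  Ve = %.4f  [%s, %d it]\n",
              x$h2, x$se_h2, x$vg, x$ve,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' Haseman-Elston regression heritability
#'
#' Moment-based estimate: regress the pairwise cross-products of the
#' standardized trait, `z_j z_k` (j < k), on the corresponding GRM
#' entries; the slope estimates h2. Serves as an independent cross-check
#' for [reml_h2()].
#'
#' @param grm a [compute_grm()] result.
#' @param trait numeric trait vector.
#' @return list with `h2`, `se` (OLS slope SE), `n_pairs`.
#' @export
he_regression <- function(grm, trait) {
  z <- as.numeric(scale(trait))
  ut <- upper.tri(grm$A)
  a <- grm$A[ut]
  zz <- tcrossprod(z)[ut]
  am <- a - mean(a)
  slope <- sum(am * zz) / sum(am^2)
  res <- zz - mean(zz) - slope * am
  se <- sqrt(sum(res^2) / (length(a) - 2) / sum(am^2))
  list(h2 = slope, se = se, n_pairs = length(a))
}

#' Persist / load a GRM as a plain-text triplet file
#'
#' Writes the lower triangle (including diagonal) as `i`, `j`, `value`
#' rows plus a companion `<path>.ids` file with sample ids, and reads the
#' pair back into a [compute_grm()]-shaped object.
#'
#' @param grm a `grm` object.
#' @param path file path for the triplet TSV.
#' @return `read_grm` returns a `grm` object.
#' @export
write_grm <- function(grm, path) {
  lt <- which(lower.tri(grm$A, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(i = lt[, 1], j = lt[, 2], value = grm$A[lt])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(c(as.character(grm$m), grm$ids), paste0(path, ".ids"))
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  df <- utils::read.delim(path)
  meta <- readLines(paste0(path, ".ids"))
  m <- as.integer(meta[1])
  ids <- meta[-1]
  n <- length(ids)
  A <- matrix(0, n, n)
  A[cbind(df$i, df$j)] <- df$value
  A[cbind(df$j, df$i)] <- df$value
  structure(list(A = A, m = m, excluded = 0L, ids = ids), class = "grm")
}
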