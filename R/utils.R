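#' @keywords internal
"_PACKAGE"

# Run an expression with a private RNG stream seeded from `seed`, restoring
# the caller's .Random.seed afterwards so generators are deterministic
# without clobbering the session RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a sub-stream seed below 2^31 from a base seed and a stage label.
derive_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + offs) %% .Machine$integer.max)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower ||
      x > upper) {
    stopf("`%s` must be a single number in [%s, %s]", name,
          format(lower), format(upper))
  }
  invisible(x)
}

# Column-wise residualization on a design matrix via QR; returns the matrix
# of residuals. Errors naming collinear columns so model misuse is loud.
residualize <- function(y, X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stopf("collinear design columns: %s", paste(bad, collapse = ", "))
  }
  y - qr.fitted(qrX, y)
}

# Build a design matrix from an optional covariate data.frame/matrix;
# factors/characters are expanded to dummies, an intercept is prepended.
design_matrix <- function(covariates, n) {
  if (is.null(covariates)) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  df <- as.data.frame(covariates)
  if (nrow(df) != n) stopf("covariates have %d rows, expected %d", nrow(df), n)
  stats::model.matrix(~ ., data = df)
}
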