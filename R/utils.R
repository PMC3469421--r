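# Internal numerical primitives shared by the decay, association and
# QTL modules.  All model fits in the package reduce to simple linear
# regression y ~ 1 + x; these helpers compute the closed-form normal
# equations row-wise so that thousands of fits run as a handful of
# matrix operations.

# Row-wise OLS of y on x (one regression per row; columns are
# observations).  NA pairs are dropped per row.  Returns vectors:
#   beta, intercept, se, tstat, p, df, n, exact (zero-residual fit).
# Rows with a constant regressor (sxx == 0) or n < 3 come back as NA.
.rowOLS <- function(x, y) {
  stopifnot(is.matrix(x), is.matrix(y), all(dim(x) == dim(y)))
  ok <- !(is.na(x) | is.na(y))
  x0 <- x; x0[!ok] <- 0
  y0 <- y; y0[!ok] <- 0
  n <- rowSums(ok)
  n_safe <- pmax(n, 1L)
  mx <- rowSums(x0) / n_safe
  my <- rowSums(y0) / n_safe
  xc <- (x0 - mx) * ok
  yc <- (y0 - my) * ok
  sxx <- rowSums(xc * xc)
  syy <- rowSums(yc * yc)
  sxy <- rowSums(xc * yc)
  beta <- sxy / sxx
  rss <- pmax(syy - beta^2 * sxx, 0)
  df <- n - 2L
  sigma2 <- rss / ifelse(df > 0, df, NA_real_)
  se <- sqrt(sigma2 / sxx)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  # exact fit: residual variation numerically zero relative to the data
  exact <- rss <= 1e-12 * pmax(syy, .Machine$double.eps)
  if (any(exact)) {
    i <- which(exact)
    flat <- abs(beta[i]) <= 1e-12 * pmax(abs(my[i]), 1)
    se[i] <- 0
    p[i] <- ifelse(flat, 1, 0)
    tstat[i] <- ifelse(flat, 0, sign(beta[i]) * Inf)
  }
  bad <- sxx <= 0 | n < 3L
  beta[bad] <- se[bad] <- tstat[bad] <- p[bad] <- NA_real_
  exact[bad] <- NA
  list(beta = beta, intercept = my - beta * mx, se = se, tstat = tstat,
       p = p, df = df, n = n, exact = exact)
}

# Simple regression of each row of `y` on the single vector `x`.
.rowOLSvec <- function(x, y) {
  .rowOLS(matrix(x, nrow = nrow(y), ncol = length(x), byrow = TRUE), y)
}

# Residuals of each row of `y` regressed on intercept + columns of `X`.
.rowResiduals <- function(y, X) {
  X1 <- cbind(1, X)
  # y rows are observation vectors: resid = y - y X1 (X1'X1)^-1 X1'
  coefs <- t(solve(crossprod(X1), crossprod(X1, t(y))))
  y - coefs %*% t(X1)
}

# Derive a deterministic child seed (< 2^31) from a root seed + label.
.childSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 1000003L) * 2047L + (h %% 104729L)
}

.assertFraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single number in [0, 1]", name),
         call. = FALSE)
  invisible(x)
}
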