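# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Weighted least squares with intercept: y ~ a + b x, weights w.
# Returns coefficients, their unscaled (fixed-effect) standard errors, the
# weighted residual sum of squares Q and the residual degrees of freedom.
wls_line <- function(x, y, w) {
  sw <- sum(w)
  xbar <- sum(w * x) / sw
  ybar <- sum(w * y) / sw
  sxx <- sum(w * (x - xbar)^2)
  if (sxx <= .Machine$double.eps * sum(w * x^2)) {
    stop("design is collinear: no variation in the predictor", call. = FALSE)
  }
  b <- sum(w * (x - xbar) * (y - ybar)) / sxx
  a <- ybar - b * xbar
  res <- y - a - b * x
  q <- sum(w * res^2)
  se_b <- sqrt(1 / sxx)
  se_a <- sqrt(1 / sw + xbar^2 / sxx)
  list(intercept = a, slope = b, se_intercept = se_a, se_slope = se_b,
       q = q, df = length(y) - 2L)
}

# Weighted least squares through the origin for a design matrix X.
wls_origin <- function(X, y, w) {
  X <- as.matrix(X)
  xtwx <- crossprod(X, X * w)
  qrd <- qr(xtwx)
  if (qrd$rank < ncol(X)) {
    stop("design is rank deficient", call. = FALSE)
  }
  xtwy <- crossprod(X, y * w)
  beta <- solve(qrd, xtwy)
  cov_unscaled <- solve(qrd, diag(ncol(X)))
  res <- y - drop(X %*% beta)
  q <- sum(w * res^2)
  list(beta = unname(drop(beta)), se = unname(sqrt(diag(cov_unscaled))),
       q = q, df = length(y) - ncol(X))
}

read_tsv_file <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rbind a list of data frames, NULL when the list is empty.
rbind_all <- function(lst) {
  if (length(lst) == 0) return(NULL)
  do.call(rbind, c(lst, make.row.names = FALSE))
}
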