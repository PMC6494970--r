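# Single-random-intercept linear mixed model, fitted by profiling the
# likelihood over the variance ratio lambda = sigma2_line / sigma2_E.
#
# The model is y = X beta + Z u + e with Z the line indicator matrix,
# u ~ N(0, sigma2_line I), e ~ N(0, sigma2_E I). Rotating each line's rows
# by an orthonormal basis whose first vector is the scaled within-line mean
# (a per-line Helmert rotation) diagonalizes Z Z': the rotated model has
# independent errors with variances sigma2_E * (1 + lambda * d), where d is
# the line's replicate count on its mean component and 0 on the contrasts.
# The rotation does not depend on X, so a genome scan can rotate the
# phenotype and base design once and refit only the small weighted least
# squares problem per marker and per lambda.

block_basis <- function(r) {
  if (r == 1L) return(matrix(1, 1L, 1L))
  Q <- qr.Q(qr(matrix(1, r, 1L)), complete = TRUE)
  if (Q[1L, 1L] < 0) Q[, 1L] <- -Q[, 1L]
  t(Q)
}

#' Line-mean rotation for the mixed-model engine
#'
#' Builds the per-line orthonormal rotation used by [fit_line_lmm()] and the
#' marker scan. Rows are grouped by line; the returned `rotate` closure
#' applies the rotation to any matrix or vector whose rows follow `order`.
#'
#' @param line Character/factor vector of line ids, one per observation.
#' @return A list: `order` (row permutation grouping lines), `line` (line id
#'   per rotated row), `d` (eigenvalue of the random-intercept structure per
#'   rotated row: the line's replicate count on its mean row, 0 on contrast
#'   rows), `is_mean` (logical), and `rotate(M)`.
#' @keywords internal
#' @export
make_line_rotation <- function(line) {
  line <- as.character(line)
  ord <- order(line, method = "radix")
  lf <- line[ord]
  rl <- rle(lf)
  sizes <- rl$lengths
  bases <- lapply(stats::setNames(nm = unique(sizes)), block_basis)
  offsets <- cumsum(c(0L, sizes))
  balanced <- length(unique(sizes)) == 1L
  d <- unlist(lapply(sizes, function(r) c(r, rep(0, r - 1L))),
              use.names = FALSE)
  rotate <- function(M) {
    M <- as.matrix(M)
    out <- matrix(0, nrow(M), ncol(M))
    if (balanced) {
      r <- sizes[1L]
      B <- bases[[as.character(r)]]
      for (j in seq_len(ncol(M)))
        out[, j] <- as.vector(B %*% matrix(M[, j], r))
    } else {
      for (b in seq_along(sizes)) {
        idx <- (offsets[b] + 1L):offsets[b + 1L]
        out[idx, ] <- bases[[as.character(sizes[b])]] %*%
          M[idx, , drop = FALSE]
      }
    }
    out
  }
  list(order = ord, line = lf, d = d,
       is_mean = unlist(lapply(sizes, function(r) c(TRUE, rep(FALSE, r - 1L))),
                        use.names = FALSE),
       rotate = rotate)
}

# -2 log-likelihood (ML) or -2 restricted log-likelihood (REML) of the
# rotated model at a given log(lambda), profiled over beta and sigma2_E.
rotated_deviance <- function(loglam, X, y, d, REML = FALSE) {
  w <- 1 / (1 + exp(loglam) * d)
  sw <- sqrt(w)
  fit <- .lm.fit(X * sw, y * sw)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  p <- fit$rank
  ldet <- sum(log1p(exp(loglam) * d))
  if (REML) {
    rdiag <- abs(diag(fit$qr)[seq_len(p)])
    df <- n - p
    df * log(2 * pi * rss / df) + ldet + 2 * sum(log(rdiag)) + df
  } else {
    n * log(2 * pi * rss / n) + ldet + n
  }
}

fit_rotated <- function(X, y, d, REML = FALSE, interval = c(-18, 18)) {
  if (all(d == 0)) {
    # no replication: lambda unidentifiable, collapses to OLS
    opt <- list(minimum = -Inf,
                objective = rotated_deviance(-50, X, y, d, REML))
  } else {
    opt <- stats::optimize(rotated_deviance, interval = interval, X = X,
                           y = y, d = d, REML = REML, tol = 1e-6)
    # guard against boundary optima the golden search cannot reach
    for (edge in interval) {
      de <- rotated_deviance(edge, X, y, d, REML)
      if (de < opt$objective) opt <- list(minimum = edge, objective = de)
    }
  }
  lam <- exp(opt$minimum)
  w <- 1 / (1 + lam * d)
  sw <- sqrt(w)
  fit <- .lm.fit(X * sw, y * sw)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  p <- fit$rank
  sigma2 <- if (REML) rss / (n - p) else rss / n
  list(deviance = opt$objective, lambda = lam, sigma2_E = sigma2,
       sigma2_line = lam * sigma2, beta = fit$coefficients, rank = p, n = n)
}

#' Fit a single-random-intercept mixed model by profiled likelihood
#'
#' The small variance-component engine behind the marker scan: a linear
#' mixed model with one random intercept per line, fitted by profiling the
#' (restricted) likelihood over the variance ratio. Exact for any fixed
#' design; intended for repeated fits that share the line structure.
#'
#' @param y Numeric response.
#' @param X Fixed-effects design matrix (rows match `y`).
#' @param line Line id per observation (the random-intercept grouping).
#' @param REML Use the restricted likelihood (default) or full ML (used for
#'   likelihood-ratio tests between fixed-effect specifications).
#' @return A list with `deviance` (-2 log-likelihood at the optimum),
#'   `sigma2_line`, `sigma2_E`, `lambda`, fixed-effect estimates `beta`, and
#'   the fit's `rank` and `n`.
#' @examples
#' d <- data.frame(line = rep(letters[1:6], each = 3))
#' d$y <- rnorm(6)[as.integer(factor(d$line))] + rnorm(18)
#' fit <- fit_line_lmm(d$y, cbind(1, rnorm(18)), d$line)
#' @export
fit_line_lmm <- function(y, X, line, REML = TRUE) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), length(line) == length(y))
  keep <- !is.na(y) & stats::complete.cases(X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]; line <- line[keep]
  rot <- make_line_rotation(line)
  Xr <- rot$rotate(X[rot$order, , drop = FALSE])
  yr <- drop(rot$rotate(matrix(y[rot$order], ncol = 1L)))
  fit <- fit_rotated(Xr, yr, rot$d, REML = REML)
  fit$n_lines <- length(unique(line))
  fit
}
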