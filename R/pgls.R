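## Phylogenetic generalized least squares -------------------------------------

#' Bivariate GLS regression under a phylogenetic covariance
#'
#' Fits `y = b0 + b1 * x + e`, `e ~ MVN(0, sigma2 * C)`, by generalized
#' least squares: `beta = (X' C^-1 X)^-1 X' C^-1 y`.  The residual rate
#' `sigma2` uses the `n - 2` denominator for coefficient standard errors
#' and t-based confidence intervals; the log-likelihood is evaluated at
#' the ML rate (`n` denominator) so it is directly comparable with
#' [fit_model()] likelihoods.  With `C = I` this reduces exactly to
#' ordinary least squares.
#'
#' @param pair A `variable_pair` (log10 trait values with species names).
#' @param C Phylogenetic covariance matrix whose rownames exactly match
#'   the pair's species (any order).
#' @param alpha Significance level for coefficient intervals.
#' @return A `pgls_fit`: `intercept`, `slope`, `coef_ci` (2x2 matrix),
#'   `sigma2` (n-2 denominator), `sigma2_ml`, `loglik`, `residuals`
#'   (species-named), `fitted`, `n`.
#' @export
fit_pgls <- function(pair, C, alpha = 0.05) {
  .check_pair(pair)
  if (is.null(rownames(C)))
    stop("C must have species rownames", call. = FALSE)
  if (!setequal(pair$species, rownames(C))) {
    only_pair <- setdiff(pair$species, rownames(C))
    only_C <- setdiff(rownames(C), pair$species)
    stop("species mismatch between pair and C",
         if (length(only_pair)) paste0("; only in pair: ",
                                       paste(only_pair, collapse = ", ")),
         if (length(only_C)) paste0("; only in C: ",
                                    paste(only_C, collapse = ", ")),
         call. = FALSE)
  }
  ord <- match(rownames(C), pair$species)
  x <- pair$x[ord]; y <- pair$y[ord]; sp <- pair$species[ord]
  n <- length(y)
  X <- cbind(`(Intercept)` = 1, slope = x)
  R <- .safe_chol(C)
  Xw <- backsolve(R, X, transpose = TRUE)
  yw <- backsolve(R, y, transpose = TRUE)
  XtX <- crossprod(Xw)
  beta <- drop(solve(XtX, crossprod(Xw, yw)))
  rw <- yw - Xw %*% beta
  rss <- sum(rw^2)
  sigma2 <- rss / (n - 2)
  sigma2_ml <- rss / n
  Vbeta <- sigma2 * solve(XtX)
  t_crit <- stats::qt(1 - alpha / 2, n - 2)
  se <- sqrt(diag(Vbeta))
  coef_ci <- cbind(low = beta - t_crit * se, high = beta + t_crit * se)
  rownames(coef_ci) <- names(beta) <- c("intercept", "slope")
  logdet <- 2 * sum(log(diag(R)))
  loglik <- -0.5 * n * log(2 * pi * sigma2_ml) - 0.5 * logdet - 0.5 * n
  fitted <- drop(X %*% beta)
  resid <- stats::setNames(y - fitted, sp)
  structure(list(intercept = beta[1], slope = beta[2], coef_ci = coef_ci,
                 se = se, sigma2 = sigma2, sigma2_ml = sigma2_ml,
                 loglik = loglik, residuals = resid,
                 fitted = stats::setNames(fitted, sp), n = n,
                 alpha = alpha, x_name = pair$x_name, y_name = pair$y_name),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, digits = 4, ...) {
  cat(sprintf("PGLS fit: log10(%s) = %s + %s * log10(%s)   [n = %d]\n",
              x$y_name, format(x$intercept, digits = digits),
              format(x$slope, digits = digits), x$x_name, x$n))
  cat(sprintf("  slope %g%% CI: (%s, %s)   logLik = %s\n",
              100 * (1 - x$alpha),
              format(x$coef_ci["slope", 1], digits = digits),
              format(x$coef_ci["slope", 2], digits = digits),
              format(x$loglik, digits = digits)))
  invisible(x)
}

#' Residuals of a PGLS fit, indexed by species
#'
#' Raw-scale residuals `y - (intercept + slope * x)`, named by species so
#' they can be fed directly into [fit_model()] or [pmc()] for trait
#' co-diversification analyses.
#'
#' @param fit A `pgls_fit`.
#' @return Named numeric vector.
#' @export
pgls_residuals <- function(fit) {
  stopifnot(inherits(fit, "pgls_fit"))
  fit$residuals
}
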