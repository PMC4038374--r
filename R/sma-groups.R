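## Multi-group SMA: common slope and elevation --------------------------------
##
## Likelihood-ratio test of slope homogeneity across groups under the
## bivariate-normal SMA formulation, and Wald tests of equality of
## elevations (intercepts) at the common slope.

.group_label <- function(groups) {
  nm <- names(groups)
  if (is.null(nm) || any(nm == ""))
    nm <- vapply(groups, function(g) g$y_name, character(1))
  if (anyDuplicated(nm)) nm <- paste0(nm, " [", seq_along(nm), "]")
  nm
}

.check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least 2 variable_pair groups", call. = FALSE)
  nm <- .group_label(groups)
  for (i in seq_along(groups)) {
    ok <- tryCatch({ .check_pair(groups[[i]]); TRUE },
                   error = function(e) e)
    if (!isTRUE(ok))
      stop(sprintf("group '%s': %s", nm[i], conditionMessage(ok)),
           call. = FALSE)
  }
  nm
}

## squared residual-axis correlation at slope b, per group
.r2_uv <- function(pair, b) {
  u <- pair$y - b * pair$x
  v <- pair$y + b * pair$x
  su <- stats::sd(u); sv <- stats::sd(v)
  if (su == 0 || sv == 0) return(0)
  stats::cor(u, v)^2
}

## pooled LR statistic profile: S(b) = sum w_i * log(1 / (1 - r_uv_i(b)^2));
## zero at each group's own SMA slope, minimized at the common slope MLE.
## The weight w_i = n_i - 2.5 is the Warton-Weber small-sample (Bartlett-type)
## correction, which brings the chi-square reference into calibration at
## the group sizes typical of allometric samples.
.common_slope_profile <- function(groups, b) {
  ## 1 - r2 is clamped away from zero: exactly collinear groups would
  ## otherwise put an infinite wall at every slope but their own
  sum(vapply(groups, function(g)
    -(g$n - 2.5) * log(pmax(1 - .r2_uv(g, b), 1e-12)), numeric(1)))
}

#' Likelihood-ratio test for a common SMA slope across groups
#'
#' Under the bivariate-normal formulation of the SMA, the profile
#' log-likelihood for a shared slope `b` is (up to a constant)
#' `-0.5 * sum_i n_i * log(1 / (1 - r_uv_i(b)^2))`, where `r_uv_i(b)` is
#' the group-i correlation between residual scores `y - b*x` and axis
#' scores `y + b*x`.  The common slope maximizes this pooled profile, and
#' the statistic `sum_i n_i * log(1 / (1 - r_uv_i(b_common)^2))` is
#' referred to a chi-square with `k - 1` degrees of freedom (each group's
#' own SMA slope zeroes its term, so the free-slopes likelihood is the
#' reference point).  Group weights carry the Warton-Weber small-sample
#' correction `n_i - 2.5`, which keeps the test near its nominal size at
#' typical allometric sample sizes.
#'
#' @param groups List of `variable_pair` objects (names used as labels).
#' @param alpha Rejection level.
#' @return A `common_slope_test`: `b_common`, `statistic`, `df`, `p`,
#'   `group_fits` (per-group [fit_sma()] results), `var_b_common`.
#' @export
test_common_slope <- function(groups, alpha = 0.05) {
  nm <- .check_groups(groups)
  fits <- lapply(groups, fit_sma, alpha = alpha)
  names(fits) <- nm
  slopes <- vapply(fits, `[[`, numeric(1), "slope")
  if (any(slopes > 0) && any(slopes < 0))
    stop("group SMA slopes differ in sign; a common slope is not meaningful",
         call. = FALSE)
  span <- range(slopes)
  pad <- 0.5 * max(diff(span), 1e-3 * max(abs(span)))
  lower <- span[1] - pad; upper <- span[2] + pad
  opt <- stats::optimize(function(b) .common_slope_profile(groups, b),
                         lower = lower, upper = upper, tol = 1e-10)
  ## the group slopes themselves are natural candidates; with exactly
  ## collinear groups the continuous search cannot land on them
  cand_b <- c(opt$minimum, slopes)
  cand_s <- c(opt$objective,
              vapply(slopes, function(b) .common_slope_profile(groups, b),
                     numeric(1)))
  best <- which.min(cand_s)
  b_c <- unname(cand_b[best])
  statistic <- max(cand_s[best], 0)
  df <- length(groups) - 1L
  p <- stats::pchisq(statistic, df, lower.tail = FALSE)
  ## curvature of the pooled profile -> large-sample variance of b_common
  h <- max(1e-4, 1e-4 * abs(b_c))
  d2 <- (.common_slope_profile(groups, b_c + h) - 2 * statistic +
           .common_slope_profile(groups, b_c - h)) / h^2
  var_b <- if (is.finite(d2) && d2 > 0) 2 / d2 else NA_real_
  structure(list(b_common = b_c, statistic = statistic, df = df, p = p,
                 alpha = alpha, group_fits = fits, var_b_common = var_b),
            class = "common_slope_test")
}

#' @export
print.common_slope_test <- function(x, ...) {
  cat(sprintf("Common SMA slope test: b_common = %.4g, LR = %.4g, df = %d, p = %.4g (%s)\n",
              x$b_common, x$statistic, x$df, x$p,
              if (x$p < x$alpha) "slopes differ" else "common slope retained"))
  invisible(x)
}

## elevations and their covariance matrix at a fixed common slope
.elevation_stats <- function(groups, b_c, var_b) {
  k <- length(groups)
  a <- num <- xbar <- va <- numeric(k)
  for (i in seq_len(k)) {
    g <- groups[[i]]
    u <- g$y - b_c * g$x
    a[i] <- mean(u)
    xbar[i] <- mean(g$x)
    va[i] <- stats::var(u) / g$n
  }
  V <- diag(va, k) + outer(xbar, xbar) * var_b
  list(a = a, V = V)
}

#' Wald test for equal SMA elevations (intercepts) across groups
#'
#' Compares group elevations `mean(y_i) - b_common * mean(x_i)` at the
#' pooled common slope.  Elevation variances combine the residual
#' variation about the common-slope axis with the shared uncertainty in
#' the common slope itself (which also induces covariance between
#' elevations).  The omnibus statistic is a Wald chi-square with `k - 1`
#' degrees of freedom.  Intended for use after [test_common_slope()] has
#' retained a shared slope; a warning is issued otherwise.
#'
#' @param groups List of `variable_pair` objects.
#' @param alpha Rejection level.
#' @param common Optionally, a precomputed `common_slope_test` for these
#'   groups (avoids refitting).
#' @return An `elevation_test`: `statistic`, `df`, `p`, `b_common_used`,
#'   `elevations`.
#' @export
test_elevation <- function(groups, alpha = 0.05, common = NULL) {
  nm <- .check_groups(groups)
  if (is.null(common)) common <- test_common_slope(groups, alpha = alpha)
  if (common$p < alpha)
    warning("common slope was rejected (p = ", signif(common$p, 3),
            "); elevation comparison at a shared slope is questionable",
            call. = FALSE)
  es <- .elevation_stats(groups, common$b_common, common$var_b_common)
  k <- length(groups)
  L <- cbind(diag(k - 1), -1)          # contrasts a_i - a_k
  d <- drop(L %*% es$a)
  V_d <- L %*% es$V %*% t(L)
  W <- tryCatch(drop(t(d) %*% solve(V_d, d)), error = function(e) NULL)
  if (is.null(W)) {
    ## degenerate (noise-free) groups: elevation differences carry no
    ## sampling variance, so any nonzero difference is conclusive
    W <- if (max(abs(d)) < 1e-10) 0 else Inf
  }
  p <- stats::pchisq(W, k - 1, lower.tail = FALSE)
  structure(list(statistic = W, df = k - 1L, p = p, alpha = alpha,
                 b_common_used = common$b_common,
                 elevations = stats::setNames(es$a, nm)),
            class = "elevation_test")
}

#' @export
print.elevation_test <- function(x, ...) {
  cat(sprintf("Elevation (Wald) test at b_common = %.4g: W = %.4g, df = %d, p = %.4g\n",
              x$b_common_used, x$statistic, x$df, x$p))
  invisible(x)
}

#' Pairwise elevation comparisons
#'
#' One-degree-of-freedom Wald tests of elevation for every pair of
#' groups, at the overall common slope.  P-values are unadjusted: the
#' analysis philosophy pairs effect-size intervals with raw significance
#' values rather than Bonferroni-style corrections.
#'
#' @param groups List of `variable_pair` objects.
#' @param alpha Rejection level.
#' @return List with `p`: symmetric matrix of pairwise p-values,
#'   `statistic`: matching Wald statistics, `b_common_used`.
#' @export
pairwise_elevation <- function(groups, alpha = 0.05) {
  nm <- .check_groups(groups)
  common <- test_common_slope(groups, alpha = alpha)
  es <- .elevation_stats(groups, common$b_common, common$var_b_common)
  k <- length(groups)
  P <- W <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    v <- es$V[i, i] + es$V[j, j] - 2 * es$V[i, j]
    dd <- es$a[i] - es$a[j]
    w <- if (v > 0) dd^2 / v else if (abs(dd) < 1e-10) 0 else Inf
    W[i, j] <- W[j, i] <- w
    P[i, j] <- P[j, i] <- stats::pchisq(w, 1, lower.tail = FALSE)
  }
  list(p = P, statistic = W, b_common_used = common$b_common)
}
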