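## Segment mass proportions and coefficient-of-variation comparison ----------

#' Per-species hindlimb segment mass proportions
#'
#' For each species with thigh, shank, tarsometatarsal, and digit masses
#' all present, expresses each segment as a share of their sum (the pes
#' is the tars + digit composite, so it is not a fifth component).
#' Species lacking any component are dropped and counted.
#'
#' @param table A `trait_table`.
#' @return A `proportion_table`: data frame with `species` and the four
#'   shares (rows sum to 1), plus attribute `n_dropped`.
#' @export
segment_proportions <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  comp <- c("thigh_mass", "shank_mass", "tars_mass", "digit_mass")
  M <- as.matrix(as.data.frame(table)[, comp])
  keep <- stats::complete.cases(M)
  n_dropped <- sum(!keep)
  if (!any(keep))
    stop("no species has all four segment masses", call. = FALSE)
  M <- M[keep, , drop = FALSE]
  tot <- rowSums(M)
  if (any(tot <= 0)) stop("zero total segment mass", call. = FALSE)
  out <- data.frame(species = table$species[keep], M / tot,
                    stringsAsFactors = FALSE)
  names(out) <- c("species", "thigh", "shank", "tars", "digits")
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("proportion_table", "data.frame")
  out
}

.cv <- function(v) stats::sd(v) / mean(v)

.cv_groups_check <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  nm <- names(groups)
  if (is.null(nm) || any(nm == "")) nm <- paste0("group", seq_along(groups))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    if (length(g) < 3L)
      stop(sprintf("group '%s' has fewer than 3 values", nm[i]), call. = FALSE)
    if (any(!is.finite(g)) || any(g <= 0))
      stop(sprintf("group '%s' contains non-positive or non-finite values",
                   nm[i]), call. = FALSE)
  }
  nm
}

#' Test equality of coefficients of variation across groups
#'
#' For positive data the coefficient of variation is monotonically tied
#' to the dispersion of the log values (Var(log v) ~ CV^2 for moderate
#' CVs), so equal CVs correspond to homogeneous log-scale variances.
#' The test log-transforms each group and applies a Levene-type
#' homogeneity test: a one-way ANOVA of absolute deviations of the log
#' values from their group means.  When a `block` factor is supplied
#' (e.g. species measured on every segment), an additive group + block
#' model is removed from the log values first and deviations are taken
#' about the resulting cell fits, so between-block size variation does
#' not masquerade as dispersion.
#'
#' @param groups Named list of positive numeric vectors.
#' @param alpha Rejection level.
#' @param block Optional list (parallel to `groups`) of blocking labels.
#' @return A `cv_test`: `cv` per group, `statistic` (F), `df`, `p`.
#' @export
test_cv_equality <- function(groups, alpha = 0.05, block = NULL) {
  nm <- .cv_groups_check(groups)
  cvs <- stats::setNames(vapply(groups, .cv, numeric(1)), nm)
  lv <- lapply(groups, log)
  g <- factor(rep(nm, lengths(groups)), levels = nm)
  v <- unlist(lv, use.names = FALSE)
  if (is.null(block)) {
    dev <- abs(v - stats::ave(v, g))
    fit <- stats::aov(dev ~ g)
  } else {
    b <- factor(unlist(block, use.names = FALSE))
    if (length(b) != length(v))
      stop("block must parallel groups in shape", call. = FALSE)
    two_way <- stats::lm(v ~ g + b)
    dev <- abs(stats::residuals(two_way))
    fit <- stats::aov(dev ~ g)
  }
  an <- stats::anova(fit)
  structure(list(cv = cvs, statistic = an$`F value`[1],
                 df = an$Df[1:2], p = an$`Pr(>F)`[1], alpha = alpha),
            class = "cv_test")
}

#' @export
print.cv_test <- function(x, ...) {
  cat("CV equality test (Levene-type on log values)\n")
  cat("  per-group CV:",
      paste(sprintf("%s = %.3f", names(x$cv), x$cv), collapse = ", "), "\n")
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n", x$df[1], x$df[2],
              x$statistic, x$p))
  invisible(x)
}

#' Pairwise CV equality tests
#'
#' Runs [test_cv_equality()] on every pair of groups; p-values are
#' unadjusted.  Pairs are always compared without blocking: with only
#' two groups, the additive group + block fit forces the two groups'
#' absolute residuals to coincide, so the blocked statistic is
#' identically zero and carries no information.
#'
#' @inheritParams test_cv_equality
#' @return Symmetric matrix of p-values.
#' @export
pairwise_cv_tests <- function(groups, alpha = 0.05) {
  nm <- .cv_groups_check(groups)
  k <- length(groups)
  P <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    P[i, j] <- P[j, i] <-
      test_cv_equality(groups[c(i, j)], alpha = alpha)$p
  }
  P
}
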