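## Maximum-likelihood trait-evolution models ----------------------------------
##
## Single continuous trait on a time-calibrated tree.  Models: BM
## (constant-rate Brownian motion), lambda (phylogenetic-signal scaling
## of shared covariances), delta (power transform of node depths).  The
## rate sigma2 and root state are profiled out analytically, leaving a
## 1-D bounded likelihood in the transform parameter.

.delta_eps <- 1e-6   # open lower bound of the delta search interval

## Cholesky with a single jitter retry; errors if still not PD.
.safe_chol <- function(C) {
  R <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(R)) {
    jitter <- 1e-10 * mean(diag(C))
    R <- tryCatch(chol(C + diag(jitter, nrow(C))), error = function(e) NULL)
    if (is.null(R))
      stop("covariance matrix is not positive definite (even after jitter); ",
           "check the tree and transform parameter", call. = FALSE)
  }
  R
}

#' Profile log-likelihood of a trait under a Gaussian phylogenetic model
#'
#' For tip values `y ~ MVN(root * 1, sigma2 * C)`, profiles out the root
#' state (GLS mean) and the rate (ML estimate with denominator `n`),
#' returning the maximized log-likelihood:
#' `-(n/2) * log(2*pi*sigma2_hat) - log(det(C))/2 - n/2`.
#'
#' @param y Named numeric vector of tip values (names must match `C`'s
#'   rownames, in any order; unnamed vectors are taken as already
#'   aligned).
#' @param C Phylogenetic covariance matrix (possibly transformed).
#' @return List with `loglik`, `sigma2`, `root`.
#' @export
mvn_profile_loglik <- function(y, C) {
  if (!is.null(names(y)) && !is.null(rownames(C))) {
    if (!setequal(names(y), rownames(C)))
      stop("names of y do not match rownames of C", call. = FALSE)
    y <- y[rownames(C)]
  }
  if (length(y) != nrow(C))
    stop("length(y) must equal nrow(C)", call. = FALSE)
  .profile_ll(as.numeric(y), C)
}

## profile likelihood without name checks, for aligned inputs (hot path)
.profile_ll <- function(y, C) {
  n <- length(y)
  R <- .safe_chol(C)
  z <- backsolve(R, y, transpose = TRUE)
  w <- backsolve(R, rep(1, n), transpose = TRUE)
  root <- sum(w * z) / sum(w * w)
  sigma2 <- sum((z - root * w)^2) / n
  if (sigma2 <= .Machine$double.eps * max(1, sum(z^2)))
    stop("degenerate trait: zero variance after removing the root state",
         call. = FALSE)
  list(loglik = -0.5 * n * log(2 * pi * sigma2) - sum(log(diag(R))) - 0.5 * n,
       sigma2 = sigma2, root = root)
}

## 1-D bounded ML in the transform parameter, given the untransformed C
## (y must already be aligned with C's rows)
.fit_theta_core <- function(y, C, model) {
  if (model == "BM") {
    prof <- .profile_ll(y, C)
    return(list(theta = NA_real_, loglik = prof$loglik,
                sigma2 = prof$sigma2, root = prof$root,
                at_boundary = FALSE))
  }
  bounds <- .theta_bounds(model)
  d <- diag(C)
  f <- if (model == "lambda") {
    function(th) { Ct <- C * th; diag(Ct) <- d; .profile_ll(y, Ct)$loglik }
  } else {
    function(th) .profile_ll(y, C^th)$loglik
  }
  eps <- 1e-4 * diff(bounds)
  starts <- if (1 > bounds[1] + eps && 1 < bounds[2] - eps)
    list(c(bounds[1], 1), c(1, bounds[2])) else list(bounds)
  cand_theta <- cand_ll <- numeric(0)
  for (iv in starts) {
    opt <- stats::optimize(f, lower = iv[1], upper = iv[2],
                           maximum = TRUE, tol = 1e-8)
    cand_theta <- c(cand_theta, opt$maximum)
    cand_ll <- c(cand_ll, opt$objective)
  }
  for (b in c(bounds, if (bounds[1] < 1 && 1 < bounds[2]) 1)) {
    cand_theta <- c(cand_theta, b)
    cand_ll <- c(cand_ll, f(b))
  }
  best <- max(cand_ll)
  near <- which(cand_ll >= best - 1e-8)
  theta <- cand_theta[near][which.min(abs(cand_theta[near] - 1))]
  prof <- .profile_ll(y, .transform_C(C, model, theta))
  list(theta = theta, loglik = prof$loglik, sigma2 = prof$sigma2,
       root = prof$root,
       at_boundary = theta <= bounds[1] + 1e-6 || theta >= bounds[2] - 1e-6)
}

.transform_C <- function(C, model, theta) {
  switch(model,
         BM = C,
         lambda = lambda_transform(C, theta),
         delta = delta_transform(C, theta),
         stop("unknown model '", model, "'", call. = FALSE))
}

.theta_bounds <- function(model) {
  switch(model,
         lambda = c(0, 1),
         delta = c(.delta_eps, 3),
         NULL)
}

#' Fit a trait-evolution model by maximum likelihood
#'
#' Fits BM, the lambda model (`lambda` in \[0, 1\]), or the delta model
#' (`delta` in (0, 3\]) to tip values on a time-calibrated tree.  The
#' transform parameter is estimated by bounded 1-D optimization of the
#' profile likelihood, with multiple starts (near both bounds and at the
#' Brownian-motion reference value 1) to avoid local optima; near-ties
#' are broken toward the value closest to 1.  Boundary optima are
#' reported as such.
#'
#' @param y Named numeric vector of tip values.
#' @param tree An `ape::phylo` covering exactly the names of `y` (the
#'   tree is pruned to `names(y)` if it has extra tips).
#' @param model One of `"BM"`, `"lambda"`, `"delta"`.
#' @return An `evo_fit`: `model`, `theta` (`NA` for BM), `sigma2`,
#'   `root_state`, `loglik`, `at_boundary`, `n`.
#' @export
fit_model <- function(y, tree, model = c("BM", "lambda", "delta")) {
  model <- match.arg(model)
  if (is.null(names(y)))
    stop("y must be named by species", call. = FALSE)
  if (length(y) < 4L)
    stop("need at least 4 tips to fit a trait-evolution model", call. = FALSE)
  extra <- setdiff(names(y), tree$tip.label)
  if (length(extra))
    stop("species in y absent from tree: ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (length(setdiff(tree$tip.label, names(y))) > 0)
    tree <- prune_to(tree, names(y))
  if (model == "delta" && !is_ultrametric(tree))
    stop("delta model requires an ultrametric tree", call. = FALSE)
  C <- vcv_matrix(tree)
  y <- y[rownames(C)]
  core <- .fit_theta_core(as.numeric(y), C, model)
  structure(list(model = model, theta = core$theta, sigma2 = core$sigma2,
                 root_state = core$root, loglik = core$loglik,
                 at_boundary = core$at_boundary, n = length(y),
                 tree = tree, y = y),
            class = "evo_fit")
}

#' @export
print.evo_fit <- function(x, ...) {
  cat(sprintf("Trait-evolution fit: %s model, n = %d tips\n", x$model, x$n))
  if (!is.na(x$theta))
    cat(sprintf("  %s = %.4g%s\n",
                if (x$model == "lambda") "lambda" else "delta", x$theta,
                if (x$at_boundary) " (at search bound)" else ""))
  cat(sprintf("  sigma2 = %.4g, root = %.4g, logLik = %.4f\n",
              x$sigma2, x$root_state, x$loglik))
  invisible(x)
}

## One MVN draw per column: root + t(R) %*% z with R = chol(sigma2 * C)
.simulate_tips <- function(n_sim, root, sigma2, C) {
  R <- .safe_chol(sigma2 * C)
  Z <- matrix(stats::rnorm(nrow(C) * n_sim), nrow(C), n_sim)
  sims <- crossprod(R, Z) + root
  rownames(sims) <- rownames(C)
  sims
}

#' Parametric-bootstrap confidence interval for a transform parameter
#'
#' Simulates `n_sim` datasets under the fitted model (its estimated
#' transform parameter, rate, and root state), refits the same model to
#' each, and returns percentile limits of the refitted parameter.  With
#' few species and deep divergences these intervals are characteristically
#' wide, often pinned at the parameter bounds.
#'
#' @param y Named numeric vector of tip values.
#' @param tree An `ape::phylo`.
#' @param model `"lambda"` or `"delta"`.
#' @param n_sim Number of bootstrap replicates (values below 100 warn).
#' @param seed Integer seed (mandatory, recorded in the result).
#' @param level Confidence level.
#' @return A `boot_ci`: `ci` (low, high), `theta_hat`, `theta_sims`,
#'   `n_sim`, `seed`, `level`.
#' @export
bootstrap_ci <- function(y, tree, model = c("lambda", "delta"),
                         n_sim = 1000, seed, level = 0.95) {
  model <- match.arg(model)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (n_sim < 100)
    warning("n_sim < 100 gives unstable percentile limits", call. = FALSE)
  fit <- fit_model(y, tree, model)
  C <- vcv_matrix(fit$tree)
  Ct <- .transform_C(C, model, fit$theta)
  set.seed(as.integer(seed))
  sims <- .simulate_tips(n_sim, fit$root_state, fit$sigma2, Ct)
  theta_sims <- vapply(seq_len(n_sim), function(i)
    fit_model(sims[, i], fit$tree, model)$theta, numeric(1))
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- stats::quantile(theta_sims, probs, names = FALSE)
  structure(list(ci = ci, theta_hat = fit$theta, theta_sims = theta_sims,
                 n_sim = n_sim, seed = as.integer(seed), level = level,
                 model = model),
            class = "boot_ci")
}

#' @export
print.boot_ci <- function(x, ...) {
  cat(sprintf("Parametric-bootstrap %g%% CI for %s: (%.3f, %.3f)  [%d sims, seed %d]\n",
              100 * x$level, x$model, x$ci[1], x$ci[2], x$n_sim, x$seed))
  invisible(x)
}
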