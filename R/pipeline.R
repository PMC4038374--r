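## Study-reproduction pipeline ------------------------------------------------
##
## High-level drivers that run the full analysis batteries over a trait
## table: the SMA scaling tables (with isometry, common-slope, and
## elevation tests), the phylogenetic battery (trait-evolution fits,
## PGLS, co-diversification pmc), and the CV comparison.  Each returns
## plain data frames mirroring the published table layouts, with a
## full-precision column next to a display-rounded one so exact-match
## checking is unambiguous.

.segment_traits <- c(thigh_mass = "Thigh mass", shank_mass = "Shank mass",
                     pes_mass = "Pes mass", tars_mass = "Tars. mass",
                     digit_mass = "Digit mass")

.null_slope_for <- function(x_name)
  if (x_name == "hindlimb_length") 3.0 else 1.0

.fmt_ci <- function(lo, hi, digits = 3)
  sprintf(paste0("%.", digits, "f, %.", digits, "f"), lo, hi)

#' SMA scaling battery for the five segment masses
#'
#' Regresses each segment mass on one size variable across a trait
#' table: SMA fit, confidence intervals, and the isometry F-test against
#' the geometric-similarity null slope (1.0 against body mass, 3.0
#' against hindlimb length).
#'
#' @param table A `trait_table`.
#' @param x_name `"body_mass"` or `"hindlimb_length"`.
#' @param alpha Significance level.
#' @return Data frame with one row per segment: `trait`, `n`,
#'   `intercept`, `intercept_ci`, `slope`, `slope_ci`, `r2`, `p_iso`,
#'   `ci_excludes_null`, plus display-rounded columns (`*_disp`).
#' @export
scaling_table <- function(table, x_name = "body_mass", alpha = 0.05) {
  .check_trait_name(x_name)
  b0 <- .null_slope_for(x_name)
  rows <- lapply(names(.segment_traits), function(seg) {
    pair <- pair_complete(table, x_name, seg)
    fit <- fit_sma(pair, alpha = alpha)
    ft <- test_slope(pair, b0, alpha = alpha)
    data.frame(trait = .segment_traits[[seg]], n = fit$n,
               intercept = fit$intercept,
               intercept_low = fit$intercept_ci[1],
               intercept_high = fit$intercept_ci[2],
               slope = fit$slope,
               slope_low = fit$slope_ci[1], slope_high = fit$slope_ci[2],
               r2 = fit$r2, p_iso = ft$p,
               ci_excludes_null = ci_excludes(fit, b0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$intercept_disp <- sprintf("%.2f", out$intercept)
  out$intercept_ci_disp <- .fmt_ci(out$intercept_low, out$intercept_high)
  out$slope_disp <- sprintf("%.2f", out$slope)
  out$slope_ci_disp <- .fmt_ci(out$slope_low, out$slope_high)
  out$r2_disp <- sprintf("%.4f", out$r2)
  out$p_disp <- ifelse(out$p_iso < 1e-4, "< 0.0001", sprintf("%.4f", out$p_iso))
  attr(out, "x_name") <- x_name
  attr(out, "null_slope") <- b0
  out
}

#' Common-slope, elevation, and pairwise structure for one battery
#'
#' Runs [test_common_slope()], [test_elevation()], and
#' [pairwise_elevation()] over the five segment-vs-size pairings of a
#' trait table.
#'
#' @inheritParams scaling_table
#' @return List with `common_slope`, `elevation`, `pairwise_p`.
#' @export
group_structure_tests <- function(table, x_name = "body_mass", alpha = 0.05) {
  groups <- lapply(names(.segment_traits), function(seg)
    pair_complete(table, x_name, seg))
  names(groups) <- .segment_traits
  cs <- test_common_slope(groups, alpha = alpha)
  el <- test_elevation(groups, alpha = alpha, common = cs)
  pw <- pairwise_elevation(groups, alpha = alpha)
  list(common_slope = cs, elevation = el, pairwise_p = pw$p)
}

#' Reproduce the scaling analysis tables
#'
#' The full SMA battery: five segment masses against body mass and
#' hindlimb length, for the whole table and (when present) one subclade,
#' together with the common-slope/elevation test structure of each
#' battery.
#'
#' @param table A `trait_table` (default: the bundled neognath data).
#' @param clade Subclade label to analyse separately, or `NULL` to skip
#'   (default `"Land birds"` when that label exists in the table).
#' @param alpha Significance level.
#' @return List of scaling tables `whole_body_mass`,
#'   `whole_hindlimb_length`, `clade_body_mass`, `clade_hindlimb_length`
#'   and a parallel list `tests` of [group_structure_tests()] results.
#' @export
reproduce_tables <- function(table = fixture_neognath(), clade = NULL,
                             alpha = 0.05) {
  if (is.null(clade) && "Land birds" %in% attr(table, "clades"))
    clade <- "Land birds"
  out <- list(
    whole_body_mass = scaling_table(table, "body_mass", alpha),
    whole_hindlimb_length = scaling_table(table, "hindlimb_length", alpha))
  tests <- list(
    whole_body_mass = group_structure_tests(table, "body_mass", alpha),
    whole_hindlimb_length = group_structure_tests(table, "hindlimb_length",
                                                  alpha))
  if (!is.null(clade)) {
    sub <- subset_clade(table, clade)
    out$clade_body_mass <- scaling_table(sub, "body_mass", alpha)
    out$clade_hindlimb_length <- scaling_table(sub, "hindlimb_length", alpha)
    tests$clade_body_mass <- group_structure_tests(sub, "body_mass", alpha)
    tests$clade_hindlimb_length <- group_structure_tests(sub,
                                                         "hindlimb_length",
                                                         alpha)
  }
  out$tests <- tests
  out$clade <- clade
  out
}

#' Phylogenetic battery: trait-evolution fits, PGLS, co-diversification
#'
#' For every trait: lambda and delta model fits with parametric-bootstrap
#' confidence intervals.  For every segment-vs-size pairing: a PGLS
#' regression under the Brownian covariance and a [pmc()] comparison of
#' the lambda and delta models on its residuals.
#'
#' @param table A `trait_table`.
#' @param tree An ultrametric `ape::phylo` covering the table's species.
#' @param n_sim Bootstrap/Monte Carlo size (the study-scale default is
#'   1000; reduce for exploratory runs).
#' @param seed Integer master seed (mandatory).
#' @param traits Trait identifiers for the single-trait fits.
#' @return List of data frames `trait_models` (per-trait lambda/delta
#'   fits and CIs), `pgls` (per-pairing coefficients), and
#'   `codiversification` (per-pairing pmc summaries).
#' @export
run_phylo_analysis <- function(table, tree, n_sim = 1000, seed,
                               traits = trait_names()) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  seed <- as.integer(seed)
  miss <- setdiff(table$species, tree$tip.label)
  if (length(miss))
    stop("species missing from tree: ", paste(miss, collapse = ", "),
         call. = FALSE)

  trait_models <- do.call(rbind, lapply(seq_along(traits), function(i) {
    tr_name <- .check_trait_name(traits[i])
    v <- table[[tr_name]]
    keep <- !is.na(v)
    y <- stats::setNames(log10(v[keep]), table$species[keep])
    tr <- prune_to(tree, names(y))
    fl <- fit_model(y, tr, "lambda")
    fd <- fit_model(y, tr, "delta")
    cil <- bootstrap_ci(y, tr, "lambda", n_sim = n_sim, seed = seed + 10L * i)
    cid <- bootstrap_ci(y, tr, "delta", n_sim = n_sim,
                        seed = seed + 10L * i + 5L)
    data.frame(trait = tr_name, n = length(y),
               lambda = fl$theta, lambda_low = cil$ci[1],
               lambda_high = cil$ci[2], loglik_lambda = fl$loglik,
               delta = fd$theta, delta_low = cid$ci[1],
               delta_high = cid$ci[2], loglik_delta = fd$loglik,
               lr_delta_minus_lambda = fd$loglik - fl$loglik,
               stringsAsFactors = FALSE)
  }))

  pairings <- expand.grid(y = names(.segment_traits),
                          x = c("body_mass", "hindlimb_length"),
                          stringsAsFactors = FALSE)
  pgls_rows <- list(); codiv_rows <- list()
  for (i in seq_len(nrow(pairings))) {
    yn <- pairings$y[i]; xn <- pairings$x[i]
    pair <- pair_complete(table, xn, yn)
    tr <- prune_to(tree, pair$species)
    fit <- fit_pgls(pair, vcv_matrix(tr))
    pgls_rows[[i]] <- data.frame(
      trait = .segment_traits[[yn]], x = xn, n = fit$n,
      intercept = fit$intercept,
      intercept_low = fit$coef_ci["intercept", 1],
      intercept_high = fit$coef_ci["intercept", 2],
      slope = fit$slope,
      slope_low = fit$coef_ci["slope", 1],
      slope_high = fit$coef_ci["slope", 2],
      loglik = fit$loglik, stringsAsFactors = FALSE)
    cmp <- pmc(pgls_residuals(fit), tr, n_sim = n_sim,
               seed = seed + 1000L + 7L * i)
    codiv_rows[[i]] <- data.frame(
      trait = .segment_traits[[yn]], x = xn, n = fit$n,
      lambda = cmp$fit_lambda$theta, loglik_lambda = cmp$fit_lambda$loglik,
      ci_lambda_low = cmp$ci_lambda[1], ci_lambda_high = cmp$ci_lambda[2],
      delta = cmp$fit_delta$theta, loglik_delta = cmp$fit_delta$loglik,
      ci_delta_low = cmp$ci_delta[1], ci_delta_high = cmp$ci_delta[2],
      lr_observed = cmp$lr_observed,
      verdict_lambda = cmp$verdict_lambda,
      verdict_delta = cmp$verdict_delta, stringsAsFactors = FALSE)
  }
  list(trait_models = trait_models,
       pgls = do.call(rbind, pgls_rows),
       codiversification = do.call(rbind, codiv_rows),
       n_sim = n_sim, seed = seed)
}

#' CV comparison of segment mass proportions
#'
#' Computes per-species segment shares of total limb mass and compares
#' their coefficients of variation across segments (omnibus and
#' pairwise).  The omnibus comparison uses species as the blocking unit;
#' pairwise comparisons are unblocked (see [pairwise_cv_tests()]).
#'
#' @param table A `trait_table`.
#' @param alpha Rejection level.
#' @return List with `proportions`, `cv` (per segment), `omnibus` (a
#'   `cv_test`), `pairwise_p`.
#' @export
run_cv_analysis <- function(table, alpha = 0.05) {
  prop <- segment_proportions(table)
  groups <- list(thigh = prop$thigh, shank = prop$shank,
                 tars = prop$tars, digits = prop$digits)
  block <- rep(list(prop$species), 4)
  omni <- test_cv_equality(groups, alpha = alpha, block = block)
  pw <- pairwise_cv_tests(groups, alpha = alpha)
  list(proportions = prop, cv = omni$cv, omnibus = omni, pairwise_p = pw)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper pairing [simulate_allometric_table()] (with
#' phylogenetically correlated residuals) and its tree, ready to be fed
#' through [reproduce_tables()] and [run_phylo_analysis()].
#'
#' @param n_species Number of species.
#' @param seed Integer seed (mandatory).
#' @param ... Passed to [simulate_allometric_table()].
#' @return List with `table`, `tree`, `truth`.
#' @export
simulate_study <- function(n_species = 38, seed, ...) {
  simulate_allometric_table(n_species = n_species, seed = seed,
                            phylo_resid = TRUE, ...)
}
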