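## Synthetic data with known ground truth -------------------------------------
##
## Emulates the statistical structure of the study data: a few dozen
## species spanning ~2.6 decades of body mass, segment masses following
## a log-linear allometry, and an ultrametric time-calibrated tree with
## deep (~110 My) divergences.

#' Simulate an ultrametric Yule tree
#'
#' Pure-birth tree with `n_tips` extant species, optionally rescaled so
#' the root-to-tip depth equals `depth` (e.g. 110 My, the scale of the
#' deepest divergences among sampled neognath lineages).
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate (per lineage per unit time).
#' @param seed Integer seed (mandatory).
#' @param depth Optional target root-to-tip depth.
#' @return An ultrametric `ape::phylo` with tips `t1..tn`.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed, depth = NULL) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (n_tips < 2) stop("need at least 2 tips", call. = FALSE)
  set.seed(as.integer(seed))
  tr <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  if (!is.null(depth)) {
    d0 <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * depth / d0
  }
  tr
}

#' Simulate a trait on a tree under BM, lambda, or delta
#'
#' Draws one realization from `MVN(root_state * 1, sigma2 * C_theta)`,
#' where `C_theta` is the tree's Brownian covariance after the requested
#' transform.
#'
#' @param tree An `ape::phylo`.
#' @param model `"BM"`, `"lambda"`, or `"delta"`.
#' @param theta Transform parameter (ignored for BM).
#' @param sigma2 Brownian rate (trait^2 per unit branch length; may be 0).
#' @param root_state Ancestral mean.
#' @param seed Integer seed (mandatory).
#' @return Named numeric vector of tip values.
#' @export
simulate_trait <- function(tree, model = c("BM", "lambda", "delta"),
                           theta = NULL, sigma2 = 1, root_state = 0, seed) {
  model <- match.arg(model)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (sigma2 < 0) stop("sigma2 must be non-negative", call. = FALSE)
  C <- vcv_matrix(tree)
  if (sigma2 == 0)
    return(stats::setNames(rep(root_state, nrow(C)), rownames(C)))
  if (model != "BM" && is.null(theta))
    stop("theta is required for the ", model, " model", call. = FALSE)
  Ct <- .transform_C(C, model, if (model == "BM") NA else theta)
  set.seed(as.integer(seed))
  drop(.simulate_tips(1, root_state, sigma2, Ct))[rownames(C)]
}

#' Simulate a species-by-trait allometric table
#'
#' Generates a synthetic trait table with the bundled data's structure:
#' log10 body mass drawn log-uniformly over a configurable span (the
#' study deliberately sampled functional extremes, so a log-uniform draw
#' is the default rather than a lognormal), hindlimb length scaling as
#' the cube root of body mass, and each of thigh, shank, tarsometatarsal,
#' and digit mass as `10^(intercept + slope * log10(M) + e)` with normal
#' residuals; the pes is their anatomical composite (tars + digits), an
#' exact power law whenever those two share a slope.
#' Residuals are iid by default, or phylogenetically correlated (BM on a
#' supplied or freshly simulated tree) when `phylo_resid = TRUE`.
#' Missing values can be punched in at a configurable rate.
#'
#' @param n_species Number of species.
#' @param slope,intercept,residual_sd Either scalars (shared by the five
#'   segments) or length-5 vectors ordered thigh, shank, pes, tars,
#'   digits; slopes are log-log against body mass, `residual_sd` is the
#'   log10-scale residual standard deviation.
#' @param log_mass_range Span of log10 body mass in grams (default
#'   matches the bundled table's 18-6975 g range).
#' @param missing_rate Fraction of segment-mass cells set missing
#'   (in \[0, 0.3\]).
#' @param phylo_resid Draw residuals as BM on a tree instead of iid.
#' @param tree Tree to use when `phylo_resid` (default: a fresh Yule
#'   tree of `n_species` tips, depth 110).
#' @param seed Integer seed (mandatory).
#' @return List with `table` (a `trait_table`), `tree` (or `NULL`), and
#'   `truth` (the generating parameters).
#' @export
simulate_allometric_table <- function(n_species = 38, slope = 1.1,
                                      intercept = c(-1.8, -1.9, -2.4, -2.8, -2.6),
                                      residual_sd = 0.1,
                                      log_mass_range = c(1.26, 3.84),
                                      missing_rate = 0, phylo_resid = FALSE,
                                      tree = NULL, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (missing_rate < 0 || missing_rate > 0.3)
    stop("missing_rate must lie in [0, 0.3]", call. = FALSE)
  segs <- c("thigh_mass_g", "shank_mass_g", "pes_mass_g", "tars_mass_g",
            "digit_mass_g")
  rep5 <- function(v) if (length(v) == 1L) rep(v, 5) else
    if (length(v) == 5L) v else stop("expected length 1 or 5", call. = FALSE)
  slope <- rep5(slope); intercept <- rep5(intercept)
  residual_sd <- rep5(residual_sd)

  seed <- as.integer(seed)
  species <- sprintf("t%d", seq_len(n_species))
  if (phylo_resid && is.null(tree))
    tree <- simulate_yule_tree(n_species, seed = seed + 101L, depth = 110)
  if (phylo_resid) species <- tree$tip.label

  set.seed(seed)
  logM <- stats::runif(n_species, log_mass_range[1], log_mass_range[2])
  logL <- (1 / 3) * logM + 0.55 + stats::rnorm(n_species, 0, 0.03)

  tab <- data.frame(species = species, clade = "Synthetic", n = 1,
                    body_mass_g = 10^logM,
                    hindlimb_length_cm = 10^logL,
                    stringsAsFactors = FALSE, check.names = FALSE)
  ## thigh, shank, tars, digits follow their allometries directly; the pes
  ## is their anatomical composite (tars + digits), which is itself an
  ## exact power law whenever the two share a slope
  for (s in c(1, 2, 4, 5)) {
    e <- if (residual_sd[s] == 0) {
      rep(0, n_species)
    } else if (phylo_resid) {
      v <- simulate_trait(tree, "BM", sigma2 = residual_sd[s]^2 / 110,
                          seed = seed + 200L + s)
      as.numeric(v[species])
    } else {
      stats::rnorm(n_species, 0, residual_sd[s])
    }
    tab[[segs[s]]] <- 10^(intercept[s] + slope[s] * logM + e)
  }
  tab$pes_mass_g <- tab$tars_mass_g + tab$digit_mass_g
  tab <- tab[, c("species", "clade", "n", "body_mass_g",
                 "hindlimb_length_cm", segs)]

  if (missing_rate > 0) {
    set.seed(seed + 999L)
    for (s in segs) {
      miss <- stats::runif(n_species) < missing_rate
      tab[[s]][miss] <- NA_real_
    }
  }

  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  utils::write.csv(tab, tmp, row.names = FALSE, na = "--")
  table <- read_trait_table(tmp, provenance = sprintf(
    "synthetic allometric table (n = %d, seed = %d)", n_species, seed))
  list(table = table, tree = tree,
       truth = list(slope = stats::setNames(slope, segs),
                    intercept = stats::setNames(intercept, segs),
                    residual_sd = stats::setNames(residual_sd, segs),
                    log_mass_range = log_mass_range,
                    missing_rate = missing_rate, seed = seed))
}
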