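# shared helpers: lightweight constructors and independent oracles

make_pair <- function(x, y, species = paste0("s", seq_along(x))) {
  structure(list(x = x, y = y, n = length(x), species = species,
                 x_name = "x", y_name = "y"),
            class = "variable_pair")
}

# bivariate sample with a known true SMA slope sqrt(1 + tau^2)
rpair <- function(n, tau = 0.6) {
  x <- stats::rnorm(n)
  make_pair(x, x + stats::rnorm(n, 0, tau))
}

# independent BM simulator: sums independent normal increments along each
# root-to-tip path, never touching the package's covariance code
simulate_bm_by_edges <- function(tree, n_rep, sigma2 = 1) {
  tree <- stats::reorder(tree, "cladewise")  # parents before children
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  incr <- matrix(stats::rnorm(nrow(tree$edge) * n_rep,
                              sd = sqrt(sigma2 * tree$edge.length)),
                 nrow(tree$edge), n_rep)
  vals <- matrix(0, n_node, n_rep)
  for (e in seq_len(nrow(tree$edge)))   # ape edges are in preorder
    vals[tree$edge[e, 2], ] <- vals[tree$edge[e, 1], ] + incr[e, ]
  tips <- vals[seq_len(n_tip), , drop = FALSE]
  rownames(tips) <- tree$tip.label
  tips
}

# dense multivariate-normal log-density via solve()/determinant(), as an
# independent check on the Cholesky profile likelihood
dense_mvn_loglik <- function(y, mu, S) {
  d <- y - mu
  as.numeric(-0.5 * t(d) %*% solve(S, d) -
               0.5 * determinant(S, logarithm = TRUE)$modulus -
               0.5 * length(y) * log(2 * pi))
}
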