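make_pgls_inputs <- function(n = 30, seed = 1) {
  set.seed(seed)
  tr <- simulate_yule_tree(n, seed = seed + 40, depth = 110)
  x <- simulate_trait(tr, "BM", sigma2 = 0.02, root_state = 2, seed = seed)
  e <- simulate_trait(tr, "BM", sigma2 = 0.004, seed = seed + 1)
  y <- -1.5 + 1.1 * x + e
  pair <- make_pair(as.numeric(x), as.numeric(y), species = names(x))
  list(pair = pair, tree = tr, C = vcv_matrix(tr))
}

test_that("PGLS with identity covariance is ordinary least squares", {
  set.seed(21)
  x <- rnorm(25); y <- 1 + 0.8 * x + rnorm(25, 0, 0.3)
  pair <- make_pair(x, y)
  C <- diag(25); dimnames(C) <- list(pair$species, pair$species)
  fit <- fit_pgls(pair, C)
  ols <- lm(y ~ x)
  expect_equal(unname(fit$intercept), unname(coef(ols)[1]), tolerance = 1e-12)
  expect_equal(unname(fit$slope), unname(coef(ols)[2]), tolerance = 1e-12)
  expect_equal(unname(fit$coef_ci),
               unname(confint(ols)), tolerance = 1e-10)
})

test_that("PGLS equals OLS on Cholesky-whitened data", {
  inp <- make_pgls_inputs()
  fit <- fit_pgls(inp$pair, inp$C)
  # independent whitening route
  ord <- match(rownames(inp$C), inp$pair$species)
  x <- inp$pair$x[ord]; y <- inp$pair$y[ord]
  W <- solve(t(chol(inp$C)))
  ols <- lm.fit(W %*% cbind(1, x), W %*% y)
  expect_equal(unname(fit$intercept), unname(ols$coefficients[1]),
               tolerance = 1e-10)
  expect_equal(unname(fit$slope), unname(ols$coefficients[2]),
               tolerance = 1e-10)
})

test_that("PGLS matches the gls(corBrownian) oracle", {
  inp <- make_pgls_inputs(seed = 5)
  fit <- fit_pgls(inp$pair, inp$C)
  df <- data.frame(x = inp$pair$x, y = inp$pair$y,
                   species = inp$pair$species)
  oracle <- nlme::gls(y ~ x, data = df, method = "ML",
                      correlation = ape::corBrownian(phy = inp$tree,
                                                     form = ~species))
  expect_equal(unname(fit$intercept), unname(coef(oracle)[1]),
               tolerance = 1e-8)
  expect_equal(unname(fit$slope), unname(coef(oracle)[2]), tolerance = 1e-8)
  expect_equal(fit$loglik, as.numeric(logLik(oracle)), tolerance = 1e-6)
})

test_that("GLS normal equations: C-inverse-weighted residuals sum to zero", {
  inp <- make_pgls_inputs(seed = 9)
  fit <- fit_pgls(inp$pair, inp$C)
  r <- fit$residuals[rownames(inp$C)]
  expect_lt(abs(sum(solve(inp$C, r))), 1e-10)
})

test_that("PGLS slope is invariant to additive shifts", {
  inp <- make_pgls_inputs(seed = 11)
  fit <- fit_pgls(inp$pair, inp$C)
  shifted <- make_pair(inp$pair$x + 3, inp$pair$y - 2,
                       species = inp$pair$species)
  fit2 <- fit_pgls(shifted, inp$C)
  expect_equal(fit2$slope, fit$slope, tolerance = 1e-10)
  expect_equal(fit2$intercept, fit$intercept - 2 - 3 * fit$slope,
               tolerance = 1e-10)
})

test_that("collinear pairs yield zero residuals", {
  inp <- make_pgls_inputs(seed = 2)
  exact <- make_pair(inp$pair$x, 0.5 + 2 * inp$pair$x,
                     species = inp$pair$species)
  fit <- fit_pgls(exact, inp$C)
  expect_lt(max(abs(pgls_residuals(fit))), 1e-10)
  expect_equal(unname(fit$slope), 2, tolerance = 1e-10)
})

test_that("GLS slopes attenuate relative to SMA slopes", {
  # exact in the OLS limit: b_OLS = r * b_SMA < b_SMA whenever r2 < 1
  tab <- fixture_neognath()
  for (seg in c("thigh_mass", "shank_mass", "pes_mass", "tars_mass",
                "digit_mass")) {
    pair <- pair_complete(tab, "body_mass", seg)
    fit <- fit_sma(pair)
    I_n <- diag(pair$n)
    dimnames(I_n) <- list(pair$species, pair$species)
    b_ols <- unname(fit_pgls(pair, I_n)$slope)
    expect_equal(b_ols, fit$r * fit$slope, tolerance = 1e-10)
    expect_lt(b_ols, fit$slope)
  }
  # under a phylogenetic C the same identity holds in whitened coordinates
  for (i in 1:5) {
    tr <- simulate_yule_tree(40, seed = 810 + i, depth = 110)
    x <- simulate_trait(tr, "BM", sigma2 = 0.02, root_state = 2,
                        seed = 820 + i)
    e <- simulate_trait(tr, "BM", sigma2 = 0.004, seed = 830 + i)
    pair <- make_pair(as.numeric(x), 1 + 1.1 * x + e, species = names(x))
    C <- vcv_matrix(tr)
    b_pgls <- unname(fit_pgls(pair, C)$slope)
    # whitened, centred coordinates: GLS slope = r_w * (sd ratio), the
    # SMA-in-whitened-space slope, attenuated by |r_w| < 1
    W <- solve(t(chol(C)))
    xw <- W %*% pair$x; yw <- W %*% pair$y; ones <- W %*% rep(1, 40)
    xc <- lm.fit(ones, xw)$residuals; yc <- lm.fit(ones, yw)$residuals
    # uncentred moments: the whitened intercept column, not the constant
    # vector, has been projected out (Frisch-Waugh)
    r_w <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
    scale_w <- sqrt(sum(yc^2) / sum(xc^2))
    expect_equal(b_pgls, r_w * scale_w, tolerance = 1e-10)
    expect_lt(abs(b_pgls), scale_w)  # attenuated SMA analogue, |r_w| < 1
  }
})

test_that("co-diversifying traits leave strongly phylogenetic residuals", {
  lam_hat <- vapply(1:10, function(i) {
    tr <- simulate_yule_tree(128, seed = 300 + i, depth = 110)
    x <- simulate_trait(tr, "BM", sigma2 = 0.02, root_state = 2,
                        seed = 400 + i)
    e <- simulate_trait(tr, "BM", sigma2 = 0.002, seed = 500 + i)
    y <- 1 + 1.1 * x + e
    pair <- make_pair(as.numeric(x), as.numeric(y), species = names(x))
    fit <- fit_pgls(pair, vcv_matrix(tr))
    fit_model(pgls_residuals(fit), tr, "lambda")$theta
  }, numeric(1))
  expect_gte(median(lam_hat), 0.8)
})

test_that("species mismatches are reported with the symmetric difference", {
  inp <- make_pgls_inputs()
  C_bad <- inp$C
  rownames(C_bad)[1] <- colnames(C_bad)[1] <- "interloper"
  expect_error(fit_pgls(inp$pair, C_bad), "interloper")
})
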