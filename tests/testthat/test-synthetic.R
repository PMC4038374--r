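test_that("Yule trees are ultrametric with controllable depth", {
  cherry <- simulate_yule_tree(2, seed = 1)
  expect_equal(length(cherry$tip.label), 2L)
  expect_true(is_ultrametric(cherry))

  tr <- simulate_yule_tree(38, seed = 2, depth = 110)
  depths <- ape::node.depth.edgelength(tr)[1:38]
  expect_equal(max(depths), 110)
  expect_true(is_ultrametric(tr))
  expect_error(simulate_yule_tree(1, seed = 1), "at least 2")
})

test_that("speciation events per unit tree length recover the birth rate", {
  # in a pure-birth tree, each lineage speciates at rate b, so the n - 1
  # events divided by the total lineage-time should estimate b
  for (b in c(0.5, 2)) {
    tot_len <- vapply(1:500, function(i)
      sum(simulate_yule_tree(20, birth_rate = b, seed = 5000 + i)$edge.length),
      numeric(1))
    expect_equal(19 / mean(tot_len), b, tolerance = 0.1)
  }
})

test_that("trait simulation is seeded, degenerate-safe, and moment-correct", {
  tr <- simulate_yule_tree(16, seed = 3, depth = 110)
  a <- simulate_trait(tr, "BM", sigma2 = 0.01, root_state = 2, seed = 12)
  b <- simulate_trait(tr, "BM", sigma2 = 0.01, root_state = 2, seed = 12)
  expect_identical(a, b)
  flat <- simulate_trait(tr, "BM", sigma2 = 0, root_state = 3, seed = 1)
  expect_equal(unname(flat), rep(3, 16))

  star <- read_newick(paste0("(", paste0("s", 1:8, ":2", collapse = ","), ");"))
  draws <- vapply(1:2000, function(i)
    simulate_trait(star, "BM", sigma2 = 0.5, seed = 10000 + i)[1],
    numeric(1))
  # tip variance = sigma2 * depth = 1; 3-SE band for a variance estimate
  expect_equal(var(draws), 1, tolerance = 3 * sqrt(2 / 2000))
})

test_that("tip covariance of simulated traits matches sigma2 * C", {
  tr <- simulate_yule_tree(6, seed = 21, depth = 5)
  C <- vcv_matrix(tr)
  n_rep <- 4000
  tips <- sapply(1:n_rep, function(i)
    simulate_trait(tr, "BM", sigma2 = 0.3, seed = 40000 + i)[rownames(C)])
  emp <- cov(t(tips))
  S <- 0.3 * C
  se <- sqrt((outer(diag(S), diag(S)) + S^2) / n_rep)
  expect_true(all(abs(emp - S) < 3.5 * se))
})

test_that("lambda-generated traits hand their parameter back to the fitter", {
  lam_hat <- vapply(1:8, function(i) {
    tr <- simulate_yule_tree(96, seed = 1200 + i, depth = 110)
    y <- simulate_trait(tr, "lambda", theta = 0.5, sigma2 = 0.01,
                        seed = 1300 + i)
    fit_model(y, tr, "lambda")$theta
  }, numeric(1))
  expect_lt(abs(median(lam_hat) - 0.5), 0.15)
})

test_that("noiseless allometric tables return the generating slopes", {
  sim <- simulate_allometric_table(n_species = 30, slope = 1.2,
                                   residual_sd = 0, seed = 8)
  for (seg in c("thigh_mass", "shank_mass", "tars_mass", "digit_mass",
                "pes_mass")) {
    fit <- fit_sma(pair_complete(sim$table, "body_mass", seg))
    expect_equal(fit$slope, 1.2, tolerance = 1e-10)
    expect_equal(fit$r2, 1, tolerance = 1e-10)
  }
  # thigh intercept is the configured one (pes is a composite)
  fit_thigh <- fit_sma(pair_complete(sim$table, "body_mass", "thigh_mass"))
  expect_equal(fit_thigh$intercept, sim$truth$intercept[["thigh_mass_g"]],
               tolerance = 1e-10)
})

test_that("SMA confidence intervals cover the generating slope", {
  covered <- vapply(1:500, function(i) {
    sim <- simulate_allometric_table(n_species = 38, slope = 1.11,
                                     residual_sd = 0.06, seed = 20000 + i)
    fit <- fit_sma(pair_complete(sim$table, "body_mass", "thigh_mass"))
    fit$slope_ci[1] <= 1.11 && 1.11 <= fit$slope_ci[2]
  }, logical(1))
  expect_gt(mean(covered), 0.92)
  expect_lt(mean(covered), 0.98)
})

test_that("missing-value bookkeeping is exact", {
  sim <- simulate_allometric_table(n_species = 60, missing_rate = 0.15,
                                   seed = 31)
  tab <- sim$table
  for (seg in c("thigh_mass", "shank_mass", "tars_mass", "digit_mass")) {
    pair <- pair_complete(tab, "body_mass", seg)
    expect_identical(pair$n, sum(!is.na(tab[[seg]])))
  }
  expect_error(simulate_allometric_table(n_species = 10, missing_rate = 0.5,
                                         seed = 1), "missing_rate")
})

test_that("generation is bit-reproducible under a fixed seed", {
  a <- simulate_study(n_species = 20, seed = 77)
  b <- simulate_study(n_species = 20, seed = 77)
  expect_identical(as.data.frame(a$table), as.data.frame(b$table))
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$truth, b$truth)
})
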