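test_that("bundled neognath table parses with the expected structure", {
  tab <- fixture_neognath()
  expect_s3_class(tab, "trait_table")
  expect_equal(nrow(tab), 38L)
  expect_equal(sum(tab$clade == "Land birds"), 24L)
  expect_setequal(attr(tab, "clades"),
                  c("Land birds", "Charadriiformes", "Water Birds",
                    "Core Gruiformes", "Galloanseraes", "Apodiformes",
                    "Columbiformes"))
  # missing measurements stay missing, extremes are as recorded
  kestrel <- tab[tab$species == "Falco tinnunculus", ]
  expect_true(is.na(kestrel$tars_mass) && is.na(kestrel$digit_mass))
  expect_false(is.na(kestrel$thigh_mass))
  expect_equal(max(tab$body_mass), 6975.0)  # Branta canadensis
  expect_equal(min(tab$body_mass), 18.0)    # Fringilla coelebs
})

test_that("complete-case pair sizes reproduce the published N columns", {
  tab <- fixture_neognath()
  segs <- c("thigh_mass", "shank_mass", "pes_mass", "tars_mass", "digit_mass")
  n_body <- vapply(segs, function(s) pair_complete(tab, "body_mass", s)$n,
                   integer(1))
  n_len <- vapply(segs, function(s)
    pair_complete(tab, "hindlimb_length", s)$n, integer(1))
  expect_equal(unname(n_body), c(38L, 38L, 38L, 36L, 36L))
  expect_equal(unname(n_len), c(35L, 35L, 35L, 33L, 33L))

  lb <- subset_clade(tab, "Land birds")
  n_body_lb <- vapply(segs, function(s) pair_complete(lb, "body_mass", s)$n,
                      integer(1))
  n_len_lb <- vapply(segs, function(s)
    pair_complete(lb, "hindlimb_length", s)$n, integer(1))
  expect_equal(unname(n_body_lb), c(24L, 24L, 24L, 23L, 23L))
  expect_equal(unname(n_len_lb), c(21L, 21L, 21L, 20L, 20L))
})

test_that("pair_complete accounts for every row and log10 round-trips", {
  tab <- fixture_neognath()
  traits <- trait_names()
  for (xn in traits) for (yn in setdiff(traits, xn)) {
    pair <- pair_complete(tab, xn, yn)
    n_missing <- sum(is.na(tab[[xn]]) | is.na(tab[[yn]]))
    expect_identical(pair$n + n_missing, nrow(tab))
    raw <- tab[[yn]][match(pair$species, tab$species)]
    expect_lt(max(abs(10^pair$y - raw) / raw), 1e-12)
  }
})

test_that("malformed tables are rejected with informative errors", {
  tab <- fixture_neognath()
  path <- system.file("extdata", "neognath_hindlimb_masses.csv",
                      package = "allomorph")
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)

  rewrite <- function(d) {
    f <- withr::local_tempfile(fileext = ".csv",
                               .local_envir = parent.frame())
    write.csv(d, f, row.names = FALSE)
    f
  }

  bad_col <- raw; names(bad_col)[4] <- "mass_in_stones"
  expect_error(read_trait_table(rewrite(bad_col)), "schema")

  dup <- rbind(raw, raw[1, ])
  expect_error(read_trait_table(rewrite(dup)), "duplicate")

  neg <- raw; neg$thigh_mass_g[3] <- "-1.2"
  expect_error(read_trait_table(rewrite(neg)), "non-positive.*thigh_mass_g")

  txt <- raw; txt$body_mass_g[2] <- "heavy"
  expect_error(read_trait_table(rewrite(txt)), "non-numeric.*body_mass_g")

  empty <- raw[0, ]
  expect_error(read_trait_table(rewrite(empty)), "empty")

  expect_error(subset_clade(tab, "Sphenisciformes"), "known clades")
  expect_error(pair_complete(tab, "wing_mass", "thigh_mass"), "unknown trait")
})

test_that("degenerate clade subsets are caught downstream", {
  tab <- fixture_neognath()
  apods <- subset_clade(tab, "Apodiformes")
  expect_equal(nrow(apods), 1L)
  expect_error(pair_complete(apods, "body_mass", "thigh_mass"),
               "insufficient")
})

test_that("inconsistent segment sums only warn (printed tables are rounded)", {
  path <- system.file("extdata", "neognath_hindlimb_masses.csv",
                      package = "allomorph")
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  raw$pes_mass_g[2] <- "9.99"  # far from tars + digits
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(raw, f, row.names = FALSE)
  expect_warning(read_trait_table(f), "deviates from pes")
})
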