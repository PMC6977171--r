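test_that("default grid is uniform, symmetric and contains zero exactly", {
  g <- sigma_grid()
  expect_equal(g$n_bins, 61L)
  expect_identical(g$sigma[[31]], 0)
  expect_lt(abs((g$sigma_max - g$sigma_min) - (g$n_bins - 1) * g$step), 1e-12)
  expect_equal(g$sigma, rev(-g$sigma))
  expect_error(sigma_grid(-0.02, 0.03, 0.001), "symmetric")
  expect_error(sigma_grid(-0.03, 0.03, 0.0007), "uniform")
})

test_that("profile reading apportions area onto the grid conservatively", {
  g <- sigma_grid()
  f <- withr::local_tempfile(fileext = ".prf")

  writeLines("0.000 43.0", f)
  p <- read_sigma_profile(f)
  expect_equal(p$total_area, 43.0)
  expect_equal(p$area_per_bin[[31]], 43.0)
  expect_equal(sum(p$area_per_bin[-31]), 0)

  # off-grid point midway between bins: split 50/50
  writeLines("0.0005 10.0", f)
  p <- read_sigma_profile(f)
  expect_equal(p$area_per_bin[[31]], 5.0)
  expect_equal(p$area_per_bin[[32]], 5.0)
  expect_equal(p$total_area, 10.0)

  # general off-grid point conserves area
  writeLines(c("# comment", "-0.01230 7.5"), f)
  p <- read_sigma_profile(f)
  expect_equal(p$total_area, 7.5, tolerance = 1e-12)
})

test_that("profile parsing rejects malformed and unphysical input", {
  f <- withr::local_tempfile(fileext = ".prf")
  writeLines(c("0.001 2.0", "0.002 oops"), f)
  expect_error(read_sigma_profile(f), "line 2")
  writeLines(c("0.002 2.0", "0.001 1.0"), f)
  expect_error(read_sigma_profile(f), "monotone")
  writeLines("0.045 2.0", f)
  expect_error(read_sigma_profile(f), "outside grid range")
  writeLines("0.001 -2.0", f)
  expect_error(read_sigma_profile(f), "negative segment area")
  g <- sigma_grid()
  expect_error(write_sigma_profile(sigma_profile(g, numeric(g$n_bins)),
                                   tempfile()),
               "zero total area")
})

test_that("write/read round trip is a bitwise identity", {
  g <- sigma_grid()
  p <- make_gaussian_profile(g, data.frame(center = c(-0.012, 0, 0.009),
                                           width = c(0.002, 0.004, 0.003),
                                           area = c(17.3, 61.2, 24.9)))
  f <- withr::local_tempfile(fileext = ".prf")
  write_sigma_profile(p, f)
  p2 <- read_sigma_profile(f)
  expect_identical(p2$area_per_bin, p$area_per_bin)
})

test_that("normalisation yields a proper distribution", {
  g <- sigma_grid()
  a <- numeric(g$n_bins); a[[31]] <- 5
  expect_identical(normalize_profile(sigma_profile(g, a))[[31]], 1)
  a2 <- numeric(g$n_bins); a2[c(10, 50)] <- 2
  expect_equal(normalize_profile(sigma_profile(g, a2))[c(10, 50)], c(0.5, 0.5))
  p <- rand_profile(g, 11)
  expect_lt(abs(sum(normalize_profile(p)) - 1), 1e-12)
  expect_error(normalize_profile(sigma_profile(g, numeric(g$n_bins))),
               "zero total area")
})

test_that("mixture profiles are mole-fraction-weighted and conserve area", {
  g <- sigma_grid()
  cc <- test_species("choline chloride", c(-0.008, 0.01), c(0.003, 0.003),
                     c(40, 35))
  urea <- test_species("urea", c(-0.012, 0.013), c(0.002, 0.002), c(18, 20))

  # single component: identity
  m1 <- mix_profiles(solvent_mixture(list(cc), 1))
  expect_equal(m1$area_per_bin, cc$profile$area_per_bin)

  # choline chloride : urea at 1:2 -> weights 1/3 and 2/3
  cu <- mix_profiles(solvent_mixture(list(cc, urea), c(1, 2)))
  expect_equal(cu$area_per_bin,
               cc$profile$area_per_bin / 3 + 2 * urea$profile$area_per_bin / 3)
  expect_equal(cu$total_area,
               (cc$profile$total_area + 2 * urea$profile$total_area) / 3)

  # 50:50 of two copies of one profile: idempotent
  cc2 <- cosmo_species("cc copy", cc$molar_mass, cc$profile)
  half <- mix_profiles(solvent_mixture(list(cc, cc2), c(1, 1)))
  expect_equal(half$area_per_bin, cc$profile$area_per_bin)

  # grid mismatch is an error
  g2 <- sigma_grid(-0.02, 0.02, 0.001)
  other <- cosmo_species("other", 100, sigma_profile(g2, rep(1, g2$n_bins)))
  expect_error(mix_profiles(solvent_mixture(list(cc, other), c(1, 1))),
               "same sigma grid")
})

test_that("area conservation and mixing linearity hold on random mixtures", {
  g <- sigma_grid()
  set.seed(42)
  for (rep in 1:10) {
    sps <- lapply(1:3, function(i)
      cosmo_species(paste0("s", i), 100, rand_profile(g, 100 * rep + i)))
    w <- stats::runif(3, 0.1, 2)
    mx <- solvent_mixture(sps, w)
    mp <- mix_profiles(mx)
    areas <- vapply(sps, function(s) s$profile$total_area, numeric(1))
    expect_lt(abs(mp$total_area - sum(mx$x * areas)) / mp$total_area, 1e-9)

    # mixing a mixture equals mixing the flattened set with product weights
    inner <- cosmo_species("inner", 100, mix_profiles(
      solvent_mixture(sps[1:2], w[1:2])))
    outer <- mix_profiles(solvent_mixture(list(inner, sps[[3]]),
                                          c(sum(w[1:2]), w[[3]])))
    flat_w <- c(w[1:2], w[[3]]) / sum(w)
    flat <- flat_w[[1]] * sps[[1]]$profile$area_per_bin +
      flat_w[[2]] * sps[[2]]$profile$area_per_bin +
      flat_w[[3]] * sps[[3]]$profile$area_per_bin
    expect_equal(outer$area_per_bin, flat, tolerance = 1e-12)
  }
})

test_that("species and mixture constructors enforce their invariants", {
  g <- sigma_grid()
  p <- rand_profile(g, 3)
  expect_error(cosmo_species("x", -1, p), "molar_mass")
  expect_error(cosmo_species("x", 100, p, cosmo_area = p$total_area * 1.1),
               "disagrees")
  expect_error(cosmo_species("x", 100, p, gibbs_fusion = -2), ">= 0")
  s <- cosmo_species("x", 100, p)
  expect_error(solvent_mixture(list(s, s), c(1, 1)), "unique")
  expect_error(solvent_mixture(list(s), -1), "ratios")
})
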