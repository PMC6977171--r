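make_pair <- function() {
  g <- sigma_grid()
  solute <- test_species("drug", c(-0.011, 0, 0.012), c(0.002, 0.004, 0.002),
                         c(15, 55, 12), molar_mass = 250)
  solvent_sp <- test_species("medium", c(-0.009, 0.005), c(0.003, 0.003),
                             c(22, 30), molar_mass = 60)
  list(g = g, solute = solute,
       solvent = solvent_mixture(list(solvent_sp), 1, label = "medium"))
}

test_that("solute chemical potential is the area-weighted quadrature of the potential", {
  env <- make_pair()
  params <- interaction_params()

  # zero potential everywhere -> zero chemical potential
  pot0 <- solve_sigma_potential(mix_profiles(env$solvent),
                                interaction_params(c_misfit = 0, c_hb = 0))
  expect_identical(
    solute_chemical_potential(env$solute, pot0, env$solvent,
                              interaction_params(c_misfit = 0, c_hb = 0)), 0)

  pot <- solve_sigma_potential(mix_profiles(env$solvent), params, tol = 1e-12)
  mu <- solute_chemical_potential(env$solute, pot, env$solvent, params)
  expect_equal(mu, oracle_quadrature(env$solute, pot$mu), tolerance = 1e-12)

  g2 <- sigma_grid(-0.02, 0.02, 0.001)
  alien <- cosmo_species("alien", 100, sigma_profile(g2, rep(1, g2$n_bins)))
  expect_error(solute_chemical_potential(alien, pot, env$solvent, params),
               "different sigma grids")
})

test_that("pure-liquid chemical potential is the self-solvation identity", {
  env <- make_pair()
  params <- interaction_params()
  sp <- env$solvent$components[[1]]
  pot <- solve_sigma_potential(sp$profile, params, tol = 1e-10)
  expect_equal(pure_chemical_potential(sp, params, tol = 1e-10),
               solute_chemical_potential(sp, pot,
                                         solvent_mixture(list(sp), 1), params),
               tolerance = 1e-10)
  # conductor limit
  expect_identical(
    pure_chemical_potential(sp, interaction_params(c_misfit = 0, c_hb = 0)), 0)
  # delta species at sigma = 0 with no hydrogen bonding: mu ~ c sigma^2 but
  # all profile mass sits at sigma = 0, so the pure potential vanishes
  g <- env$g
  a <- numeric(g$n_bins); a[[31]] <- 40
  delta <- cosmo_species("delta", 50, sigma_profile(g, a))
  expect_lt(abs(pure_chemical_potential(delta, interaction_params(c_hb = 0))),
            1e-8)
})

test_that("dilute solubility follows the chemical-potential balance", {
  env <- make_pair()
  params <- interaction_params()
  RT <- 8.31446261815324e-3 * params$temperature

  # solute identical to the solvent: mu_pure = mu_solution, so
  # dG_fus = 0 gives full miscibility and dG_fus = RT gives ln x = -1
  sp <- env$solvent$components[[1]]
  self <- solvent_mixture(list(sp), 1, label = "self")
  r0 <- ln_solubility_dilute(sp, self, params, gibbs_fusion = 0)
  expect_equal(r0$ln_x, 0, tolerance = 1e-8)
  expect_true(r0$miscible)
  r1 <- ln_solubility_dilute(sp, self, params, gibbs_fusion = RT)
  expect_equal(r1$ln_x, -1, tolerance = 1e-8)

  # linearity: raising dG_fus by delta lowers ln x by delta / RT
  ra <- ln_solubility_dilute(env$solute, env$solvent, params, gibbs_fusion = 5)
  rb <- ln_solubility_dilute(env$solute, env$solvent, params, gibbs_fusion = 12)
  expect_equal(ra$ln_x - rb$ln_x, 7 / RT, tolerance = 1e-9)

  # a solid without fusion data is an explicit error
  expect_error(ln_solubility_dilute(env$solute, env$solvent, params),
               "gibbs_fusion")
})

test_that("the self-consistent loop reduces to the dilute limit and caps at miscibility", {
  env <- make_pair()
  params <- interaction_params()

  # strongly insoluble: iterative == dilute
  d <- ln_solubility_dilute(env$solute, env$solvent, params, gibbs_fusion = 40)
  expect_lt(exp(d$ln_x), 1e-4)
  it <- ln_solubility_iterative(env$solute, env$solvent, params,
                                gibbs_fusion = 40)
  expect_true(it$converged)
  expect_equal(it$ln_x, d$ln_x, tolerance = 1e-6)

  # solute = solvent species with no fusion penalty: miscible, x = 1
  sp <- env$solvent$components[[1]]
  self <- solvent_mixture(list(sp), 1, label = "self")
  rm <- ln_solubility_iterative(sp, self, params, gibbs_fusion = 0)
  expect_equal(rm$ln_x, 0, tolerance = 1e-8)
  expect_true(rm$miscible)
})

test_that("the self-consistent loop matches an independently coded outer loop", {
  env <- make_pair()
  params <- interaction_params()
  gf <- 8 # mid-solubility case: finite concentration matters
  it <- ln_solubility_iterative(env$solute, env$solvent, params,
                                gibbs_fusion = gf, tol = 1e-9)
  expect_true(it$converged)

  # independent outer loop: hand-built saturated mixture + naive quadrature
  RT <- 8.31446261815324e-3 * params$temperature
  mu_pure <- pure_chemical_potential(env$solute, params)
  solv_prof <- mix_profiles(env$solvent)
  ln_x <- -Inf; ln_new <- ln_solubility_dilute(env$solute, env$solvent, params,
                                               gibbs_fusion = gf)$ln_x
  for (i in 1:200) {
    if (abs(ln_new - ln_x) < 1e-10) break
    ln_x <- ln_new
    x <- exp(ln_x)
    comb <- sigma_profile(env$g, (1 - x) * solv_prof$area_per_bin +
                                 x * env$solute$profile$area_per_bin)
    pot <- solve_sigma_potential(comb, params, tol = 1e-12)
    mu <- oracle_quadrature(env$solute, pot$mu)
    ln_new <- min((mu_pure - mu - gf) / RT, 0)
  }
  expect_equal(it$ln_x, ln_new, tolerance = 1e-6)
})

test_that("relative solubility cancels the solid-state terms exactly", {
  env <- make_pair()
  params <- interaction_params()
  other_sp <- test_species("other", c(-0.006, 0.01), c(0.004, 0.002), c(35, 18),
                           molar_mass = 90)
  solvent_b <- solvent_mixture(list(other_sp), 1, label = "other")

  # identical solvents: exactly zero; antisymmetry under exchange
  expect_identical(relative_log10_solubility(env$solute, env$solvent,
                                             env$solvent, params)$log10_relative,
                   0)
  rab <- relative_log10_solubility(env$solute, env$solvent, solvent_b, params,
                                   tol = 1e-11)
  rba <- relative_log10_solubility(env$solute, solvent_b, env$solvent, params,
                                   tol = 1e-11)
  expect_equal(rab$log10_relative, -rba$log10_relative, tolerance = 1e-12)
  expect_identical(rab$used_gibbs_fusion, "cancelled")

  # bit-identical whatever fusion energy is attached to the solute
  vals <- vapply(c(0, 10, 50), function(gf) {
    s <- env$solute; s$gibbs_fusion <- gf
    relative_log10_solubility(s, env$solvent, solvent_b, params)$log10_relative
  }, numeric(1))
  expect_identical(vals[[1]], vals[[2]])
  expect_identical(vals[[1]], vals[[3]])

  # consistency with the difference of absolute dilute predictions
  # (fusion energies large enough that neither solvent hits the
  # miscibility cap, where the identity ceases to apply)
  for (gf in c(25, 40)) {
    da <- ln_solubility_dilute(env$solute, env$solvent, params,
                               gibbs_fusion = gf, tol = 1e-11)
    db <- ln_solubility_dilute(env$solute, solvent_b, params,
                               gibbs_fusion = gf, tol = 1e-11)
    expect_equal(rab$log10_relative, (da$ln_x - db$ln_x) / log(10),
                 tolerance = 1e-7)
  }
})

test_that("solvent ranking is reference-invariant with lexicographic ties", {
  env <- make_pair()
  params <- interaction_params()
  # competitors without hydrogen-bond-capable surface: the
  # self-complementary solute then prefers its own liquid (competing
  # donor/acceptor solvents could in general beat self-solvation)
  apolar <- test_species("apolar", c(0, 0.004), c(0.005, 0.003), c(70, 10),
                         molar_mass = 120)
  mild <- test_species("mildpolar", c(-0.006, 0.006), c(0.0015, 0.0015),
                       c(30, 30), molar_mass = 80)
  solvents <- list(
    solvent_mixture(list(apolar), 1, label = "apolar"),
    solvent_mixture(list(mild), 1, label = "mildpolar"),
    solvent_mixture(list(env$solute), 1, label = "soluteliquid")
  )
  rk <- rank_solvents(env$solute, solvents, params)
  expect_identical(rk$solvent[[1]], "soluteliquid")
  sp <- env$solvent$components[[1]]

  # ranking order is invariant to which solvent is the reference
  rk2 <- rank_solvents(env$solute, solvents[c(2, 1, 3)], params)
  expect_identical(rk$solvent, rk2$solvent)
  expect_equal(diff(rk$log10_relative), diff(rk2$log10_relative),
               tolerance = 1e-9)

  # two identical solvents tie and order lexicographically
  twins <- list(solvent_mixture(list(sp), 1, label = "zeta"),
                solvent_mixture(list(sp), 1, label = "alpha"))
  rt <- rank_solvents(env$solute, twins, params)
  expect_identical(rt$solvent, c("alpha", "zeta"))
})

test_that("the area/volume combinatorial correction behaves sanely", {
  env <- make_pair()
  params <- interaction_params(combinatorial_form = "area_volume")
  solute <- env$solute
  solute$cosmo_volume <- 260
  comp <- env$solvent$components[[1]]
  comp$cosmo_volume <- 70
  solvent <- solvent_mixture(list(comp), 1, label = "medium")
  pot <- solve_sigma_potential(mix_profiles(solvent), params)
  mu_corr <- solute_chemical_potential(solute, pot, solvent, params)
  mu_none <- solute_chemical_potential(solute, pot, solvent,
                                       interaction_params())
  expect_false(isTRUE(all.equal(mu_corr, mu_none)))
  # a solute identical in size and shape to the solvent gets no correction
  same <- comp
  mu_same <- solute_chemical_potential(same, pot, solvent, params)
  expect_equal(mu_same, solute_chemical_potential(same, pot, solvent,
                                                  interaction_params()),
               tolerance = 1e-10)
  # missing volumes are an explicit error
  expect_error(solute_chemical_potential(env$solute, pot, solvent, params),
               "cosmo_volume")
})
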