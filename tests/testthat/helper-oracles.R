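# Brute-force reference implementations: plain scalar loops over the
# model's defining formulas, independent of the package's vectorised
# code paths.  Used as oracles in the unit and acceptance tests.

oracle_misfit <- function(s, sp, p) p$a_eff * p$c_misfit * (s + sp)^2

oracle_hb <- function(s, sp, p) {
  d <- min(s, sp)
  a <- max(s, sp)
  p$a_eff * p$c_hb * min(0, min(0, d + p$sigma_hb) * max(0, a - p$sigma_hb))
}

oracle_total <- function(s, sp, p) oracle_misfit(s, sp, p) + oracle_hb(s, sp, p)

oracle_matrix <- function(grid, p) {
  n <- grid$n_bins
  m <- matrix(0, n, n)
  for (k in seq_len(n))
    for (l in seq_len(n))
      m[k, l] <- oracle_total(grid$sigma[[k]], grid$sigma[[l]], p)
  m
}

# Naive successive-substitution solution of the sigma-potential:
# unvectorised loops, plain sums (no log-sum-exp), fixed half-step
# damping (the undamped map 2-cycles for hydrogen-bond-active
# profiles; damping moves the iterate, not the fixed point).
oracle_potential <- function(profile, p, tol = 1e-13, max_iter = 5000L) {
  g <- profile$grid
  n <- g$n_bins
  w <- profile$area_per_bin / sum(profile$area_per_bin)
  RT <- 8.31446261815324e-3 * p$temperature
  beta <- p$a_eff / RT
  e <- oracle_matrix(g, p) / p$a_eff
  mu <- rep(0, n)
  for (iter in seq_len(max_iter)) {
    mu_new <- numeric(n)
    for (k in seq_len(n)) {
      s <- 0
      for (l in seq_len(n))
        if (w[[l]] > 0)
          s <- s + w[[l]] * exp(beta * (mu[[l]] - e[k, l]))
      mu_new[[k]] <- -log(s) / beta
    }
    if (max(abs(mu_new - mu)) < tol) return(mu_new)
    mu <- (mu + mu_new) / 2
  }
  stop("oracle potential did not converge")
}

# Naive area-weighted quadrature of a potential over a solute profile.
oracle_quadrature <- function(solute, mu) {
  s <- 0
  for (k in seq_along(mu))
    s <- s + solute$profile$area_per_bin[[k]] * mu[[k]]
  s
}

# Spearman coefficient from the textbook rank-difference formula
# (valid without ties).
oracle_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Closed-form OLS statistics.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  list(slope = slope, intercept = intercept,
       r_squared = 1 - sum(res^2) / sum((y - mean(y))^2),
       rmse = sqrt(mean(res^2)))
}

# Random strictly positive profile with a physical shape: most surface
# area near sigma = 0, tails decaying like real molecular profiles.
rand_profile <- function(grid, seed, envelope_sd = 0.006) {
  set.seed(seed)
  sigma_profile(grid, stats::runif(grid$n_bins, 0.05, 1) *
                  exp(-grid$sigma^2 / (2 * envelope_sd^2)) * 10)
}

# Small Gaussian test species.
test_species <- function(name, centers, widths, areas, molar_mass = 200,
                         gibbs_fusion = NULL, grid = sigma_grid()) {
  cosmo_species(name, molar_mass,
                make_gaussian_profile(grid, data.frame(center = centers,
                                                       width = widths,
                                                       area = areas)),
                gibbs_fusion = gibbs_fusion)
}
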