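#' Default peak library for synthetic sigma-profiles
#'
#' Gaussian building blocks emulating the qualitative structure of real
#' sigma-profiles: a large apolar peak near zero, polar shoulders, and
#' donor/acceptor peaks beyond the +/-0.0082 e/A^2 hydrogen-bond
#' threshold.  Areas are in A^2, centres and widths in e/A^2.
#'
#' @return data.frame with columns `role`, `center`, `width`, `area`.
#' @export
default_peak_library <- function() {
  data.frame(
    role = c("neutral", "polar_neg", "polar_pos", "donor", "acceptor"),
    center = c(0, -0.005, 0.005, -0.010, 0.010),
    width = c(0.004, 0.0025, 0.0025, 0.0015, 0.0015),
    area = c(60, 20, 20, 6, 6),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic screening study
#'
#' Defines a reproducible in-silico analogue of a solubility screening
#' campaign: a set of solid solutes and multicomponent solvents built
#' from Gaussian sigma-profile peaks, true solubilities computed by the
#' segment model, and "experimental" tables obtained by multiplicative
#' lognormal measurement noise (additive on the log10 scale, matching
#' how screening data are compared).
#'
#' @param seed integer seed; the same seed reproduces the study
#'   bit-for-bit, and the measurement-noise substream is derived from it
#'   deterministically (so studies with the same seed and different
#'   `noise_sd` share species and standardised noise draws).
#' @param n_solutes,n_solvents study size.
#' @param peak_library peak triples as in [default_peak_library()].
#' @param noise_sd standard deviation of the measurement noise in log10
#'   units.
#' @param gibbs_fusion_range interval (kJ/mol) from which solute fusion
#'   energies are drawn uniformly.
#' @return Object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(seed, n_solutes = 8L, n_solvents = 6L,
                           peak_library = default_peak_library(),
                           noise_sd = 0.5, gibbs_fusion_range = c(18, 40)) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed == round(seed),
            n_solutes >= 1L, n_solvents >= 2L,
            all(c("center", "width", "area") %in% names(peak_library)),
            all(peak_library$width > 0), all(peak_library$area > 0),
            is.numeric(noise_sd), noise_sd >= 0,
            length(gibbs_fusion_range) == 2L,
            gibbs_fusion_range[1] >= 0,
            gibbs_fusion_range[2] >= gibbs_fusion_range[1])
  structure(
    list(seed = as.integer(seed), n_solutes = as.integer(n_solutes),
         n_solvents = as.integer(n_solvents), peak_library = peak_library,
         noise_sd = noise_sd, gibbs_fusion_range = gibbs_fusion_range),
    class = "synthetic_spec"
  )
}

#' Build a sigma-profile as a sum of discretised Gaussian peaks
#'
#' Each peak is discretised on the grid and renormalised so that it
#' contributes exactly its nominal area; peaks therefore add: the
#' profile's total area is the sum of the peak areas.
#'
#' @param grid a [sigma_grid()].
#' @param peaks data.frame with columns `center` (e/A^2, must lie inside
#'   the grid), `width` (> 0, e/A^2), `area` (> 0, A^2).
#' @return A [sigma_profile()].
#' @export
make_gaussian_profile <- function(grid, peaks) {
  stopifnot(inherits(grid, "sigma_grid"),
            all(c("center", "width", "area") %in% names(peaks)),
            nrow(peaks) >= 1L)
  if (any(peaks$width <= 0)) stop("peak widths must be positive")
  if (any(peaks$area <= 0)) stop("peak areas must be positive")
  bad <- peaks$center < grid$sigma_min | peaks$center > grid$sigma_max
  if (any(bad))
    stop("peak center ", peaks$center[which(bad)[1]], " outside grid range [",
         grid$sigma_min, ", ", grid$sigma_max, "]")
  area <- numeric(grid$n_bins)
  for (i in seq_len(nrow(peaks))) {
    dens <- stats::dnorm(grid$sigma, peaks$center[[i]], peaks$width[[i]])
    area <- area + dens / sum(dens) * peaks$area[[i]]
  }
  sigma_profile(grid, area)
}

# Deterministic substream seed for the measurement-noise draws; kept
# within 32-bit integer range.
noise_seed <- function(seed) as.integer((abs(seed) + 777663L) %% 2147483647L)

# Random species from the peak library: apolar backbone plus randomly
# scaled polar/donor/acceptor character.  Uses the current RNG stream.
random_species <- function(name, grid, peak_library, molar_mass_range,
                           gibbs_fusion_range = NULL) {
  lib <- peak_library
  scale <- stats::runif(nrow(lib), 0.2, 1.5)
  keep <- rep(TRUE, nrow(lib))
  if (nrow(lib) > 1L) {
    # backbone always present, other peaks coin-flipped; at least one
    # non-backbone peak is retained, otherwise all single-peak species
    # would share one profile shape and be thermodynamically identical
    u <- stats::runif(nrow(lib) - 1L)
    keep[-1] <- u < 0.7
    if (!any(keep[-1])) keep[which.max(u) + 1L] <- TRUE
  }
  peaks <- lib[keep, ]
  peaks$area <- peaks$area * scale[keep]
  gf <- if (is.null(gibbs_fusion_range)) NULL else
    stats::runif(1, gibbs_fusion_range[1], gibbs_fusion_range[2])
  cosmo_species(name, stats::runif(1, molar_mass_range[1], molar_mass_range[2]),
                make_gaussian_profile(grid, peaks), gibbs_fusion = gf)
}

#' Generate a full synthetic screening study
#'
#' Draws solutes (solids with fusion energies) and multicomponent
#' solvents (1-3 liquid components at random molar ratios) from the peak
#' library, computes the true mole-fraction solubility of every pair
#' with the segment model at infinite dilution, converts to mg per g
#' solvent via the solvent compositions, and perturbs these by
#' multiplicative lognormal noise to produce an "experimental" table.
#' All randomness derives from `spec$seed`; the global RNG state is
#' restored on exit.
#'
#' @param spec a [synthetic_spec()].
#' @param params an [interaction_params()].
#' @return list with `solutes` (list of [cosmo_species()]), `solvents`
#'   (list of [solvent_mixture()]), `compositions` (named list of
#'   [composition_spec()]), `truth` (data.frame: `api`, `solvent`,
#'   `ln_x`, `log10_x`, `log10_relative` vs. the first solvent,
#'   `mg_per_g`), and `experimental` (data.frame: `api`, `solvent`,
#'   `mg_per_g`, `log10_x`).
#' @export
synthetic_study <- function(spec, params = interaction_params()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  grid <- sigma_grid()

  set.seed(spec$seed)
  solutes <- lapply(seq_len(spec$n_solutes), function(i)
    random_species(sprintf("solute%02d", i), grid, spec$peak_library,
                   c(150, 500), spec$gibbs_fusion_range))
  solvents <- list()
  compositions <- list()
  for (j in seq_len(spec$n_solvents)) {
    n_comp <- sample(1:3, 1)
    comps <- lapply(seq_len(n_comp), function(k)
      random_species(sprintf("solv%02d_c%d", j, k), grid, spec$peak_library,
                     c(40, 200)))
    ratios <- stats::runif(n_comp, 0.5, 2)
    label <- sprintf("solvent%02d", j)
    solvents[[j]] <- solvent_mixture(comps, ratios, label = label)
    compositions[[label]] <-
      composition_spec(label, vapply(comps, `[[`, character(1), "name"),
                       vapply(comps, `[[`, numeric(1), "molar_mass"),
                       ratios)
  }

  RT <- .R_GAS * params$temperature
  potentials <- lapply(solvents, function(s)
    solve_sigma_potential(mix_profiles(s), params))
  mu_pure <- vapply(solutes, pure_chemical_potential, numeric(1), params = params)

  truth <- do.call(rbind, lapply(seq_along(solutes), function(i) {
    mu_sol <- vapply(seq_along(solvents), function(j)
      solute_chemical_potential(solutes[[i]], potentials[[j]],
                                solvents[[j]], params), numeric(1))
    ln_x <- pmin((mu_pure[[i]] - mu_sol - solutes[[i]]$gibbs_fusion) / RT, 0)
    mg <- vapply(seq_along(solvents), function(j)
      mole_fraction_to_mg_per_g(min(exp(ln_x[[j]]), 1 - 1e-9),
                                solutes[[i]]$molar_mass,
                                compositions[[solvents[[j]]$label]]),
      numeric(1))
    data.frame(api = solutes[[i]]$name,
               solvent = vapply(solvents, `[[`, character(1), "label"),
               ln_x = ln_x, log10_x = ln_x / log(10),
               log10_relative = (ln_x - ln_x[[1]]) / log(10),
               mg_per_g = mg, stringsAsFactors = FALSE)
  }))
  row.names(truth) <- NULL

  set.seed(noise_seed(spec$seed))
  z <- stats::rnorm(nrow(truth)) # standardised draws, scaled by noise_sd
  experimental <- truth[c("api", "solvent")]
  experimental$mg_per_g <- truth$mg_per_g * 10^(spec$noise_sd * z)
  experimental$log10_x <- vapply(seq_len(nrow(experimental)), function(r) {
    i <- match(experimental$api[[r]], vapply(solutes, `[[`, character(1), "name"))
    log10(mg_per_g_to_mole_fraction(
      experimental$mg_per_g[[r]], solutes[[i]]$molar_mass,
      compositions[[experimental$solvent[[r]]]]))
  }, numeric(1))

  list(solutes = solutes, solvents = solvents, compositions = compositions,
       truth = truth, experimental = experimental)
}
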