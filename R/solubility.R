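# One-row data.frame carrying a single solubility prediction.
prediction_record <- function(solute_name, solvent_name, ln_x = NA_real_,
                              reference_solvent_name = NA_character_,
                              log10_relative = NA_real_,
                              temperature = NA_real_,
                              used_gibbs_fusion = NA_character_,
                              miscible = FALSE, converged = TRUE,
                              iterations = NA_integer_) {
  out <- data.frame(
    solute = solute_name, solvent = solvent_name, ln_x = ln_x,
    reference_solvent = reference_solvent_name,
    log10_relative = log10_relative, temperature = temperature,
    used_gibbs_fusion = used_gibbs_fusion, miscible = miscible,
    converged = converged, iterations = iterations,
    stringsAsFactors = FALSE
  )
  class(out) <- c("prediction_record", class(out))
  out
}

# Staverman-Guggenheim-style size/shape correction (kJ/mol) for a solute
# at infinite dilution in a mixture, from cavity areas/volumes.
sg_combinatorial <- function(solute, solvent, params) {
  cc <- params$combinatorial_coefficients
  vol <- function(sp) {
    if (is.null(sp$cosmo_volume))
      stop("area_volume combinatorial correction needs cosmo_volume for '",
           sp$name, "'")
    sp$cosmo_volume
  }
  r_x <- vol(solute) / cc$r_norm
  q_x <- solute$cosmo_area / cc$q_norm
  r_s <- sum(mapply(function(sp, x) x * vol(sp) / cc$r_norm,
                    solvent$components, solvent$x))
  q_s <- sum(mapply(function(sp, x) x * sp$cosmo_area / cc$q_norm,
                    solvent$components, solvent$x))
  l <- function(r, q) (cc$z / 2) * (r - q) - (r - 1)
  l_s <- sum(mapply(function(sp, x) {
    r <- vol(sp) / cc$r_norm; q <- sp$cosmo_area / cc$q_norm
    x * l(r, q)
  }, solvent$components, solvent$x))
  phi_over_x <- r_x / r_s
  theta_over_phi <- (q_x / r_x) * (r_s / q_s)
  ln_gamma <- log(phi_over_x) + (cc$z / 2) * q_x * log(theta_over_phi) +
    l(r_x, q_x) - phi_over_x * l_s
  .R_GAS * params$temperature * ln_gamma
}

#' Chemical potential of a solute in a solvent
#'
#' Area-weighted sum of the solvent's sigma-potential over the solute's
#' sigma-profile, plus an optional combinatorial (size/shape)
#' correction:
#' `mu_S^X = gamma_comb + sum_k p^X(sigma_k) * mu_S(sigma_k)`,
#' with `p^X` in A^2 per bin and `mu_S` per unit area.
#'
#' @param solute a [cosmo_species()].
#' @param potential the solvent's [solve_sigma_potential()] result, on the
#'   solute's grid.
#' @param solvent the [solvent_mixture()] the potential belongs to; only
#'   needed when `params$combinatorial_form == "area_volume"`.
#' @param params an [interaction_params()].
#' @return Chemical potential, kJ/mol.
#' @export
solute_chemical_potential <- function(solute, potential, solvent = NULL,
                                      params = interaction_params()) {
  stopifnot(inherits(solute, "cosmo_species"),
            inherits(potential, "sigma_potential"))
  if (!same_grid(solute$profile$grid, potential$grid))
    stop("solute profile and potential are on different sigma grids")
  residual <- sum(solute$profile$area_per_bin * potential$mu)
  comb <- 0
  if (params$combinatorial_form == "area_volume") {
    if (is.null(solvent))
      stop("the area_volume combinatorial correction needs the solvent mixture")
    comb <- sg_combinatorial(solute, solvent, params)
  }
  comb + residual
}

#' Chemical potential of a species in its own pure liquid
#'
#' Solves the sigma-potential of the pure liquid and evaluates the
#' species' own chemical potential in it.  This is the reference state
#' entering the solubility equation.  (For the pure liquid the
#' combinatorial correction vanishes by construction.)
#'
#' @param species a [cosmo_species()].
#' @param params an [interaction_params()].
#' @param ... passed to [solve_sigma_potential()].
#' @return Chemical potential, kJ/mol.
#' @export
pure_chemical_potential <- function(species, params = interaction_params(), ...) {
  pot <- solve_sigma_potential(species$profile, params, ...)
  if (!pot$converged)
    stop("sigma-potential of pure '", species$name, "' did not converge (residual ",
         format(pot$residual), ")")
  sum(species$profile$area_per_bin * pot$mu)
}

resolve_gibbs_fusion <- function(solute, gibbs_fusion) {
  gf <- if (is.null(gibbs_fusion)) solute$gibbs_fusion else gibbs_fusion
  if (is.null(gf))
    stop("no free energy of fusion for solid solute '", solute$name,
         "': supply gibbs_fusion (0 for a liquid) or use relative mode, ",
         "where it cancels")
  stopifnot(is.numeric(gf), length(gf) == 1L, gf >= 0)
  gf
}

#' Mole-fraction solubility at infinite dilution
#'
#' Solubility from the chemical-potential balance
#' `ln x = (mu_pure - mu_solution - dG_fus) / (R T)`, evaluated at
#' infinite dilution (the solvent potential is not perturbed by the
#' solute).  Results above `x = 1` are capped at `ln x = 0` and flagged
#' miscible.
#'
#' @param solute a [cosmo_species()].
#' @param solvent a [solvent_mixture()].
#' @param params an [interaction_params()].
#' @param gibbs_fusion free energy of fusion, kJ/mol (0 for liquid
#'   solutes); defaults to the value stored on the species.
#' @param ... passed to [solve_sigma_potential()].
#' @return A one-row `prediction_record` data frame with `ln_x`,
#'   temperature, the fusion energy used and a `miscible` flag.
#' @export
ln_solubility_dilute <- function(solute, solvent, params = interaction_params(),
                                 gibbs_fusion = NULL, ...) {
  stopifnot(inherits(solvent, "solvent_mixture"))
  gf <- resolve_gibbs_fusion(solute, gibbs_fusion)
  RT <- .R_GAS * params$temperature
  pot <- solve_sigma_potential(mix_profiles(solvent), params, ...)
  if (!pot$converged)
    stop("sigma-potential of solvent '", solvent$label, "' did not converge")
  mu_solution <- solute_chemical_potential(solute, pot, solvent, params)
  mu_pure <- pure_chemical_potential(solute, params, ...)
  ln_x <- (mu_pure - mu_solution - gf) / RT
  miscible <- ln_x >= 0
  prediction_record(
    solute$name, solvent$label, ln_x = min(ln_x, 0),
    temperature = params$temperature,
    used_gibbs_fusion = format(gf), miscible = miscible
  )
}

# Solvent + dissolved solute at mole fraction x, as one mixture.  If the
# solute coincides with a solvent component the mole fractions merge.
saturated_mixture <- function(solute, solvent, x) {
  nm <- vapply(solvent$components, `[[`, character(1), "name")
  xs <- solvent$x * (1 - x)
  hit <- match(solute$name, nm)
  if (!is.na(hit)) {
    xs[hit] <- xs[hit] + x
    solvent_mixture(solvent$components, xs, label = solvent$label)
  } else {
    solvent_mixture(c(solvent$components, list(solute)), c(xs, x),
                    label = solvent$label)
  }
}

#' Self-consistent (finite-concentration) mole-fraction solubility
#'
#' Iterates the solubility equation to self-consistency in the dissolved
#' solute concentration: starting from the infinite-dilution estimate,
#' each step rebuilds the liquid as solvent plus solute at the current
#' mole fraction, re-solves the sigma-potential, and recomputes `ln x`.
#' Converged when successive `ln x` values differ by less than `tol`;
#' capped at `x = 1` (miscible).  In the dilute regime this reproduces
#' [ln_solubility_dilute()].
#'
#' @inheritParams ln_solubility_dilute
#' @param tol convergence tolerance on `ln x`.
#' @param max_iter outer-iteration cap; on oscillation without
#'   convergence the record is returned with `converged = FALSE`.
#' @return A one-row `prediction_record` data frame.
#' @export
ln_solubility_iterative <- function(solute, solvent, params = interaction_params(),
                                    gibbs_fusion = NULL, tol = 1e-6,
                                    max_iter = 50L) {
  stopifnot(inherits(solvent, "solvent_mixture"), tol > 0)
  gf <- resolve_gibbs_fusion(solute, gibbs_fusion)
  RT <- .R_GAS * params$temperature
  mu_pure <- pure_chemical_potential(solute, params)

  step_ln_x <- function(x) {
    mixt <- saturated_mixture(solute, solvent, x)
    pot <- solve_sigma_potential(mix_profiles(mixt), params)
    if (!pot$converged)
      stop("sigma-potential at x = ", format(x), " did not converge")
    mu <- solute_chemical_potential(solute, pot, mixt, params)
    min((mu_pure - mu - gf) / RT, 0)
  }

  ln_x <- ln_solubility_dilute(solute, solvent, params, gibbs_fusion = gf)$ln_x
  converged <- FALSE
  it <- 0L
  damp <- 0
  prev_delta <- NULL
  while (it < max_iter) {
    it <- it + 1L
    ln_new <- step_ln_x(exp(ln_x))
    delta <- ln_new - ln_x
    if (abs(delta) < tol) {
      ln_x <- ln_new
      converged <- TRUE
      break
    }
    if (!is.null(prev_delta) && delta * prev_delta < 0) damp <- 0.5
    prev_delta <- delta
    ln_x <- ln_x + (1 - damp) * delta
  }
  prediction_record(
    solute$name, solvent$label, ln_x = ln_x,
    temperature = params$temperature, used_gibbs_fusion = format(gf),
    miscible = ln_x >= 0, converged = converged, iterations = it
  )
}

#' Relative solubility of a solute between two solvents (log10 units)
#'
#' `log10(x_a / x_b) = (mu_Sb^X - mu_Sa^X) / (R T ln 10)` at infinite
#' dilution.  The pure-liquid reference and the free energy of fusion
#' cancel exactly between the two solvents, so no fusion data are
#' needed: this is the quantity of choice for solvent screening of
#' solids with unknown fusion thermodynamics.
#'
#' @param solute a [cosmo_species()].
#' @param solvent_a,solvent_b two [solvent_mixture()]s; `solvent_b` is the
#'   reference.
#' @param params an [interaction_params()].
#' @param ... passed to [solve_sigma_potential()].
#' @return A one-row `prediction_record` with `log10_relative` and the
#'   reference solvent name (`ln_x` is `NA`: no absolute scale).
#' @export
relative_log10_solubility <- function(solute, solvent_a, solvent_b,
                                      params = interaction_params(), ...) {
  stopifnot(inherits(solvent_a, "solvent_mixture"),
            inherits(solvent_b, "solvent_mixture"))
  RT <- .R_GAS * params$temperature
  mu_in <- function(solv) {
    pot <- solve_sigma_potential(mix_profiles(solv), params, ...)
    if (!pot$converged)
      stop("sigma-potential of solvent '", solv$label, "' did not converge")
    solute_chemical_potential(solute, pot, solv, params)
  }
  mu_a <- mu_in(solvent_a)
  mu_b <- mu_in(solvent_b)
  prediction_record(
    solute$name, solvent_a$label,
    reference_solvent_name = solvent_b$label,
    log10_relative = (mu_b - mu_a) / (RT * log(10)),
    temperature = params$temperature,
    used_gibbs_fusion = "cancelled"
  )
}

#' Rank solvents by predicted relative solubility of one solute
#'
#' Computes the solute's chemical potential in every solvent and orders
#' the solvents by decreasing predicted solubility, reported as log10
#' solubility relative to the first solvent in the input list.  The
#' ranking is independent of that reference choice (a common additive
#' shift).  Ties are broken lexicographically by solvent label.
#'
#' @param solute a [cosmo_species()].
#' @param solvents list of at least two [solvent_mixture()]s.
#' @param params an [interaction_params()].
#' @return data.frame with columns `solvent`, `log10_relative`, ordered
#'   best solvent first.
#' @export
rank_solvents <- function(solute, solvents, params = interaction_params()) {
  stopifnot(is.list(solvents), length(solvents) >= 2L,
            all(vapply(solvents, inherits, logical(1), "solvent_mixture")))
  RT <- .R_GAS * params$temperature
  labels <- vapply(solvents, `[[`, character(1), "label")
  mu <- vapply(solvents, function(solv) {
    pot <- solve_sigma_potential(mix_profiles(solv), params)
    if (!pot$converged)
      stop("sigma-potential of solvent '", solv$label, "' did not converge")
    solute_chemical_potential(solute, pot, solv, params)
  }, numeric(1))
  rel <- (mu[1] - mu) / (RT * log(10)) # log10(x_i / x_ref), ref = first
  ord <- order(-rel, labels)
  data.frame(solvent = labels[ord], log10_relative = rel[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}
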