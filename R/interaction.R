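# Molar gas constant, kJ/(mol K).  Segment energies are molar, so the
# thermal energy entering the Boltzmann factors is R*T rather than k*T.
.R_GAS <- 8.31446261815324e-3

#' Model constants for segment-segment interactions
#'
#' Collects every tunable constant of the segment model.  Two contacting
#' surface segments of charge density sigma and sigma' interact through
#'
#' * a misfit (electrostatic mismatch) penalty
#'   `a_eff * c_misfit * (sigma + sigma')^2 >= 0`, zero only for a
#'   perfect electrostatic fit `sigma' = -sigma`; and
#' * a hydrogen-bond gain (<= 0) that switches on only when the donor
#'   side is more negative than `-sigma_hb` and the acceptor side more
#'   positive than `+sigma_hb`.
#'
#' The dispersive (van der Waals) contribution is measured from a
#' reference state that already contains it, so it is identically zero
#' here.  The contact area `a_eff` is a single constant used both as the
#' contact area in the energies and as the segment size in the
#' sigma-potential equation.
#'
#' Default energetic coefficients derive from the published original
#' open parameterisation of the segment model (alpha'/2 = 8233.36
#' kcal A^4 mol^-1 e^-2, c_hb = 85580 kcal A^4 mol^-1 e^-2 at a
#' segment area of 7.5 A^2), converted to kJ per unit contact area; the
#' hydrogen-bond threshold is 0.0082 e/A^2.  They are shipped,
#' versioned, in `inst/extdata/interaction_params.txt`.
#'
#' @param temperature working temperature, K (room temperature default).
#' @param a_eff effective contact area of one segment pair, A^2.
#' @param c_misfit misfit coefficient, kJ mol^-1 A^-2 (e/A^2)^-2.
#' @param c_hb hydrogen-bond coefficient, same units; enters with a
#'   negative (attractive) sign.
#' @param sigma_hb donor/acceptor polarity threshold, e/A^2.
#' @param hb_form `"donor_acceptor"` (default): the bond energy is
#'   `c_hb * min(0, sigma_don + sigma_hb) * max(0, sigma_acc - sigma_hb)`
#'   per unit area, which realises the stated threshold behaviour
#'   exactly; `"product_threshold"`: the literal transcription
#'   `c_hb * min(0, sigma * sigma' + sigma_hb^2)`, kept selectable for
#'   sensitivity analysis.
#' @param combinatorial_form `"none"` (default) or `"area_volume"` for a
#'   Staverman-Guggenheim-style size/shape correction to the solute
#'   chemical potential (requires cavity areas and volumes).
#' @param combinatorial_coefficients list of dimensionless constants for
#'   the area/volume correction: coordination number `z`, and the
#'   volume/area normalisers `r_norm` (A^3), `q_norm` (A^2).
#' @return Object of class `"interaction_params"`.
#' @export
interaction_params <- function(temperature = 298.15,
                               a_eff = 7.5,
                               c_misfit = 4593.1170986666667,
                               c_hb = 47742.229333333333,
                               sigma_hb = 0.0082,
                               hb_form = c("donor_acceptor", "product_threshold"),
                               combinatorial_form = c("none", "area_volume"),
                               combinatorial_coefficients =
                                 list(z = 10, r_norm = 66.69, q_norm = 79.53)) {
  hb_form <- match.arg(hb_form)
  combinatorial_form <- match.arg(combinatorial_form)
  stopifnot(is.numeric(temperature), temperature > 0,
            is.numeric(a_eff), a_eff > 0,
            is.numeric(c_misfit), c_misfit >= 0,
            is.numeric(c_hb), c_hb >= 0,
            is.numeric(sigma_hb), sigma_hb > 0)
  structure(
    list(temperature = temperature, a_eff = a_eff,
         c_misfit = c_misfit, c_hb = c_hb, sigma_hb = sigma_hb,
         hb_form = hb_form, combinatorial_form = combinatorial_form,
         combinatorial_coefficients = combinatorial_coefficients,
         gas_constant = .R_GAS),
    class = "interaction_params"
  )
}

#' @export
print.interaction_params <- function(x, ...) {
  cat(sprintf(paste0("segment interaction parameters: T = %.2f K, a_eff = %g A^2,\n",
                     "  c_misfit = %g, c_hb = %g kJ/mol/A^2/(e/A^2)^2, sigma_hb = %g e/A^2\n",
                     "  hb_form = %s, combinatorial = %s\n"),
              x$temperature, x$a_eff, x$c_misfit, x$c_hb, x$sigma_hb,
              x$hb_form, x$combinatorial_form))
  invisible(x)
}

#' Read / write the interaction-parameter file
#'
#' Flat key-value text format (`key value` per line, `#` comments), with
#' numeric values written at full precision so a write/read round trip is
#' bit-exact.
#'
#' @param path file to read or write.
#' @return `read_interaction_params()` returns an [interaction_params()];
#'   `write_interaction_params()` returns `path` invisibly.
#' @export
read_interaction_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(trimws(lines), "\\s+")
  keys <- vapply(kv, `[[`, character(1), 1L)
  vals <- vapply(kv, `[[`, character(1), 2L)
  named <- stats::setNames(as.list(vals), keys)
  num <- function(k) as.numeric(named[[k]])
  interaction_params(
    temperature = num("temperature"),
    a_eff = num("a_eff"),
    c_misfit = num("c_misfit"),
    c_hb = num("c_hb"),
    sigma_hb = num("sigma_hb"),
    hb_form = named[["hb_form"]],
    combinatorial_form = named[["combinatorial_form"]]
  )
}

#' @rdname read_interaction_params
#' @param params an [interaction_params()] object.
#' @export
write_interaction_params <- function(params, path) {
  stopifnot(inherits(params, "interaction_params"))
  fmt <- function(k, v, unit) {
    if (is.numeric(v)) sprintf("%s %.17g  # %s", k, v, unit)
    else sprintf("%s %s  # %s", k, v, unit)
  }
  writeLines(c(
    "# segment interaction parameters, v1",
    fmt("temperature", params$temperature, "K"),
    fmt("a_eff", params$a_eff, "A^2"),
    fmt("c_misfit", params$c_misfit, "kJ mol^-1 A^-2 (e/A^2)^-2"),
    fmt("c_hb", params$c_hb, "kJ mol^-1 A^-2 (e/A^2)^-2"),
    fmt("sigma_hb", params$sigma_hb, "e/A^2"),
    fmt("hb_form", params$hb_form, "donor_acceptor | product_threshold"),
    fmt("combinatorial_form", params$combinatorial_form, "none | area_volume")
  ), path)
  invisible(path)
}

#' Misfit energy of one segment-segment contact
#'
#' Electrostatic mismatch penalty `a_eff * c_misfit * (sigma + sigma')^2`
#' in kJ/mol per contact; zero exactly when the two charge densities
#' cancel (perfect electrostatic fit).
#'
#' @param sigma,sigma_prime screening charge densities, e/A^2 (vectorised).
#' @param params an [interaction_params()].
#' @return Energy per contact, kJ/mol; always >= 0.
#' @export
misfit_energy <- function(sigma, sigma_prime, params) {
  params$a_eff * params$c_misfit * (sigma + sigma_prime)^2
}

#' Hydrogen-bond energy of one segment-segment contact
#'
#' Attractive (<= 0) contribution that requires the donor side below
#' `-sigma_hb` and the acceptor side above `+sigma_hb` (default
#' `donor_acceptor` form), or the literal product-threshold form
#' `c_hb * min(0, sigma*sigma' + sigma_hb^2)`.  Symmetric in its
#' arguments under both forms.
#'
#' @inheritParams misfit_energy
#' @return Energy per contact, kJ/mol; always <= 0.
#' @export
hb_energy <- function(sigma, sigma_prime, params) {
  C <- params$a_eff * params$c_hb
  if (params$hb_form == "donor_acceptor") {
    s_don <- pmin(sigma, sigma_prime)
    s_acc <- pmax(sigma, sigma_prime)
    C * pmin(0, pmin(0, s_don + params$sigma_hb) *
                  pmax(0, s_acc - params$sigma_hb))
  } else {
    C * pmin(0, sigma * sigma_prime + params$sigma_hb^2)
  }
}

#' Total interaction energy of one segment-segment contact
#'
#' Sum of misfit and hydrogen-bond terms; the dispersive part is zero by
#' construction (it is absorbed in the reference state).
#'
#' @inheritParams misfit_energy
#' @return Energy per contact, kJ/mol.
#' @export
total_energy <- function(sigma, sigma_prime, params) {
  misfit_energy(sigma, sigma_prime, params) +
    hb_energy(sigma, sigma_prime, params)
}

#' Precompute the segment interaction matrix on a grid
#'
#' @param grid a [sigma_grid()].
#' @param params an [interaction_params()].
#' @return Object of class `"interaction_matrix"`: list with `grid` and
#'   the symmetric `n_bins x n_bins` matrix `energy` of per-contact
#'   energies (kJ/mol for a contact of area `a_eff`).
#' @export
build_interaction_matrix <- function(grid, params) {
  stopifnot(inherits(grid, "sigma_grid"), inherits(params, "interaction_params"))
  sk <- matrix(grid$sigma, grid$n_bins, grid$n_bins)
  sl <- t(sk)
  # misfit uses sk + sl (commutative) and hb uses pmin/pmax of the pair,
  # so the result is exactly symmetric bit-for-bit.
  energy <- total_energy(sk, sl, params)
  structure(list(grid = grid, energy = energy), class = "interaction_matrix")
}
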