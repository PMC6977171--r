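#' Solvent composition by molar ratio
#'
#' Bookkeeping record for a (multi)component solvent: component names,
#' molar masses and molar ratios, e.g. choline chloride : urea = 1 : 2.
#' Every component, including any water in the recipe, is a
#' mole-bearing particle.
#'
#' @param label solvent label (e.g. `"CU"`, `"CLW"`).
#' @param names character vector of component names.
#' @param molar_masses g/mol, one per component.
#' @param ratios positive molar ratios, one per component.
#' @return Object of class `"composition_spec"`.
#' @export
composition_spec <- function(label, names, molar_masses, ratios) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label),
            is.character(names), length(names) >= 1L,
            length(molar_masses) == length(names),
            length(ratios) == length(names),
            all(molar_masses > 0), all(ratios > 0))
  if (anyDuplicated(names)) stop("component names must be unique")
  structure(
    list(label = label,
         components = data.frame(name = names, molar_mass = molar_masses,
                                 ratio = ratios, stringsAsFactors = FALSE)),
    class = "composition_spec"
  )
}

#' @export
print.composition_spec <- function(x, ...) {
  cat(sprintf("%s: %s (molar ratio %s), mean M = %.2f g/mol\n",
              x$label, paste(x$components$name, collapse = "-"),
              paste(format(x$components$ratio), collapse = ":"),
              mean_molar_mass(x)))
  invisible(x)
}

#' Mean molar mass of a solvent composition
#'
#' Mole-weighted mean `sum(ratio_i * M_i) / sum(ratio_i)`: the mass of
#' one mole of mixed solvent particles.  Scale-invariant in the ratios.
#'
#' @param spec a [composition_spec()].
#' @return g/mol.
#' @export
mean_molar_mass <- function(spec) {
  stopifnot(inherits(spec, "composition_spec"))
  with(spec$components, sum(ratio * molar_mass) / sum(ratio))
}

#' Convert measured solubility between mg/g-solvent and mole fraction
#'
#' `mg_per_g_to_mole_fraction()` maps a gravimetric solubility (mg solute
#' per g solvent) to mole fraction using the solvent's mean molar mass:
#' per gram of solvent there are `1/mean_molar_mass` moles of solvent
#' particles and `(mg/1000)/M_solute` moles of solute.
#' `mole_fraction_to_mg_per_g()` is the exact inverse.
#'
#' @param mg_per_g solubility, mg solute per g solvent (>= 0).
#' @param x mole fraction of solute (0 <= x < 1).
#' @param solute_molar_mass g/mol.
#' @param spec the solvent's [composition_spec()].
#' @return Mole fraction, or mg per g solvent.
#' @export
mg_per_g_to_mole_fraction <- function(mg_per_g, solute_molar_mass, spec) {
  stopifnot(is.numeric(mg_per_g), all(mg_per_g >= 0), solute_molar_mass > 0)
  n_api <- (mg_per_g / 1000) / solute_molar_mass
  n_solvent <- 1 / mean_molar_mass(spec)
  n_api / (n_api + n_solvent)
}

#' @rdname mg_per_g_to_mole_fraction
#' @export
mole_fraction_to_mg_per_g <- function(x, solute_molar_mass, spec) {
  stopifnot(is.numeric(x), all(x >= 0), all(x < 1), solute_molar_mass > 0)
  n_solvent <- 1 / mean_molar_mass(spec)
  n_api <- x / (1 - x) * n_solvent
  n_api * solute_molar_mass * 1000
}

#' Fold ratio between two solubilities
#'
#' `a / b` with the rounding conventions used when quoting fold
#' increases: `"printed"` (default) rounds to one decimal below 10 and
#' to the nearest integer at 10 or above — the convention that yields
#' "1.8-fold" and "12-fold" from one pair of measurement tables —
#' `"one_decimal"`, `"nearest_integer"`, or `"none"`.
#'
#' @param a,b solubilities in the same unit; `b > 0`.  `NA` operands
#'   (e.g. below-LOQ cells) are an error: the ratio is undefined.
#' @param rounding rounding convention.
#' @return Dimensionless fold ratio.
#' @export
fold_ratio <- function(a, b, rounding = c("printed", "one_decimal",
                                          "nearest_integer", "none")) {
  rounding <- match.arg(rounding)
  if (anyNA(a) || anyNA(b))
    stop("fold ratio undefined: an operand is missing (below LOQ?)")
  if (any(b == 0)) stop("fold ratio undefined for zero denominator")
  r <- a / b
  switch(rounding,
         printed = ifelse(r >= 10, round(r), round(r, 1)),
         one_decimal = round(r, 1),
         nearest_integer = round(r),
         none = r)
}

#' Difference of two solubilities in log10 units
#'
#' `log10(x_a) - log10(x_b)` for positive mole fractions (or any
#' positive solubilities on a common scale).
#'
#' @param x_a,x_b positive values.
#' @return Log10-unit difference.
#' @export
log10_units_difference <- function(x_a, x_b) {
  if (any(x_a <= 0) || any(x_b <= 0))
    stop("log10 difference requires strictly positive values")
  log10(x_a) - log10(x_b)
}

#' Water mass fraction of a hydrate formula
#'
#' `100 * n_water * M_water / sum(n_i * M_i)` for a formula given as
#' components with counts, e.g. sodium tartrate dihydrate =
#' anhydrous salt (1) + water (2) -> 15.7 wt% water.  This is the
#' stoichiometry behind Karl Fischer titer standardisation.
#'
#' @param names component names; water is recognised by the name
#'   `"water"` (case-insensitive).
#' @param molar_masses g/mol per component.
#' @param counts formula counts per component.
#' @return Water content, wt%.
#' @export
water_mass_fraction <- function(names, molar_masses, counts) {
  stopifnot(length(names) == length(molar_masses),
            length(names) == length(counts),
            all(molar_masses > 0), all(counts >= 0))
  mass <- counts * molar_masses
  is_water <- tolower(names) == "water"
  100 * sum(mass[is_water]) / sum(mass)
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "descreen")
  if (!nzchar(p)) stop("packaged fixture '", file, "' not found")
  p
}

#' Packaged solvent compositions of the DES screening study
#'
#' Loads the shipped composition table: six deep eutectic solvents
#' (choline chloride-urea 1:2; choline chloride-glycerol 1:2; choline
#' chloride-lactic acid-water 1:0.9:0.6; betaine-glycerol-water 1:2:1;
#' choline chloride-glucose-water 1:0.4:1; lactic acid-glucose-water
#' 1:0.2:1.2), the four single solvents (water, ethanol, glycerol,
#' PEG 300), and lactic acid alone.  Glucose-containing recipes use
#' anhydrous glucose with water as an explicit component at the stated
#' ratio.  Compositions are nominal (as weighed in), not
#' titration-corrected.
#'
#' @return Named list of [composition_spec()] objects.
#' @export
load_compositions <- function() {
  tab <- utils::read.csv(fixture_path("compositions.csv"),
                         stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("label", "component", "molar_mass", "ratio")
  if (!all(needed %in% names(tab)))
    stop("composition fixture integrity error: missing columns")
  out <- lapply(split(tab, tab$label), function(d)
    composition_spec(d$label[[1]], d$component, d$molar_mass, d$ratio))
  out[unique(tab$label)]
}

#' Packaged experimental solubility table of the DES screening study
#'
#' Measured solubilities (mg API per g solvent, mean and SD of n = 3,
#' 24 h agitation at room temperature) of 11 drugs in 10 solvents, plus
#' three measurements in lactic acid alone.  Cells that could not be
#' quantified carry a flag instead of a mean: `below_LOQ` (aprepitant
#' and probucol in water), `phase_separation` (cinnarizine in LGW), and
#' `viscous` marks the lidocaine/LGW cell whose dissolution made the
#' medium too viscous to stir (value retained).
#'
#' @return data.frame with columns `api`, `solvent`, `mean_mg_per_g`,
#'   `sd_mg_per_g`, `n`, `flag` (empty string when none).
#' @export
load_solubilities <- function() {
  tab <- utils::read.csv(fixture_path("solubilities.csv"),
                         stringsAsFactors = FALSE, comment.char = "#",
                         na.strings = "NA")
  needed <- c("api", "solvent", "mean_mg_per_g", "sd_mg_per_g", "n", "flag")
  if (!all(needed %in% names(tab)))
    stop("solubility fixture integrity error: missing columns")
  tab$flag[is.na(tab$flag)] <- ""
  tab
}

#' Packaged solute (API) metadata
#'
#' @return data.frame with columns `api`, `molar_mass` (g/mol) for the
#'   11 drugs of the screening study.
#' @export
load_apis <- function() {
  utils::read.csv(fixture_path("apis.csv"), stringsAsFactors = FALSE,
                  comment.char = "#")
}

#' Load and integrity-check all packaged study fixtures
#'
#' Loads compositions, solubilities and API metadata and validates the
#' study layout: 11 APIs x 10 solvents with every cell carrying either a
#' (mean, SD) pair or an explicit flag, plus the three lactic-acid-alone
#' records; every solvent label resolvable to a composition.  Any
#' violation raises an integrity error.
#'
#' @return list with elements `compositions` (named list of
#'   [composition_spec()]), `solubilities` (data.frame), `apis`
#'   (data.frame).
#' @export
load_fixtures <- function() {
  comps <- load_compositions()
  sols <- load_solubilities()
  apis <- load_apis()

  core_solvents <- c("CU", "CG", "CLW", "BGW", "LGW", "CGW",
                     "Ethanol", "Glycerol", "PEG300", "Water")
  if (nrow(apis) != 11L)
    stop("fixture integrity error: expected 11 APIs, found ", nrow(apis))
  if (!all(c(core_solvents, "LacticAcid") %in% names(comps)))
    stop("fixture integrity error: missing solvent compositions")
  core <- sols[sols$solvent %in% core_solvents, ]
  cells <- with(core, table(api, solvent))
  if (nrow(cells) != 11L || ncol(cells) != 10L || any(cells != 1L))
    stop("fixture integrity error: expected one record per API x solvent cell ",
         "(11 x 10)")
  ok <- !is.na(core$mean_mg_per_g) | nzchar(core$flag)
  if (!all(ok))
    stop("fixture integrity error: cells without value or flag: ",
         paste(core$api[!ok], core$solvent[!ok], collapse = ", "))
  has_mean <- !is.na(core$mean_mg_per_g)
  if (any(core$mean_mg_per_g[has_mean] < 0) ||
      any(core$sd_mg_per_g[has_mean] < 0, na.rm = TRUE))
    stop("fixture integrity error: negative solubility or SD")
  if (any(core$flag == "below_LOQ" & has_mean))
    stop("fixture integrity error: below-LOQ cells must not carry a mean")
  if (!all(sols$api %in% apis$api))
    stop("fixture integrity error: unknown API in solubility table")
  list(compositions = comps, solubilities = sols, apis = apis)
}
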