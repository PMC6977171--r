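#' Sigma-profile: area-weighted histogram of screening-charge density
#'
#' A sigma-profile p(sigma) records how much molecular surface area (A^2)
#' carries each screening-charge density.  It is the molecular
#' fingerprint the segment model operates on: the area beyond
#' -sigma_hb marks hydrogen-bond-donor surface, beyond +sigma_hb
#' acceptor surface, and the area near zero apolar surface.
#'
#' Profiles are stored area-weighted (A^2 per bin), not
#' probability-weighted; normalisation to a distribution is explicit via
#' [normalize_profile()].
#'
#' @param grid a [sigma_grid()].
#' @param area_per_bin numeric vector of segment areas (A^2), one per grid
#'   bin, all non-negative.
#' @return An object of class `"sigma_profile"`: list with `grid`,
#'   `area_per_bin`, `total_area`.
#' @seealso [read_sigma_profile()], [mix_profiles()]
#' @export
sigma_profile <- function(grid, area_per_bin) {
  stopifnot(inherits(grid, "sigma_grid"), is.numeric(area_per_bin))
  if (length(area_per_bin) != grid$n_bins)
    stop("area_per_bin must have one entry per grid bin")
  if (any(!is.finite(area_per_bin)))
    stop("area_per_bin must be finite")
  if (any(area_per_bin < 0))
    stop("area_per_bin must be non-negative")
  structure(
    list(grid = grid, area_per_bin = as.numeric(area_per_bin),
         total_area = sum(area_per_bin)),
    class = "sigma_profile"
  )
}

#' @export
print.sigma_profile <- function(x, ...) {
  cat(sprintf("sigma profile on %d bins, total area %.4g A^2\n",
              x$grid$n_bins, x$total_area))
  invisible(x)
}

#' Read a sigma-profile from a two-column text file
#'
#' Parses the community two-column plain-text dialect: whitespace-
#' separated `sigma [e/A^2]` and `segment area [A^2]` columns, with
#' `#` comment lines.  Rows whose sigma does not fall exactly on a grid
#' bin centre are apportioned linearly between the two bracketing bins,
#' which conserves total area (the standard histogramming choice).
#'
#' @param path file to read.
#' @param dialect input dialect; only `"vt2005"` (the two-column text
#'   convention of the public sigma-profile databases) is supported.
#' @param grid target [sigma_grid()]; input sigma values must lie within
#'   its bounds.
#' @return A [sigma_profile()] on `grid`.
#' @export
read_sigma_profile <- function(path, dialect = "vt2005", grid = sigma_grid()) {
  dialect <- match.arg(dialect, "vt2005")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  s <- numeric(0); a <- numeric(0)
  for (i in idx) {
    fields <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) != 2L || any(is.na(vals)))
      stop(sprintf("parse error at line %d of '%s': expected two numeric columns, got '%s'",
                   i, path, lines[[i]]))
    s <- c(s, vals[[1]]); a <- c(a, vals[[2]])
  }
  if (length(s) == 0L) stop("no data rows in '", path, "'")
  if (is.unsorted(s)) stop("sigma column must be monotone non-decreasing in '", path, "'")
  if (any(a < 0))
    stop(sprintf("negative segment area at line %d of '%s'",
                 idx[which(a < 0)[1]], path))
  bin_areas <- apportion_to_grid(s, a, grid)
  sigma_profile(grid, bin_areas)
}

# Linear area apportionment of (sigma, area) points onto grid bins.
# Exact bin centres go wholly to their bin so that write/read round-trips
# are bitwise identities.
apportion_to_grid <- function(s, a, grid, snap = 1e-9) {
  out_of_range <- s < grid$sigma_min - 1e-12 | s > grid$sigma_max + 1e-12
  if (any(out_of_range))
    stop(sprintf("sigma value %g outside grid range [%g, %g]",
                 s[which(out_of_range)[1]], grid$sigma_min, grid$sigma_max))
  bin_areas <- numeric(grid$n_bins)
  pos <- (s - grid$sigma_min) / grid$step
  lo <- pmin(pmax(floor(pos), 0), grid$n_bins - 1L)
  frac <- pos - lo
  for (j in seq_along(s)) {
    i <- lo[[j]] + 1L
    f <- frac[[j]]
    if (f < snap || i == grid$n_bins) {
      bin_areas[i] <- bin_areas[i] + a[[j]]
    } else if (f > 1 - snap) {
      bin_areas[i + 1L] <- bin_areas[i + 1L] + a[[j]]
    } else {
      bin_areas[i] <- bin_areas[i] + a[[j]] * (1 - f)
      bin_areas[i + 1L] <- bin_areas[i + 1L] + a[[j]] * f
    }
  }
  bin_areas
}

#' Write a sigma-profile to a two-column text file
#'
#' Full-precision output (`%.17g`), so [read_sigma_profile()] inverts it
#' bitwise.
#'
#' @param profile a [sigma_profile()] with positive total area.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_sigma_profile <- function(profile, path) {
  stopifnot(inherits(profile, "sigma_profile"))
  if (profile$total_area <= 0)
    stop("refusing to write a profile with zero total area")
  g <- profile$grid
  lines <- c(
    "# sigma-profile: sigma[e/A^2]  area[A^2]",
    sprintf("%.17g %.17g", g$sigma, profile$area_per_bin)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Normalise a sigma-profile to a probability distribution over bins
#'
#' @param profile a [sigma_profile()] with positive total area.
#' @return Numeric weights, one per bin, non-negative and summing to 1.
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "sigma_profile"))
  if (profile$total_area <= 0)
    stop("cannot normalise a profile with zero total area")
  profile$area_per_bin / profile$total_area
}

#' A chemical species with its sigma-profile and metadata
#'
#' One species = one sigma-profile (the most stable conformation);
#' salts such as choline chloride enter as a single neutral (unionised)
#' species with one profile.
#'
#' @param name species identifier.
#' @param molar_mass molar mass, g/mol.
#' @param profile the species' [sigma_profile()].
#' @param cosmo_area cavity surface area, A^2; defaults to the profile's
#'   total area and must agree with it to 1e-6 relative when supplied.
#' @param cosmo_volume cavity volume, A^3 (optional; required only for the
#'   area/volume combinatorial correction).
#' @param gibbs_fusion free energy of fusion at the working temperature,
#'   kJ/mol; `NULL` for liquids.  This is the solid-state penalty in the
#'   solubility equation; it cancels in relative solubility.
#' @return Object of class `"cosmo_species"`.
#' @export
cosmo_species <- function(name, molar_mass, profile,
                          cosmo_area = NULL, cosmo_volume = NULL,
                          gibbs_fusion = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(molar_mass), length(molar_mass) == 1L, molar_mass > 0,
            inherits(profile, "sigma_profile"))
  if (profile$total_area <= 0)
    stop("a physical species must have positive surface area")
  if (is.null(cosmo_area)) cosmo_area <- profile$total_area
  if (abs(cosmo_area - profile$total_area) > 1e-6 * max(cosmo_area, profile$total_area))
    stop("cosmo_area disagrees with the profile's total area")
  if (!is.null(gibbs_fusion)) {
    stopifnot(is.numeric(gibbs_fusion), length(gibbs_fusion) == 1L)
    if (gibbs_fusion < 0) stop("gibbs_fusion must be >= 0 (a solid's fusion penalty)")
  }
  structure(
    list(name = name, molar_mass = molar_mass, profile = profile,
         cosmo_area = cosmo_area, cosmo_volume = cosmo_volume,
         gibbs_fusion = gibbs_fusion),
    class = "cosmo_species"
  )
}

#' @export
print.cosmo_species <- function(x, ...) {
  cat(sprintf("species '%s': M = %.2f g/mol, area %.4g A^2%s\n",
              x$name, x$molar_mass, x$cosmo_area,
              if (is.null(x$gibbs_fusion)) " (liquid)"
              else sprintf(", dG_fus = %.3g kJ/mol", x$gibbs_fusion)))
  invisible(x)
}

#' A (possibly multicomponent) solvent as named species with mole fractions
#'
#' Every component of a multicomponent solvent (e.g. each DES
#' constituent, including water) is an independent mole-bearing species:
#' a 1:0.9:0.6 molar-ratio DES contributes 2.5 mol of particles per
#' formula set.  Ratios are normalised to mole fractions.
#'
#' @param components list of [cosmo_species()].
#' @param ratios positive molar ratios (or mole fractions), one per
#'   component; normalised internally to sum to 1.
#' @param label name for the mixture; defaults to the component names
#'   joined by `"+"`.
#' @return Object of class `"solvent_mixture"` with elements `components`,
#'   `x` (mole fractions) and `label`.
#' @export
solvent_mixture <- function(components, ratios = rep(1, length(components)),
                            label = NULL) {
  if (inherits(components, "cosmo_species")) components <- list(components)
  stopifnot(length(components) >= 1L,
            all(vapply(components, inherits, logical(1), "cosmo_species")),
            is.numeric(ratios), length(ratios) == length(components))
  if (any(!is.finite(ratios)) || any(ratios < 0) || sum(ratios) <= 0)
    stop("molar ratios must be non-negative with positive sum")
  nm <- vapply(components, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("component names must be unique: ", nm[duplicated(nm)][1])
  x <- ratios / sum(ratios)
  if (abs(sum(x) - 1) > 1e-12) x <- x / sum(x)
  if (is.null(label)) label <- paste(nm, collapse = "+")
  structure(list(components = components, x = x, label = label),
            class = "solvent_mixture")
}

#' @export
print.solvent_mixture <- function(x, ...) {
  nm <- vapply(x$components, `[[`, character(1), "name")
  cat(sprintf("solvent '%s': %s\n", x$label,
              paste(sprintf("%s (x = %.4f)", nm, x$x), collapse = ", ")))
  invisible(x)
}

#' Mole-fraction-weighted mixture sigma-profile
#'
#' The mixture profile is the bin-wise mole-fraction-weighted sum of the
#' component profiles, so its total area is the weighted mean of the
#' component areas (area per mole of mixed particles).
#'
#' @param mixture a [solvent_mixture()]; all component profiles must share
#'   one grid.
#' @return A [sigma_profile()] on the common grid.
#' @export
mix_profiles <- function(mixture) {
  stopifnot(inherits(mixture, "solvent_mixture"))
  g <- mixture$components[[1]]$profile$grid
  for (comp in mixture$components)
    if (!same_grid(g, comp$profile$grid))
      stop("all component profiles must be on the same sigma grid")
  area <- numeric(g$n_bins)
  for (i in seq_along(mixture$components))
    area <- area + mixture$x[[i]] * mixture$components[[i]]$profile$area_per_bin
  sigma_profile(g, area)
}
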