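#' Discretisation grid for surface screening-charge density
#'
#' Builds the uniform grid of screening-charge-density values (sigma, in
#' e/A^2) on which sigma-profiles and sigma-potentials live.  The default
#' covers -0.030 ... +0.030 e/A^2 in steps of 0.001 (61 bins), the
#' conventional axis for segment-thermodynamics work; polar surfaces of
#' drug-like molecules rarely reach beyond +/-0.025 e/A^2.
#'
#' The grid must be symmetric about zero and contain sigma = 0 exactly:
#' the zero bin is the reference state (a perfectly screened, apolar
#' contact) and several closed-form limits of the model are anchored
#' there.
#'
#' @param sigma_min,sigma_max grid end points, e/A^2.
#' @param step bin width, e/A^2.
#' @return An object of class `"sigma_grid"`: a list with elements
#'   `sigma_min`, `sigma_max`, `step`, `n_bins` and the bin centres
#'   `sigma`.
#' @examples
#' g <- sigma_grid()
#' g$n_bins            # 61
#' g$sigma[31]         # exactly 0
#' @export
sigma_grid <- function(sigma_min = -0.030, sigma_max = 0.030, step = 0.001) {
  stopifnot(is.numeric(sigma_min), is.numeric(sigma_max), is.numeric(step),
            length(sigma_min) == 1L, length(sigma_max) == 1L, length(step) == 1L,
            is.finite(sigma_min), is.finite(sigma_max), is.finite(step),
            step > 0, sigma_max > sigma_min)
  n_bins <- as.integer(round((sigma_max - sigma_min) / step)) + 1L
  if (abs((sigma_max - sigma_min) - (n_bins - 1L) * step) > 1e-12)
    stop("grid is not uniform: (sigma_max - sigma_min) must be an integer multiple of step")
  if (abs(sigma_min + sigma_max) > 1e-12)
    stop("grid must be symmetric about sigma = 0")
  sigma <- sigma_min + step * (seq_len(n_bins) - 1L)
  i0 <- which.min(abs(sigma))
  if (abs(sigma[i0]) > 1e-12)
    stop("grid must contain sigma = 0 exactly")
  sigma[i0] <- 0 # snap away floating-point residue so sigma = 0 is exact
  structure(
    list(sigma_min = sigma_min, sigma_max = sigma_max, step = step,
         n_bins = n_bins, sigma = sigma),
    class = "sigma_grid"
  )
}

#' @export
print.sigma_grid <- function(x, ...) {
  cat(sprintf("sigma grid: %g ... %g e/A^2, step %g (%d bins)\n",
              x$sigma_min, x$sigma_max, x$step, x$n_bins))
  invisible(x)
}

# Two grids are interchangeable if they have the same bins (to fp noise).
same_grid <- function(a, b, tol = 1e-12) {
  inherits(a, "sigma_grid") && inherits(b, "sigma_grid") &&
    a$n_bins == b$n_bins && max(abs(a$sigma - b$sigma)) <= tol
}
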