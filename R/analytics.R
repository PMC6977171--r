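#' Linear-fit statistics for predicted vs. experimental log-solubility
#'
#' Ordinary least squares of the experimental values on the predicted
#' ones (the identity line is the ideal fit), with R^2 of that fit, the
#' root-mean-square of its residuals, and the Spearman rank correlation
#' of the pairs.  Pairs with a missing member (e.g. below-LOQ
#' measurements) are excluded and counted.
#'
#' @param predicted,experimental paired numeric vectors of
#'   log-solubility values (same length, matched by solute/solvent).
#' @return Object of class `"comparison_stats"`: list with `slope`,
#'   `intercept`, `r_squared`, `rmse`, `spearman_rho`, `n` (pairs used)
#'   and `n_excluded`.
#' @export
linear_fit_stats <- function(predicted, experimental) {
  stopifnot(is.numeric(predicted), is.numeric(experimental),
            length(predicted) == length(experimental))
  ok <- is.finite(predicted) & is.finite(experimental)
  n_excluded <- sum(!ok)
  if (n_excluded > 0)
    message(n_excluded, " pair(s) excluded (missing or non-finite values)")
  p <- predicted[ok]; e <- experimental[ok]
  if (length(p) < 2L)
    stop("insufficient data: need at least 2 valid pairs, have ", length(p))
  fit <- stats::lm(e ~ p)
  # noise-free closure produces an exact fit; summary.lm warns about it
  sm <- suppressWarnings(summary(fit))
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = sm$r.squared,
         rmse = sqrt(mean(stats::residuals(fit)^2)),
         spearman_rho = stats::cor(p, e, method = "spearman"),
         n = length(p), n_excluded = n_excluded),
    class = "comparison_stats"
  )
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat(sprintf(paste0("predicted vs. experimental (n = %d%s):\n",
                     "  slope = %.3f, intercept = %.3f, R^2 = %.3f, ",
                     "RMSE = %.3f, Spearman rho = %.3f\n"),
              x$n,
              if (x$n_excluded > 0) sprintf(", %d excluded", x$n_excluded) else "",
              x$slope, x$intercept, x$r_squared, x$rmse, x$spearman_rho))
  invisible(x)
}

#' Rank agreement between predicted and experimental solvent order
#'
#' Spearman correlation (ties mid-ranked) of the predicted vs.
#' experimental solvent ranking for one solute, across the solvents with
#' valid values in both tables.
#'
#' @param predictions,experiments data.frames with columns `api`,
#'   `solvent`, `value` (any monotone solubility scale; only ranks are
#'   used).
#' @param api which solute to evaluate.
#' @return Spearman rho.
#' @export
per_api_rank_agreement <- function(predictions, experiments, api) {
  p <- predictions[predictions$api == api & is.finite(predictions$value), ]
  e <- experiments[experiments$api == api & is.finite(experiments$value), ]
  common <- intersect(p$solvent, e$solvent)
  if (length(common) < 3L)
    stop("insufficient data: need >= 3 solvents with valid values for '",
         api, "', have ", length(common))
  stats::cor(p$value[match(common, p$solvent)],
             e$value[match(common, e$solvent)],
             method = "spearman")
}

#' Per-solute relative solubilities against a reference solvent
#'
#' For each (API, solvent) pair present in both tables, computes the
#' experimental and predicted log10 solubility relative to the API's
#' reference solvent (e.g. water for most drugs, ethanol where the
#' aqueous solubility was unquantifiable).  APIs whose reference value
#' is missing in either table are skipped with a message.  Absolute
#' scale cancels: shifting all of an API's values leaves its rows
#' unchanged.
#'
#' @param predictions,experiments data.frames with columns `api`,
#'   `solvent`, `value`, where `value` is log10 mole-fraction solubility
#'   (any common additive offset per table is immaterial).
#' @param reference_map named character vector mapping API -> reference
#'   solvent.
#' @return data.frame with columns `api`, `solvent`, `reference`,
#'   `predicted`, `experimental` (log10 relative values), excluding the
#'   reference rows themselves.
#' @export
relative_solubility_table <- function(predictions, experiments, reference_map) {
  stopifnot(all(c("api", "solvent", "value") %in% names(predictions)),
            all(c("api", "solvent", "value") %in% names(experiments)),
            !is.null(names(reference_map)))
  out <- list()
  for (api in unique(experiments$api)) {
    ref <- reference_map[[api]]
    if (is.null(ref) || is.na(ref)) {
      message("no reference solvent for '", api, "': skipped")
      next
    }
    p <- predictions[predictions$api == api, ]
    e <- experiments[experiments$api == api, ]
    p_ref <- p$value[p$solvent == ref]
    e_ref <- e$value[e$solvent == ref]
    if (length(p_ref) != 1L || length(e_ref) != 1L ||
        !is.finite(p_ref) || !is.finite(e_ref)) {
      message("missing reference value for '", api, "' in '", ref,
              "': skipped")
      next
    }
    common <- setdiff(intersect(p$solvent, e$solvent), ref)
    pv <- p$value[match(common, p$solvent)] - p_ref
    ev <- e$value[match(common, e$solvent)] - e_ref
    keep <- is.finite(pv) & is.finite(ev)
    if (any(!keep))
      message(sum(!keep), " cell(s) for '", api, "' excluded (missing value)")
    if (any(keep))
      out[[api]] <- data.frame(api = api, solvent = common[keep],
                               reference = ref, predicted = pv[keep],
                               experimental = ev[keep],
                               stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(api = character(0), solvent = character(0),
                      reference = character(0), predicted = numeric(0),
                      experimental = numeric(0)))
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}
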