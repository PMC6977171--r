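#' Screen a set of solutes across a set of solvents
#'
#' The package's top-level modelling function.  For every
#' (solute, solvent) pair it computes the predicted log10 mole-fraction
#' solubility from the segment model (dilute or self-consistent mode)
#' and, when an experimental table is supplied, the per-solute relative
#' solubilities against a reference solvent and the
#' predicted-vs-experimental fit statistics.
#'
#' @param solutes list of [cosmo_species()] (with `gibbs_fusion` set for
#'   absolute solubilities; relative screening needs none).
#' @param solvents list of [solvent_mixture()]s.
#' @param params an [interaction_params()].
#' @param data optional experimental table: data.frame with columns
#'   `api`, `solvent`, `value` = log10 mole-fraction solubility.
#' @param reference_map named character vector API -> reference solvent
#'   for the relative comparison; defaults to the first solvent for all
#'   solutes.
#' @param mode `"dilute"` (infinite dilution, default) or `"iterative"`
#'   (self-consistent in the dissolved concentration; needs fusion
#'   energies).
#' @return Object of class `"des_screen"` with elements `predictions`
#'   (data.frame `api`, `solvent`, `value` = predicted log10 x up to a
#'   per-solute constant in relative mode), `rankings` (named list of
#'   [rank_solvents()] tables), and, when `data` is given, `relative`
#'   (the [relative_solubility_table()]) and `stats`
#'   ([linear_fit_stats()] on the relative values).
#' @examples
#' spec <- synthetic_spec(seed = 1, n_solutes = 3, n_solvents = 3,
#'                        noise_sd = 0.2)
#' study <- synthetic_study(spec)
#' exp_tab <- data.frame(api = study$experimental$api,
#'                       solvent = study$experimental$solvent,
#'                       value = study$experimental$log10_x)
#' scr <- des_screen(study$solutes, study$solvents, data = exp_tab)
#' summary(scr)
#' @export
des_screen <- function(solutes, solvents, params = interaction_params(),
                       data = NULL, reference_map = NULL,
                       mode = c("dilute", "iterative")) {
  mode <- match.arg(mode)
  if (inherits(solutes, "cosmo_species")) solutes <- list(solutes)
  stopifnot(length(solutes) >= 1L, length(solvents) >= 2L,
            all(vapply(solutes, inherits, logical(1), "cosmo_species")),
            all(vapply(solvents, inherits, logical(1), "solvent_mixture")))
  RT <- .R_GAS * params$temperature
  solvent_labels <- vapply(solvents, `[[`, character(1), "label")

  potentials <- lapply(solvents, function(s)
    solve_sigma_potential(mix_profiles(s), params))
  for (j in seq_along(potentials))
    if (!potentials[[j]]$converged)
      stop("sigma-potential of solvent '", solvent_labels[[j]],
           "' did not converge")

  predictions <- do.call(rbind, lapply(solutes, function(sol) {
    value <- if (mode == "iterative") {
      vapply(solvents, function(sv)
        ln_solubility_iterative(sol, sv, params)$ln_x / log(10), numeric(1))
    } else if (!is.null(sol$gibbs_fusion)) {
      vapply(solvents, function(sv)
        ln_solubility_dilute(sol, sv, params)$ln_x / log(10), numeric(1))
    } else {
      # no fusion data: values are log10 x up to one per-solute constant,
      # which cancels in rankings and relative comparisons
      mu <- vapply(seq_along(solvents), function(j)
        solute_chemical_potential(sol, potentials[[j]], solvents[[j]], params),
        numeric(1))
      -mu / (RT * log(10))
    }
    data.frame(api = sol$name, solvent = solvent_labels, value = value,
               stringsAsFactors = FALSE)
  }))
  row.names(predictions) <- NULL

  rankings <- lapply(solutes, rank_solvents, solvents = solvents,
                     params = params)
  names(rankings) <- vapply(solutes, `[[`, character(1), "name")

  relative <- NULL
  stats <- NULL
  if (!is.null(data)) {
    stopifnot(all(c("api", "solvent", "value") %in% names(data)))
    if (is.null(reference_map)) {
      apis <- unique(data$api)
      reference_map <- stats::setNames(rep(solvent_labels[[1]], length(apis)),
                                       apis)
    }
    relative <- relative_solubility_table(predictions, data, reference_map)
    stats <- linear_fit_stats(relative$predicted, relative$experimental)
  }

  structure(
    list(predictions = predictions, rankings = rankings, relative = relative,
         stats = stats, params = params, mode = mode,
         solutes = solutes, solvents = solvents,
         reference_map = reference_map),
    class = "des_screen"
  )
}

#' @export
print.des_screen <- function(x, ...) {
  cat(sprintf("solubility screen: %d solute(s) x %d solvent(s), mode = %s\n",
              length(x$solutes), length(x$solvents), x$mode))
  if (!is.null(x$stats)) print(x$stats)
  invisible(x)
}

#' @export
summary.des_screen <- function(object, ...) {
  print(object)
  cat("\nbest solvent per solute:\n")
  for (api in names(object$rankings)) {
    top <- object$rankings[[api]][1, ]
    cat(sprintf("  %-12s %s (log10 rel. %+0.2f vs. %s)\n", api, top$solvent,
                top$log10_relative, object$solvents[[1]]$label))
  }
  invisible(object)
}

#' @export
coef.des_screen <- function(object, ...) {
  if (is.null(object$stats))
    stop("no experimental data attached: no fit coefficients")
  c(intercept = object$stats$intercept, slope = object$stats$slope)
}

#' @export
residuals.des_screen <- function(object, ...) {
  if (is.null(object$relative))
    stop("no experimental data attached: no residuals")
  fit <- stats::lm(experimental ~ predicted, data = object$relative)
  stats::residuals(fit)
}

#' @export
predict.des_screen <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$predictions)
  stopifnot(is.list(newdata),
            all(vapply(newdata, inherits, logical(1), "solvent_mixture")))
  RT <- .R_GAS * object$params$temperature
  pots <- lapply(newdata, function(s)
    solve_sigma_potential(mix_profiles(s), object$params))
  do.call(rbind, lapply(object$solutes, function(sol) {
    mu <- vapply(seq_along(newdata), function(j)
      solute_chemical_potential(sol, pots[[j]], newdata[[j]], object$params),
      numeric(1))
    data.frame(api = sol$name,
               solvent = vapply(newdata, `[[`, character(1), "label"),
               value = -mu / (RT * log(10)), stringsAsFactors = FALSE)
  }))
}

#' @export
plot.des_screen <- function(x, ...) {
  if (is.null(x$relative))
    stop("no experimental data attached: nothing to plot")
  graphics::plot(x$relative$predicted, x$relative$experimental,
                 xlab = "predicted log10 relative solubility",
                 ylab = "experimental log10 relative solubility",
                 pch = 19, ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' @export
simulate.des_screen <- function(object, nsim = 1, seed = NULL,
                                noise_sd = 0.5, ...) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  lapply(seq_len(nsim), function(i) {
    out <- object$predictions
    out$value <- out$value + noise_sd * stats::rnorm(nrow(out))
    out
  })
}

#' Run a complete screening study from a single configuration
#'
#' Thin orchestration over the module functions: generates (or accepts)
#' the study inputs, computes predictions and rankings, and, when an
#' experimental table is present, the comparison statistics.  The
#' report is deterministic given the configuration.
#'
#' @param config list with elements `seed` (required for synthetic
#'   studies), `n_solutes`, `n_solvents`, `noise_sd` (synthetic-study
#'   size and noise), `params` (an [interaction_params()], default
#'   defaults), `mode` (`"dilute"`/`"iterative"`); or `solutes`,
#'   `solvents` and optional `data`/`reference_map` for user-supplied
#'   inputs.
#' @return list with `config`, `screen` (the [des_screen()] object) and,
#'   for synthetic studies, `study` (the [synthetic_study()] output).
#' @export
run_study <- function(config) {
  stopifnot(is.list(config))
  params <- config$params
  if (is.null(params)) params <- interaction_params()
  mode <- if (is.null(config$mode)) "dilute" else config$mode
  if (!is.null(config$solutes)) {
    screen <- des_screen(config$solutes, config$solvents, params,
                         data = config$data,
                         reference_map = config$reference_map, mode = mode)
    return(list(config = config, screen = screen))
  }
  if (is.null(config$seed))
    stop("config error: synthetic studies need a seed")
  spec <- synthetic_spec(
    seed = config$seed,
    n_solutes = if (is.null(config$n_solutes)) 8L else config$n_solutes,
    n_solvents = if (is.null(config$n_solvents)) 6L else config$n_solvents,
    noise_sd = if (is.null(config$noise_sd)) 0.5 else config$noise_sd
  )
  study <- synthetic_study(spec, params)
  exp_tab <- data.frame(api = study$experimental$api,
                        solvent = study$experimental$solvent,
                        value = study$experimental$log10_x,
                        stringsAsFactors = FALSE)
  screen <- des_screen(study$solutes, study$solvents, params,
                       data = exp_tab, mode = mode)
  list(config = config, screen = screen, study = study)
}
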