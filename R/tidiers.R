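#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an EM set into a per-mode tibble
#'
#' With a model attached, returns the per-mode yield table of
#' [mode_yields()]; without one, the mode index and support size.
#'
#' @param x An `emset`.
#' @param model Optional source [stoich_model()].
#' @param ... Unused.
#' @return A tibble with one row per elementary mode.
#' @method tidy emset
#' @export
tidy.emset <- function(x, model = NULL, ...) {
  if (is.null(model)) {
    tibble::tibble(mode = seq_len(n_modes(x)),
                   n_support = vapply(x$supports, length, 0L))
  } else {
    mode_yields(x, model)
  }
}

#' One-row summary of an EM set
#'
#' The mode census (and thermodynamic feasibility summary, when a thermo
#' table is supplied) for a model's elementary modes.
#'
#' @param x An `emset`.
#' @param model Source [stoich_model()].
#' @param thermo Optional [thermo_table()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance emset
#' @export
glance.emset <- function(x, model, thermo = NULL, ...) {
  out <- classify_modes(x, model)
  if (!is.null(thermo)) {
    out <- dplyr::bind_cols(out, feasibility_census(x, thermo)[, -1])
  }
  out
}

#' @rdname run_ga
#' @param x A `ga_result`.
#' @param ... Unused.
#' @method tidy ga_result
#' @export
tidy.ga_result <- function(x, ...) x$history

#' @rdname run_ga
#' @method glance ga_result
#' @export
glance.ga_result <- function(x, ...) {
  dplyr::bind_cols(
    x$best$record,
    tibble::tibble(generations = nrow(x$history),
                   n_evaluations = x$n_evaluations,
                   fitness_fn = x$cfg$fitness,
                   weighting = x$cfg$weighting_scheme)
  )
}

#' @rdname run_moga
#' @param x A `pareto_front`.
#' @param ... Unused.
#' @method tidy pareto_front
#' @export
tidy.pareto_front <- function(x, ...) {
  dplyr::select(x$members, -"chromosome")
}

#' @rdname run_moga
#' @method glance pareto_front
#' @export
glance.pareto_front <- function(x, ...) {
  prod_best <- max(x$members$product_fraction * x$members$biomass_fraction)
  tibble::tibble(n_front = nrow(x$members),
                 front_fraction = x$front_fraction,
                 best_objective_product = prod_best,
                 hypervolume = x$hypervolume_history[length(x$hypervolume_history)])
}

#' @rdname fba_fluxes
#' @param x An `fba_result`.
#' @param ... Unused.
#' @method tidy fba_result
#' @export
tidy.fba_result <- function(x, ...) x$fluxes

#' @rdname fba_fluxes
#' @method glance fba_result
#' @export
glance.fba_result <- function(x, ...) {
  tibble::tibble(objective_rxn = x$objective_rxn,
                 objective_value = x$objective_value, status = x$status)
}
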