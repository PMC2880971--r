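#' Yield trade-off scatter of an EM set
#'
#' Plots each elementary mode's product yield against its biomass yield,
#' both as fractions of the model's theoretical yields — the classic
#' growth-versus-production trade-off picture.
#'
#' @param object An `emset`.
#' @param model Source [stoich_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot emset
#' @export
autoplot.emset <- function(object, model, ...) {
  ym <- mode_yields(object, model)
  theo_p <- max_yield(object, model, "product")$value
  theo_b <- max_yield(object, model, "biomass")$value
  df <- dplyr::mutate(
    ym,
    product_fraction = if (theo_p > 0) .data$product_yield_mass / theo_p else 0,
    biomass_fraction = if (theo_b > 0) .data$biomass_per_substrate / theo_b else 0
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$biomass_fraction,
                                   .data$product_fraction)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "Biomass yield (fraction of theoretical)",
                  y = "Product yield (fraction of theoretical)",
                  title = paste("Elementary mode yields:", object$model_name)) +
    ggplot2::theme_minimal()
}

#' Convergence plot of a GA run
#'
#' Best and mean population fitness per generation.
#'
#' @param object A `ga_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ga_result
#' @export
autoplot.ga_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("best_fitness", "mean_fitness"),
                            names_to = "series", values_to = "fitness")
  ggplot2::ggplot(df, ggplot2::aes(.data$generation, .data$fitness,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_discrete(labels = c(best_fitness = "best",
                                              mean_fitness = "population mean")) +
    ggplot2::labs(x = "Generation", y = "Fitness", colour = NULL,
                  title = paste("GA convergence:", object$model_name)) +
    ggplot2::theme_minimal()
}

#' Pareto front scatter
#'
#' Final population in objective space with the non-inferior (Pareto) set
#' highlighted.
#'
#' @param object A `pareto_front`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pareto_front
#' @export
autoplot.pareto_front <- function(object, ...) {
  ggplot2::ggplot(object$population,
                  ggplot2::aes(.data$biomass_fraction,
                               .data$product_fraction)) +
    ggplot2::geom_point(alpha = 0.3) +
    ggplot2::geom_point(data = object$members, colour = "red") +
    ggplot2::geom_line(data = object$members, colour = "red",
                       linetype = "dashed") +
    ggplot2::labs(x = "Biomass yield fraction", y = "Product yield fraction",
                  title = paste("Pareto front:", object$model_name)) +
    ggplot2::theme_minimal()
}

#' Flux bar chart
#'
#' Reaction-wise bar plot of a flux distribution; pass several named
#' distributions to compare, e.g. FBA against EM-weighted fluxes.
#'
#' @param ... Named tibbles with columns `reaction`, `flux` (e.g. from
#'   [reconstruct_flux()] or `tidy()` on an `fba_result`).
#' @return A ggplot object.
#' @export
plot_flux_comparison <- function(...) {
  sets <- list(...)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  df <- dplyr::bind_rows(lapply(names(sets), function(nm) {
    dplyr::mutate(sets[[nm]], method = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$reaction, .data$flux,
                                   fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Flux (per unit substrate)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
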