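# Diagnostic figures.

#' Plot the similarity planes of a fit result
#'
#' Raster of similarity over the (tau, C) grid per target, with the
#' optimum marked.
#'
#' @param object A `fit_result`.
#' @param targets Targets to facet over (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fit_result
#' @export
autoplot.fit_result <- function(object, targets = names(object$planes), ...) {
  long <- purrr::map_dfr(targets, function(nm) {
    p <- object$planes[[nm]]
    tibble::tibble(
      target = nm,
      tau = rep(object$grid$tau_values, times = ncol(p)),
      C = rep(object$grid$C_values, each = nrow(p)),
      similarity = as.vector(p)
    )
  })
  opt <- dplyr::filter(object$summary, .data$target %in% targets)
  ggplot2::ggplot(long, ggplot2::aes(.data$tau, .data$C)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$similarity)) +
    ggplot2::geom_point(
      data = opt,
      ggplot2::aes(.data$tau_opt, .data$C_opt),
      shape = 21, colour = "white", fill = NA, size = 3
    ) +
    ggplot2::facet_wrap(~target) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "global delay tau (s)", y = "global coupling C",
      title = sprintf(
        "%s model, subject %s, level %s",
        object$model_kind, object$subject_id, object$parcellation
      )
    )
}

#' Distributions of data variables across parcellations
#'
#' @param variables Table from [cohort_variable_table()].
#' @param columns Variables to show (default four representative ones).
#' @return A ggplot object with one panel per variable.
#' @export
plot_variable_distributions <- function(variables,
                                        columns = c(
                                          "aver[std(BOLD)]",
                                          "std[aver(eFC)]",
                                          "corr(eFC,eSC)",
                                          "aver[std(eSC)]"
                                        )) {
  long <- tidyr::pivot_longer(
    variables[c("subject", "parcellation", "scope", columns)],
    dplyr::all_of(columns),
    names_to = "variable", values_to = "value"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$parcellation, .data$value)
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "parcellation level", y = NULL)
}
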