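#' Plot a trajectory's cover dynamics
#'
#' Coral and macroalgal cover through time, one thin line per reef.
#'
#' @param object A `reef_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.reef_trajectory <- function(object, ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(c("M", "C", "F"), names_to = "cover",
                        values_to = "proportion") |>
    dplyr::mutate(cover = factor(.data$cover, c("C", "M", "F"),
                                 c("coral", "macroalgae", "free space")))
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$proportion,
                                     group = .data$reef_id)) +
    ggplot2::geom_line(alpha = 0.3, linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$cover)) +
    ggplot2::labs(x = "time", y = "proportion of cover") +
    ggplot2::theme_minimal()
}

#' Plot intervention effects relative to baseline
#'
#' Boxplots of per-reef change in final coral (or macroalgal) cover under
#' each intervention, faceted by grazing scenario; the zero line marks
#' reefs unchanged from baseline.
#'
#' @param object A `reef_grid`.
#' @param response `"delta_C"` (default) or `"delta_M"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.reef_grid <- function(object, response = c("delta_C", "delta_M"),
                               ...) {
  response <- match.arg(response)
  dat <- object$results |>
    dplyr::filter(.data$intervention != "baseline")
  ggplot2::ggplot(dat, ggplot2::aes(.data$intervention,
                                    .data[[response]])) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$scenario)) +
    ggplot2::labs(x = NULL,
                  y = sprintf("change in final %% %s cover vs baseline",
                              if (response == "delta_C") "coral"
                              else "macroalgal")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Map a per-reef quantity over the seascape
#'
#' Scatter of reef positions coloured by any column of the reef table or
#' a supplied per-reef vector.
#'
#' @param reefs A reef table.
#' @param value Column name (string) in `reefs`, or a numeric vector in
#'   reef order.
#' @param label Legend title.
#' @return A ggplot.
#' @export
plot_seascape <- function(reefs, value = "initial_coral", label = value) {
  v <- if (is.character(value) && length(value) == 1) reefs[[value]] else value
  ggplot2::ggplot(reefs, ggplot2::aes(.data$lon, .data$lat)) +
    ggplot2::geom_point(ggplot2::aes(colour = v), size = 2) +
    ggplot2::scale_colour_viridis_c(name = if (is.character(label)) label
                                    else "value") +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "longitude", y = "latitude") +
    ggplot2::theme_minimal()
}
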