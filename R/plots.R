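#' Plot a Marey profile
#'
#' Anchor scatter with the isotonic fit on top, and the windowed
#' recombination rate below the x-axis of a second panel when
#' `rates = TRUE`.
#'
#' @param object a `marey_profile`.
#' @param rates overlay the windowed rate track (default `TRUE`).
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.marey_profile <- function(object, rates = TRUE, ...) {
  p <- ggplot2::ggplot(object$points,
                       ggplot2::aes(x = .data$physical_Mb)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cM), alpha = 0.5, size = 0.8) +
    ggplot2::geom_step(ggplot2::aes(y = .data$cM_fit), colour = "firebrick") +
    ggplot2::labs(x = "physical position (Mb)", y = "genetic position (cM)",
                  title = object$chromosome)
  if (rates) {
    scale <- max(object$points$cM) /
      max(object$window_rates$rate_cM_per_Mb, 1e-9) / 4
    p <- p +
      ggplot2::geom_line(data = object$window_rates,
                         ggplot2::aes(x = .data$window_mid_Mb,
                                      y = .data$rate_cM_per_Mb * scale),
                         colour = "steelblue", linetype = 2) +
      ggplot2::scale_y_continuous(
        sec.axis = ggplot2::sec_axis(~ . / scale,
                                     name = "rate (cM/Mb)"))
  }
  p
}

#' Plot link-peak profiles
#'
#' Peak score signed by direction (right-pointing positive) with the noise
#' score shown as a negative-alpha ribbon, faceted by scaffold.
#'
#' @param object a `link_profile` tibble.
#' @param scaffolds optional subset of scaffolds to show.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.link_profile <- function(object, scaffolds = NULL, ...) {
  d <- as_tibble(object)
  if (!is.null(scaffolds)) d <- d |> filter(.data$source_scaffold %in% scaffolds)
  d <- d |> mutate(signed = ifelse(.data$direction == "left",
                                   -.data$peak_score, .data$peak_score))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$start / 1e3)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$signed), fill = "firebrick",
                      width = 4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$noise_score),
                       colour = "grey40", linetype = 3) +
    ggplot2::facet_wrap(~ source_scaffold, scales = "free_x") +
    ggplot2::labs(x = "window start (kb)",
                  y = "link-peak score (signed by direction)")
}

#' Plot assembly statistics
#'
#' Anchored vs. oriented Mb per chromosome.
#'
#' @param object a `pm_assembly`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pm_assembly <- function(object, ...) {
  d <- object$stats |>
    filter(.data$chromosome != "Total") |>
    tidyr::pivot_longer(c("anchored_Mb", "oriented_Mb"),
                        names_to = "class", values_to = "Mb")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$chromosome, y = .data$Mb,
                                  fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Mb", fill = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
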