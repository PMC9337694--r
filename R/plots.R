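# ggplot2 displays for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a measurement set
#'
#' Dose-vs-distance diagnostic: H*(10) against distance from the isocenter
#' with one-sigma error bars.
#'
#' @param object A [measurement_set()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot measurement_set
#' @export
autoplot.measurement_set <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$distance_cm,
                                       y = .data$h10_per_gray)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$h10_per_gray - .data$sd_per_gray,
                   ymax = .data$h10_per_gray + .data$sd_per_gray),
      width = 1.5) +
    ggplot2::geom_point() +
    ggplot2::geom_line(linetype = "dashed") +
    ggplot2::labs(x = "Distance from isocenter (cm)",
                  y = "H*(10) (mSv/Gy)",
                  title = "Neutron ambient dose equivalent at the patient table") +
    ggplot2::theme_minimal()
}

#' Plot an organ dose table
#'
#' Per-organ neutron equivalent dose per photon gray, colored by depth
#' class.
#'
#' @param object An `organ_dose_tbl`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot organ_dose_tbl
#' @export
autoplot.organ_dose_tbl <- function(object, ...) {
  df <- object[!is.na(object$per_gray), , drop = FALSE]
  df$organ_name <- stats::reorder(df$organ_name, df$per_gray)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$organ_name, y = .data$per_gray,
                                   fill = .data$depth_class)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Neutron equivalent dose (mSv/Gy)",
                  fill = "Depth class") +
    ggplot2::theme_minimal()
}

#' Plot effective-dose contributions
#'
#' @param object An `effective_dose` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot effective_dose
#' @export
autoplot.effective_dose <- function(object, ...) {
  df <- object$contributions
  df$compartment <- stats::reorder(df$compartment, df$contribution_mSv)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$compartment,
                                   y = .data$contribution_mSv)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Contribution to effective dose (mSv)",
                  title = sprintf("Effective dose %.2f mSv",
                                  object$effective_dose_mSv)) +
    ggplot2::theme_minimal()
}
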