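#' Plot a PBPK simulation
#'
#' Semilogarithmic plasma concentration-time profiles for both drugs, with
#' an optional cumulative-urine panel.
#'
#' @param object A `pbpk_simulation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pbpk_simulation <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(sim_profile(object, "pa"), drug = "PA"),
    dplyr::mutate(sim_profile(object, "napa"), drug = "NAPA")
  )
  df <- df[df$conc > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$conc, colour = .data$drug)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time (min)", y = "Plasma concentration (µg/mL)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an Ract fit
#'
#' Observed versus predicted values at the optimum, faceted by dataset.
#'
#' @param object An `ract_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ract_fit <- function(object, ...) {
  df <- object$predictions
  df$dataset <- paste(toupper(df$drug), df$kind)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$pred), colour = "steelblue") +
    ggplot2::facet_wrap(~dataset, scales = "free") +
    ggplot2::labs(x = "Time (min)", y = "Observed (points) / predicted (line)") +
    ggplot2::theme_minimal()
}

#' Plot a generated bolus study
#'
#' Spaghetti plot of per-animal plasma profiles from
#' [generate_bolus_study()].
#'
#' @param study A list as returned by [generate_bolus_study()].
#' @return A ggplot object.
#' @export
plot_study_profiles <- function(study) {
  df <- study$profiles
  df <- df[df$conc > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$conc,
                                   group = .data$animal)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~drug, scales = "free_y") +
    ggplot2::labs(x = "Time (min)", y = "Plasma concentration (µg/mL)") +
    ggplot2::theme_minimal()
}
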