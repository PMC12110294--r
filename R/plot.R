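#' Plot a multiscale entropy profile
#'
#' Entropy against scale factor, one line per simplex dimension `k`, with a
#' ribbon of plus/minus one standard error over subseries where available.
#'
#' @param object A [scale_profile][ms_scae].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.scale_profile <- function(object, ...) {
  df <- tidy(object)
  df$k_lab <- ifelse(is.na(df$k), attr(object, "method"), paste0("k = ", df$k))
  p <- ggplot2::ggplot(df[df$defined, ],
                       ggplot2::aes(x = .data$scale, y = .data$entropy,
                                    colour = .data$k_lab, group = .data$k_lab))
  if (any(!is.na(df$se))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$entropy - .data$se,
                   ymax = .data$entropy + .data$se, fill = .data$k_lab),
      alpha = 0.2, colour = NA)
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(tau), y = "entropy",
                  colour = NULL, fill = NULL,
                  title = attr(object, "method")) +
    ggplot2::theme_minimal()
}

#' Plot several profiles together
#'
#' Overlays the mean entropy curves of a named list of profiles (e.g. white
#' vs 1/f noise, or cohorts), one colour per profile.
#'
#' @param profiles Named list of [scale_profile][ms_scae] objects.
#' @param k Simplex dimension to show when profiles carry several (default:
#'   first present).
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles, k = NULL) {
  stopifnot(is.list(profiles), !is.null(names(profiles)))
  df <- dplyr::bind_rows(purrr::map(profiles, tidy), .id = "series")
  if (is.null(k)) k <- df$k[1]
  df <- df[df$k %in% k | (is.na(k) & is.na(df$k)), ]
  ggplot2::ggplot(df[df$defined, ],
                  ggplot2::aes(x = .data$scale, y = .data$entropy,
                               colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(tau), y = "entropy", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-scale p-values of a group comparison
#'
#' P-value against scale with the conventional 0.05 threshold drawn as a
#' dashed line; log10 y-axis.
#'
#' @param object A [group_comparison][compare_groups].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.group_comparison <- function(object, ...) {
  df <- tidy(object)
  df$k_lab <- ifelse(is.na(df$k), "SampEn", paste0("k = ", df$k))
  lb <- attr(object, "labels")
  ggplot2::ggplot(df[!is.na(df$p_value), ],
                  ggplot2::aes(x = .data$scale, y = .data$p_value,
                               colour = .data$k_lab)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.05, linetype = "dashed", colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(tau), y = "p-value", colour = NULL,
                  title = sprintf("%s vs %s", lb[1], lb[2])) +
    ggplot2::theme_minimal()
}
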