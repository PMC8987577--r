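#' Plot a dorsal-ventral sliding-window score profile
#'
#' Mean score per group along the 0-100 ventral-dorsal depth axis, with a
#' mean +/- SEM ribbon (SEM across animals within each window).
#'
#' @param profile A `window_profile` from [sliding_window()].
#' @param score `"ami"` or `"ais"`.
#' @return A ggplot object.
#' @export
plot_window_profile <- function(profile, score = c("ami", "ais")) {
  score <- match.arg(score)
  mean_col <- paste0(score, "_mean")
  sem_col <- paste0(score, "_sem")
  df <- profile[!is.na(profile$group) & !is.na(profile[[mean_col]]), ]
  df$mean <- df[[mean_col]]
  df$sem <- df[[sem_col]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window_center, y = .data$mean,
                                   color = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, color = NA, na.rm = TRUE) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "depth (% ventral to dorsal)",
                  y = paste(toupper(score), "(mean ± SEM)"),
                  color = "group", fill = "group") +
    ggplot2::theme_minimal()
}

#' Plot the windowed AMI-AIS correlation along depth
#'
#' Spearman's rho between windowed AMI and AIS (animals pooled over groups)
#' as a function of depth, with windows whose correlation is significant at
#' `p_threshold` shaded.
#'
#' @param profile A `window_profile` from [sliding_window()].
#' @param p_threshold Significance level for shading (default 0.001).
#' @return A ggplot object.
#' @export
plot_window_correlation <- function(profile, p_threshold = 0.001) {
  df <- profile |>
    dplyr::distinct(.data$window_center, .data$rho, .data$p_value) |>
    dplyr::filter(!is.na(.data$rho))
  sig <- df[!is.na(df$p_value) & df$p_value < p_threshold, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$window_center, y = .data$rho))
  if (nrow(sig) > 0) {
    step <- attr(profile, "step") %||% 1
    p <- p + ggplot2::geom_rect(
      data = sig,
      ggplot2::aes(xmin = .data$window_center - step / 2,
                   xmax = .data$window_center + step / 2),
      ymin = -1, ymax = 1, fill = "gold", alpha = 0.35, inherit.aes = FALSE)
  }
  p +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = "depth (% ventral to dorsal)",
                  y = "Spearman ρ (AMI vs AIS)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.window_profile <- function(object, score = c("ami", "ais", "rho"), ...) {
  score <- match.arg(score)
  if (score == "rho") plot_window_correlation(object, ...)
  else plot_window_profile(object, score)
}

#' Plot automated versus manual validation scores
#'
#' Scatter of automated against manual scores with the fitted regression
#' line, the identity line, and discrepancy outliers highlighted.
#'
#' @param x A `validation_regression`.
#' @param manual,auto The score vectors the fit was computed from.
#' @return A ggplot object.
#' @export
plot_validation <- function(x, manual, auto) {
  stopifnot(inherits(x, "validation_regression"))
  df <- tibble::tibble(manual = manual, auto = auto,
                       outlier = x$outlier)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$manual, y = .data$auto)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::geom_abline(slope = x$slope, intercept = x$intercept) +
    ggplot2::geom_point(ggplot2::aes(color = .data$outlier)) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "black", `TRUE` = "red")) +
    ggplot2::labs(x = "manual score", y = "automated score",
                  color = paste0("|diff| > ", x$discrepancy_threshold)) +
    ggplot2::theme_minimal()
}
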