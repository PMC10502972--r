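#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a B-scan (optionally with a mask overlay)
#'
#' @param object A [bscan()].
#' @param mask Optional [seg_mask()] or `prob_map` overlaid in colour.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bscan <- function(object, mask = NULL, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$pixels)),
                           col = seq_len(ncol(object$pixels)))
  df$intensity <- as.vector(object$pixels)[(df$col - 1) * nrow(object$pixels) + df$row]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "A-scan (lateral)", y = "depth (axial)",
                  fill = "intensity") +
    ggplot2::theme_minimal()
  if (!is.null(mask)) {
    mm <- if (inherits(mask, "prob_map")) mask$pixels >= 0.5 else
      as_mask_matrix(mask) == 1
    ov <- df[as.vector(mm)[(df$col - 1) * nrow(object$pixels) + df$row], ]
    p <- p + ggplot2::geom_raster(data = ov, fill = "gold", alpha = 0.35)
  }
  p
}

#' Plot the training loss curve
#' @param object A `train_result`.
#' @param ... Unused.
#' @return A ggplot of dice loss per epoch.
#' @export
autoplot.train_result <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(.data$epoch, .data$dice_loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = "mean dice loss") +
    ggplot2::theme_minimal()
}

#' Plot per-image evaluation metrics
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot of per-image DSC and ASSD.
#' @export
autoplot.eval_report <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object), c("dsc", "assd"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$id), .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "image", y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of manual vs automated thickness
#' @param object A `manual_auto_fit`.
#' @param ... Unused.
#' @return A ggplot with the OLS line and correlation annotation.
#' @export
autoplot.manual_auto_fit <- function(object, ...) {
  d <- object$fit$model
  ggplot2::ggplot(d, ggplot2::aes(.data$manual, .data$auto)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::annotate("text", x = min(d$manual), y = max(d$auto), hjust = 0,
                      label = sprintf("R = %.3f", object$r)) +
    ggplot2::labs(x = "manual SfChT (µm)", y = "automated SfChT (µm)") +
    ggplot2::theme_minimal()
}

#' Plot adjusted group mean SfChT changes over visits
#'
#' The longitudinal treatment-effect figure: covariate-adjusted mean change
#' from baseline (± SEM) per group at each post-baseline visit.
#'
#' @param changes A change table from [change_from_baseline()].
#' @return A ggplot.
#' @export
plot_cohort_changes <- function(changes) {
  visits <- intersect(sfcht_visits(), unique(as.character(changes$visit)))
  per_visit <- dplyr::bind_rows(lapply(visits, function(v) {
    adj <- adjusted_group_change(changes, visit = v)
    out <- tibble::as_tibble(adj)
    out$visit <- v
    out
  }))
  per_visit$visit <- factor(per_visit$visit, levels = visits)
  ggplot2::ggplot(per_visit,
                  ggplot2::aes(.data$visit, .data$adjusted_mean,
                               colour = .data$group, group = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$adjusted_mean - .data$sem,
      ymax = .data$adjusted_mean + .data$sem)) +
    ggplot2::labs(x = "visit", y = "adjusted change in SfChT (µm)",
                  colour = "group") +
    ggplot2::theme_minimal()
}
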