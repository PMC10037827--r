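#' Plot global property curves over the sparsity grid
#'
#' One panel per metric, one line per subject (or group-mean ribbons when a
#' grouping table is supplied).
#'
#' @param object A `hippnet_property_curves` tibble from
#'   [global_property_curves()].
#' @param groups Optional data frame `subject_id`, `group` to colour and
#'   average by group.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hippnet_property_curves
#' @export
autoplot.hippnet_property_curves <- function(object, groups = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(groups)) {
    df <- dplyr::inner_join(df, tibble::as_tibble(groups), by = "subject_id") |>
      dplyr::group_by(.data$group, .data$metric, .data$sparsity) |>
      dplyr::summarise(mid = mean(.data$value, na.rm = TRUE),
                       lo = quantile(.data$value, 0.25, na.rm = TRUE),
                       hi = quantile(.data$value, 0.75, na.rm = TRUE),
                       .groups = "drop")
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$sparsity, .data$mid,
                                          colour = .data$group,
                                          fill = .data$group)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           alpha = 0.2, colour = NA) +
      ggplot2::geom_line() +
      ggplot2::labs(y = "metric value")
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$sparsity, .data$value,
                                          group = .data$subject_id)) +
      ggplot2::geom_line(alpha = 0.4) +
      ggplot2::labs(y = "metric value")
  }
  p +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "sparsity") +
    ggplot2::theme_minimal()
}

#' Plot simple slopes of a moderation analysis
#'
#' Shows the fitted `y`-on-`x` slope at the moderator mean and mean +/- 1 SD.
#'
#' @param object A `hippnet_moderation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hippnet_moderation
#' @export
autoplot.hippnet_moderation <- function(object, ...) {
  ss <- object$simple_slopes
  v <- object$variables
  xr <- c(-1, 1)
  df <- purrr::map_dfr(seq_len(nrow(ss)), function(i) {
    tibble::tibble(at = ss$at[i], x = xr, y = ss$slope[i] * xr)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$at)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = paste(v["x"], "(centred)"),
                  y = paste("fitted change in", v["y"]),
                  colour = paste(v["m"], "at")) +
    ggplot2::theme_minimal()
}

#' Plot node-selection evidence for an identified network
#'
#' Bar chart of -log10 p-values per candidate node, marking the selection
#' threshold and the structural-constraint status.
#'
#' @param network A `hippnet_network` from [select_nodes()].
#' @return A ggplot object.
#' @export
plot_selection <- function(network) {
  stopifnot(inherits(network, "hippnet_network"))
  ev <- network$evidence
  if (nrow(ev) == 0) stop_schema("network has no selection evidence to plot")
  ggplot2::ggplot(ev, ggplot2::aes(stats::reorder(.data$region, -.data$p_value),
                                   -log10(.data$p_value),
                                   fill = .data$selected,
                                   alpha = .data$wm_connected)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(network$rule$alpha),
                        linetype = "dashed") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  title = paste("Seed", network$seed)) +
    ggplot2::theme_minimal()
}
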