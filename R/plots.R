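#' Plot a screening result
#'
#' Candidate p-values from the bivariable models on a -log10 scale with
#' the retention threshold marked.
#'
#' @param object A `screen_result`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot screen_result
#' @export
autoplot.screen_result <- function(object, ...) {
  alpha <- attr(object, "alpha")
  d <- dplyr::arrange(tibble::as_tibble(object), .data$p_value) |>
    dplyr::mutate(candidate = factor(.data$candidate,
                                     levels = rev(.data$candidate)))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$p_value),
                                  y = .data$candidate,
                                  colour = .data$retained)) +
    ggplot2::geom_point() +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = -log10(.data$p_value),
                                       yend = .data$candidate)) +
    ggplot2::geom_vline(xintercept = -log10(alpha), linetype = 2) +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL,
                  colour = "retained",
                  title = "Bivariable screening (baseline outcome forced in)") +
    ggplot2::theme_minimal()
}

#' Plot an optimism report
#'
#' Distribution of the per-replicate difference between the bootstrap
#' model's apparent performance (on its resample) and its test
#' performance (on the original cohort); the mean is the optimism.
#'
#' @param object An `optimism_report`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot optimism_report
#' @export
autoplot.optimism_report <- function(object, ...) {
  d <- dplyr::mutate(object$replicates,
                     delta = .data$apparent - .data$test)
  metric <- if (object$family == "linear") "adjusted R²" else "c-statistic"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$optimism, colour = "red") +
    ggplot2::labs(
      x = sprintf("apparent - test %s per replicate", metric),
      y = "replicates",
      title = sprintf("Bootstrap optimism: %.3f (corrected %s = %.3f)",
                      object$optimism, metric, object$corrected)) +
    ggplot2::theme_minimal()
}

#' Draw a nomogram
#'
#' The classic horizontal-lines chart: one axis per predictor (longer
#' line = stronger influence), the shared points axis on top, the
#' total-points axis and the predicted-response axis at the bottom. The
#' numeric [build_nomogram()] table is the contract; this chart is a
#' faithful rendering of it.
#'
#' @param object A `nomogram_table`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot nomogram_table
#' @export
autoplot.nomogram_table <- function(object, ...) {
  ax <- object$axes
  k <- nrow(ax)
  rows <- list()
  # points reference axis
  pts_ticks <- pretty(c(0, 100), n = 10)
  rows[[1]] <- tibble::tibble(
    label = "Points", y = k + 1,
    x = pts_ticks, tick = pts_ticks, xmin = 0, xmax = 100
  )
  for (i in seq_len(k)) {
    a <- ax[i, ]
    ticks <- pretty(c(a$range_min, a$range_max), n = 6)
    ticks <- ticks[ticks >= a$range_min & ticks <= a$range_max]
    pts <- a$estimate * (ticks - a$zero_value) / object$scale
    rows[[i + 1]] <- tibble::tibble(
      label = a$term, y = k + 1 - i,
      x = pts, tick = ticks, xmin = 0, xmax = a$points_max
    )
  }
  tot_ticks <- pretty(c(0, object$total_points_max), n = 10)
  tot_ticks <- tot_ticks[tot_ticks <= object$total_points_max]
  tot_scale <- 100 / max(object$total_points_max, 1)
  rows[[k + 2]] <- tibble::tibble(
    label = "Total points", y = 0,
    x = tot_ticks * tot_scale, tick = tot_ticks,
    xmin = 0, xmax = object$total_points_max * tot_scale
  )
  resp <- total_points_to_response(object, tot_ticks)$response
  rows[[k + 3]] <- tibble::tibble(
    label = sprintf("%s response", object$outcome), y = -1,
    x = tot_ticks * tot_scale, tick = signif(resp, 3),
    xmin = 0, xmax = object$total_points_max * tot_scale
  )
  d <- dplyr::bind_rows(rows)
  seg <- dplyr::distinct(d, .data$label, .data$y, .data$xmin, .data$xmax)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$xmin, xend = .data$xmax,
                                       y = .data$y, yend = .data$y)) +
    ggplot2::geom_point(data = d, ggplot2::aes(x = .data$x, y = .data$y),
                        shape = 3) +
    ggplot2::geom_text(data = d,
                       ggplot2::aes(x = .data$x, y = .data$y + 0.25,
                                    label = .data$tick), size = 2.6) +
    ggplot2::scale_y_continuous(
      breaks = seg$y, labels = seg$label, limits = c(-1.5, k + 1.6)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Nomogram: %s", object$outcome)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_blank())
}
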