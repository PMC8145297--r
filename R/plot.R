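#' Plot replicate-averaged ThT curves with the plate threshold
#'
#' One panel per sample, plotting the arithmetic mean of the replicate
#' wells at each dilution as a function of time, with the positivity
#' threshold drawn as a horizontal dashed line -- the conventional display
#' for RT-QuIC runs. Purely presentational: calling always uses the
#' individual wells, never these averages.
#'
#' @param plate A [plate_run()].
#' @param threshold Plate threshold in RFU (drawn as a horizontal line).
#' @return A ggplot object.
#' @export
plot_curves <- function(plate, threshold) {
  stopifnot(inherits(plate, "plate_run"))
  meta <- plate$well_meta[!plate$well_meta$excluded, ]
  long <- tibble::tibble(
    well_id = rep(meta$well_id, each = length(plate$times_h)),
    time_h = rep(plate$times_h, times = nrow(meta)),
    rfu = as.vector(t(plate$rfu[meta$well_id, , drop = FALSE]))
  )
  long <- dplyr::left_join(
    long, meta[, c("well_id", "sample_id", "dilution_exponent")],
    by = "well_id")
  avg <- dplyr::summarise(
    dplyr::group_by(long, .data$sample_id, .data$dilution_exponent,
                    .data$time_h),
    mean_rfu = mean(.data$rfu), .groups = "drop")
  avg$dilution <- factor(sprintf("1e%d", avg$dilution_exponent),
                         levels = sprintf("1e%d",
                                          sort(unique(avg$dilution_exponent),
                                               decreasing = TRUE)))
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$time_h, y = .data$mean_rfu,
                                    colour = .data$dilution)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::facet_wrap(~sample_id) +
    ggplot2::labs(x = "Time (h)", y = "ThT fluorescence (RFU)",
                  colour = "Dilution",
                  title = sprintf("Plate %s (threshold %.0f RFU)",
                                  plate$plate_id, threshold)) +
    ggplot2::theme_bw()
}

#' Replicate-mean traces underlying [plot_curves()]
#'
#' Exposed separately so the averaging can be checked independently of the
#' graphics layer.
#'
#' @param plate A [plate_run()].
#' @return Tibble with `sample_id`, `dilution_exponent`, `time_h`,
#'   `mean_rfu`.
#' @export
replicate_means <- function(plate) {
  meta <- plate$well_meta[!plate$well_meta$excluded, ]
  long <- tibble::tibble(
    well_id = rep(meta$well_id, each = length(plate$times_h)),
    time_h = rep(plate$times_h, times = nrow(meta)),
    rfu = as.vector(t(plate$rfu[meta$well_id, , drop = FALSE]))
  )
  long <- dplyr::left_join(
    long, meta[, c("well_id", "sample_id", "dilution_exponent")],
    by = "well_id")
  dplyr::summarise(
    dplyr::group_by(long, .data$sample_id, .data$dilution_exponent,
                    .data$time_h),
    mean_rfu = mean(.data$rfu), .groups = "drop")
}
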