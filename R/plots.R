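# ggplot2 display helpers for the main result types.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col autoplot
#'   labs scale_x_continuous scale_y_log10 scale_x_log10 geom_hline
#'   geom_pointrange facet_wrap
NULL

#' Plot a position profile
#'
#' @param object a `position_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.position_profile <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$offset, y = .data$value)) +
    geom_line() +
    labs(x = "position relative to site midpoint (bp)",
         y = sprintf("average %s per site", attr(object, "lesion_class")),
         title = sprintf("%s profile (%d sites, %s resolution)",
                         attr(object, "lesion_class"),
                         attr(object, "n_sites"),
                         attr(object, "resolution")))
}

#' Plot per-TF core damage enrichment against total core lesions
#'
#' @param object a `cpd_enrichment` from [core_flank_enrichment()].
#' @param ... unused.
#' @return a ggplot (log-log axes, unit enrichment marked).
#' @export
autoplot.cpd_enrichment <- function(object, ...) {
  df <- as_tibble(object)[as_tibble(object)$included, ]
  ggplot(df, aes(x = .data$total_core_lesions, y = .data$core_enrichment)) +
    geom_point() +
    geom_hline(yintercept = 1, linetype = 2) +
    scale_x_log10() + scale_y_log10() +
    labs(x = "total core lesions", y = "scaled CPD enrichment (cells/naked)")
}

#' Plot a geometry summary
#'
#' Mean +/- SEM of d and eta per motif offset.
#'
#' @param object a `geometry_summary` from [summarize_geometry()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.geometry_summary <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(cols = c("d_mean", "eta_mean"),
                        names_to = "metric", values_to = "mean") |>
    dplyr::mutate(sem = ifelse(.data$metric == "d_mean", .data$d_sem,
                               .data$eta_sem),
                  metric = ifelse(.data$metric == "d_mean",
                                  "d (Angstrom)", "eta (degrees)"))
  ggplot(df, aes(x = .data$offset_label, y = .data$mean)) +
    geom_pointrange(aes(ymin = .data$mean - .data$sem,
                        ymax = .data$mean + .data$sem)) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "motif offset (step)", y = "mean +/- SEM")
}
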