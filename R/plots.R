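#' Plot a spatial enrichment Z-profile
#'
#' Z-score along the chromosome with the call threshold marked; enriched and
#' depleted windows are coloured.
#'
#' @param object a `zprofile`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.zprofile <- function(object, ...) {
  thr <- attr(object, "threshold") %||% 2
  len <- attr(object, "chromosome_length")
  df <- as_tibble(object) |>
    mutate(mid = ((.data$start + .data$end) / 2) %% len)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid / 1e6, y = .data$z)) +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_point(
      data = ~ filter(.x, .data$call %in% c("enriched", "depleted")),
      ggplot2::aes(colour = .data$call), size = 1
    ) +
    ggplot2::scale_colour_manual(
      values = c(enriched = "firebrick", depleted = "steelblue")
    ) +
    ggplot2::labs(
      x = "chromosome position (Mb)", y = "Z-score",
      title = attr(object, "set_name"),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a temporal expression profile
#'
#' Unit-normalised average expression over the growth cycle; when a remapping
#' envelope is attached it is drawn as a +-1 SD ribbon.
#'
#' @param object a `temporal_profile`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.temporal_profile <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value))
  if ("envelope_sd" %in% names(df)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$value - .data$envelope_sd,
                   ymax = .data$value + .data$envelope_sd),
      fill = "grey80"
    )
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "time after inoculation (min)",
      y = "normalised expression",
      title = attr(object, "set_name"),
      subtitle = sprintf(
        "n = %d genes, pre-normalisation range [%.2f; %.2f]",
        attr(object, "n_genes_used"),
        attr(object, "pre_norm_min"), attr(object, "pre_norm_max")
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a promoter GC profile
#' @param object a `gc_profile`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.gc_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$position, y = .data$gc)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position relative to TSS (bp)", y = "mean GC fraction") +
    ggplot2::theme_minimal()
}

#' Plot a three-curve GC comparison
#' @param object a `gc_comparison`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.gc_comparison <- function(object, ...) {
  long <- as_tibble(object) |>
    select("position", "gc_all", "gc_a", "gc_b") |>
    tidyr::pivot_longer(-"position", names_to = "curve", values_to = "gc")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$gc,
                                     colour = .data$curve)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(gc_all = "black", gc_a = "firebrick", gc_b = "steelblue")
    ) +
    ggplot2::labs(x = "position relative to TSS (bp)", y = "mean GC fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of couplon sizes
#' @param ct a `couplon_table`.
#' @return A ggplot.
#' @export
plot_couplon_table <- function(ct) {
  ggplot2::ggplot(as_tibble(ct),
                  ggplot2::aes(x = .data$sigma, y = .data$nap_or_tf,
                               fill = .data$size)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$size), colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "sigma factor", y = "NAP / global TF", fill = "genes") +
    ggplot2::theme_minimal()
}
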