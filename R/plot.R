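#' Plot a tension trace
#'
#' Tension (N) per ligament against the rotation step, the package's
#' standard view of a PER run. Interosseous fibers are summed into a single
#' `IOL` curve.
#'
#' @param object a `tension_trace` from [run_per_protocol()].
#' @param ligaments which curves to draw; default: deltoid plus syndesmosis.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.tension_trace <- function(object,
                                   ligaments = c("TNL", "TSL", "TCL",
                                                 "dATTL", "dPTTL", "AITFL",
                                                 "PITFL", "IOL"),
                                   ...) {
  df <- tibble::as_tibble(object)
  iol <- grep("^IOL_", names(df), value = TRUE)
  if (length(iol) > 0 && "IOL" %in% ligaments) {
    df$IOL <- rowSums(df[, iol, drop = FALSE])
  }
  keep <- intersect(ligaments, names(df))
  long <- tidyr::pivot_longer(df[, c("step", keep)], -"step",
                              names_to = "ligament", values_to = "tension")
  long$ligament <- factor(long$ligament, levels = keep)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$tension,
                                     colour = .data$ligament)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "rotation step (degrees external rotation)",
                  y = "ligament tension (N)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname autoplot.tension_trace
#' @param trace a `tension_trace`.
#' @export
plot_tension_trace <- function(trace, ...) autoplot.tension_trace(trace, ...)
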