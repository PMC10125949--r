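#' Plot performance and descriptives across a window grid
#'
#' Metric curves against window width with mean +/- one standard deviation
#' bands across outer folds, alongside Utility and base rate, for one trimming
#' mode. Requires ggplot2.
#'
#' @param reports List of `evaluation_report` objects with descriptives (one
#'   per window, e.g., from [evaluate_window()] over a [window_grid()]).
#' @param metrics Metrics to display (subset of the report columns).
#' @return A ggplot object.
#' @export
plot_window_performance <- function(reports,
                                    metrics = c("auc", "phi", "sensitivity",
                                                "specificity")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_window_performance() requires the ggplot2 package",
         call. = FALSE)
  }
  rows <- do.call(rbind, lapply(reports, function(r) {
    d <- r$descriptives
    if (is.null(d)) stop("reports must carry window descriptives",
                         call. = FALSE)
    data.frame(mode = d$mode, w = d$w,
               metric = c(names(r$mean), "utility", "base_rate"),
               mean = c(unname(r$mean), d$utility, d$base_rate),
               sd = c(unname(r$sd), 0, 0),
               stringsAsFactors = FALSE)
  }))
  rows <- rows[rows$metric %in% c(metrics, "utility", "base_rate"), ]
  names(rows)[names(rows) == "mean"] <- "value"
  names(rows)[names(rows) == "sd"] <- "spread"
  ggplot2::ggplot(rows, ggplot2::aes(x = w, y = value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = value - spread,
                                      ymax = value + spread),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(metric ~ mode, scales = "free_x") +
    ggplot2::labs(x = "early-window width", y = NULL) +
    ggplot2::theme_minimal()
}
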