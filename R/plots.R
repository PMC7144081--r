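#' QC figures
#'
#' ggplot2 builders for each result type of a [run_qc()] report. All
#' builders return ggplot objects and never touch a graphics device, so
#' the numeric pipeline stays independent of plotting.
#'
#' * `plot_length_hist()` -- read-length histogram (log10 x).
#' * `plot_std_coverage()` -- standardized per-read coverage per
#'   read-length bin, drawn as whiskers with dashed reference lines at
#'   +/- the configured number of standard deviations.
#' * `plot_coverage_dist()` -- distribution of per-read mean depth.
#' * `plot_gc_hist()` -- per-read GC-content histogram.
#' * `plot_qv_error()` -- per-read mean QV against the overlap-based
#'   error estimate (empty when no Phred values exist).
#'
#' @param report A `qc_report` object.
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @name qc_plots
NULL

#' @rdname qc_plots
#' @export
plot_length_hist <- function(report, bins = 60) {
  lens <- report$all_read_stats$length
  ggplot2::ggplot(tibble::tibble(length = lens),
                  ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", color = "grey30") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "read length (bases)", y = "reads",
                  title = "Read length distribution") +
    ggplot2::theme_minimal()
}

#' @rdname qc_plots
#' @export
plot_std_coverage <- function(report) {
  b <- report$length_bins
  sd_lines <- report$params$sd_lines
  ggplot2::ggplot(b, ggplot2::aes(x = factor(.data$bin))) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.3, color = "grey40") +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$median_std,
                                        ymin = .data$q25, ymax = .data$q75),
                           fill = "steelblue", alpha = 0.6, width = 0.6) +
    ggplot2::geom_hline(yintercept = c(-sd_lines, sd_lines),
                        linetype = "dashed", color = "blue") +
    ggplot2::labs(x = "read-length bin (short to long)",
                  y = "standardized per-read coverage",
                  title = "Per-read coverage by read length") +
    ggplot2::theme_minimal()
}

#' @rdname qc_plots
#' @export
plot_coverage_dist <- function(report, bins = 60) {
  ggplot2::ggplot(report$per_read, ggplot2::aes(x = .data$mean_depth)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", color = "grey30") +
    ggplot2::labs(x = "per-read mean depth", y = "reads",
                  title = "Per-read coverage distribution") +
    ggplot2::theme_minimal()
}

#' @rdname qc_plots
#' @export
plot_gc_hist <- function(report, bins = 50) {
  ggplot2::ggplot(report$all_read_stats, ggplot2::aes(x = .data$gc)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", color = "grey30",
                            na.rm = TRUE) +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "per-read GC fraction", y = "reads",
                  title = "GC content distribution") +
    ggplot2::theme_minimal()
}

#' @rdname qc_plots
#' @export
plot_qv_error <- function(report) {
  d <- report$per_read
  d <- d[!is.na(d$mean_qv) & !is.na(d$est_error), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_qv, y = .data$est_error)) +
    ggplot2::geom_point(alpha = 0.4, color = "steelblue", na.rm = TRUE) +
    ggplot2::labs(x = "per-read mean QV (sequencer)",
                  y = "estimated per-read error rate",
                  title = "Sequencer QV vs estimated error") +
    ggplot2::theme_minimal()
}

#' @rdname qc_plots
#' @param object A `qc_report` object.
#' @param type One of `"length"`, `"std_coverage"`, `"coverage"`, `"gc"`,
#'   `"qv_error"`.
#' @param ... Ignored.
#' @method autoplot qc_report
#' @export
autoplot.qc_report <- function(object, type = c("length", "std_coverage",
                                                "coverage", "gc", "qv_error"),
                               ...) {
  type <- match.arg(type)
  switch(type,
    length = plot_length_hist(object),
    std_coverage = plot_std_coverage(object),
    coverage = plot_coverage_dist(object),
    gc = plot_gc_hist(object),
    qv_error = plot_qv_error(object)
  )
}

#' Render report figures to files
#'
#' Writes the standard figure set as PNG files plus a single HTML page
#' embedding them. Headless-safe; the QV/error scatter is skipped when no
#' Phred values are present.
#'
#' @param report A `qc_report` object.
#' @param dir Output directory (created if needed).
#' @param width,height,dpi Passed to [ggplot2::ggsave()].
#' @return Character vector of files written, invisibly.
#' @export
render_plots <- function(report, dir, width = 7, height = 5, dpi = 120) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(
    length_hist = plot_length_hist(report),
    std_coverage = plot_std_coverage(report),
    coverage_dist = plot_coverage_dist(report),
    gc_hist = plot_gc_hist(report)
  )
  if (report$summary$qv_available &&
      any(!is.na(report$per_read$est_error) & !is.na(report$per_read$mean_qv))) {
    specs$qv_error <- plot_qv_error(report)
  }
  files <- character(0)
  for (nm in names(specs)) {
    f <- file.path(dir, paste0(nm, ".png"))
    ggplot2::ggsave(f, specs[[nm]], width = width, height = height,
                    dpi = dpi)
    files <- c(files, f)
  }
  html <- file.path(dir, "report.html")
  body <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>overqc report</title></head><body>",
    "<h1>overqc quality-control report</h1>",
    sprintf("<p>%d reads, %s bases; estimated non-sense fraction %.3f</p>",
            report$input$n_reads,
            format(report$input$total_bases, big.mark = ","),
            report$summary$nonsense_fraction),
    sprintf("<h2>%s</h2><img src='%s' width='700'>",
            names(specs), basename(files)),
    "</body></html>"
  )
  writeLines(body, html)
  invisible(c(files, html))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
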