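#' Run the full quality-control pipeline
#'
#' End-to-end reference-free QC: ingest (or accept) a read set, compute
#' descriptive per-read statistics, build the minimizer index over the
#' whole dataset, sample reads, detect and filter read-to-read overlaps,
#' derive per-read coverage, classify non-sense reads and estimate the
#' dataset noise fraction, estimate per-read error rates, standardize
#' coverage, and infer adapter-like terminal boundaries. The result is a
#' self-contained report object that serializes losslessly to JSON.
#'
#' The run is deterministic for a fixed input and sampling seed.
#'
#' @param x A file path (FASTA/FASTQ/uBAM, see [read_seqs()]) or a read
#'   tibble.
#' @param format Input format hint, passed to [read_seqs()].
#' @param sketch A [sketch_params()] object.
#' @param filter An [overlap_filter_params()] object.
#' @param coverage A [coverage_params()] object.
#' @param calibration Error-estimator calibration constant.
#' @param complexity_window Window (bases) for sequence-complexity
#'   statistics.
#' @param noise_alert Warn when the estimated noise fraction exceeds this
#'   level (default 0.10, the upper end of what a healthy library
#'   typically shows).
#' @param verbose Emit per-stage progress messages.
#' @return An object of class `qc_report`. Key components: `summary`
#'   (noise fraction with CI, coverage moments, adapter boundaries),
#'   `per_read` (per sampled read: coverage, partners, non-sense flag,
#'   error estimate, plus length/GC/QV/complexity), `length_stats`,
#'   `gc_modes`, `length_bins` (whisker payload), `params`.
#' @export
run_qc <- function(x, format = "auto",
                   sketch = sketch_params(),
                   filter = overlap_filter_params(),
                   coverage = coverage_params(),
                   calibration = 1.0,
                   complexity_window = 64L,
                   noise_alert = 0.10,
                   verbose = FALSE) {
  say <- function(...) if (verbose) message("[overqc] ", ...)
  t0 <- Sys.time()
  if (is.character(x)) {
    input_path <- x
    say("reading ", x)
    reads <- read_seqs(x, format = format)
  } else {
    input_path <- NA_character_
    reads <- x
    stopifnot(all(c("read_id", "seq", "length") %in% names(reads)))
    if (!"quals" %in% names(reads)) reads$quals <- rep(list(NULL), nrow(reads))
  }
  if (nrow(reads) == 0L) stop("no reads in input", call. = FALSE)
  say(nrow(reads), " reads, ", sum(reads$length), " bases")

  stats_tbl <- read_stats(reads, window = complexity_window)
  lstats <- length_stats(reads$length)
  has_qv <- any(!is.na(stats_tbl$mean_qv))

  say("building minimizer index (k=", sketch$k, ", w=", sketch$w, ")")
  index <- build_overlap_index(reads, sketch)
  say(format(nrow(index$postings), big.mark = ","), " postings, ",
      index$n_masked, " hashes masked")

  sampled <- sample_reads(reads, coverage)
  say(nrow(sampled), " reads sampled (seed ", coverage$seed, ")")
  overlaps <- find_overlaps(sampled, index, filter)
  say(nrow(overlaps), " accepted overlaps")

  per_read <- coverage_table(sampled, overlaps, coverage, sketch, calibration)
  per_read <- standardize_coverage(per_read)
  per_read <- dplyr::left_join(
    per_read,
    stats_tbl[, c("read_id", "gc", "mean_qv", "mean_entropy",
                  "low_complexity_fraction")],
    by = "read_id"
  )
  noise <- estimate_nonsense_fraction(per_read)
  bins <- length_bin_summary(per_read, coverage)
  adapter <- withCallingHandlers(
    detect_adapter_boundary(per_read, sketch),
    warning = function(w) {
      say(conditionMessage(w)); invokeRestart("muffleWarning")
    }
  )
  if (noise$nonsense_fraction > noise_alert) {
    warning(sprintf(
      "estimated non-sense read fraction %.1f%% exceeds the alert level %.0f%%",
      100 * noise$nonsense_fraction, 100 * noise_alert), call. = FALSE)
  }
  say(sprintf("done in %.1f s", as.numeric(Sys.time() - t0, units = "secs")))

  structure(list(
    tool = "overqc",
    schema_version = "1.0",
    input = list(path = input_path,
                 format = if (is.character(x)) format else "tibble",
                 n_reads = nrow(reads),
                 total_bases = sum(reads$length)),
    params = list(
      k = sketch$k, w = sketch$w,
      min_shared = filter$min_shared, min_span = filter$min_span,
      max_gap = filter$max_gap, terminal_slack = filter$terminal_slack,
      sample_size = coverage$sample_size,
      min_read_len = coverage$min_read_len,
      nonsense_max_partners = coverage$nonsense_max_partners,
      sd_lines = coverage$sd_lines, seed = coverage$seed,
      n_length_bins = coverage$n_length_bins,
      calibration = calibration,
      complexity_window = as.integer(complexity_window),
      n_masked_hashes = index$n_masked
    ),
    summary = list(
      n_sampled = noise$n_sampled,
      n_flagged = noise$n_flagged,
      nonsense_fraction = noise$nonsense_fraction,
      nonsense_ci = c(noise$ci_lower, noise$ci_upper),
      coverage_mean = mean(per_read$mean_depth),
      coverage_sd = stats::sd(per_read$mean_depth),
      median_est_error = stats::median(per_read$est_error, na.rm = TRUE),
      qv_available = has_qv,
      mean_qv = if (has_qv) mean(stats_tbl$mean_qv, na.rm = TRUE) else NA_real_,
      adapter_left = adapter$adapter_left,
      adapter_right = adapter$adapter_right,
      adapter_determined = adapter$determined
    ),
    length_stats = lstats,
    gc_modes = find_gc_modes(stats_tbl$gc),
    length_bins = bins,
    per_read = per_read,
    all_read_stats = stats_tbl
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  s <- x$summary
  cat("<qc_report> ", x$input$n_reads, " reads, ",
      format(x$input$total_bases, big.mark = ","), " bases\n", sep = "")
  cat(sprintf("  non-sense fraction: %.3f (95%% CI %.3f-%.3f) from %d sampled reads\n",
              s$nonsense_fraction, s$nonsense_ci[1], s$nonsense_ci[2],
              s$n_sampled))
  cat(sprintf("  per-read coverage: mean %.2f, sd %.2f\n",
              s$coverage_mean, s$coverage_sd))
  cat(sprintf("  median estimated error rate: %s\n",
              ifelse(is.na(s$median_est_error), "n/a",
                     sprintf("%.3f", s$median_est_error))))
  cat(sprintf("  mean QV: %s\n",
              ifelse(s$qv_available, sprintf("%.2f", s$mean_qv),
                     "unavailable (no Phred scores)")))
  adl <- if (!s$adapter_determined) "undetermined" else
    sprintf("left %g / right %g bases", s$adapter_left, s$adapter_right)
  cat("  adapter boundary: ", adl, "\n", sep = "")
  ls <- x$length_stats
  cat(sprintf("  lengths: mean %.0f, median %.0f, N50 %.0f\n",
              ls$mean_len, ls$median_len, ls$n50))
  invisible(x)
}

#' Tidiers for QC reports
#'
#' `tidy()` returns the per-sampled-read table (coverage, partner count,
#' non-sense flag, error estimate, length/GC/QV/complexity); `glance()`
#' returns a one-row dataset summary.
#'
#' @param x A `qc_report` object.
#' @param ... Ignored.
#' @return A tibble.
#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) {
  x$per_read
}

#' @rdname tidy.qc_report
#' @method glance qc_report
#' @export
glance.qc_report <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_reads = x$input$n_reads,
    total_bases = x$input$total_bases,
    n_sampled = s$n_sampled,
    nonsense_fraction = s$nonsense_fraction,
    ci_lower = s$nonsense_ci[1],
    ci_upper = s$nonsense_ci[2],
    coverage_mean = s$coverage_mean,
    coverage_sd = s$coverage_sd,
    median_est_error = s$median_est_error,
    mean_qv = s$mean_qv,
    adapter_left = s$adapter_left,
    adapter_right = s$adapter_right,
    n50 = x$length_stats$n50
  )
}

#' Serialize a QC report to JSON
#'
#' Lossless, deterministic serialization (no timestamps, full numeric
#' precision); [read_qc_report()] restores an equivalent object.
#'
#' @param report A `qc_report` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  payload <- report
  payload$length_stats <- list(
    summary = as.list(report$length_stats[, setdiff(names(report$length_stats),
                                                    "histogram")]),
    histogram = report$length_stats$histogram[[1]]
  )
  class(payload) <- NULL
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_qc_report
#' @export
read_qc_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ls <- tibble::as_tibble(x$length_stats$summary)
  ls$histogram <- list(tibble::as_tibble(x$length_stats$histogram))
  x$length_stats <- ls
  x$per_read <- tibble::as_tibble(x$per_read)
  x$all_read_stats <- tibble::as_tibble(x$all_read_stats)
  x$length_bins <- tibble::as_tibble(x$length_bins)
  x$gc_modes <- tibble::as_tibble(x$gc_modes)
  structure(x, class = "qc_report")
}
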