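#' Coverage-analysis parameters
#'
#' @param sample_size Number of reads sampled for overlap analysis
#'   (default 5000; all eligible reads are used when fewer exist). A
#'   warning is issued below 100, where the noise-fraction estimate is
#'   unreliable.
#' @param min_read_len Minimum length (bases) for a read to be eligible
#'   for sampling (default 1000).
#' @param nonsense_max_partners A sampled read with this many or fewer
#'   distinct overlapping partners is classified as a non-sense read
#'   (default 2).
#' @param sd_lines Reference level (in standard deviations) drawn on the
#'   standardized-coverage plot (default 3).
#' @param seed RNG seed for read sampling (default 7).
#' @param n_length_bins Number of equal-count read-length bins for the
#'   standardized-coverage summary (default 10).
#' @return An object of class `coverage_params`.
#' @export
coverage_params <- function(sample_size = 5000L, min_read_len = 1000L,
                            nonsense_max_partners = 2L, sd_lines = 3,
                            seed = 7L, n_length_bins = 10L) {
  p <- list(sample_size = as.integer(sample_size),
            min_read_len = as.integer(min_read_len),
            nonsense_max_partners = as.integer(nonsense_max_partners),
            sd_lines = sd_lines,
            seed = as.integer(seed),
            n_length_bins = as.integer(n_length_bins))
  stopifnot(p$nonsense_max_partners >= 0L, p$sample_size >= 1L,
            p$min_read_len >= 0L, p$n_length_bins >= 2L)
  if (p$sample_size < 100L) {
    warning("sample_size < 100: the noise-fraction estimate will be noisy",
            call. = FALSE)
  }
  structure(p, class = "coverage_params")
}

#' Sample reads for coverage analysis
#'
#' Uniform random sample without replacement of `sample_size` reads with
#' length at least `min_read_len`, taken by single-pass reservoir sampling
#' with the configured seed. Deterministic for a fixed seed and input
#' order; returns all eligible reads when fewer than `sample_size` exist.
#'
#' @param reads Read tibble.
#' @param params A [coverage_params()] object.
#' @return The sampled rows of `reads`, in input order.
#' @export
sample_reads <- function(reads, params = coverage_params()) {
  eligible <- which(reads$length >= params$min_read_len)
  if (length(eligible) == 0L) {
    stop("no reads of length >= ", params$min_read_len,
         " (min_read_len) to sample from", call. = FALSE)
  }
  if (length(eligible) <= params$sample_size) {
    return(reads[eligible, , drop = FALSE])
  }
  keep <- reservoir_sample(length(eligible), params$sample_size, params$seed)
  reads[eligible[sort(keep)], , drop = FALSE]
}

# classic reservoir sampling: indices of a size-`size` uniform sample of 1..n
reservoir_sample <- function(n, size, seed) {
  withr::with_seed(seed, {
    res <- seq_len(size)
    if (n > size) {
      for (i in (size + 1L):n) {
        j <- sample.int(i, 1L)
        if (j <= size) res[j] <- i
      }
    }
    res
  })
}

#' Per-read coverage from accepted overlaps
#'
#' Stacks the query intervals of the accepted overlaps of one sampled read
#' into a depth profile and summarizes it: distinct partner count, covered
#' fraction (union length over read length), mean depth, uncovered prefix
#' and suffix, the non-sense flag (`n_partners <= nonsense_max_partners`)
#' and, when at least one partner exists, the k-mer-survival error-rate
#' estimate of [estimate_error_rate()].
#'
#' @param query One-row read tibble (the sampled read).
#' @param overlaps Accepted overlaps of that read (post-filter); every row
#'   must carry its `read_id` as `query_id`.
#' @param params A [coverage_params()] object.
#' @param sketch Sketch parameters used for the error estimate.
#' @param calibration Calibration constant for [estimate_error_rate()].
#' @return A one-row tibble (see [coverage_table()] for the columns).
#' @export
per_read_coverage <- function(query, overlaps, params = coverage_params(),
                              sketch = sketch_params(), calibration = 1.0) {
  stopifnot(nrow(query) == 1L)
  if (nrow(overlaps) > 0L && any(overlaps$query_id != query$read_id)) {
    bad <- overlaps$query_id[overlaps$query_id != query$read_id][1]
    stop("overlap with foreign query_id '", bad, "' passed for read '",
         query$read_id, "'", call. = FALSE)
  }
  coverage_table(query, overlaps, params, sketch, calibration)
}

#' Per-read coverage table for a read sample
#'
#' Vectorized driver behind [per_read_coverage()]: one row per sampled
#' read.
#'
#' @inheritParams per_read_coverage
#' @param samples Read tibble of sampled reads.
#' @param overlaps Accepted overlaps of those reads.
#' @return A tibble with columns `read_id`, `length`, `n_partners`,
#'   `covered_fraction`, `mean_depth`, `std_coverage` (`NA` until
#'   [standardize_coverage()]), `is_nonsense`, `left_uncovered`,
#'   `right_uncovered`, `est_error`, `n_minimizers`.
#' @export
coverage_table <- function(samples, overlaps, params = coverage_params(),
                           sketch = sketch_params(), calibration = 1.0) {
  n <- nrow(samples)
  idx_split <- split(seq_len(nrow(overlaps)),
                     factor(overlaps$query_id, levels = samples$read_id))
  n_partners <- integer(n)
  covered_fraction <- numeric(n)
  mean_depth <- numeric(n)
  left_unc <- integer(n)
  right_unc <- integer(n)
  est_error <- rep(NA_real_, n)
  n_mz <- integer(n)
  for (i in seq_len(n)) {
    len <- samples$length[i]
    s <- cpp_sketch(samples$seq[i], sketch$k, sketch$w)
    n_mz[i] <- length(s$pos)
    ix <- idx_split[[samples$read_id[i]]]
    if (length(ix) == 0L) {
      left_unc[i] <- len
      next
    }
    qs <- overlaps$q_start[ix]
    qe <- overlaps$q_end[ix]
    # interval union by sweeping sorted starts against the running max end
    o <- order(qs)
    qs_s <- qs[o]; qe_s <- qe[o]
    run_end <- cummax(c(0L, utils::head(qe_s, -1L)))
    covered <- sum(pmax(0L, qe_s - pmax(qs_s, run_end)))
    n_partners[i] <- length(unique(overlaps$target_id[ix]))
    covered_fraction[i] <- covered / len
    mean_depth[i] <- sum(qe - qs) / len
    left_unc[i] <- min(qs)
    right_unc[i] <- len - max(qe)
    est_error[i] <- survival_error(s$pos, qs, qe, overlaps$n_shared[ix],
                                   sketch$k, calibration)
  }
  tibble::tibble(
    read_id = samples$read_id,
    length = samples$length,
    n_partners = n_partners,
    covered_fraction = covered_fraction,
    mean_depth = mean_depth,
    std_coverage = NA_real_,
    is_nonsense = n_partners <= params$nonsense_max_partners,
    left_uncovered = left_unc,
    right_uncovered = right_unc,
    est_error = est_error,
    n_minimizers = n_mz
  )
}

# shared core of the k-mer-survival estimator (positions are 0-based)
survival_error <- function(mz_pos, q_start, q_end, n_shared, k, calibration) {
  per_ov <- vapply(seq_along(q_start), function(j) {
    n_q <- sum(mz_pos >= q_start[j] & mz_pos + k <= q_end[j])
    if (n_q == 0L) return(NA_real_)
    f <- min(1, n_shared[j] / n_q)
    1 - f^(1 / (2 * k))
  }, numeric(1))
  per_ov <- per_ov[!is.na(per_ov)]
  if (length(per_ov) == 0L) return(NA_real_)
  min(1, calibration * stats::median(per_ov))
}

#' Estimate the non-sense read fraction of a dataset
#'
#' The fraction of sampled reads flagged as non-sense, with a 95% Wilson
#' score confidence interval.
#'
#' @param records Per-read coverage tibble from [coverage_table()].
#' @return A one-row tibble: `n_sampled`, `n_flagged`, `nonsense_fraction`,
#'   `ci_lower`, `ci_upper`.
#' @export
estimate_nonsense_fraction <- function(records) {
  if (nrow(records) == 0L) stop("empty per-read coverage table", call. = FALSE)
  n <- nrow(records)
  x <- sum(records$is_nonsense)
  ci <- stats::prop.test(x, n, correct = FALSE)$conf.int
  tibble::tibble(
    n_sampled = n, n_flagged = x,
    nonsense_fraction = x / n,
    ci_lower = ci[1], ci_upper = ci[2]
  )
}

#' Standardize per-read coverage
#'
#' Centers each read's mean depth by the sample mean and divides by the
#' sample standard deviation (n-1) of all sampled reads, filling the
#' `std_coverage` column. A degenerate sample (zero standard deviation)
#' yields all-zero standardized values with a warning.
#'
#' @param records Per-read coverage tibble.
#' @return `records` with `std_coverage` filled; the mean/sd used are
#'   attached as attributes `center` and `scale`.
#' @export
standardize_coverage <- function(records) {
  if (nrow(records) < 2L) stop("need >= 2 reads to standardize", call. = FALSE)
  m <- mean(records$mean_depth)
  s <- stats::sd(records$mean_depth)
  if (s == 0) {
    warning("per-read coverage has zero variance; standardized values set to 0",
            call. = FALSE)
    records$std_coverage <- 0
  } else {
    records$std_coverage <- (records$mean_depth - m) / s
  }
  attr(records, "center") <- m
  attr(records, "scale") <- s
  records
}

#' Length-binned standardized coverage
#'
#' Splits sampled reads into equal-count read-length quantile bins and
#' summarizes the standardized coverage of each bin (whisker-plot payload).
#' The reference level at `sd_lines` standard deviations is attached as
#' attribute `sd_lines`.
#'
#' @param records Standardized per-read coverage tibble.
#' @param params A [coverage_params()] object (`n_length_bins`, `sd_lines`).
#' @return A tibble with one row per bin: `bin`, `n`, `min_len`, `max_len`,
#'   `median_std`, `q25`, `q75`, `lo`, `hi` (whisker ends at 1.5 IQR).
#' @export
length_bin_summary <- function(records, params = coverage_params()) {
  records$bin <- dplyr::ntile(records$length, params$n_length_bins)
  out <- records |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      min_len = min(.data$length),
      max_len = max(.data$length),
      median_std = stats::median(.data$std_coverage),
      q25 = stats::quantile(.data$std_coverage, 0.25, names = FALSE),
      q75 = stats::quantile(.data$std_coverage, 0.75, names = FALSE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      lo = .data$q25 - 1.5 * (.data$q75 - .data$q25),
      hi = .data$q75 + 1.5 * (.data$q75 - .data$q25)
    )
  attr(out, "sd_lines") <- params$sd_lines
  out
}

#' Estimate a read's error rate from k-mer survival in its overlaps
#'
#' For each accepted overlap the fraction `f` of the query's minimizers in
#' the overlap window that survived as chained shared minimizers estimates
#' the probability that a k-mer is error-free in both reads. Attributing
#' errors symmetrically to the two reads gives a per-overlap per-base error
#' `1 - f^(1/(2k))`; the read's estimate is the median over its overlaps,
#' multiplied by a fixed calibration constant that absorbs
#' minimizer-sampling bias (minimizer selection is perturbed by errors in
#' the partner read, so raw survival underestimates `f` slightly). The
#' default calibration was frozen once by parameter recovery on simulated
#' reads of known error rate.
#'
#' @param query One-row read tibble.
#' @param overlaps Accepted overlaps of that read.
#' @param sketch A [sketch_params()] object (must match the index).
#' @param calibration Multiplicative calibration constant (default 1.0).
#' @param mz Optional precomputed minimizer tibble of the query.
#' @return Estimated per-base error rate in `[0, 1]`, or `NA` when no
#'   overlap window contains a query minimizer.
#' @export
estimate_error_rate <- function(query, overlaps, sketch = sketch_params(),
                                calibration = 1.0, mz = NULL) {
  if (nrow(overlaps) == 0L) return(NA_real_)
  if (is.null(mz)) mz <- compute_minimizers(query$seq, sketch)
  survival_error(mz$pos, overlaps$q_start, overlaps$q_end,
                 overlaps$n_shared, sketch$k, calibration)
}

# estimator detection ceiling for a read with m minimizers: the error rate
# implied by a survival fraction at the smallest resolvable value 1/(m+1)
error_detection_ceiling <- function(n_minimizers, sketch = sketch_params()) {
  1 - (1 / (n_minimizers + 1))^(1 / (2 * sketch$k))
}

#' Infer adapter-like terminal boundaries
#'
#' Un-trimmed terminal adapters are foreign sequence, so read-to-read
#' overlaps start only after them: the uncovered prefix (suffix) lengths of
#' well-supported reads pile up at the adapter length. The boundary on each
#' side is the median uncovered length over reads with at least 3 partners,
#' corrected for the sketching lag (see below) and reported as 0 when the
#' raw median does not exceed the noise floor `w + k + 5` bases.
#'
#' The first shared minimizer of an overlap sits, on average, one thinned
#' minimizer spacing past the true boundary: selected minimizers are
#' `(w+1)/2` bases apart and only a fraction `(1-e)^k` of k-mers are
#' error-free at a per-base error rate `e`. The correction subtracts the
#' median of that lag, `log(2) * (w+1) / (2 * (1-e)^k)`, using the median
#' estimated error rate of the contributing reads for `e`.
#'
#' @param records Per-read coverage tibble.
#' @param sketch A [sketch_params()] object.
#' @param min_contributing Minimum number of contributing reads before the
#'   boundary is reported (default 50); below it the result is
#'   undetermined (`NA`) with a warning.
#' @return A one-row tibble: `adapter_left`, `adapter_right` (bases, 0 =
#'   no adapter signal, `NA` = undetermined), `n_contributing`,
#'   `determined`.
#' @export
detect_adapter_boundary <- function(records, sketch = sketch_params(),
                                    min_contributing = 50L) {
  contrib <- records[records$n_partners >= 3L, , drop = FALSE]
  if (nrow(contrib) < min_contributing) {
    warning("only ", nrow(contrib), " reads with >= 3 partners; ",
            "adapter boundary undetermined", call. = FALSE)
    return(tibble::tibble(adapter_left = NA_real_, adapter_right = NA_real_,
                          n_contributing = nrow(contrib), determined = FALSE))
  }
  floor_b <- sketch$w + sketch$k + 5
  e_hat <- stats::median(contrib$est_error, na.rm = TRUE)
  if (is.na(e_hat)) e_hat <- 0
  lag <- log(2) * (sketch$w + 1) / (2 * (1 - e_hat)^sketch$k)
  left_med <- stats::median(contrib$left_uncovered)
  right_med <- stats::median(contrib$right_uncovered)
  tibble::tibble(
    adapter_left = if (left_med > floor_b) max(0, left_med - lag) else 0,
    adapter_right = if (right_med > floor_b) max(0, right_med - lag) else 0,
    n_contributing = nrow(contrib),
    determined = TRUE
  )
}

#' QV versus estimated-error association
#'
#' Spearman rank correlation between per-read mean QV (sequencer-assigned
#' quality) and the overlap-based error estimate. Reads whose error rate
#' could not be estimated (no accepted overlaps, typical of random
#' artifact reads) are right-censored at the estimator's detection
#' ceiling, mirroring the observation that such reads behave as
#' maximally erroneous.
#'
#' @param records Per-read coverage tibble carrying a `mean_qv` column.
#' @param sketch A [sketch_params()] object (for the detection ceiling).
#' @return A one-row tibble: `n`, `rho`.
#' @export
qv_error_association <- function(records, sketch = sketch_params()) {
  stopifnot("mean_qv" %in% names(records))
  err <- ifelse(is.na(records$est_error),
                error_detection_ceiling(records$n_minimizers, sketch),
                records$est_error)
  ok <- !is.na(records$mean_qv)
  tibble::tibble(
    n = sum(ok),
    rho = stats::cor(records$mean_qv[ok], err[ok], method = "spearman")
  )
}
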