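#' Read-length statistics
#'
#' Summary of a read-length distribution: count, yield, mean, median
#' (lower of the two middle values for an even count), N50 (the length
#' `L` such that reads of length `>= L` contain at least half of all
#' bases) and a histogram.
#'
#' @param lengths Integer vector of read lengths (positive).
#' @return A one-row tibble: `n_reads`, `total_bases`, `mean_len`,
#'   `median_len`, `n50`, plus a `histogram` list column holding a tibble
#'   of `lower`, `upper`, `count` bin rows.
#' @examples
#' length_stats(c(2, 2, 2, 3, 3, 4))
#' @export
length_stats <- function(lengths) {
  if (length(lengths) == 0L) stop("no read lengths given", call. = FALSE)
  if (any(lengths <= 0)) stop("read lengths must be positive", call. = FALSE)
  lengths <- as.numeric(lengths)
  srt <- sort(lengths, decreasing = TRUE)
  total <- sum(srt)
  n50 <- srt[which(cumsum(srt) >= total / 2)[1]]
  n <- length(lengths)
  asc <- sort(lengths)
  med <- if (n %% 2 == 1L) asc[(n + 1L) %/% 2L] else asc[n %/% 2L]
  h <- graphics::hist(lengths, breaks = "Sturges", plot = FALSE)
  tibble::tibble(
    n_reads = n,
    total_bases = total,
    mean_len = mean(lengths),
    median_len = med,
    n50 = n50,
    histogram = list(tibble::tibble(
      lower = utils::head(h$breaks, -1),
      upper = utils::tail(h$breaks, -1),
      count = h$counts
    ))
  )
}

#' GC content of sequences
#'
#' `(G + C) / (A + C + G + T)` per sequence; `N`s are excluded from the
#' denominator, and an all-`N` sequence yields `NA`. Invariant under
#' reverse complement.
#'
#' @param seq Character vector of uppercase `A,C,G,T,N` sequences.
#' @return Numeric vector of GC fractions in `[0, 1]`.
#' @examples
#' gc_content(c("ATGC", "GGCC"))
#' @export
gc_content <- function(seq) {
  lf <- Biostrings::letterFrequency(Biostrings::BStringSet(seq),
                                    letters = c("A", "C", "G", "T"))
  denom <- rowSums(lf)
  out <- (lf[, "G"] + lf[, "C"]) / denom
  out[denom == 0] <- NA_real_
  unname(out)
}

#' Per-read mean quality value
#'
#' The arithmetic mean of a read's Phred scores, matching the convention
#' of reporting "per-read QV" as the average sequencer-assigned quality.
#' (The alternative -- Phred-transforming the mean error probability --
#' down-weights occasional low-quality bases and is not used here.)
#'
#' @param quals Integer vector of Phred values, or a list of such vectors
#'   (one per read; `NULL` elements give `NA`).
#' @return Mean QV (numeric scalar or vector).
#' @export
per_read_qv <- function(quals) {
  if (is.list(quals)) {
    return(vapply(quals, function(q) {
      if (is.null(q) || length(q) == 0L) NA_real_ else mean(q)
    }, numeric(1)))
  }
  if (length(quals) == 0L) stop("empty quality vector", call. = FALSE)
  mean(quals)
}

#' Windowed sequence complexity
#'
#' Shannon entropy (bits, over A/C/G/T frequencies, `N`s ignored) of tiled
#' windows along one read. A window is called low-complexity when its
#' entropy falls below `low_threshold` bits; a read shorter than one
#' window is scored as a single window.
#'
#' @param seq A single uppercase sequence.
#' @param window Window size in bases (>= 16, default 64).
#' @param step Step between window starts (default: `window`, i.e.
#'   non-overlapping tiles).
#' @param low_threshold Entropy below which a window is low-complexity
#'   (default 1 bit, the entropy of a two-letter repeat).
#' @return A one-row tibble: `mean_entropy` (bits in `[0, 2]`),
#'   `low_complexity_fraction`, `n_windows`.
#' @examples
#' sequence_complexity(strrep("AT", 100))
#' @export
sequence_complexity <- function(seq, window = 64L, step = window,
                                low_threshold = 1.0) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (window < 16L) stop("window must be >= 16 bases", call. = FALSE)
  ent <- cpp_window_entropy(seq, as.integer(window), as.integer(step))
  tibble::tibble(
    mean_entropy = mean(ent),
    low_complexity_fraction = mean(ent < low_threshold),
    n_windows = length(ent)
  )
}

#' Descriptive per-read statistics table
#'
#' Length, GC content, mean QV (when Phred values are present) and
#' windowed-entropy complexity for every read.
#'
#' @param reads Read tibble.
#' @param window Complexity window size in bases.
#' @return A tibble with one row per read: `read_id`, `length`, `gc`,
#'   `mean_qv`, `mean_entropy`, `low_complexity_fraction`.
#' @export
read_stats <- function(reads, window = 64L) {
  cx <- dplyr::bind_rows(lapply(reads$seq, sequence_complexity,
                                window = window))
  tibble::tibble(
    read_id = reads$read_id,
    length = reads$length,
    gc = gc_content(reads$seq),
    mean_qv = per_read_qv(reads$quals),
    mean_entropy = cx$mean_entropy,
    low_complexity_fraction = cx$low_complexity_fraction
  )
}

#' Locate modes of a GC-content distribution
#'
#' Histogram-based mode finder used to flag contamination: per-read GC is
#' binned, counts are lightly smoothed with a running mean, and local
#' maxima supported by at least `min_prop` of the reads are reported. A
#' clean single-source library shows one mode; a GC-divergent contaminant
#' adds a secondary mode.
#'
#' @param gc Numeric vector of per-read GC fractions (`NA` dropped).
#' @param binwidth Histogram bin width (default 0.02).
#' @param min_prop Minimum fraction of reads a mode must hold
#'   (default 0.01).
#' @return A tibble of modes: `gc` (bin center), `count`.
#' @export
find_gc_modes <- function(gc, binwidth = 0.02, min_prop = 0.01) {
  gc <- gc[!is.na(gc)]
  if (length(gc) == 0L) return(tibble::tibble(gc = numeric(0), count = integer(0)))
  breaks <- seq(0, 1, by = binwidth)
  cnt <- graphics::hist(pmin(gc, 1 - 1e-9), breaks = breaks, plot = FALSE)$counts
  # 3-bin running mean, edges padded with zero
  sm <- (c(0, utils::head(cnt, -1)) + cnt + c(utils::tail(cnt, -1), 0)) / 3
  nb <- length(sm)
  left <- c(-Inf, utils::head(sm, -1))
  right <- c(utils::tail(sm, -1), -Inf)
  is_mode <- sm > left & sm >= right & cnt >= min_prop * length(gc)
  mids <- breaks[-1] - binwidth / 2
  tibble::tibble(gc = mids[is_mode], count = cnt[is_mode])
}
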