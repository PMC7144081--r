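#' Minimizer sketch parameters
#'
#' Controls the (w,k)-minimizer scheme used for read-to-read overlap
#' detection: every window of `w` consecutive k-mers contributes the k-mer
#' with the smallest canonical hash. Canonical hashing makes the sketch
#' strand-invariant; an odd `k` guarantees no k-mer equals its own reverse
#' complement.
#'
#' @param k K-mer length (bases, >= 5). Default 15.
#' @param w Window length in k-mers (>= 1). Default 10.
#' @param max_occ Optional hard cap on the number of reads a minimizer hash
#'   may occur in before it is masked from the index. The default (`NULL`)
#'   uses an automatic rule: mask hashes above the 99.9th percentile of the
#'   per-hash read-occurrence distribution, and never below 100 reads.
#'   Masking suppresses repeat-induced spurious overlaps.
#' @return An object of class `sketch_params`.
#' @export
sketch_params <- function(k = 15L, w = 10L, max_occ = NULL) {
  k <- as.integer(k); w <- as.integer(w)
  stopifnot(length(k) == 1L, length(w) == 1L, !is.na(k), !is.na(w))
  if (k < 5L || k > 31L) stop("k must be in [5, 31]", call. = FALSE)
  if (w < 1L) stop("w must be >= 1", call. = FALSE)
  if (!is.null(max_occ)) stopifnot(max_occ >= 1)
  structure(list(k = k, w = w, max_occ = max_occ), class = "sketch_params")
}

#' Compute the minimizer sketch of one sequence
#'
#' For every window of `w` consecutive k-mers, the k-mer with the smallest
#' canonical hash is selected (leftmost on ties); duplicate selections are
#' collapsed. K-mers containing `N` are skipped, and runs of valid k-mers
#' shorter than one window contribute nothing. Hashes are identical for a
#' k-mer and its reverse complement; `strand` records which orientation is
#' canonical.
#'
#' @param seq A single uppercase `A,C,G,T,N` string.
#' @param params A [sketch_params()] object.
#' @return A tibble with columns `hash` (double, 53-bit), `pos` (0-based
#'   k-mer start on the forward strand) and `strand` (`"+"`/`"-"`), sorted
#'   by `pos`. A sequence shorter than `k` yields zero rows.
#' @examples
#' compute_minimizers("ACGTACGTACGTACGTACGTACGT", sketch_params(k = 5, w = 3))
#' @export
compute_minimizers <- function(seq, params = sketch_params()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- cpp_sketch(seq, params$k, params$w)
  tibble::tibble(
    hash = s$hash,
    pos = s$pos,
    strand = ifelse(s$strand < 0L, "-", "+")
  )
}

#' Build a minimizer index over a read set
#'
#' Sketches every read and stores a hash -> postings mapping
#' (read, position, strand). Hashes occurring in more reads than the
#' high-frequency cutoff (see [sketch_params()]) are masked and counted.
#'
#' @param reads Read tibble (`read_id`, `seq`, ...).
#' @param params A [sketch_params()] object.
#' @return An object of class `overlap_index`.
#' @export
build_overlap_index <- function(reads, params = sketch_params()) {
  if (nrow(reads) == 0L) stop("no reads: cannot build an overlap index", call. = FALSE)
  if (anyDuplicated(reads$read_id)) stop("read ids must be unique", call. = FALSE)
  sk <- lapply(reads$seq, cpp_sketch, k = params$k, w = params$w)
  nper <- vapply(sk, function(s) length(s$hash), integer(1))
  postings <- data.table::data.table(
    read = rep.int(seq_len(nrow(reads)), nper),
    hash = unlist(lapply(sk, `[[`, "hash"), use.names = FALSE),
    pos = unlist(lapply(sk, `[[`, "pos"), use.names = FALSE),
    mstrand = unlist(lapply(sk, `[[`, "strand"), use.names = FALSE)
  )
  # per-hash occurrence (distinct reads), masking rule
  occ <- unique(postings, by = c("hash", "read"))[, list(n_reads = .N),
                                                  by = "hash"]
  cutoff <- if (!is.null(params$max_occ)) {
    as.numeric(params$max_occ)
  } else {
    max(100, stats::quantile(occ$n_reads, 0.999, names = FALSE))
  }
  masked <- occ$hash[occ$n_reads > cutoff]
  if (length(masked)) {
    postings <- postings[!list(hash = masked), on = "hash"]
  }
  data.table::setkeyv(postings, "hash")
  structure(list(
    postings = postings,
    read_id = reads$read_id,
    read_len = nchar(reads$seq),
    n_minimizers = nper,
    params = params,
    n_reads = nrow(reads),
    total_bases = sum(nchar(reads$seq)),
    n_hashes = nrow(occ),
    n_masked = length(masked),
    occ_cutoff = cutoff
  ), class = "overlap_index")
}

#' @export
print.overlap_index <- function(x, ...) {
  cat("<overlap_index> ", x$n_reads, " reads, ",
      format(x$total_bases, big.mark = ","), " bases\n",
      "  k=", x$params$k, " w=", x$params$w,
      "; ", format(nrow(x$postings), big.mark = ","), " postings, ",
      x$n_masked, " high-frequency hash(es) masked (cutoff ",
      round(x$occ_cutoff), " reads)\n", sep = "")
  invisible(x)
}

#' Overlap filter parameters
#'
#' Controls which raw minimizer chains are accepted as genuine read-to-read
#' overlaps, suppressing the spurious matches that repeats and chance k-mer
#' sharing produce.
#'
#' @param min_shared Minimum chained shared minimizers (default 4).
#' @param min_span Minimum overlap span on the query, bases (default 500).
#' @param max_gap Maximum positional gap between consecutive chained
#'   minimizers on either read, bases (default 2000).
#' @param terminal_slack Bases of unaligned overhang tolerated at each
#'   overlap end before the overlap is called internal-only and rejected
#'   (default 1000). Genuine overlaps between fragments of one molecule
#'   pool are dovetails or containments; internal-only matches are
#'   repeat-induced.
#' @return An object of class `overlap_filter_params`.
#' @export
overlap_filter_params <- function(min_shared = 4L, min_span = 500L,
                                  max_gap = 2000L, terminal_slack = 1000L) {
  p <- list(min_shared = as.integer(min_shared),
            min_span = as.integer(min_span),
            max_gap = as.integer(max_gap),
            terminal_slack = as.integer(terminal_slack))
  if (any(vapply(p, function(v) is.na(v) || v <= 0L, logical(1)))) {
    stop("all overlap filter parameters must be positive", call. = FALSE)
  }
  structure(p, class = "overlap_filter_params")
}

empty_overlaps <- function() {
  tibble::tibble(
    query_id = character(0), q_len = integer(0),
    q_start = integer(0), q_end = integer(0),
    strand = character(0),
    target_id = character(0), t_len = integer(0),
    t_start = integer(0), t_end = integer(0),
    n_shared = integer(0), q_span = integer(0)
  )
}

#' Find overlaps between query reads and an indexed read set
#'
#' Minimizer hits of each query against the index are collected per target
#' read and relative strand, chained into the longest collinear run under
#' the `max_gap` constraint, and the resulting candidate overlaps are
#' passed through [filter_overlaps()]. Self-hits (target equals query) are
#' always discarded. All coordinates are 0-based half-open on the forward
#' strand of each read; for `-` overlaps the target interval is reported on
#' the target's forward strand.
#'
#' @param queries Read tibble of one or more query reads (typically a
#'   sample of the indexed set).
#' @param index An [build_overlap_index()] object built with the same
#'   sketch parameters.
#' @param filt An [overlap_filter_params()] object.
#' @param batch_size Queries processed per internal batch (memory knob).
#' @return An overlap tibble: `query_id`, `q_len`, `q_start`, `q_end`,
#'   `strand`, `target_id`, `t_len`, `t_start`, `t_end`, `n_shared`,
#'   `q_span`.
#' @export
find_overlaps <- function(queries, index, filt = overlap_filter_params(),
                          batch_size = 250L) {
  stopifnot(inherits(index, "overlap_index"))
  if (nrow(queries) == 0L) return(empty_overlaps())
  k <- index$params$k
  w <- index$params$w
  batches <- split(seq_len(nrow(queries)),
                   ceiling(seq_len(nrow(queries)) / batch_size))
  out <- lapply(batches, function(ix) {
    raw <- chain_batch(queries[ix, , drop = FALSE], index, filt$max_gap)
    if (nrow(raw) == 0L) return(empty_overlaps())
    filter_overlaps(raw, filt)
  })
  dplyr::bind_rows(out)
}

# raw chained overlaps (pre-filter) for a batch of queries
chain_batch <- function(queries, index, max_gap) {
  k <- index$params$k
  w <- index$params$w
  sk <- lapply(queries$seq, cpp_sketch, k = k, w = w)
  nper <- vapply(sk, function(s) length(s$hash), integer(1))
  if (sum(nper) == 0L) return(empty_overlaps())
  qdt <- data.table::data.table(
    q = rep.int(seq_len(nrow(queries)), nper),
    hash = unlist(lapply(sk, `[[`, "hash"), use.names = FALSE),
    qpos = unlist(lapply(sk, `[[`, "pos"), use.names = FALSE),
    qstrand = unlist(lapply(sk, `[[`, "strand"), use.names = FALSE)
  )
  hits <- index$postings[qdt, on = "hash", nomatch = NULL,
                         allow.cartesian = TRUE]
  if (nrow(hits) == 0L) return(empty_overlaps())
  # drop self-hits by id, not position, so duplicated reads still overlap
  qid <- queries$read_id
  hits <- hits[index$read_id[hits$read] != qid[hits$q]]
  if (nrow(hits) == 0L) return(empty_overlaps())
  hits[, rev := (mstrand * qstrand) < 0L]
  data.table::setorderv(hits, c("q", "read", "rev", "qpos", "pos"))
  hits[, grp := data.table::rleidv(hits, c("q", "read", "rev"))]
  ch <- cpp_chain_groups(hits$grp, hits$qpos, hits$pos, hits$rev, max_gap)
  firsts <- hits[!duplicated(grp)]
  stopifnot(nrow(firsts) == nrow(ch))
  tibble::tibble(
    query_id = qid[firsts$q],
    q_len = queries$length[firsts$q],
    q_start = ch$q_first,
    q_end = ch$q_last + k,
    strand = ifelse(firsts$rev, "-", "+"),
    target_id = index$read_id[firsts$read],
    t_len = index$read_len[firsts$read],
    t_start = ch$t_first,
    t_end = ch$t_last + k,
    n_shared = ch$n_shared,
    q_span = ch$q_last + k - ch$q_first
  )
}

#' Filter candidate overlaps
#'
#' Keeps an overlap iff it has at least `min_shared` chained shared
#' minimizers, spans at least `min_span` bases, and is "proper": on each
#' side it reaches within `terminal_slack` bases of an end of the query or
#' of the target (dovetail or containment). Purely internal matches, the
#' signature of repeats, are rejected. At most one overlap is kept per
#' (target, strand): the one with the largest `n_shared`, ties broken by
#' larger `q_span`, then by target id.
#'
#' The span test uses the dovetail-implied span: the chained-minimizer
#' span plus, on each side, the smaller of the query and target overhangs
#' (the overlap a proper layout implies beyond the outermost seeds). The
#' chain itself systematically stops one thinned-minimizer spacing short
#' of each true overlap end, so filtering on the bare chain span would
#' drop genuine overlaps barely above `min_span`. Reported coordinates
#' remain the chain bounds.
#'
#' @param raw Overlap tibble (from the chaining stage) for one or more
#'   queries.
#' @param filt An [overlap_filter_params()] object.
#' @return The filtered overlap tibble.
#' @export
filter_overlaps <- function(raw, filt = overlap_filter_params()) {
  if (nrow(raw) == 0L) return(raw)
  slack <- filt$terminal_slack
  t_left <- ifelse(raw$strand == "+", raw$t_start, raw$t_len - raw$t_end)
  t_right <- ifelse(raw$strand == "+", raw$t_len - raw$t_end, raw$t_start)
  left_ok <- raw$q_start <= slack | t_left <= slack
  right_ok <- (raw$q_len - raw$q_end) <= slack | t_right <= slack
  implied_span <- raw$q_span + pmin(raw$q_start, t_left) +
    pmin(raw$q_len - raw$q_end, t_right)
  keep <- raw$n_shared >= filt$min_shared &
    implied_span >= filt$min_span & left_ok & right_ok
  out <- raw[keep, , drop = FALSE]
  out <- dplyr::arrange(out, .data$query_id, .data$target_id, .data$strand,
                        dplyr::desc(.data$n_shared), dplyr::desc(.data$q_span))
  dplyr::distinct(out, .data$query_id, .data$target_id, .data$strand,
                  .keep_all = TRUE)
}

#' Write overlaps as a PAF-like TSV
#'
#' Tab-delimited, one accepted overlap per row, with a header:
#' `query_id, q_len, q_start, q_end, strand, target_id, t_len, t_start,
#' t_end, n_shared, q_span`.
#'
#' @param overlaps Overlap tibble from [find_overlaps()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(overlaps, path) {
  readr::write_tsv(overlaps, path)
  invisible(path)
}
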