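# shared helpers: sequence generators and independent oracles

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc_chr <- function(x) {
  # pure-R reverse complement, independent of the package's helper
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# tibble of reads from plain sequences
as_reads <- function(seqs, ids = sprintf("r%03d", seq_along(seqs)),
                     quals = NULL) {
  tibble::tibble(
    read_id = ids,
    seq = seqs,
    quals = if (is.null(quals)) rep(list(NULL), length(seqs)) else quals,
    length = nchar(seqs)
  )
}

# set of distinct canonical k-mers of a sequence (string-level oracle)
canon_kmers <- function(s, k = 15L) {
  n <- nchar(s)
  if (n < k) return(character(0))
  km <- substring(s, 1:(n - k + 1), k:n)
  km <- km[!grepl("N", km, fixed = TRUE)]
  if (length(km) == 0L) return(character(0))
  unique(pmin(km, rc_chr(km)))
}

# brute-force (w,k)-minimizer oracle: enumerate every window of w
# consecutive valid k-mers and take the leftmost arg-min hash. Uses the
# same per-k-mer hash primitive as the engine but none of its windowing.
brute_minimizers <- function(seq, k, w) {
  kh <- overqc:::cpp_kmer_hashes(seq, k)
  h <- kh$hash
  nk <- length(h)
  sel <- integer(0)
  if (nk >= w) {
    for (i in 1:(nk - w + 1)) {
      win <- h[i:(i + w - 1)]
      if (anyNA(win)) next
      sel <- c(sel, i + which.min(win) - 1L)
    }
  }
  sel <- sort(unique(sel))
  data.frame(pos = sel - 1L, hash = h[sel])
}
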