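test_that("degenerate sequences sketch as expected", {
  p <- sketch_params(k = 5, w = 3)
  expect_equal(nrow(compute_minimizers("ACGT", p)), 0L) # shorter than k
  h <- compute_minimizers(strrep("A", 20), p)
  expect_gt(nrow(h), 0L)
  expect_equal(length(unique(h$hash)), 1L) # homopolymer: one distinct k-mer
  # N-containing k-mers are skipped entirely
  expect_equal(nrow(compute_minimizers("ACGTNNNNACGT", p)), 0L)
})

test_that("minimizer selection matches a brute-force window scan", {
  withr::local_seed(7)
  for (rep in 1:5) {
    s <- rand_seq(2000)
    got <- compute_minimizers(s, sketch_params(k = 15, w = 10))
    want <- brute_minimizers(s, 15, 10)
    expect_equal(got$pos, want$pos)
    expect_equal(got$hash, want$hash)
  }
})

test_that("sketches are canonical: a read and its reverse complement share hashes", {
  withr::local_seed(11)
  for (rep in 1:10) {
    s <- rand_seq(500 + rep * 100)
    a <- sort(compute_minimizers(s, sketch_params())$hash)
    b <- sort(compute_minimizers(rc_chr(s), sketch_params())$hash)
    expect_equal(a, b)
  }
})

test_that("index postings reflect read content and duplication", {
  withr::local_seed(3)
  s <- rand_seq(1500)
  one <- build_overlap_index(as_reads(s))
  expect_equal(sort(unique(one$postings$hash)),
               sort(unique(compute_minimizers(s)$hash)))
  two <- build_overlap_index(as_reads(c(s, s), ids = c("a", "b")))
  per_hash <- table(two$postings$hash)
  expect_true(all(per_hash >= 2)) # every surviving hash occurs in both copies
  expect_error(build_overlap_index(as_reads(character(0))), "no reads")
})

test_that("distinct index hashes match brute-force counting over read sketches", {
  withr::local_seed(19)
  g <- rand_seq(20000)
  starts <- sample(1:(20000 - 1500), 60, replace = TRUE)
  reads <- as_reads(vapply(starts, function(s) substr(g, s, s + 1499),
                           character(1)))
  idx <- build_overlap_index(reads, sketch_params(max_occ = 1e9))
  brute <- unique(unlist(lapply(reads$seq, function(s)
    compute_minimizers(s)$hash)))
  expect_equal(length(unique(idx$postings$hash)), length(brute))
})

test_that("a query finds no overlap against an index of itself", {
  withr::local_seed(23)
  r <- as_reads(rand_seq(5000))
  idx <- build_overlap_index(r)
  expect_equal(nrow(find_overlaps(r, idx)), 0L)
})

test_that("an exact shared substring produces one dovetail overlap", {
  withr::local_seed(31)
  shared <- rand_seq(2000)
  a <- paste0(rand_seq(3000), shared)      # shared suffix of A
  b <- paste0(shared, rand_seq(3000))      # shared prefix of B
  reads <- as_reads(c(a, b), ids = c("A", "B"))
  idx <- build_overlap_index(reads)
  ov <- find_overlaps(reads[1, ], idx)
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$target_id, "B")
  expect_equal(ov$strand, "+")
  expect_gte(ov$q_span, 2000 - (10 + 15)) # span bound from minimizer spacing
  expect_lte(ov$q_end, nchar(a))
  expect_lte(ov$t_end, nchar(b))
})

test_that("independent random reads never pass the overlap filter", {
  withr::local_seed(37)
  reads <- as_reads(c(rand_seq(10000), rand_seq(10000)), ids = c("A", "B"))
  idx <- build_overlap_index(reads)
  expect_equal(nrow(find_overlaps(reads, idx)), 0L)
  # brute-force confirmation: far fewer shared k-mers than min_shared
  shared <- length(intersect(canon_kmers(reads$seq[1]),
                             canon_kmers(reads$seq[2])))
  expect_lt(shared, overlap_filter_params()$min_shared)
})

test_that("overlap filtering enforces thresholds and the proper-overlap rule", {
  base <- tibble::tibble(
    query_id = "Q", q_len = 10000L, q_start = 0L, q_end = 2000L,
    strand = "+", target_id = "T", t_len = 10000L,
    t_start = 8000L, t_end = 10000L, n_shared = 10L, q_span = 2000L
  )
  filt <- overlap_filter_params()
  expect_equal(nrow(filter_overlaps(base[0, ], filt)), 0L)
  # at the min_shared boundary
  low <- dplyr::mutate(base, n_shared = filt$min_shared - 1L)
  expect_equal(nrow(filter_overlaps(low, filt)), 0L)
  expect_equal(nrow(filter_overlaps(base, filt)), 1L)
  # internal repeat match: far from every read end on both sides
  internal <- dplyr::mutate(base, q_start = 4000L, q_end = 6000L,
                            t_start = 4000L, t_end = 6000L)
  both <- dplyr::bind_rows(base, dplyr::mutate(internal, target_id = "T2"))
  kept <- filter_overlaps(both, filt)
  expect_equal(kept$target_id, "T")
  # one overlap kept per (target, strand): best n_shared wins
  dup <- dplyr::bind_rows(base, dplyr::mutate(base, n_shared = 7L))
  expect_equal(filter_overlaps(dup, filt)$n_shared, 10L)
})

test_that("raising filter thresholds never yields more overlaps", {
  withr::local_seed(41)
  g <- rand_seq(30000)
  starts <- sample(1:(30000 - 2500), 40, replace = TRUE)
  reads <- as_reads(vapply(starts, function(s) substr(g, s, s + 2499),
                           character(1)))
  idx <- build_overlap_index(reads)
  n_prev <- Inf
  for (ms in c(4L, 8L, 16L, 32L)) {
    n <- nrow(find_overlaps(reads, idx, overlap_filter_params(min_shared = ms)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  n_prev <- Inf
  for (sp in c(500L, 1000L, 1500L, 2400L)) {
    n <- nrow(find_overlaps(reads, idx, overlap_filter_params(min_span = sp)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})
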