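test_that("read sampling is deterministic, length-filtered and uniform", {
  withr::local_seed(1)
  reads <- as_reads(vapply(sample(c(400, 1200, 3000), 50, replace = TRUE),
                           rand_seq, character(1)))
  p <- coverage_params(sample_size = 5000, min_read_len = 1000)
  got <- sample_reads(reads, p)
  expect_true(all(got$length >= 1000))
  expect_equal(nrow(got), sum(reads$length >= 1000)) # undersized pool: all
  expect_identical(sample_reads(reads, p), sample_reads(reads, p))
  expect_error(sample_reads(reads[reads$length < 500, ], p), "min_read_len")

  # inclusion frequencies consistent with uniform sampling (chi-square GOF)
  pool <- as_reads(vapply(rep(1500, 400), rand_seq, character(1)))
  counts <- integer(400)
  for (s in 1:150) {
    sel <- sample_reads(pool, coverage_params(sample_size = 100, seed = s))
    counts[match(sel$read_id, pool$read_id)] <-
      counts[match(sel$read_id, pool$read_id)] + 1L
  }
  gof <- suppressWarnings(stats::chisq.test(counts))
  expect_gt(gof$p.value, 1e-4)
})

test_that("per-read coverage follows interval arithmetic and the partner rule", {
  q <- as_reads(rand_seq(10000), ids = "Q")
  ov2 <- tibble::tibble(
    query_id = "Q", q_len = 10000L,
    q_start = c(0L, 4000L), q_end = c(6000L, 10000L), strand = "+",
    target_id = c("T1", "T2"), t_len = 10000L, t_start = 0L,
    t_end = c(6000L, 6000L), n_shared = 50L,
    q_span = c(6000L, 6000L)
  )
  pc <- per_read_coverage(q, ov2)
  expect_equal(pc$n_partners, 2L)
  expect_equal(pc$covered_fraction, 1.0)
  expect_equal(pc$mean_depth, 1.2)
  expect_true(pc$is_nonsense) # 2 partners does not exceed the threshold of 2
  expect_equal(pc$left_uncovered, 0L)

  ov3 <- dplyr::bind_rows(ov2, dplyr::mutate(ov2[1, ], target_id = "T3"))
  expect_false(per_read_coverage(q, ov3)$is_nonsense) # 3 partners exceeds 2

  none <- per_read_coverage(q, ov2[0, ])
  expect_equal(none$n_partners, 0L)
  expect_equal(none$covered_fraction, 0)
  expect_true(none$is_nonsense)
  expect_equal(none$left_uncovered, 10000L)
  expect_true(is.na(none$est_error))

  foreign <- dplyr::mutate(ov2, query_id = "X")
  expect_error(per_read_coverage(q, foreign), "foreign")
})

test_that("coverage standardization is an exact z-score", {
  rec <- tibble::tibble(read_id = c("a", "b", "c"), length = 1000L,
                        n_partners = 5L, covered_fraction = 1,
                        mean_depth = c(2, 4, 6), std_coverage = NA_real_,
                        is_nonsense = FALSE, left_uncovered = 0L,
                        right_uncovered = 0L, est_error = NA_real_,
                        n_minimizers = 100L)
  z <- standardize_coverage(rec)
  expect_equal(z$std_coverage, c(-1, 0, 1)) # sample sd of (2,4,6) is 2
  expect_warning(zc <- standardize_coverage(dplyr::mutate(rec, mean_depth = 5)),
                 "zero variance")
  expect_equal(zc$std_coverage, c(0, 0, 0))
  withr::local_seed(5)
  big <- dplyr::mutate(rec[rep(1, 200), ], read_id = paste0("r", 1:200),
                       mean_depth = runif(200, 0, 40))
  zb <- standardize_coverage(big)
  expect_lt(abs(mean(zb$std_coverage)), 1e-9)
  expect_lt(abs(sd(zb$std_coverage) - 1), 1e-9)
})

test_that("non-sense fraction estimates carry a Wilson interval", {
  rec <- tibble::tibble(is_nonsense = rep(TRUE, 10))
  all_f <- estimate_nonsense_fraction(rec)
  expect_equal(all_f$nonsense_fraction, 1.0)
  none_f <- estimate_nonsense_fraction(tibble::tibble(is_nonsense = rep(FALSE, 1000)))
  expect_equal(none_f$nonsense_fraction, 0)
  expect_equal(none_f$ci_lower, 0)
  mix <- estimate_nonsense_fraction(tibble::tibble(is_nonsense = rep(c(TRUE, FALSE), c(3, 17))))
  expect_true(mix$ci_lower < mix$nonsense_fraction &
                mix$nonsense_fraction < mix$ci_upper)
  # Wilson score interval, cross-checked against prop.test without correction
  ref <- stats::prop.test(3, 20, correct = FALSE)$conf.int
  expect_equal(c(mix$ci_lower, mix$ci_upper), as.numeric(ref))
  expect_error(estimate_nonsense_fraction(rec[0, ]), "empty")
})

test_that("the error estimator inverts k-mer survival exactly", {
  withr::local_seed(9)
  q <- as_reads(rand_seq(5000), ids = "Q")
  mz <- compute_minimizers(q$seq)
  m <- nrow(mz)
  ov <- function(s) tibble::tibble(
    query_id = "Q", q_len = 5000L, q_start = 0L, q_end = 5000L,
    strand = "+", target_id = "T", t_len = 5000L, t_start = 0L,
    t_end = 5000L, n_shared = as.integer(s), q_span = 5000L
  )
  # full survival -> zero error
  expect_equal(estimate_error_rate(q, ov(m)), 0)
  # algebraic inversion of a known survival fraction
  s <- floor(0.2 * m)
  expect_equal(estimate_error_rate(q, ov(s)), 1 - (s / m)^(1 / 30))
  # median over overlaps, calibration multiplies
  two <- dplyr::bind_rows(ov(s), ov(s))
  expect_equal(estimate_error_rate(q, two, calibration = 0.5),
               0.5 * (1 - (s / m)^(1 / 30)))
  expect_true(is.na(estimate_error_rate(q, ov(1)[0, ])))
})

test_that("adapter boundaries need support and respect the noise floor", {
  mk <- function(n, left, partners = 5L, err = 0.1) tibble::tibble(
    read_id = paste0("r", seq_len(n)), length = 8000L,
    n_partners = partners, covered_fraction = 1, mean_depth = 10,
    std_coverage = 0, is_nonsense = FALSE,
    left_uncovered = as.integer(left), right_uncovered = 2L,
    est_error = err, n_minimizers = 1400L
  )
  expect_warning(und <- detect_adapter_boundary(mk(10, 60)), "undetermined")
  expect_true(is.na(und$adapter_left))
  expect_false(und$determined)

  # uncovered prefixes below the w+k+5 floor report no adapter
  clean <- detect_adapter_boundary(mk(100, 8))
  expect_equal(clean$adapter_left, 0)
  expect_equal(clean$adapter_right, 0)

  # a clear prefix pile-up is reported after the sketching-lag correction
  ad <- detect_adapter_boundary(mk(100, 70))
  lag <- log(2) * 11 / (2 * 0.9^15)
  expect_equal(ad$adapter_left, 70 - lag)
  # reads with fewer than 3 partners do not contribute
  expect_warning(detect_adapter_boundary(mk(100, 70, partners = 2L)),
                 "undetermined")
})

test_that("QV/error association censors unestimable reads at the ceiling", {
  withr::local_seed(13)
  n <- 200
  err <- runif(n, 0.05, 0.15)
  rec <- tibble::tibble(
    read_id = paste0("r", 1:n), length = 8000L, n_partners = 20L,
    covered_fraction = 1, mean_depth = 10, std_coverage = 0,
    is_nonsense = FALSE, left_uncovered = 0L, right_uncovered = 0L,
    est_error = err, n_minimizers = 1400L,
    mean_qv = round(-10 * log10(err))
  )
  a <- qv_error_association(rec)
  expect_equal(a$n, n)
  expect_lt(a$rho, -0.9)
  # unestimable reads rank near the top of the error scale
  rec$est_error[1:50] <- NA
  rec$mean_qv[1:50] <- 10
  a2 <- qv_error_association(rec)
  expect_equal(a2$n, n)
  expect_false(is.na(a2$rho))
})
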