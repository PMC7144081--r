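test_that("random genomes hit their GC target and are reproducible", {
  g <- generate_genome(1e5, gc = 0.5, seed = 1)
  expect_equal(nchar(g), 1e5)
  expect_lt(abs(gc_content(g) - 0.5), 0.01)
  expect_identical(g, generate_genome(1e5, gc = 0.5, seed = 1))
  g2 <- generate_genome(1e5, gc = 0.3, seed = 2)
  expect_lt(abs(gc_content(g2) - 0.3), 0.01)
  expect_error(generate_genome(1e5, gc = 0), "gc")
  expect_error(generate_genome(1e5, gc = 1), "gc")
  expect_error(generate_genome(100, gc = 0.5), "10,000")
})

test_that("simulated datasets respect depth, truth bookkeeping and determinism", {
  cfg <- sim_config(genome_length = 1e5, depth = 15, seed = 21)
  d <- simulate_dataset(cfg)
  expect_equal(nrow(d$reads), nrow(d$truth))
  expect_identical(d$reads$read_id, d$truth$read_id) # truth covers each read once
  expect_false(anyDuplicated(d$reads$read_id) > 0)
  realized <- sum(d$reads$length) / cfg$genome_length
  expect_lt(abs(realized - 15) / 15, 0.10)
  expect_true(all(d$truth$origin == "genome"))
  d2 <- simulate_dataset(cfg)
  expect_identical(d$reads$seq, d2$reads$seq)
})

test_that("k-mer survival of genomic reads reflects the configured error rate", {
  e <- 0.05
  cfg <- sim_config(genome_length = 5e4, depth = 5,
                    error_rates = c(mismatch = e, insertion = 0, deletion = 0),
                    seed = 22)
  d <- suppressWarnings(simulate_dataset(cfg))
  withr::local_seed(1)
  genome <- withr::with_seed(cfg$seed, generate_genome(cfg$genome_length, cfg$gc))
  gk <- canon_kmers(genome)
  est <- vapply(sample(nrow(d$reads), 15), function(i) {
    rk <- canon_kmers(d$reads$seq[i])
    surv <- mean(rk %in% gk)
    1 - surv^(1 / 15) # genome side is error-free
  }, numeric(1))
  expect_lt(abs(mean(est) - e), 0.02)
})

test_that("pure noise libraries are flagged almost completely downstream", {
  cfg <- sim_config(genome_length = 5e4, depth = 10, nonsense_fraction = 1,
                    seed = 23)
  d <- suppressWarnings(simulate_dataset(cfg))
  rep <- suppressWarnings(run_qc(d$reads,
                                 coverage = coverage_params(sample_size = 200)))
  expect_gte(rep$summary$nonsense_fraction, 0.98)
})

test_that("error-free contaminant reads trace back to the source window", {
  cfg <- sim_config(genome_length = 2e5, depth = 8,
                    error_rates = c(mismatch = 0, insertion = 0, deletion = 0),
                    contaminant = list(fraction = 0.05), seed = 24)
  d <- simulate_dataset(cfg)
  cont_genome <- withr::with_seed(cfg$seed, {
    generate_genome(cfg$genome_length, cfg$gc) # host drawn first
    generate_genome(cfg$contaminant$genome_length, cfg$contaminant$gc)
  })
  hits <- vapply(seq_len(nrow(d$reads)), function(i) {
    s <- d$reads$seq[i]
    grepl(s, cont_genome, fixed = TRUE) || grepl(rc_chr(s), cont_genome, fixed = TRUE)
  }, logical(1))
  frac <- mean(hits)
  expect_lt(abs(frac - 0.05), 0.02)
  expect_identical(hits, d$truth$origin == "contaminant")
})

test_that("adapters and quality encoding are recorded in the truth table", {
  ad <- strrep("ACGTC", 9) # 45 bases
  cfg <- sim_config(genome_length = 5e4, depth = 3, adapter_seq = ad,
                    nonsense_fraction = 0.3, seed = 25)
  d <- suppressWarnings(simulate_dataset(cfg))
  expect_true(all(d$truth$adapter_len == 45L))
  expect_true(all(startsWith(d$reads$seq, ad)))
  # genomic reads carry the Phred equivalent of their true error rate
  qv <- vapply(d$reads$quals, mean, numeric(1))
  genomic <- d$truth$origin == "genome"
  expect_true(all(abs(qv[genomic] -
                        round(-10 * log10(d$truth$true_error[genomic]))) < 1))
  # injected noise reads carry the constant decoy QV instead
  expect_true(all(abs(qv[!genomic] - 10) < 1))
  expect_true(all(is.na(d$truth$true_error[!genomic])))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(gc = 1.2), "gc")
  expect_error(sim_config(error_rates = c(mismatch = 0.4, insertion = 0.2,
                                          deletion = 0)), "0.5")
  expect_error(sim_config(nonsense_fraction = 1.5))
})
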