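#' Simulation configuration
#'
#' Describes a synthetic long-read library with full ground truth: a random
#' host genome, lognormally distributed read lengths, per-base
#' substitution/insertion/deletion errors, an injectable fraction of
#' "non-sense" reads (i.i.d. random sequence overlapping nothing else, the
#' purest testable form of a read that maps to no other molecule in the
#' library), optional un-trimmed terminal adapters, and optional
#' short-fragment contaminant reads drawn from one window of a second,
#' GC-divergent genome.
#'
#' Defaults emulate a small but realistic single-organism PacBio-style
#' run: a 1 Mb genome at 45% GC sequenced to 25x with reads averaging
#' 8 kb and a 10% total per-base error rate split 5% substitution /
#' 2.5% insertion / 2.5% deletion.
#'
#' @param genome_length Host genome length, bases (default 1e6).
#' @param gc Host GC fraction (default 0.45).
#' @param depth Mean sequencing depth (default 25).
#' @param read_len_meanlog,read_len_sdlog Lognormal log-length parameters;
#'   defaults give a mean read length of about 8000 bases.
#' @param min_len Minimum emitted read length, bases (default 500).
#' @param error_rates Named numeric: per-base `mismatch`, `insertion`,
#'   `deletion` probabilities (sum < 0.5).
#' @param error_range Optional length-2 numeric: per-read total error rates
#'   are drawn uniformly from this range (split across the three channels
#'   in the same proportions as `error_rates`) instead of being constant.
#' @param nonsense_fraction Fraction of reads replaced by non-sense reads
#'   (default 0).
#' @param nonsense_mode `"random"` (i.i.d. random sequence) or
#'   `"high_error"` (genomic origin mutated at 35% total error, the
#'   extreme-error flavor of artifact reads).
#' @param short_fragment_mode When `TRUE`, non-sense read lengths come
#'   from a short lognormal (mean about 1000 bases) instead of the main
#'   length distribution, mimicking failed libraries dominated by short
#'   artifact fragments.
#' @param hqnr_qv Constant Phred value assigned to non-sense reads
#'   (default 10), emulating high-quality non-informative reads whose
#'   sequencer quality is misleadingly good.
#' @param adapter_seq Optional adapter string: prepended verbatim to every
#'   read, with its reverse complement appended (error-free, as un-trimmed
#'   adapters are not part of the insert error process).
#' @param contaminant Optional list describing a contaminant spike:
#'   `genome_length` (default 2e5), `gc` (default 0.65), `window_length`
#'   (source window, default 5e4), `fraction` (of all reads, default
#'   0.06), `len_meanlog`/`len_sdlog` (short-fragment lengths, mean about
#'   4500 bases). Contaminant reads receive the same error process as host
#'   reads and are drawn only from the window.
#' @param seed RNG seed; the whole dataset is deterministic given the
#'   configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e6, gc = 0.45, depth = 25,
                       read_len_meanlog = log(8000) - 0.35^2 / 2,
                       read_len_sdlog = 0.35, min_len = 500,
                       error_rates = c(mismatch = 0.05, insertion = 0.025,
                                       deletion = 0.025),
                       error_range = NULL,
                       nonsense_fraction = 0,
                       nonsense_mode = c("random", "high_error"),
                       short_fragment_mode = FALSE,
                       hqnr_qv = 10L,
                       adapter_seq = NULL,
                       contaminant = NULL,
                       seed = 1L) {
  nonsense_mode <- match.arg(nonsense_mode)
  stopifnot(genome_length >= 1e4, depth > 0, min_len > 0,
            nonsense_fraction >= 0, nonsense_fraction <= 1)
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)", call. = FALSE)
  er <- error_rates[c("mismatch", "insertion", "deletion")]
  if (anyNA(er)) stop("error_rates needs mismatch, insertion, deletion", call. = FALSE)
  if (sum(er) >= 0.5) stop("total error rate must be < 0.5", call. = FALSE)
  if (!is.null(error_range)) {
    stopifnot(length(error_range) == 2L, error_range[1] <= error_range[2],
              error_range[2] < 0.5, error_range[1] >= 0)
  }
  if (!is.null(contaminant)) {
    cont_default <- list(genome_length = 2e5, gc = 0.65, window_length = 5e4,
                         fraction = 0.06,
                         len_meanlog = log(4500) - 0.15^2 / 2,
                         len_sdlog = 0.15)
    contaminant <- utils::modifyList(cont_default, contaminant)
    stopifnot(contaminant$fraction >= 0, contaminant$fraction <= 1,
              contaminant$window_length <= contaminant$genome_length)
  }
  structure(list(
    genome_length = genome_length, gc = gc, depth = depth,
    read_len_meanlog = read_len_meanlog, read_len_sdlog = read_len_sdlog,
    min_len = min_len, error_rates = er, error_range = error_range,
    nonsense_fraction = nonsense_fraction, nonsense_mode = nonsense_mode,
    short_fragment_mode = short_fragment_mode,
    short_len_meanlog = log(1000) - 0.5^2 / 2, short_len_sdlog = 0.5,
    hqnr_qv = as.integer(hqnr_qv),
    adapter_seq = adapter_seq, contaminant = contaminant,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a random genome
#'
#' I.i.d. bases with `P(G) = P(C) = gc/2`; deterministic for a fixed seed.
#'
#' @param length Genome length in bases (>= 1e4).
#' @param gc GC fraction, strictly inside (0, 1).
#' @param seed Optional RNG seed; when `NULL` the current RNG stream is
#'   used.
#' @return A single uppercase DNA string.
#' @export
generate_genome <- function(length, gc = 0.5, seed = NULL) {
  if (length < 1e4) stop("genome length must be >= 10,000 bases", call. = FALSE)
  if (gc <= 0 || gc >= 1) stop("gc must be strictly inside (0, 1)", call. = FALSE)
  draw <- function() {
    paste(sample(c("A", "T", "G", "C"), length, replace = TRUE,
                 prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
          collapse = "")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# apply per-base substitution/insertion/deletion errors to one sequence
mutate_seq <- function(seq, p_mis, p_ins, p_del) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(x)
  if (n == 0L || (p_mis + p_ins + p_del) == 0) return(seq)
  bases <- c("A", "C", "G", "T")
  u <- runif(n)
  mis <- u < p_mis
  ins <- u >= p_mis & u < p_mis + p_ins
  del <- u >= p_mis + p_ins & u < p_mis + p_ins + p_del
  if (any(mis)) {
    shift <- sample.int(3L, sum(mis), replace = TRUE)
    x[mis] <- bases[(match(x[mis], bases) - 1L + shift) %% 4L + 1L]
  }
  reps <- rep(1L, n)
  reps[del] <- 0L
  reps[ins] <- 2L
  y <- x[rep.int(seq_len(n), reps)]
  if (any(ins)) {
    # the second copy of each inserted position becomes a random base
    y[cumsum(reps)[ins]] <- sample(bases, sum(ins), replace = TRUE)
  }
  paste(y, collapse = "")
}

# integer Phred string for a read of known true error rate, lightly jittered
phred_for_error <- function(err, len, qv_cap = 60L) {
  q0 <- if (is.na(err) || err <= 0) qv_cap else round(-10 * log10(err))
  q0 <- max(1L, min(qv_cap, as.integer(q0)))
  pmax(0L, pmin(93L, q0 + sample(c(-1L, 0L, 1L), len, replace = TRUE)))
}

#' Simulate a long-read dataset with ground truth
#'
#' Draws reads uniformly over the host genome (both strands equiprobable),
#' truncates lognormal lengths at `min_len` and the genome end, applies
#' per-base errors (mismatch to a random different base, insertion of a
#' random base, deletion), injects non-sense and contaminant reads per the
#' configuration, optionally attaches terminal adapters, and assigns each
#' base the Phred equivalent of the read's true error rate (non-sense
#' reads get the configured constant `hqnr_qv` instead). Every emitted
#' read is described exactly once in the returned truth table.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `reads` (read tibble: `read_id`, `seq`,
#'   `quals`, `length`) and `truth` (tibble: `read_id`, `origin`
#'   (`genome`/`nonsense`/`contaminant`), `src_start`, `src_end`
#'   (0-based half-open on the source genome), `src_strand`,
#'   `true_error`, `adapter_len`, `length`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    genome <- generate_genome(config$genome_length, config$gc)
    mean_len <- exp(config$read_len_meanlog + config$read_len_sdlog^2 / 2)
    n_reads <- max(1L, round(config$depth * config$genome_length / mean_len))
    if (n_reads < 50L) {
      warning("only ", n_reads, " reads at this depth; ",
              "fraction estimates will be unreliable", call. = FALSE)
    }
    cont_genome <- NULL
    cont_w0 <- NA_integer_
    if (!is.null(config$contaminant)) {
      cont_genome <- generate_genome(config$contaminant$genome_length,
                                     config$contaminant$gc)
      cont_w0 <- sample.int(config$contaminant$genome_length -
                              config$contaminant$window_length + 1L, 1L) - 1L
    }
    cf <- if (is.null(config$contaminant)) 0 else config$contaminant$fraction
    nf <- config$nonsense_fraction
    origin <- sample(c("contaminant", "nonsense", "genome"), n_reads,
                     replace = TRUE,
                     prob = c(cf, (1 - cf) * nf, (1 - cf) * (1 - nf)))
    er <- config$error_rates
    er_prop <- if (sum(er) > 0) er / sum(er) else c(1, 0, 0)
    ad <- config$adapter_seq
    ad_left <- if (is.null(ad)) "" else ad
    ad_right <- if (is.null(ad)) "" else revcomp(ad)
    ad_len <- if (is.null(ad)) 0L else nchar(ad)

    rows <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      org <- origin[i]
      e_read <- if (!is.null(config$error_range)) {
        runif(1, config$error_range[1], config$error_range[2])
      } else {
        sum(er)
      }
      e3 <- e_read * er_prop
      if (org == "nonsense" && config$nonsense_mode == "high_error") {
        e_read <- 0.35
        e3 <- 0.35 * er_prop
      }
      use_short <- org == "nonsense" && config$short_fragment_mode
      len <- if (org == "contaminant") {
        round(rlnorm(1, config$contaminant$len_meanlog,
                     config$contaminant$len_sdlog))
      } else if (use_short) {
        round(rlnorm(1, config$short_len_meanlog, config$short_len_sdlog))
      } else {
        round(rlnorm(1, config$read_len_meanlog, config$read_len_sdlog))
      }
      len <- max(config$min_len, len)

      if (org == "nonsense" && config$nonsense_mode == "random") {
        seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = "")
        src_start <- NA_integer_; src_end <- NA_integer_; strand <- NA_character_
        true_err <- NA_real_
      } else {
        src <- if (org == "contaminant") cont_genome else genome
        src_len <- if (org == "contaminant") {
          config$contaminant$window_length
        } else {
          config$genome_length
        }
        src_off <- if (org == "contaminant") cont_w0 else 0L
        len <- min(len, src_len)
        start <- sample.int(src_len - len + 1L, 1L) - 1L + src_off
        frag <- substr(src, start + 1L, start + len)
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-") frag <- revcomp(frag)
        seq <- mutate_seq(frag, e3[1], e3[2], e3[3])
        src_start <- start; src_end <- start + len
        true_err <- e_read
      }
      seq <- paste0(ad_left, seq, ad_right)
      out_len <- nchar(seq)
      quals <- if (org == "nonsense") {
        pmax(0L, pmin(93L, config$hqnr_qv +
                        sample(c(-1L, 0L, 1L), out_len, replace = TRUE)))
      } else {
        phred_for_error(true_err, out_len)
      }
      rows[[i]] <- list(
        read_id = sprintf("read%06d", i),
        seq = seq, quals = quals, length = out_len,
        origin = org, src_start = src_start, src_end = src_end,
        src_strand = strand, true_error = true_err, adapter_len = ad_len
      )
    }
    reads <- tibble::tibble(
      read_id = vapply(rows, `[[`, character(1), "read_id"),
      seq = vapply(rows, `[[`, character(1), "seq"),
      quals = lapply(rows, `[[`, "quals"),
      length = vapply(rows, `[[`, integer(1), "length")
    )
    truth <- tibble::tibble(
      read_id = reads$read_id,
      origin = vapply(rows, `[[`, character(1), "origin"),
      src_start = vapply(rows, function(r) as.integer(r$src_start), integer(1)),
      src_end = vapply(rows, function(r) as.integer(r$src_end), integer(1)),
      src_strand = vapply(rows, function(r) as.character(r$src_strand), character(1)),
      true_error = vapply(rows, function(r) as.numeric(r$true_error), numeric(1)),
      adapter_len = vapply(rows, `[[`, integer(1), "adapter_len"),
      length = reads$length
    )
    list(reads = reads, truth = truth)
  })
}
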