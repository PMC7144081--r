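#' Read long-read sequences into a tibble
#'
#' Reads FASTA, FASTQ (plain or gzip-compressed) or unaligned BAM (uBAM, the
#' native PacBio container) and normalizes every record to one row of a read
#' tibble: bases are uppercased, `U` is mapped to `T`, and any character
#' outside `{A,C,G,T,N}` becomes `N` (a message reports how many). BAM input
#' is treated as unaligned: only the read name, sequence and base qualities
#' are used and alignment information is ignored.
#'
#' @param path Path to the input file. Gzip compression is transparent for
#'   FASTA/FASTQ.
#' @param format One of `"auto"`, `"fasta"`, `"fastq"`, `"bam"`. With
#'   `"auto"` the format is sniffed from the file extension and leading
#'   bytes.
#' @return A tibble with columns `read_id` (character, unique), `seq`
#'   (character over `A,C,G,T,N`), `quals` (list column of integer Phred
#'   vectors, `NULL` where the format carries no qualities) and `length`
#'   (integer, bases).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "ACGTACGT"), fa)
#' read_seqs(fa)
#' @export
read_seqs <- function(path, format = c("auto", "fasta", "fastq", "bam")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  if (format == "auto") format <- sniff_format(path)
  res <- switch(format,
    fasta = read_fasta(path),
    fastq = read_fastq(path),
    bam   = read_ubam(path)
  )
  res$seq <- normalize_bases(res$seq)
  res$length <- nchar(res$seq)
  if (anyDuplicated(res$read_id)) {
    dup <- res$read_id[duplicated(res$read_id)][1]
    stop("duplicate read id in ", path, ": '", dup, "'", call. = FALSE)
  }
  bad_q <- which(vapply(res$quals, function(q) {
    !is.null(q) && (anyNA(q) || any(q < 0L | q > 93L))
  }, logical(1)))
  if (length(bad_q)) {
    stop("Phred values outside [0, 93] in record '",
         res$read_id[bad_q[1]], "'", call. = FALSE)
  }
  mism <- which(vapply(seq_len(nrow(res)), function(i) {
    q <- res$quals[[i]]
    !is.null(q) && length(q) != res$length[i]
  }, logical(1)))
  if (length(mism)) {
    stop("sequence/quality length mismatch in record '",
         res$read_id[mism[1]], "' (record ", mism[1], ")", call. = FALSE)
  }
  res
}

sniff_format <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) return("bam")
  con <- gzfile(path, "rt")
  on.exit(close(con))
  first <- tryCatch(readLines(con, n = 1L, warn = FALSE), error = function(e) character(0))
  if (length(first) == 0L) {
    # empty file: fall back to the extension, default FASTA
    if (grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE)) return("fastq")
    return("fasta")
  }
  c1 <- substr(first, 1L, 1L)
  if (c1 == ">") return("fasta")
  if (c1 == "@") return("fastq")
  stop("cannot recognize sequence format of ", path,
       " (first record starts with '", c1, "')", call. = FALSE)
}

read_fasta <- function(path) {
  x <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("FASTA parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  ids <- sub("\\s.*$", "", names(x))
  tibble::tibble(
    read_id = ids,
    seq = unname(as.character(x)),
    quals = rep(list(NULL), length(x)),
    length = Biostrings::width(x)
  )
}

read_fastq <- function(path) {
  x <- tryCatch(
    Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("FASTQ parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  ids <- sub("\\s.*$", "", names(x))
  qual_set <- S4Vectors::mcols(x)$qualities
  bad <- which(Biostrings::width(qual_set) != Biostrings::width(x))
  qstr <- tryCatch(as.character(qual_set), error = function(e) {
    stop("FASTQ parse error in ", path,
         ": sequence/quality length mismatch (record ",
         if (length(bad)) bad[1] else "?", ", approx. line ",
         if (length(bad)) 4L * (bad[1] - 1L) + 4L else "?", ")",
         call. = FALSE)
  })
  if (length(bad)) {
    stop("FASTQ parse error in ", path,
         ": sequence/quality length mismatch in record ", bad[1],
         " (approx. line ", 4L * (bad[1] - 1L) + 4L, ")", call. = FALSE)
  }
  quals <- lapply(qstr, function(s) utf8ToInt(s) - 33L)
  tibble::tibble(
    read_id = ids,
    seq = unname(as.character(x)),
    quals = quals,
    length = Biostrings::width(x)
  )
}

read_ubam <- function(path) {
  param <- Rsamtools::ScanBamParam(what = c("qname", "seq", "qual"))
  res <- tryCatch(
    Rsamtools::scanBam(path, param = param)[[1]],
    error = function(e) stop("BAM read error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  seqs <- unname(as.character(res$seq))
  if (any(nchar(seqs) == 0L)) {
    bad <- res$qname[which(nchar(seqs) == 0L)[1]]
    stop("BAM record '", bad, "' has no stored sequence ('*')", call. = FALSE)
  }
  qstr <- as.character(res$qual)
  quals <- lapply(seq_along(qstr), function(i) {
    q <- qstr[i]
    if (is.na(q) || q == "*" || nchar(q) != nchar(seqs[i])) return(NULL)
    v <- utf8ToInt(q) - 33L
    # 0xff / blank fills mean qualities were not stored
    if (all(v == 255L - 33L) || all(v == -1L)) return(NULL)
    v
  })
  tibble::tibble(
    read_id = res$qname,
    seq = seqs,
    quals = quals,
    length = nchar(seqs)
  )
}

# uppercase, U -> T, anything outside ACGTN -> N (with a message)
normalize_bases <- function(seq) {
  seq <- chartr("u", "U", toupper(seq))
  seq <- chartr("U", "T", seq)
  odd <- sum(nchar(seq) - nchar(gsub("[^ACGTN]", "", seq)))
  if (odd > 0L) {
    seq <- gsub("[^ACGTN]", "N", seq)
    rlang::inform(paste0("replaced ", odd,
                         " non-ACGTN character(s) with N during ingest"))
  }
  seq
}

#' Write reads to FASTA or FASTQ
#'
#' @param records Read tibble as returned by [read_seqs()] or
#'   [simulate_dataset()].
#' @param path Output path.
#' @param format `"fasta"` or `"fastq"`.
#' @param fill_qual Optional constant Phred value used for records without
#'   qualities when writing FASTQ. By default such records are an error:
#'   base-call confidence is never fabricated silently.
#' @return The number of records written, invisibly.
#' @export
write_fastx <- function(records, path, format = c("fasta", "fastq"),
                        fill_qual = NULL) {
  format <- match.arg(format)
  n <- nrow(records)
  if (format == "fasta") {
    lines <- character(2L * n)
    if (n > 0) {
      lines[seq(1L, 2L * n, by = 2L)] <- paste0(">", records$read_id)
      lines[seq(2L, 2L * n, by = 2L)] <- records$seq
    }
    writeLines(lines, path)
    return(invisible(n))
  }
  qstr <- vapply(seq_len(n), function(i) {
    q <- records$quals[[i]]
    if (is.null(q)) {
      if (is.null(fill_qual)) {
        stop("record '", records$read_id[i], "' has no qualities; ",
             "set fill_qual to write FASTQ anyway", call. = FALSE)
      }
      q <- rep(as.integer(fill_qual), records$length[i])
    }
    intToUtf8(q + 33L)
  }, character(1))
  lines <- character(4L * n)
  if (n > 0) {
    lines[seq(1L, 4L * n, by = 4L)] <- paste0("@", records$read_id)
    lines[seq(2L, 4L * n, by = 4L)] <- records$seq
    lines[seq(3L, 4L * n, by = 4L)] <- "+"
    lines[seq(4L, 4L * n, by = 4L)] <- qstr
  }
  writeLines(lines, path)
  invisible(n)
}

#' Write a per-read table as TSV
#'
#' Tab-delimited with a header row; missing values are written as `.`
#' (list columns are dropped).
#'
#' @param tbl A tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_read_tsv <- function(tbl, path) {
  keep <- !vapply(tbl, is.list, logical(1))
  readr::write_tsv(tbl[keep], path, na = ".")
  invisible(path)
}

# reverse complement of plain character DNA
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
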