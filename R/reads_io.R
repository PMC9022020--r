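## FASTQ records, sliding-window quality filtering, and seeded subsampling.

#' Construct a sequencing read record
#'
#' A minimal in-memory representation of one FASTQ record: identifier,
#' nucleotide sequence (A/C/G/T/N) and per-base Phred quality scores.
#'
#' @param read_id read identifier (without the leading `@`).
#' @param sequence nucleotide string, alphabet `A`,`C`,`G`,`T`,`N`.
#' @param qualities integer vector of per-base Phred scores, same length as
#'   `sequence`; all values must be `>= 0`.
#' @return an object of class `read_record`.
#' @export
#' @examples
#' read_record("r1", "ACGT", c(30L, 30L, 30L, 30L))
read_record <- function(read_id, sequence, qualities) {
  stopifnot(is.character(read_id), length(read_id) == 1L, nzchar(read_id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  qualities <- as.integer(qualities)
  if (nchar(sequence) != length(qualities)) {
    abort("read '%s': sequence length (%d) != number of quality scores (%d)",
          read_id, nchar(sequence), length(qualities))
  }
  if (any(qualities < 0L)) abort("read '%s': negative Phred score", read_id)
  if (grepl("[^ACGTN]", sequence)) {
    abort("read '%s': sequence contains characters outside A/C/G/T/N", read_id)
  }
  structure(list(read_id = read_id, sequence = sequence,
                 qualities = qualities),
            class = "read_record")
}

#' @export
print.read_record <- function(x, ...) {
  cat(sprintf("<read %s> %d bp, mean Q %.1f\n", x$read_id,
              nchar(x$sequence),
              if (length(x$qualities)) mean(x$qualities) else NA_real_))
  invisible(x)
}

#' Quality-control parameters
#'
#' Defaults implement the standard short-read filter: drop reads shorter
#' than 50 bases and truncate at the first 50-base window whose mean
#' Phred quality falls below 20 (Trimmomatic `SLIDINGWINDOW:50:20` +
#' `MINLEN:50` semantics).
#'
#' @param min_length minimum surviving read length in bases.
#' @param window_len sliding-window width in bases.
#' @param min_mean_q minimum mean Phred quality within a window.
#' @return an object of class `qc_params`.
#' @export
qc_params <- function(min_length = 50L, window_len = 50L, min_mean_q = 20) {
  min_length <- as.integer(min_length)
  window_len <- as.integer(window_len)
  if (min_length <= 0L || window_len <= 0L || min_mean_q <= 0) {
    abort("all QC parameters must be strictly positive")
  }
  structure(list(min_length = min_length, window_len = window_len,
                 min_mean_q = min_mean_q),
            class = "qc_params")
}

#' Sliding-window quality filter for one read
#'
#' Scans the read 5' to 3' with windows of `params$window_len` bases
#' advancing one base at a time.  The read is truncated at the start of
#' the first window whose mean quality is below `params$min_mean_q`; the
#' survivor is kept only if it is at least `params$min_length` bases long.
#' Reads shorter than one window are judged on their whole-read mean.
#'
#' @param read a [read_record()].
#' @param params a [qc_params()] object.
#' @return the (possibly truncated) `read_record`, or `NULL` if the read
#'   is rejected.
#' @seealso [qc_filter_reads()] for a whole-file wrapper.
#' @export
qc_filter_read <- function(read, params = qc_params()) {
  stopifnot(inherits(read, "read_record"), inherits(params, "qc_params"))
  q <- read$qualities
  n <- length(q)
  if (n == 0L) return(NULL)
  w <- params$window_len
  if (n < w) {
    keep <- if (mean(q) < params$min_mean_q) 0L else n
  } else {
    ## rolling mean over all n - w + 1 window starts via cumulative sums
    cs <- cumsum(c(0, q))
    means <- (cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]) / w
    bad <- which(means < params$min_mean_q)
    keep <- if (length(bad)) bad[1L] - 1L else n
  }
  if (keep < params$min_length) return(NULL)
  if (keep == n) return(read)
  read_record(read$read_id, substr(read$sequence, 1L, keep), q[seq_len(keep)])
}

#' Quality-filter a list of reads
#'
#' @param reads list of [read_record()] objects.
#' @param params a [qc_params()] object.
#' @return list of surviving (possibly truncated) reads, with attributes
#'   `n_input`, `n_kept`, `n_rejected`.
#' @export
qc_filter_reads <- function(reads, params = qc_params()) {
  out <- lapply(reads, qc_filter_read, params = params)
  kept <- out[!vapply(out, is.null, logical(1))]
  attr(kept, "n_input") <- length(reads)
  attr(kept, "n_kept") <- length(kept)
  attr(kept, "n_rejected") <- length(reads) - length(kept)
  kept
}

#' Seeded uniform subsampling of reads without replacement
#'
#' Draws exactly `min(n, length(reads))` reads uniformly without
#' replacement and emits them in their original input order.  The sampled
#' index set depends only on `(seed, length(reads), n)`, so paired files
#' subsampled with one seed stay mate-consistent.  This reproduces the
#' role of `seqtk sample -s<seed>` in a read-rarefaction workflow but is
#' not bit-compatible with seqtk's stream; the contract is determinism
#' under a fixed seed plus order preservation.
#'
#' @param reads list of [read_record()] objects.
#' @param n number of reads to keep (`>= 0`).
#' @param seed integer random seed.
#' @return list of sampled reads, a subsequence of `reads`.
#' @export
subsample_reads <- function(reads, n, seed) {
  if (length(n) != 1L || is.na(n) || n < 0) abort("n must be a single count >= 0")
  n <- as.integer(n)
  total <- length(reads)
  if (n >= total) return(reads)
  if (n == 0L) return(reads[integer(0)])
  idx <- with_seed(seed, sort(sample.int(total, n)))
  reads[idx]
}

#' Read a FASTQ file into read records
#'
#' Phred+33 encoding; plain or gzip-compressed input.
#'
#' @param path FASTQ file path.
#' @return list of [read_record()] objects.
#' @export
read_fastq <- function(path) {
  ## the reader warns when it drops (empty) metadata columns; nothing is lost
  qs <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"))
  seqs <- as.character(qs)
  quals <- as(Biostrings::quality(qs), "IntegerList")
  ids <- names(qs)
  if (is.null(ids)) ids <- paste0("read", seq_along(qs))
  mapply(function(id, s, q) read_record(id, s, q),
         ids, seqs, as.list(quals), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write read records to a FASTQ file
#'
#' @param reads list of [read_record()] objects.
#' @param path output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (length(reads) == 0L) {
    ## Biostrings refuses empty writes with qualities; an empty FASTQ is
    ## a legal (empty) file.
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    close(con)
    return(invisible(path))
  }
  seqs <- Biostrings::DNAStringSet(vapply(reads, `[[`, "", "sequence"))
  names(seqs) <- vapply(reads, `[[`, "", "read_id")
  quals <- Biostrings::PhredQuality(vapply(reads, function(r) {
    rawToChar(as.raw(r$qualities + 33L))
  }, ""))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
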