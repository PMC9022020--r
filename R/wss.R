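## Window-based SNV similarity (WSS): score a pair of samples against one
## species reference, calibrate a per-species cutoff, classify pairs.

#' Construct an SNV profile
#'
#' The set of single-nucleotide variant calls of one sample against one
#' species reference genome: positions are 1-based on the reference, with
#' at most one alternate allele per position.
#'
#' @param species_id species/reference identifier.
#' @param genome_length reference length in bases.
#' @param calls data.frame with columns `pos` (integer, 1-based) and
#'   `alt` (single nucleotide `A`/`C`/`G`/`T`).  Rows are sorted by `pos`.
#' @return an object of class `snv_profile`.
#' @export
snv_profile <- function(species_id, genome_length, calls) {
  stopifnot(is.character(species_id), length(species_id) == 1L)
  genome_length <- as.numeric(genome_length)
  stopifnot(length(genome_length) == 1L, genome_length >= 1)
  if (is.null(calls) || nrow(calls) == 0L) {
    calls <- data.frame(pos = integer(0), alt = character(0))
  }
  stopifnot(all(c("pos", "alt") %in% names(calls)))
  calls <- data.frame(pos = as.integer(calls$pos),
                      alt = toupper(as.character(calls$alt)))
  if (any(calls$pos < 1L | calls$pos > genome_length)) {
    abort("SNV position outside [1, %s] on %s", format(genome_length), species_id)
  }
  if (anyDuplicated(calls$pos)) {
    abort("duplicate SNV positions in profile for %s", species_id)
  }
  if (nrow(calls) && any(!calls$alt %in% c("A", "C", "G", "T"))) {
    abort("alt alleles must be single nucleotides A/C/G/T")
  }
  calls <- calls[order(calls$pos), , drop = FALSE]
  rownames(calls) <- NULL
  structure(list(species_id = species_id, genome_length = genome_length,
                 calls = calls),
            class = "snv_profile")
}

#' @export
print.snv_profile <- function(x, ...) {
  cat(sprintf("<snv_profile> %s: %d calls over %s bp\n",
              x$species_id, nrow(x$calls), format(x$genome_length, big.mark = ",")))
  invisible(x)
}

#' Load an SNV profile from a VCF file
#'
#' Keeps one call per `PASS` (or unfiltered, `FILTER == "."`) biallelic
#' single-nucleotide record.  Indels, multi-allelic records and
#' soft-filtered records are skipped; the number skipped is attached as
#' attribute `n_skipped` and reported via [message()].
#'
#' @param path VCF 4.x file (plain or bgzipped).
#' @param species_id species/reference identifier for the profile.
#' @param genome_length reference length; if `NULL`, taken from the VCF
#'   `##contig` header.
#' @return an [snv_profile()].
#' @export
load_snv_profile <- function(path, species_id, genome_length = NULL) {
  if (!file.exists(path)) abort("VCF not found: %s", path)
  check_vcf_lines(path)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) abort("malformed VCF '%s': %s", path, conditionMessage(e))
  )
  if (is.null(genome_length)) {
    hdr <- VariantAnnotation::scanVcfHeader(path)
    sl <- GenomeInfoDb::seqlengths(hdr)
    sl <- sl[!is.na(sl)]
    if (!length(sl)) {
      abort("no ##contig length in %s; supply genome_length", path)
    }
    genome_length <- sum(as.numeric(sl))
  }
  n <- length(vcf)
  if (n == 0L) {
    prof <- snv_profile(species_id, genome_length,
                        data.frame(pos = integer(0), alt = character(0)))
    attr(prof, "n_skipped") <- 0L
    return(prof)
  }
  pos <- BiocGenerics::start(SummarizedExperiment::rowRanges(vcf))
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alts)
  alt1 <- rep(NA_character_, n)
  alt1[n_alt == 1L] <- as.character(unlist(alts[n_alt == 1L]))
  filt <- as.character(VariantAnnotation::filt(vcf))
  ok <- (is.na(filt) | filt %in% c("PASS", ".")) &
    n_alt == 1L & nchar(refs) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    alt1 %in% c("A", "C", "G", "T") & refs %in% c("A", "C", "G", "T")
  n_skipped <- sum(!ok)
  calls <- data.frame(pos = pos[ok], alt = alt1[ok])
  if (anyDuplicated(calls$pos)) {
    dup <- calls$pos[duplicated(calls$pos)][1L]
    abort("VCF '%s': conflicting calls at position %d", path, dup)
  }
  if (n_skipped > 0L) {
    message(sprintf("%s: skipped %d non-SNV/filtered record(s)",
                    basename(path), n_skipped))
  }
  prof <- snv_profile(species_id, genome_length, calls)
  attr(prof, "n_skipped") <- n_skipped
  prof
}

## Cheap structural validation so that a truncated/garbled VCF fails with
## the offending line number instead of an opaque parser error.
check_vcf_lines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con, warn = FALSE)
  close(con)
  if (!length(lines) || !startsWith(lines[[1L]], "##fileformat=VCF")) {
    abort("malformed VCF '%s' at line 1: missing ##fileformat header", path)
  }
  body <- which(!startsWith(lines, "#"))
  for (i in body) {
    if (length(strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]) < 8L) {
      abort("malformed VCF '%s' at line %d: fewer than 8 tab-separated fields",
            path, i)
    }
  }
  invisible(TRUE)
}

#' Write an SNV profile as a minimal VCF 4.2 file
#'
#' Emits a single-contig VCF carrying one row per call.  The reference
#' allele is unknown to the profile, so an `N`-free placeholder is
#' chosen deterministically as any base different from the alternate.
#'
#' @param profile an [snv_profile()].
#' @param path output path.
#' @param sample_id value for the VCF `##sample` meta line.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(profile, path, sample_id = "sample") {
  stopifnot(inherits(profile, "snv_profile"))
  ref_for <- c(A = "C", C = "A", G = "A", T = "A")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", profile$species_id,
                   as.integer(profile$genome_length)),
           sprintf("##sample=%s", sample_id),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- if (nrow(profile$calls)) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", profile$species_id,
            profile$calls$pos, ref_for[profile$calls$alt], profile$calls$alt)
  } else character(0)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Window-based SNV similarity of two samples
#'
#' The reference genome is tiled into consecutive non-overlapping windows
#' of `window` bases (1-based inclusive coordinates; the final partial
#' window is included).  Every window in which at least one profile has a
#' call contributes its Jaccard similarity over `(position, alt)` call
#' sets; the WSS score is 100 times the unweighted mean over these
#' informative windows.  Identical non-empty profiles therefore score
#' 100, profiles with no shared calls score 0.
#'
#' @param a,b [snv_profile()] objects on the same species reference.
#' @param window window width in bases (default 1000).
#' @param model optional [cutoff_model()]; when supplied the result also
#'   carries the related/unrelated call, otherwise relatedness is
#'   `NA` (undecided).
#' @return an object of class `wss_result` with fields `score` (0-100),
#'   `n_windows_used`, `related` (`TRUE`/`FALSE`/`NA`) and `species_id`.
#' @export
#' @examples
#' a <- snv_profile("sp", 3000, data.frame(pos = c(100, 1500), alt = c("T", "G")))
#' b <- snv_profile("sp", 3000, data.frame(pos = c(100, 2500), alt = c("T", "A")))
#' compute_wss(a, b)$score  # windows score 1, 0, 0 -> 33.33
compute_wss <- function(a, b, window = 1000L, model = NULL) {
  stopifnot(inherits(a, "snv_profile"), inherits(b, "snv_profile"))
  if (a$species_id != b$species_id) {
    abort("profiles are on different species references (%s vs %s)",
          a$species_id, b$species_id)
  }
  if (a$genome_length != b$genome_length) {
    abort("profiles disagree on genome length")
  }
  window <- as.integer(window)
  stopifnot(window >= 1L)
  key_a <- paste(a$calls$pos, a$calls$alt)
  key_b <- paste(b$calls$pos, b$calls$alt)
  win_a <- (a$calls$pos - 1L) %/% window
  win_b <- (b$calls$pos - 1L) %/% window
  wins <- sort(unique(c(win_a, win_b)))
  if (!length(wins)) abort("no informative windows")
  sims <- vapply(wins, function(w) {
    A <- key_a[win_a == w]
    B <- key_b[win_b == w]
    length(intersect(A, B)) / length(union(A, B))
  }, numeric(1))
  res <- structure(list(score = 100 * mean(sims),
                        n_windows_used = length(wins),
                        related = NA,
                        species_id = a$species_id),
                   class = "wss_result")
  if (!is.null(model)) res$related <- classify_pair(res, model) == "related"
  res
}

#' @export
print.wss_result <- function(x, ...) {
  rel <- if (is.na(x$related)) "undecided" else if (x$related) "related" else "unrelated"
  cat(sprintf("<wss_result> %s: score %.2f over %d window(s) [%s]\n",
              x$species_id, x$score, x$n_windows_used, rel))
  invisible(x)
}

#' Construct a per-species WSS cutoff model
#'
#' @param species_id species identifier.
#' @param cutoff WSS score threshold; pairs scoring strictly above it are
#'   called related.
#' @param n_related,n_unrelated calibration sample sizes.
#' @return an object of class `cutoff_model`.
#' @export
cutoff_model <- function(species_id, cutoff, n_related = NA_integer_,
                         n_unrelated = NA_integer_) {
  stopifnot(is.character(species_id), length(species_id) == 1L,
            is.numeric(cutoff), length(cutoff) == 1L)
  structure(list(species_id = species_id, cutoff = as.numeric(cutoff),
                 calibration_n = c(n_related = as.integer(n_related),
                                   n_unrelated = as.integer(n_unrelated))),
            class = "cutoff_model")
}

#' Calibrate a WSS relatedness cutoff from labelled score sets
#'
#' Candidate thresholds are the midpoints between consecutive sorted
#' unique pooled scores.  The returned cutoff maximizes Youden's J
#' (sensitivity with related pairs scoring strictly above the cutoff,
#' specificity with unrelated pairs scoring at or below it); ties are
#' broken toward the largest candidate, making the rule deterministic.
#'
#' @param related_scores WSS scores of known-related pairs (non-empty).
#' @param unrelated_scores WSS scores of known-unrelated pairs (non-empty).
#' @param species_id species identifier recorded in the model.
#' @return a [cutoff_model()].
#' @export
#' @examples
#' calibrate_cutoff(c(90, 95), c(40, 50), "sp")$cutoff  # 70
calibrate_cutoff <- function(related_scores, unrelated_scores, species_id) {
  if (!length(related_scores) || !length(unrelated_scores)) {
    abort("both related and unrelated score sets must be non-empty")
  }
  pooled <- sort(unique(c(related_scores, unrelated_scores)))
  if (length(pooled) < 2L) {
    abort("cannot calibrate: all pooled scores are identical")
  }
  cand <- (pooled[-1L] + pooled[-length(pooled)]) / 2
  j <- vapply(cand, function(ct) {
    mean(related_scores > ct) + mean(unrelated_scores <= ct) - 1
  }, numeric(1))
  best <- max(cand[j == max(j)])  # largest candidate among ties
  cutoff_model(species_id, best,
               n_related = length(related_scores),
               n_unrelated = length(unrelated_scores))
}

#' Classify a scored pair as related or unrelated
#'
#' A pair is related iff its WSS score is strictly above the species
#' cutoff.
#'
#' @param result a [compute_wss()] result.
#' @param model a [cutoff_model()] for the same species.
#' @return `"related"` or `"unrelated"`.
#' @export
classify_pair <- function(result, model) {
  stopifnot(inherits(result, "wss_result"), inherits(model, "cutoff_model"))
  if (!is.null(result$species_id) && result$species_id != model$species_id) {
    abort("cutoff model is for species %s, result is for species %s",
          model$species_id, result$species_id)
  }
  if (result$score > model$cutoff) "related" else "unrelated"
}

#' Read / write WSS cutoff tables
#'
#' Cutoff models are persisted as a 4-column TSV:
#' `species_id`, `cutoff`, `n_related`, `n_unrelated`.
#'
#' @param models list of [cutoff_model()] objects (write) .
#' @param path TSV path.
#' @return `write_cutoff_table()` returns `path` invisibly;
#'   `read_cutoff_table()` returns a named list of models keyed by
#'   species.
#' @export
write_cutoff_table <- function(models, path) {
  if (inherits(models, "cutoff_model")) models <- list(models)
  df <- data.frame(
    species_id = vapply(models, `[[`, "", "species_id"),
    cutoff = vapply(models, `[[`, 0, "cutoff"),
    n_related = vapply(models, function(m) m$calibration_n[["n_related"]], 0L),
    n_unrelated = vapply(models, function(m) m$calibration_n[["n_unrelated"]], 0L)
  )
  write_tsv_plain(df, path)
}

#' @rdname write_cutoff_table
#' @export
read_cutoff_table <- function(path) {
  df <- read_tsv_plain(path)
  need <- c("species_id", "cutoff")
  if (!all(need %in% names(df))) {
    abort("cutoff table %s lacks columns: %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    cutoff_model(df$species_id[i], df$cutoff[i],
                 n_related = if ("n_related" %in% names(df)) df$n_related[i] else NA,
                 n_unrelated = if ("n_unrelated" %in% names(df)) df$n_unrelated[i] else NA)
  })
  setNames(out, df$species_id)
}
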