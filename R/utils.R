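## Internal helpers shared across modules.

#' Evaluate an expression with a fixed, isolated RNG state
#'
#' The global `.Random.seed` is saved and restored, so seeded operations
#' never perturb (and are never perturbed by) the caller's random stream.
#' The RNG kind is pinned so that a given seed maps to the same draws on
#' every platform and R version that supports it.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

#' Round half away from zero
#'
#' Percentages in cohort summaries are rounded half-away-from-zero (the
#' convention used when printing e.g. 13/35 as 37.1), not to even as
#' [base::round()] does.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.25, 1)   # 0.3, where round() gives 0.2
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

## Plain TSV writer: no quoting, no row names, "." decimal -- keeps pipeline
## outputs byte-stable across runs.
write_tsv_plain <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_plain <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

## stop() without the call, with sprintf-style formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
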