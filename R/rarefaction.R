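## Rarefaction calibration: sweep subsampling depths, track the
## zero-difference percentage of related pairs, and pick the working depth
## where the curve levels off.

#' Zero-difference percentage across subsampling depths
#'
#' For each depth and repeat, every sample's reads are subsampled with
#' seed `base_seed + repeat_index` (repeat index starting at 0, so the
#' first pass uses `base_seed` itself), pushed through a caller-supplied
#' per-sample pipeline, scored pairwise by WSS, and — after dropping
#' unrelated pairs — summarized with [summarize_related_pairs()].  The
#' per-depth value is the mean zero-difference percentage over repeats.
#'
#' Read alignment and variant calling are outside this package, so the
#' downstream stage is pluggable: `pipeline(reads, sample_id)` must
#' return `list(snv = <snv_profile>, pathways = <character map IDs>)`
#' for the subsampled read set.
#'
#' @param samples named list: sample ID -> list of [read_record()]s.
#' @param pairs data.frame with columns `sample_a`, `sample_b`.
#' @param depths strictly increasing vector of at least 2 read depths.
#' @param repeats_per_depth number of seeded repeats per depth (>= 1).
#' @param base_seed integer; repeat r uses seed `base_seed + r - 1`.
#' @param pipeline function `(reads, sample_id) -> list(snv, pathways)`.
#' @param model [cutoff_model()] used to drop unrelated pairs.
#' @param window WSS window width in bases.
#' @return an object of class `depth_curve`: data.frame with columns
#'   `depth`, `pct_zero` (mean over repeats), `mean_wss`, `full`
#'   (depth exceeded the available reads of at least one sample), plus
#'   attribute `repeats` (per-depth list of per-repeat pct_zero).
#' @export
zero_diff_curve <- function(samples, pairs, depths, repeats_per_depth,
                            base_seed, pipeline, model, window = 1000L) {
  stopifnot(is.list(samples), !is.null(names(samples)),
            all(c("sample_a", "sample_b") %in% names(pairs)))
  depths <- as.numeric(depths)
  if (length(depths) < 2L || any(diff(depths) <= 0)) {
    abort("need >= 2 strictly increasing depths")
  }
  if (repeats_per_depth < 1L) abort("repeats_per_depth must be >= 1")
  rows <- vector("list", length(depths))
  rep_detail <- vector("list", length(depths))
  for (di in seq_along(depths)) {
    d <- depths[[di]]
    full <- any(vapply(samples, length, 0L) < d)
    pcts <- numeric(repeats_per_depth)
    wss_means <- numeric(repeats_per_depth)
    for (r in seq_len(repeats_per_depth)) {
      seed <- base_seed + r - 1L
      calls <- lapply(names(samples), function(sid) {
        sub <- subsample_reads(samples[[sid]], d, seed)
        pipeline(sub, sid)
      })
      names(calls) <- names(samples)
      wss <- numeric(nrow(pairs))
      related <- logical(nrow(pairs))
      for (i in seq_len(nrow(pairs))) {
        res <- compute_wss(calls[[pairs$sample_a[i]]]$snv,
                           calls[[pairs$sample_b[i]]]$snv, window = window)
        wss[i] <- res$score
        related[i] <- classify_pair(res, model) == "related"
      }
      wss_means[r] <- mean(wss)
      if (!any(related)) abort("depth %s, repeat %d: no related pairs", format(d), r)
      pr <- data.frame(sample_a = pairs$sample_a, sample_b = pairs$sample_b,
                       related = related)
      callsets <- lapply(names(calls), function(sid) {
        pathway_callset(sid, calls[[sid]]$pathways)
      })
      names(callsets) <- names(calls)
      lst <- build_standard_list(callsets, pr, model$species_id, d)
      profs <- lapply(callsets, make_pks_profile, list = lst)
      rel_idx <- which(related)
      diffs <- lapply(rel_idx, function(i) {
        pks_difference(profs[[pairs$sample_a[i]]], profs[[pairs$sample_b[i]]])
      })
      pcts[r] <- summarize_related_pairs(diffs)$pct_zero
    }
    rows[[di]] <- data.frame(depth = d, pct_zero = mean(pcts),
                             mean_wss = mean(wss_means), full = full)
    rep_detail[[di]] <- pcts
  }
  curve <- do.call(rbind, rows)
  names(rep_detail) <- format(depths, scientific = FALSE, trim = TRUE)
  structure(curve, repeats = rep_detail,
            class = c("depth_curve", "data.frame"))
}

#' Select a working subsampling depth from a depth curve
#'
#' Formalizes "the curve levels off": returns the smallest depth whose
#' mean zero-difference percentage is within `tol` percentage points of
#' the deepest depth's value.  An explicit `override` (e.g. the 5e6 reads
#' conventionally used) bypasses the plateau rule but must be one of the
#' curve's depths.
#'
#' @param curve a [zero_diff_curve()] result, or any data.frame with
#'   columns `depth`, `pct_zero`.
#' @param tol plateau tolerance in percentage points (default 1.0).
#' @param override optional depth to force.
#' @return the chosen depth (numeric scalar).
#' @export
select_depth <- function(curve, tol = 1.0, override = NULL) {
  stopifnot(is.data.frame(curve), all(c("depth", "pct_zero") %in% names(curve)))
  curve <- curve[order(curve$depth), , drop = FALSE]
  if (!is.null(override)) {
    if (!override %in% curve$depth) {
      abort("override depth %s is not on the curve", format(override))
    }
    return(as.numeric(override))
  }
  if (tol < 0) abort("tol must be >= 0")
  target <- curve$pct_zero[nrow(curve)]
  ok <- abs(curve$pct_zero - target) <= tol
  as.numeric(curve$depth[which(ok)[1L]])
}

#' Write / read a depth curve as TSV
#'
#' @param curve a [zero_diff_curve()] result.
#' @param path TSV path.
#' @return `write_depth_curve()` returns `path` invisibly;
#'   `read_depth_curve()` returns a `depth_curve` data.frame (repeat
#'   detail is not persisted).
#' @export
write_depth_curve <- function(curve, path) {
  write_tsv_plain(as.data.frame(curve), path)
}

#' @rdname write_depth_curve
#' @export
read_depth_curve <- function(path) {
  df <- read_tsv_plain(path)
  if (!all(c("depth", "pct_zero") %in% names(df))) {
    abort("depth curve %s needs columns depth, pct_zero", path)
  }
  structure(df, class = c("depth_curve", "data.frame"))
}
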