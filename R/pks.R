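## PKS core: standard pathway lists, binary presence/absence profiles,
## pairwise differences, cohort summaries, and identical-pattern clusters
## with extinction/reappearance/resolution annotation.

#' Construct a species-specific standard pathway list
#'
#' The fixed, lexicographically sorted axis along which binary PKS
#' profiles are compared, together with the read depth at which it was
#' established.
#'
#' @param species_id species identifier.
#' @param depth subsampling depth (reads) the list was built at.
#' @param map_ids character vector of pathway map IDs (deduplicated,
#'   stored sorted).
#' @return an object of class `standard_pathway_list`.
#' @export
standard_pathway_list <- function(species_id, depth, map_ids) {
  map_ids <- sort(unique(as.character(map_ids)))
  if (!length(map_ids)) abort("standard pathway list cannot be empty")
  structure(list(species_id = species_id, depth = as.numeric(depth),
                 map_ids = map_ids),
            class = "standard_pathway_list")
}

#' @export
print.standard_pathway_list <- function(x, ...) {
  cat(sprintf("<standard_pathway_list> %s @ %s reads: %d pathway(s)\n",
              x$species_id, format(x$depth, big.mark = ","), length(x$map_ids)))
  invisible(x)
}

#' Build a standard pathway list from related pairs
#'
#' Combines all pathways called in samples that participate only in
#' WSS-related pairs; any sample occurring in at least one unrelated pair
#' is excluded, as are its calls.
#'
#' @param callsets named list of [pathway_callset()] objects keyed by
#'   sample ID (or carrying matching `sample_id` fields).
#' @param pair_relatedness data.frame with columns `sample_a`,
#'   `sample_b`, `related` (logical).  Every sample in `callsets` must
#'   appear in at least one pair.
#' @param species_id,depth recorded on the resulting list.
#' @return a [standard_pathway_list()].
#' @export
build_standard_list <- function(callsets, pair_relatedness, species_id, depth) {
  stopifnot(is.data.frame(pair_relatedness),
            all(c("sample_a", "sample_b", "related") %in% names(pair_relatedness)))
  if (is.null(names(callsets))) {
    names(callsets) <- vapply(callsets, `[[`, "", "sample_id")
  }
  pr <- pair_relatedness
  pr$related <- as.logical(pr$related)
  all_samples <- names(callsets)
  in_pairs <- unique(c(pr$sample_a, pr$sample_b))
  missing <- setdiff(all_samples, in_pairs)
  if (length(missing)) {
    abort("sample(s) without a relatedness label: %s",
          paste(missing, collapse = ", "))
  }
  if (!any(pr$related)) abort("no related pairs: cannot build a standard list")
  tainted <- unique(c(pr$sample_a[!pr$related], pr$sample_b[!pr$related]))
  keep <- setdiff(all_samples, tainted)
  ids <- unique(unlist(lapply(callsets[keep], `[[`, "pathways")))
  if (!length(ids)) abort("related-pair samples contribute no pathways")
  standard_pathway_list(species_id, depth, ids)
}

#' Binary PKS profile of one sample
#'
#' Projects a pathway call set onto a standard pathway list: entry `i` is
#' 1 iff the i-th list pathway was called in the sample.  Called pathways
#' outside the list are ignored; their count is attached as attribute
#' `n_ignored` and reported via [message()].
#'
#' @param callset a [pathway_callset()].
#' @param list a [standard_pathway_list()].
#' @param day integer sampling day (used to order longitudinal series).
#' @return an object of class `pks_profile` with fields `sample_id`,
#'   `day`, `vector` (named 0/1 integer vector) and `list`.
#' @export
make_pks_profile <- function(callset, list, day = NA_integer_) {
  stopifnot(inherits(callset, "pathway_callset"),
            inherits(list, "standard_pathway_list"))
  vec <- as.integer(list$map_ids %in% callset$pathways)
  names(vec) <- list$map_ids
  n_ignored <- length(setdiff(callset$pathways, list$map_ids))
  if (n_ignored > 0L) {
    message(sprintf("%s: %d called pathway(s) outside the standard list ignored",
                    callset$sample_id, n_ignored))
  }
  structure(list(sample_id = callset$sample_id, day = as.integer(day),
                 vector = vec, list = list),
            class = c("pks_profile"), n_ignored = n_ignored)
}

#' Construct a PKS profile directly from a 0/1 vector
#'
#' Lower-level companion to [make_pks_profile()] used by generators and
#' grid readers.
#'
#' @param sample_id sample identifier.
#' @param day integer day.
#' @param vector 0/1 integer vector in `list$map_ids` order.
#' @param list a [standard_pathway_list()].
#' @return a `pks_profile`.
#' @export
pks_profile <- function(sample_id, day, vector, list) {
  stopifnot(inherits(list, "standard_pathway_list"))
  vector <- as.integer(vector)
  if (length(vector) != length(list$map_ids)) {
    abort("profile length %d != standard list length %d",
          length(vector), length(list$map_ids))
  }
  if (any(!vector %in% c(0L, 1L))) abort("PKS vector must be 0/1")
  names(vector) <- list$map_ids
  structure(list(sample_id = sample_id, day = as.integer(day),
                 vector = vector, list = list),
            class = "pks_profile")
}

#' @export
print.pks_profile <- function(x, ...) {
  cat(sprintf("<pks_profile> %s (day %s): %d/%d pathways present\n",
              x$sample_id, x$day, sum(x$vector), length(x$vector)))
  invisible(x)
}

same_list <- function(a, b) {
  identical(a$list$map_ids, b$list$map_ids) &&
    identical(a$list$species_id, b$list$species_id)
}

#' Pathway-level difference between two PKS profiles
#'
#' `n_diff` is the Hamming distance between the binary vectors; `delta`
#' records per-pathway signed change relative to `a` (+1 gain, -1 loss,
#' 0 unchanged).
#'
#' @param a,b [pks_profile()] objects on the same standard list.
#' @return an object of class `pair_difference` with fields `pair_id`,
#'   `n_diff`, `delta`.
#' @export
pks_difference <- function(a, b) {
  stopifnot(inherits(a, "pks_profile"), inherits(b, "pks_profile"))
  if (!same_list(a, b)) abort("profiles use different standard pathway lists")
  delta <- b$vector - a$vector
  structure(list(pair_id = paste(a$sample_id, b$sample_id, sep = "|"),
                 n_diff = sum(delta != 0L), delta = delta),
            class = "pair_difference")
}

#' @export
print.pair_difference <- function(x, ...) {
  cat(sprintf("<pair_difference> %s: %d discordant pathway(s) (%d gained, %d lost)\n",
              x$pair_id, x$n_diff, sum(x$delta == 1L), sum(x$delta == -1L)))
  invisible(x)
}

#' Summarize pathway differences over a set of related pairs
#'
#' Percentages are rounded half-away-from-zero to one decimal.
#' `shared_pattern_groups` collects groups (size >= 2) of pairs whose
#' signed per-pathway change patterns are identical; pairs with zero
#' changes are counted by `n_zero` and not grouped (every zero pair would
#' otherwise trivially "share" the all-zero pattern).
#'
#' @param diffs list of [pks_difference()] results (non-empty).
#' @return an object of class `pks_summary`: `n_pairs`, `n_zero`,
#'   `pct_zero`, `n_nonzero`, `pct_nonzero`, `shared_pattern_groups`
#'   (list of character vectors of pair IDs).
#' @export
#' @examples
#' # 13 zero-difference pairs among 35 related pairs -> pct_zero 37.1
summarize_related_pairs <- function(diffs) {
  if (!length(diffs)) abort("need at least one pair difference")
  stopifnot(all(vapply(diffs, inherits, logical(1), "pair_difference")))
  nd <- vapply(diffs, `[[`, 0L, "n_diff")
  n <- length(diffs)
  n_zero <- sum(nd == 0L)
  nonzero <- diffs[nd > 0L]
  sig <- vapply(nonzero, function(d) paste(d$delta, collapse = ","), "")
  groups <- split(vapply(nonzero, `[[`, "", "pair_id"), sig)
  groups <- unname(groups[vapply(groups, length, 0L) >= 2L])
  structure(list(n_pairs = n,
                 n_zero = n_zero,
                 pct_zero = round_half_up(100 * n_zero / n, 1),
                 n_nonzero = n - n_zero,
                 pct_nonzero = round_half_up(100 * (n - n_zero) / n, 1),
                 shared_pattern_groups = groups),
            class = "pks_summary")
}

#' @export
print.pks_summary <- function(x, ...) {
  cat(sprintf("<pks_summary> %d pair(s): %d (%.1f%%) with 0 changes, %d (%.1f%%) with changes; %d shared-pattern group(s)\n",
              x$n_pairs, x$n_zero, x$pct_zero, x$n_nonzero, x$pct_nonzero,
              length(x$shared_pattern_groups)))
  invisible(x)
}

#' Identical-pattern clusters in a longitudinal PKS series
#'
#' A cluster is a maximal group of two or more time points of one
#' individual carrying bitwise-identical PKS vectors.  For each cluster,
#' reappearance events count the maximal runs of intervening time points
#' carrying a different pattern between consecutive cluster members: a
#' pattern that goes extinct and comes back later contributes one event
#' per extinction episode.  The series is classified `shared` when at
#' least one cluster exists, else `unique`; it is `resolved` when the
#' final time point's pattern occurs exactly once in the whole series
#' (the clusters give way to a unique pattern).
#'
#' @param series list of [pks_profile()] objects of one individual on a
#'   common standard list, with at least 2 time points and strictly
#'   increasing days (the function sorts by day and then requires strict
#'   increase).
#' @return an object of class `cluster_report`: `clusters` (list of
#'   `list(pattern, days, reappearance_events)`),
#'   `cluster_membership_count`, `reappearance_events` (total),
#'   `classification` (`"shared"`/`"unique"`), `resolved`, `days`.
#' @export
find_clusters <- function(series) {
  if (length(series) < 2L) abort("need at least 2 time points")
  stopifnot(all(vapply(series, inherits, logical(1), "pks_profile")))
  days <- vapply(series, `[[`, 0L, "day")
  if (anyNA(days)) abort("all profiles need a day for cluster analysis")
  o <- order(days)
  series <- series[o]
  days <- days[o]
  if (any(diff(days) <= 0L)) abort("days must be strictly increasing")
  for (p in series[-1L]) {
    if (!same_list(series[[1L]], p)) abort("profiles use different standard lists")
  }
  pat <- vapply(series, function(p) paste(p$vector, collapse = ""), "")
  tab <- table(pat)
  shared_pats <- names(tab)[tab >= 2L]
  clusters <- lapply(shared_pats, function(pp) {
    idx <- which(pat == pp)
    ## gaps between consecutive members holding >= 1 intervening time point;
    ## intervening points necessarily carry a different pattern (clusters are
    ## maximal), so each gap is one extinction/reappearance episode
    reap <- sum(diff(idx) > 1L)
    list(pattern = pp, days = days[idx], reappearance_events = reap)
  })
  ## stable order: by first member day
  if (length(clusters)) {
    clusters <- clusters[order(vapply(clusters, function(cl) cl$days[1L], 0L))]
  }
  membership <- sum(vapply(clusters, function(cl) length(cl$days), 0L))
  structure(list(clusters = clusters,
                 cluster_membership_count = membership,
                 reappearance_events = sum(vapply(clusters, `[[`, 0L,
                                                  "reappearance_events")),
                 classification = if (length(clusters)) "shared" else "unique",
                 resolved = tab[[pat[length(pat)]]] == 1L,
                 days = days),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> %s: %d cluster(s), %d member time point(s), %d reappearance event(s), %s\n",
              x$classification, length(x$clusters), x$cluster_membership_count,
              x$reappearance_events,
              if (x$resolved) "resolved to a unique pattern" else "not resolved"))
  for (cl in x$clusters) {
    cat(sprintf("  days %s (%d reappearance event(s))\n",
                paste(cl$days, collapse = ", "), cl$reappearance_events))
  }
  invisible(x)
}
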