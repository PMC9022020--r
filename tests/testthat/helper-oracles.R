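## Independent brute-force oracles and small fixture builders.  These stay
## deliberately naive (plain loops, exhaustive enumeration) so they cannot
## share a bug with the implementation paths they check.

## Surviving length of a read under sliding-window trimming: walk every
## window start, compute its mean with a loop, cut at the first failure.
oracle_qc_survivor_length <- function(q, window_len, min_mean_q) {
  n <- length(q)
  if (n == 0) return(0L)
  if (n < window_len) {
    return(if (sum(q) / n < min_mean_q) 0L else n)
  }
  for (s in 1:(n - window_len + 1)) {
    m <- sum(q[s:(s + window_len - 1)]) / window_len
    if (m < min_mean_q) return(s - 1L)
  }
  n
}

## Per-window Jaccard mean, computed window by window from scratch.
oracle_wss <- function(a, b, window) {
  n_win <- ceiling(a$genome_length / window)
  sims <- c()
  for (w in seq_len(n_win) - 1) {
    lo <- w * window + 1
    hi <- (w + 1) * window
    in_a <- a$calls[a$calls$pos >= lo & a$calls$pos <= hi, ]
    in_b <- b$calls[b$calls$pos >= lo & b$calls$pos <= hi, ]
    if (nrow(in_a) == 0 && nrow(in_b) == 0) next
    ka <- paste(in_a$pos, in_a$alt, sep = "_")
    kb <- paste(in_b$pos, in_b$alt, sep = "_")
    sims <- c(sims, length(intersect(ka, kb)) / length(union(ka, kb)))
  }
  if (!length(sims)) stop("oracle: no informative windows")
  100 * mean(sims)
}

## Exhaustive minimum set cover over all subsets of the pathway list.
## Returns list(size, best_ids) where best_ids applies the same tie rule
## the contract states: max summed coverage, then lexicographic.
oracle_min_cover <- function(cover_sets, universe) {
  ids <- names(cover_sets)
  n <- length(cover_sets)
  best <- NULL
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    covered <- unique(unlist(cover_sets[sel]))
    if (!all(universe %in% covered)) next
    size <- length(sel)
    total <- sum(lengths(cover_sets[sel]))
    tup <- paste(sort(ids[sel]), collapse = "\r")
    cand <- list(size = size, total = total, tup = tup, ids = sort(ids[sel]))
    if (is.null(best) ||
        cand$size < best$size ||
        (cand$size == best$size && cand$total > best$total) ||
        (cand$size == best$size && cand$total == best$total && cand$tup < best$tup)) {
      best <- cand
    }
  }
  best
}

## Random fixtures ----------------------------------------------------------

rand_snv_profile <- function(genome_length, n_calls, species = "sp") {
  pos <- sort(sample.int(genome_length, n_calls))
  snv_profile(species, genome_length,
              data.frame(pos = pos,
                         alt = sample(c("A", "C", "G", "T"), n_calls,
                                      replace = TRUE)))
}

rand_pathway_instance <- function(n_pathways, n_ecs) {
  ecs <- sprintf("%d.%d.%d.%d", sample(1:6, n_ecs, TRUE),
                 sample(1:9, n_ecs, TRUE), sample(1:9, n_ecs, TRUE),
                 seq_len(n_ecs))
  entries <- lapply(seq_len(n_pathways), function(i) {
    sample(ecs, sample(1:min(4, n_ecs), 1))
  })
  names(entries) <- sprintf("map%05d", seq_len(n_pathways) * 10)
  list(db = pathway_db(entries),
       observed = sample(ecs, sample(1:n_ecs, 1)))
}

toy_list <- function(len = 5, species = "sp") {
  standard_pathway_list(species, 5e6, sprintf("map%05d", seq_len(len) * 10))
}

toy_profile <- function(vec, sample_id = "s", day = NA, list = NULL) {
  if (is.null(list)) list <- toy_list(length(vec))
  pks_profile(sample_id, day, vec, list)
}

make_read <- function(q, id = "r1") {
  read_record(id, paste(rep("A", length(q)), collapse = ""), q)
}

## n pair_difference objects with prescribed Hamming distances, built on a
## length-23 list by flipping leading positions.
diffs_with_counts <- function(n_diffs, len = 23) {
  lst <- toy_list(len)
  a <- toy_profile(rep(0L, len), "ref", 1, lst)
  lapply(seq_along(n_diffs), function(i) {
    v <- rep(0L, len)
    if (n_diffs[i] > 0) v[seq_len(n_diffs[i])] <- 1L
    pks_difference(a, toy_profile(v, sprintf("s%d", i), 2, lst))
  })
}
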