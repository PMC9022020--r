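## Synthetic fixtures with planted ground truth: pathway databases, strain
## SNV-profile pairs at controllable similarity, longitudinal PKS series
## with planted identical-pattern clusters, and whole on-disk cohorts.
## All generators take explicit seeds; none touch global random state.

#' Generate a random pathway database
#'
#' Draws `n_pathways` EC sets from a pool of `ec_pool_size` distinct EC
#' numbers.  A fraction `overlap_frac` of each pathway's enzymes comes
#' from a small shared sub-pool (so the expected pairwise overlap between
#' pathways tracks `overlap_frac`); the remainder is private to the
#' pathway and never reused.  `overlap_frac = 0` therefore yields
#' pairwise-disjoint EC sets, under which minimal set cover recovers a
#' planted pathway set uniquely.
#'
#' @param n_pathways number of pathways (>= 1).
#' @param ec_pool_size number of distinct EC numbers available.
#' @param overlap_frac fraction in \[0, 1\] of each pathway's ECs drawn
#'   from the shared sub-pool.
#' @param seed integer seed.
#' @param ecs_per_pathway EC set size per pathway (default 5).
#' @return a [pathway_db()] with map IDs `map00010`, `map00020`, ...
#' @export
generate_pathway_db <- function(n_pathways, ec_pool_size, overlap_frac, seed,
                                ecs_per_pathway = 5L) {
  stopifnot(n_pathways >= 1L, overlap_frac >= 0, overlap_frac <= 1)
  m <- as.integer(ecs_per_pathway)
  n_shared <- as.integer(round(overlap_frac * m))
  n_private <- m - n_shared
  shared_pool_size <- max(n_shared, 1L)
  need <- shared_pool_size + n_private * n_pathways
  if (ec_pool_size < need) {
    abort("ec_pool_size %d too small: need >= %d for %d pathway(s)",
          ec_pool_size, need, n_pathways)
  }
  with_seed(seed, {
    ## distinct EC strings d.d.d.d enumerated deterministically, then shuffled
    pool <- sprintf("%d.%d.%d.%d",
                    (seq_len(ec_pool_size) - 1L) %/% 1000L %% 6L + 1L,
                    (seq_len(ec_pool_size) - 1L) %/% 100L %% 10L + 1L,
                    (seq_len(ec_pool_size) - 1L) %/% 10L %% 10L + 1L,
                    (seq_len(ec_pool_size) - 1L) %% 10L + 1L)
    pool <- sample(pool)
    shared_pool <- pool[seq_len(shared_pool_size)]
    private_pool <- pool[-seq_len(shared_pool_size)]
    entries <- vector("list", n_pathways)
    for (i in seq_len(n_pathways)) {
      priv <- if (n_private > 0L) {
        private_pool[((i - 1L) * n_private + 1L):(i * n_private)]
      } else character(0)
      shr <- if (n_shared > 0L) sample(shared_pool, n_shared) else character(0)
      entries[[i]] <- c(shr, priv)
    }
    names(entries) <- sprintf("map%05d", seq_len(n_pathways) * 10L)
    pathway_db(entries)
  })
}

#' Generate a pair of strain SNV profiles at controlled similarity
#'
#' Emits two profiles on one synthetic species reference sharing exactly
#' `floor(shared_frac * n_snv)` `(position, alt)` calls; each profile's
#' remaining calls are private and placed at positions the other profile
#' does not use.  With `separate_windows = TRUE` the private calls of the
#' two profiles are confined to disjoint window sets, which forces a WSS
#' of exactly 0 when `shared_frac = 0`.
#'
#' @param genome_length reference length in bases.
#' @param n_snv calls per profile.
#' @param shared_frac fraction in \[0, 1\] of calls shared by the pair.
#' @param seed integer seed.
#' @param species_id reference identifier (default `"synthetic_sp"`).
#' @param separate_windows place private calls of the two profiles in
#'   disjoint genome windows of width `window`.
#' @param window window width used when `separate_windows = TRUE`.
#' @return `list(a = , b = )` of [snv_profile()] objects.
#' @export
generate_strain_pair <- function(genome_length, n_snv, shared_frac, seed,
                                 species_id = "synthetic_sp",
                                 separate_windows = FALSE, window = 1000L) {
  stopifnot(shared_frac >= 0, shared_frac <= 1, n_snv >= 1)
  n_shared <- as.integer(floor(shared_frac * n_snv))
  n_priv <- n_snv - n_shared
  with_seed(seed, {
    if (separate_windows) {
      n_win <- as.integer(ceiling(genome_length / window))
      if (n_win < 3L) abort("genome too short to separate windows")
      wins <- seq_len(n_win) - 1L
      shared_w <- wins[wins %% 3L == 0L]
      a_w <- wins[wins %% 3L == 1L]
      b_w <- wins[wins %% 3L == 2L]
      draw <- function(ws, k) {
        if (k == 0L) return(integer(0))
        cand <- unlist(lapply(ws, function(w) {
          lo <- w * window + 1L
          hi <- min((w + 1L) * window, genome_length)
          lo:hi
        }))
        sort(sample(cand, k))
      }
      pos_shared <- draw(shared_w, n_shared)
      pos_a <- draw(a_w, n_priv)
      pos_b <- draw(b_w, n_priv)
    } else {
      pos <- sort(sample.int(genome_length, n_shared + 2L * n_priv))
      pos <- sample(pos)  # decouple role from genomic order
      pos_shared <- pos[seq_len(n_shared)]
      pos_a <- pos[n_shared + seq_len(n_priv)]
      pos_b <- pos[n_shared + n_priv + seq_len(n_priv)]
    }
    alt_of <- function(pos) sample(c("A", "C", "G", "T"), length(pos),
                                   replace = TRUE)
    alt_shared <- alt_of(pos_shared)
    a <- snv_profile(species_id, genome_length,
                     data.frame(pos = c(pos_shared, pos_a),
                                alt = c(alt_shared, alt_of(pos_a))))
    b <- snv_profile(species_id, genome_length,
                     data.frame(pos = c(pos_shared, pos_b),
                                alt = c(alt_shared, alt_of(pos_b))))
    list(a = a, b = b)
  })
}

#' Generate a longitudinal PKS series with planted clusters
#'
#' Builds one individual's time series of binary pathway profiles whose
#' identical-pattern structure equals `cluster_spec` exactly: each
#' spec entry pins one pattern to its member days, and every remaining
#' day receives a globally unique pattern.  [find_clusters()] applied to
#' the emitted series must therefore recover the spec, including
#' reappearance counts and the resolved flag.
#'
#' @param days strictly increasing integer sampling days.
#' @param list_length length of the standard pathway list; must allow
#'   enough distinct 0/1 patterns for all clusters and singletons.
#' @param cluster_spec list of integer vectors of member days (each of
#'   length >= 2, pairwise disjoint, all in `days`).  Empty list plants
#'   no clusters.
#' @param seed integer seed.
#' @param species_id species recorded on the standard list.
#' @return `list(profiles, list, truth)` where `truth` is a
#'   `planted_truth` list with `cluster_days`, `reappearance_events`
#'   (per cluster and total), `classification` and `resolved`.
#' @export
generate_longitudinal_series <- function(days, list_length, cluster_spec,
                                         seed, species_id = "synthetic_sp") {
  days <- as.integer(days)
  if (length(days) < 2L || any(diff(days) <= 0L)) {
    abort("days must be >= 2 strictly increasing values")
  }
  cluster_spec <- lapply(cluster_spec, as.integer)
  members <- unlist(cluster_spec)
  if (length(members)) {
    if (any(!members %in% days)) abort("cluster member day not in days")
    if (anyDuplicated(members)) abort("cluster specs must be disjoint")
    if (any(vapply(cluster_spec, length, 0L) < 2L)) {
      abort("each cluster needs >= 2 member days")
    }
  }
  singles <- setdiff(days, members)
  n_patterns <- length(cluster_spec) + length(singles)
  if (2^list_length < n_patterns) {
    abort("list_length %d yields only %d patterns; need %d",
          list_length, 2^list_length, n_patterns)
  }
  lst <- standard_pathway_list(species_id, NA,
                               sprintf("map%05d", seq_len(list_length) * 10L))
  pats <- with_seed(seed, {
    seen <- character(0)
    out <- vector("list", n_patterns)
    for (i in seq_len(n_patterns)) {
      repeat {
        v <- sample(c(0L, 1L), list_length, replace = TRUE)
        key <- paste(v, collapse = "")
        if (!key %in% seen) { seen <- c(seen, key); out[[i]] <- v; break }
      }
    }
    out
  })
  pattern_of_day <- setNames(vector("list", length(days)), days)
  for (ci in seq_along(cluster_spec)) {
    for (d in cluster_spec[[ci]]) pattern_of_day[[as.character(d)]] <- pats[[ci]]
  }
  for (si in seq_along(singles)) {
    pattern_of_day[[as.character(singles[si])]] <-
      pats[[length(cluster_spec) + si]]
  }
  profiles <- lapply(seq_along(days), function(i) {
    pks_profile(sprintf("t%02d_d%d", i, days[i]), days[i],
                pattern_of_day[[as.character(days[i])]], lst)
  })
  reap <- vapply(cluster_spec, function(mem) {
    idx <- match(sort(mem), days)
    sum(diff(idx) > 1L)
  }, 0L)
  last_day <- days[length(days)]
  truth <- structure(list(
    cluster_days = lapply(cluster_spec, sort),
    reappearance_events = reap,
    total_reappearance_events = sum(reap),
    cluster_membership_count = length(members),
    classification = if (length(cluster_spec)) "shared" else "unique",
    resolved = !last_day %in% members
  ), class = "planted_truth")
  list(profiles = profiles, list = lst, truth = truth)
}

#' Generate an on-disk synthetic cohort for the pipeline
#'
#' Writes everything `run_longitudinal_analysis()` needs into `dir`:
#' per-sample FASTQ (small), VCF (SNV calls against one synthetic
#' species reference), GFF3 (EC-annotated genes realizing each sample's
#' planted pathway profile), a pathway DB TSV, a cutoff table, a samples
#' table, a YAML run config, and `truth.json` with the planted cluster
#' structure per individual.
#'
#' Strains are planted related within each individual: every sample
#' shares `shared_frac_related` of its SNV calls with the individual's
#' last sample.  The pathway DB is built with zero overlap so that
#' parsimony inference recovers each planted pathway set exactly.
#'
#' @param dir output directory (created if needed).
#' @param individuals named list: individual ID -> list with elements
#'   `days` (integer vector) and `cluster_spec` (as in
#'   [generate_longitudinal_series()]).
#' @param seed integer master seed; per-sample seeds derive from it.
#' @param list_length standard-list length (default 23, a typical
#'   species-specific pathway list size).
#' @param genome_length,n_snv,shared_frac_related strain-pair geometry.
#' @param n_reads small per-sample FASTQ size (default 60).
#' @param species_id synthetic species identifier.
#' @param cutoff WSS cutoff written to the cutoff table.  The default 60
#'   sits well below the ~85-90 WSS of pairs sharing 95% of their calls
#'   and far above the near-zero WSS of unrelated strains.
#' @return the run-config path, invisibly; attributes `truth` (list per
#'   individual) and `config` (parsed config list).
#' @export
simulate_cohort <- function(dir, individuals, seed, list_length = 23L,
                            genome_length = 50000L, n_snv = 150L,
                            shared_frac_related = 0.95, n_reads = 60L,
                            species_id = "synthetic_sp", cutoff = 60) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  db <- generate_pathway_db(list_length, ec_pool_size = list_length * 8L,
                            overlap_frac = 0, seed = seed + 1L,
                            ecs_per_pathway = 4L)
  db_path <- file.path(dir, "pathway_db.tsv")
  write_pathway_db(db, db_path)
  cut_path <- file.path(dir, "cutoffs.tsv")
  write_cutoff_table(cutoff_model(species_id, cutoff, 0L, 0L), cut_path)

  samples <- list()
  truth <- list()
  k <- 0L
  for (ind in names(individuals)) {
    spec <- individuals[[ind]]
    k <- k + 1L
    ser <- generate_longitudinal_series(spec$days, list_length,
                                        spec$cluster_spec,
                                        seed = seed + 100L * k,
                                        species_id = species_id)
    truth[[ind]] <- ser$truth
    n_t <- length(spec$days)
    ## one strain per individual: last sample's calls are the anchor;
    ## earlier samples share shared_frac_related of them
    anchor <- generate_strain_pair(genome_length, n_snv, 1, seed = seed + 100L * k + 50L,
                                   species_id = species_id)$a
    for (i in seq_len(n_t)) {
      sid <- sprintf("%s_d%03d", ind, spec$days[i])
      samp_seed <- seed + 1000L * k + i
      prof_snv <- if (i == n_t) anchor else {
        perturb_profile(anchor, shared_frac_related, samp_seed)
      }
      vcf <- file.path(dir, paste0(sid, ".vcf"))
      write_snv_vcf(prof_snv, vcf, sample_id = sid)
      present <- ser$list$map_ids[ser$profiles[[i]]$vector == 1L]
      gff <- file.path(dir, paste0(sid, ".gff"))
      write_ec_gff(unlist(db[present], use.names = FALSE), gff)
      fq <- file.path(dir, paste0(sid, ".fastq"))
      write_fastq(random_reads(n_reads, samp_seed), fq)
      samples[[length(samples) + 1L]] <- data.frame(
        individual = ind, sample_id = sid, day = spec$days[i],
        fastq = basename(fq), vcf = basename(vcf), gff = basename(gff))
    }
  }
  st <- do.call(rbind, samples)
  st_path <- file.path(dir, "samples.tsv")
  write_tsv_plain(st, st_path)

  config <- list(species_id = species_id,
                 genome_length = genome_length,
                 pathway_db = "pathway_db.tsv",
                 cutoff_table = "cutoffs.tsv",
                 samples = "samples.tsv",
                 reference = "last",
                 depth = 5e6,
                 seed = 1000,
                 window = 1000)
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  jsonlite::write_json(
    lapply(truth, function(tr) {
      list(cluster_days = tr$cluster_days,
           reappearance_events = tr$reappearance_events,
           classification = tr$classification,
           resolved = tr$resolved)
    }),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(structure(cfg_path, truth = truth, config = config))
}

## Re-draw (1 - frac) of a profile's calls at unused positions: the result
## shares exactly floor(frac * n) calls with `anchor`.
perturb_profile <- function(anchor, frac, seed) {
  n <- nrow(anchor$calls)
  n_keep <- as.integer(floor(frac * n))
  with_seed(seed, {
    keep <- sort(sample.int(n, n_keep))
    free <- setdiff(seq_len(anchor$genome_length), anchor$calls$pos)
    new_pos <- sample(free, n - n_keep)
    snv_profile(anchor$species_id, anchor$genome_length,
                data.frame(pos = c(anchor$calls$pos[keep], new_pos),
                           alt = c(anchor$calls$alt[keep],
                                   sample(c("A", "C", "G", "T"), n - n_keep,
                                          replace = TRUE))))
  })
}

## Tiny synthetic read set (uniform bases, high quality) for QC/subsampling.
random_reads <- function(n, seed, len = 80L) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      read_record(sprintf("sr%04d", i),
                  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                        collapse = ""),
                  rep(35L, len))
    })
  })
}

## GFF3 with one CDS per EC number, Prokka-style eC_number attributes.
write_ec_gff <- function(ecs, path) {
  n <- length(ecs)
  lines <- "##gff-version 3"
  if (n) {
    starts <- (seq_len(n) - 1L) * 120L + 1L
    lines <- c(lines, sprintf(
      "ctg1\tsynthetic\tCDS\t%d\t%d\t.\t+\t0\tID=gene%04d;eC_number=%s;product=synthetic enzyme",
      starts, starts + 89L, seq_len(n), ecs))
  }
  writeLines(lines, path)
  invisible(path)
}
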