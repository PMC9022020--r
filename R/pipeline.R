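## Cohort pipeline: QC -> subsample -> WSS -> pathway inference -> PKS ->
## cluster report, driven by a YAML run config, with deterministic outputs.

#' Read and validate a run configuration
#'
#' The YAML config names a species, a pathway DB, a WSS cutoff table and
#' a samples table (`individual`, `sample_id`, `day`, `vcf`, `gff`,
#' optional `fastq`).  Relative paths resolve against the config file's
#' directory.  Days must be unique within an individual and all
#' referenced files must exist.
#'
#' @param path YAML config path.
#' @return a validated config list with absolute paths and the parsed
#'   samples data.frame in `$samples_df`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort("config not found: %s", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  for (fld in c("species_id", "pathway_db", "cutoff_table", "samples")) {
    if (is.null(cfg[[fld]])) abort("config lacks required field '%s'", fld)
  }
  cfg$pathway_db <- resolve(cfg$pathway_db)
  cfg$cutoff_table <- resolve(cfg$cutoff_table)
  cfg$samples <- resolve(cfg$samples)
  cfg$reference <- cfg$reference %||% "last"
  cfg$depth <- cfg$depth %||% 5e6
  cfg$seed <- cfg$seed %||% 1000
  cfg$window <- cfg$window %||% 1000
  for (p in c(cfg$pathway_db, cfg$cutoff_table, cfg$samples)) {
    if (!file.exists(p)) abort("config references absent file: %s", p)
  }
  st <- read_tsv_plain(cfg$samples)
  need <- c("individual", "sample_id", "day", "vcf", "gff")
  if (!all(need %in% names(st))) {
    abort("samples table lacks columns: %s",
          paste(setdiff(need, names(st)), collapse = ", "))
  }
  for (col in intersect(c("vcf", "gff", "fastq"), names(st))) {
    st[[col]] <- resolve(st[[col]])
    missing <- st[[col]][!file.exists(st[[col]])]
    if (length(missing)) abort("absent input file(s): %s",
                               paste(missing, collapse = ", "))
  }
  dup <- vapply(split(st$day, st$individual), anyDuplicated, 0L)
  if (any(dup > 0L)) {
    abort("duplicate days for individual(s): %s",
          paste(names(dup)[dup > 0L], collapse = ", "))
  }
  cfg$samples_df <- st
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the longitudinal strain/PKS analysis for a cohort
#'
#' For each individual, every sample is paired with the reference sample
#' (the last day's by default) and scored by WSS; unrelated pairs are
#' flagged and excluded from all PKS summaries.  Pathway call sets are
#' inferred per sample by minimal set cover over the configured DB, a
#' cohort standard pathway list is built from samples in related pairs
#' only, and each individual's series is scanned for identical-pattern
#' clusters.  When the samples table carries a `fastq` column, reads are
#' quality-filtered and subsampled (seeded) first and the accounting is
#' logged; variant and gene annotations are consumed from the supplied
#' VCF/GFF regardless, since alignment and calling are outside this
#' package.
#'
#' Outputs in `out_dir`: `wss.tsv`, `pks_grid.tsv`, `clusters.json`,
#' `summary.tsv`, `run.log`.  Re-running with the same config and seed
#' writes byte-identical files (the log carries no timestamps).
#'
#' @param config a config list from [read_run_config()] or the YAML path.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `wss` (data.frame), `standard_list`,
#'   `profiles`, `summary`, `clusters` (per individual), `out_dir`.
#' @export
run_longitudinal_analysis <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  note("pkstrack run: species=%s depth=%s seed=%s window=%s reference=%s",
       config$species_id, format(config$depth, scientific = FALSE),
       config$seed, config$window, config$reference)

  models <- read_cutoff_table(config$cutoff_table)
  model <- models[[config$species_id]]
  if (is.null(model)) {
    abort(paste0("no WSS cutoff for species '%s' in %s; ",
                 "calibrate one with calibrate_cutoff() first"),
          config$species_id, config$cutoff_table)
  }
  db <- read_pathway_db(config$pathway_db)
  st <- config$samples_df
  st <- st[order(st$individual, st$day), , drop = FALSE]

  ## optional read QC/subsampling stage
  if ("fastq" %in% names(st)) {
    for (i in seq_len(nrow(st))) {
      reads <- read_fastq(st$fastq[i])
      kept <- qc_filter_reads(reads)
      sub <- subsample_reads(kept, config$depth, config$seed)
      note("reads %s: %d in, %d after QC, %d after subsample%s",
           st$sample_id[i], length(reads), length(kept), length(sub),
           if (length(kept) < config$depth) " (depth marked full)" else "")
    }
  }

  ## per-sample SNV profiles and pathway call sets
  snvs <- list(); callsets <- list()
  for (i in seq_len(nrow(st))) {
    sid <- st$sample_id[i]
    prof <- withCallingHandlers(
      load_snv_profile(st$vcf[i], config$species_id,
                       genome_length = config$genome_length),
      message = function(m) {
        note("vcf %s: %s", sid, trimws(conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
    snvs[[sid]] <- prof
    ecs <- extract_ec_from_gff(st$gff[i])
    callsets[[sid]] <- minimal_pathway_set(ecs, db, sample_id = sid)
    note("sample %s: %d SNV call(s), %d EC(s), %d pathway(s), %d orphan EC(s)",
         sid, nrow(prof$calls), length(ecs),
         length(callsets[[sid]]$pathways), length(callsets[[sid]]$orphan_ecs))
  }

  ## pairs against the per-individual reference sample
  wss_rows <- list()
  for (ind in unique(st$individual)) {
    sub <- st[st$individual == ind, , drop = FALSE]
    ref_id <- switch(config$reference,
                     last = sub$sample_id[which.max(sub$day)],
                     first = sub$sample_id[which.min(sub$day)],
                     config$reference)
    if (!ref_id %in% sub$sample_id) {
      abort("reference sample '%s' not found for individual %s", ref_id, ind)
    }
    for (sid in setdiff(sub$sample_id, ref_id)) {
      res <- compute_wss(snvs[[sid]], snvs[[ref_id]], window = config$window)
      rel <- classify_pair(res, model)
      wss_rows[[length(wss_rows) + 1L]] <- data.frame(
        individual = ind, sample_a = sid, sample_b = ref_id,
        score = round(res$score, 4), n_windows = res$n_windows_used,
        related = rel == "related")
      if (rel != "related") {
        note("pair %s|%s: WSS %.2f <= cutoff %.2f, excluded as unrelated",
             sid, ref_id, res$score, model$cutoff)
      }
    }
  }
  wss_df <- do.call(rbind, wss_rows)
  if (is.null(wss_df) || !nrow(wss_df)) abort("no sample pairs to analyse")

  lst <- build_standard_list(callsets, wss_df, config$species_id, config$depth)
  note("standard pathway list: %d pathway(s) at depth %s",
       length(lst$map_ids), format(config$depth, scientific = FALSE))

  tainted <- unique(c(wss_df$sample_a[!wss_df$related],
                      wss_df$sample_b[!wss_df$related]))
  profiles <- list()
  for (sid in names(callsets)) {
    if (sid %in% tainted) next
    day <- st$day[match(sid, st$sample_id)]
    profiles[[sid]] <- withCallingHandlers(
      make_pks_profile(callsets[[sid]], lst, day = day),
      message = function(m) {
        note("pks %s: %s", sid, trimws(conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
  }

  rel_pairs <- wss_df[wss_df$related, , drop = FALSE]
  diffs <- lapply(seq_len(nrow(rel_pairs)), function(i) {
    pks_difference(profiles[[rel_pairs$sample_a[i]]],
                   profiles[[rel_pairs$sample_b[i]]])
  })
  summ <- summarize_related_pairs(diffs)

  clusters <- list()
  for (ind in unique(st$individual)) {
    ids <- st$sample_id[st$individual == ind]
    series <- profiles[intersect(ids, names(profiles))]
    if (length(series) < 2L) {
      note("individual %s: <2 related samples, no cluster analysis", ind)
      clusters[[ind]] <- NULL
      next
    }
    clusters[[ind]] <- find_clusters(unname(series))
  }

  ## ---- outputs ----------------------------------------------------------
  write_tsv_plain(wss_df, file.path(out_dir, "wss.tsv"))
  render_grid(unname(profiles), file.path(out_dir, "pks_grid.tsv"))
  jsonlite::write_json(
    lapply(clusters, function(cr) {
      list(classification = cr$classification,
           resolved = cr$resolved,
           cluster_membership_count = cr$cluster_membership_count,
           reappearance_events = cr$reappearance_events,
           clusters = lapply(cr$clusters, function(cl) {
             list(pattern = cl$pattern, days = cl$days,
                  reappearance_events = cl$reappearance_events)
           }))
    }),
    file.path(out_dir, "clusters.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  sum_df <- data.frame(
    metric = c("n_pairs", "n_related", "n_unrelated", "n_zero", "pct_zero",
               "n_nonzero", "pct_nonzero", "n_shared_pattern_groups",
               "n_standard_pathways"),
    value = c(nrow(wss_df), sum(wss_df$related), sum(!wss_df$related),
              summ$n_zero, summ$pct_zero, summ$n_nonzero, summ$pct_nonzero,
              length(summ$shared_pattern_groups), length(lst$map_ids)))
  write_tsv_plain(sum_df, file.path(out_dir, "summary.tsv"))
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(wss = wss_df, standard_list = lst, profiles = profiles,
                 summary = summ, clusters = clusters, out_dir = out_dir))
}

#' Write / read a binary PKS grid
#'
#' The grid mirrors the usual published layout: one row per pathway map
#' ID (standard-list order), one column per sample ordered by day, cells
#' 0/1.  Column headers encode `sample_id|day` so the grid round-trips
#' losslessly to [pks_profile()] objects.
#'
#' @param profiles list of [pks_profile()]s on one standard list.
#' @param path TSV path.
#' @return `render_grid()` returns `path` invisibly; `read_grid()`
#'   returns a list of `pks_profile`s.
#' @export
render_grid <- function(profiles, path) {
  stopifnot(length(profiles) >= 1L)
  for (p in profiles[-1L]) {
    if (!same_list(profiles[[1L]], p)) abort("profiles use different standard lists")
  }
  ids <- vapply(profiles, `[[`, "", "sample_id")
  if (any(grepl("|", ids, fixed = TRUE))) abort("sample IDs must not contain '|'")
  days <- vapply(profiles, `[[`, 0L, "day")
  o <- order(days, ids)
  profiles <- profiles[o]
  mat <- vapply(profiles, `[[`, integer(length(profiles[[1L]]$vector)), "vector")
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
  df <- data.frame(map_id = profiles[[1L]]$list$map_ids, mat,
                   check.names = FALSE)
  names(df)[-1L] <- sprintf("%s|%d", vapply(profiles, `[[`, "", "sample_id"),
                            vapply(profiles, `[[`, 0L, "day"))
  write_tsv_plain(df, path)
}

#' @rdname render_grid
#' @param species_id,depth metadata for the reconstructed standard list.
#' @export
read_grid <- function(path, species_id = "unknown", depth = NA) {
  df <- read_tsv_plain(path)
  if (names(df)[1L] != "map_id") abort("grid %s must start with a map_id column", path)
  lst <- standard_pathway_list(species_id, depth, df$map_id)
  ## constructor sorts map IDs; re-order rows to match
  ord <- match(lst$map_ids, df$map_id)
  lapply(names(df)[-1L], function(cn) {
    parts <- strsplit(cn, "|", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) abort("grid column '%s' is not sample_id|day", cn)
    pks_profile(parts[1L], as.integer(parts[2L]), df[[cn]][ord], lst)
  })
}
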