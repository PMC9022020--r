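## EC-number extraction from GFF3 annotations and parsimonious pathway
## inference (minimum set cover, the "minpath = 1" rule).

EC_REGEX <- "^[0-9]+\\.([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|-)$"

#' Construct a pathway database
#'
#' Maps pathway identifiers (KEGG map IDs such as `"map00010"`) to
#' non-empty sets of EC numbers.  Partial EC numbers with trailing
#' dashes (`"2.7.1.-"`) are allowed and match full ECs by prefix.
#'
#' @param entries named list; names are map IDs, elements character
#'   vectors of EC numbers.
#' @return an object of class `pathway_db`.
#' @export
pathway_db <- function(entries) {
  stopifnot(is.list(entries), length(names(entries)) == length(entries))
  if (anyDuplicated(names(entries))) abort("duplicate map IDs in pathway DB")
  entries <- lapply(entries, function(x) sort(unique(as.character(x))))
  if (any(vapply(entries, length, 0L) == 0L)) {
    abort("pathway DB contains an empty EC set")
  }
  bad <- unlist(entries)[!grepl(EC_REGEX, unlist(entries))]
  if (length(bad)) abort("invalid EC number(s): %s", paste(unique(bad), collapse = ", "))
  structure(entries[order(names(entries))], class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("<pathway_db> %d pathway(s), %d distinct EC number(s)\n",
              length(x), length(unique(unlist(x)))))
  invisible(x)
}

#' Read / write a pathway database as two-column TSV
#'
#' One `(map_id, ec_number)` pair per line, header `map_id<TAB>ec_number`.
#'
#' @param db a [pathway_db()] (write).
#' @param path TSV path.
#' @return `read_pathway_db()` returns a `pathway_db`;
#'   `write_pathway_db()` returns `path` invisibly.
#' @export
read_pathway_db <- function(path) {
  df <- read_tsv_plain(path)
  if (!all(c("map_id", "ec_number") %in% names(df))) {
    abort("pathway DB %s must have columns map_id, ec_number", path)
  }
  pathway_db(split(df$ec_number, df$map_id))
}

#' @rdname read_pathway_db
#' @export
write_pathway_db <- function(db, path) {
  stopifnot(inherits(db, "pathway_db"))
  df <- data.frame(
    map_id = rep(names(db), vapply(db, length, 0L)),
    ec_number = unlist(db, use.names = FALSE)
  )
  write_tsv_plain(df, path)
}

#' Extract EC numbers from a GFF3 annotation
#'
#' Collects the set of values of the `eC_number` attribute across all
#' features (the attribute Prokka writes on enzyme-annotated CDS).
#' Duplicates collapse: downstream pathway inference uses presence, not
#' abundance.
#'
#' @param path GFF3 file path.
#' @return sorted character vector of unique EC numbers (possibly empty).
#' @export
extract_ec_from_gff <- function(path) {
  if (!file.exists(path)) abort("GFF not found: %s", path)
  check_gff_lines(path)
  g <- tryCatch(rtracklayer::readGFF(path),
                error = function(e) abort("malformed GFF '%s': %s", path,
                                          conditionMessage(e)))
  if (!"eC_number" %in% names(g)) return(character(0))
  ec <- g$eC_number
  if (is.list(ec)) ec <- unlist(ec, use.names = FALSE)  # multi-valued attrs
  sort(unique(ec[!is.na(ec) & nzchar(ec)]))
}

## Structural pre-check: every non-comment, non-FASTA line needs 9 columns
## and a parseable attribute column; report the first offending line number.
check_gff_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  in_fasta <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, "##FASTA")) in_fasta <- TRUE
    if (in_fasta || startsWith(ln, "#") || !nzchar(ln)) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 9L) {
      abort("malformed GFF '%s' at line %d: expected 9 tab-separated columns",
            path, i)
    }
    attrs <- strsplit(fields[[9L]], ";", fixed = TRUE)[[1L]]
    attrs <- attrs[nzchar(trimws(attrs))]
    if (length(attrs) && any(!grepl("=", attrs, fixed = TRUE))) {
      abort("malformed GFF '%s' at line %d: attribute without key=value",
            path, i)
    }
  }
  invisible(TRUE)
}

## TRUE where a database EC (possibly dashed) matches an observed EC.
## Fields are compared position-wise; a dash on either side is a wildcard,
## so "2.7.1.-" covers "2.7.1.1" (and vice versa).
ec_matches <- function(db_ec, obs_ec) {
  a <- strsplit(db_ec, ".", fixed = TRUE)[[1L]]
  b <- strsplit(obs_ec, ".", fixed = TRUE)[[1L]]
  if (length(a) != 4L || length(b) != 4L) return(FALSE)
  all(a == b | a == "-" | b == "-")
}

#' Construct a per-sample pathway call set
#'
#' @param sample_id sample identifier.
#' @param pathways character vector of called map IDs.
#' @param covered_ecs observed EC numbers explained by the called set.
#' @param orphan_ecs observed EC numbers matching no pathway in the DB.
#' @return an object of class `pathway_callset`.
#' @export
pathway_callset <- function(sample_id, pathways, covered_ecs = character(0),
                            orphan_ecs = character(0)) {
  structure(list(sample_id = sample_id,
                 pathways = sort(unique(as.character(pathways))),
                 covered_ecs = sort(unique(as.character(covered_ecs))),
                 orphan_ecs = sort(unique(as.character(orphan_ecs)))),
            class = "pathway_callset")
}

#' @export
print.pathway_callset <- function(x, ...) {
  cat(sprintf("<pathway_callset> %s: %d pathway(s), %d EC(s) covered, %d orphan(s)\n",
              x$sample_id, length(x$pathways), length(x$covered_ecs),
              length(x$orphan_ecs)))
  invisible(x)
}

#' Minimal pathway set explaining the observed enzymes
#'
#' Parsimonious pathway inference in the spirit of MinPath: among all
#' subsets of the database that cover every observed EC matched by at
#' least one pathway, return one of minimum cardinality.  Observed ECs
#' matching no database entry are reported as orphans and never influence
#' the cover.  Ties between minimum covers are broken deterministically:
#' first by maximal total observed-EC coverage summed over the selected
#' pathways (counting an EC once per pathway that carries it), then by
#' the lexicographically smallest sorted tuple of map IDs.
#'
#' The solver is an exact branch and bound (always branching on the
#' uncovered EC with fewest covering pathways), followed by enumeration
#' of all covers at the optimal cardinality to apply the tie rule.
#'
#' @param observed character vector of observed EC numbers.
#' @param db a [pathway_db()].
#' @param sample_id identifier stored on the returned call set.
#' @return a [pathway_callset()].
#' @export
#' @examples
#' db <- pathway_db(list(P1 = c("1.1.1.1", "2.2.2.2"), P2 = "1.1.1.1",
#'                       P3 = c("2.2.2.2", "3.3.3.3")))
#' minimal_pathway_set(c("1.1.1.1", "2.2.2.2"), db)$pathways  # "P1"
minimal_pathway_set <- function(observed, db, sample_id = "sample") {
  stopifnot(inherits(db, "pathway_db"))
  observed <- sort(unique(as.character(observed)))
  ids <- names(db)
  ## coverage[[p]] = indices of observed ECs pathway p explains
  coverage <- lapply(db, function(ecs) {
    which(vapply(observed, function(e) {
      any(vapply(ecs, ec_matches, logical(1), obs_ec = e))
    }, logical(1)))
  })
  coverable <- sort(unique(unlist(coverage)))
  orphans <- setdiff(seq_along(observed), coverable)
  if (!length(coverable)) {
    return(pathway_callset(sample_id, character(0), character(0),
                           observed[orphans]))
  }
  useful <- which(vapply(coverage, length, 0L) > 0L)
  cov <- coverage[useful]
  sel_ids <- ids[useful]

  ## -- phase 1: minimum cover cardinality ---------------------------------
  universe <- coverable
  best_k <- length(cov)  # trivial upper bound: every useful pathway
  n_cover_of <- function(uncovered) {
    ## branch on the EC with fewest remaining covering pathways
    counts <- vapply(uncovered, function(e) {
      sum(vapply(cov, function(s) e %in% s, logical(1)))
    }, 0L)
    uncovered[which.min(counts)]
  }
  search_min <- function(uncovered, depth) {
    if (!length(uncovered)) {
      best_k <<- min(best_k, depth)
      return(invisible(NULL))
    }
    max_gain <- max(vapply(cov, function(s) length(intersect(s, uncovered)), 0L))
    if (depth + ceiling(length(uncovered) / max_gain) >= best_k) {
      return(invisible(NULL))  # cannot beat the incumbent
    }
    e <- n_cover_of(uncovered)
    for (p in which(vapply(cov, function(s) e %in% s, logical(1)))) {
      search_min(setdiff(uncovered, cov[[p]]), depth + 1L)
    }
    invisible(NULL)
  }
  search_min(universe, 0L)

  ## -- phase 2: enumerate covers at cardinality best_k, apply tie rule ----
  best <- NULL  # list(coverage_total, ids)
  consider <- function(sel) {
    total <- sum(vapply(cov[sel], length, 0L))
    tup <- sort(sel_ids[sel])
    if (is.null(best) || total > best$total ||
        (total == best$total &&
         paste(tup, collapse = "\r") < paste(best$ids, collapse = "\r"))) {
      best <<- list(total = total, ids = tup)
    }
  }
  enumerate <- function(uncovered, sel) {
    if (!length(uncovered)) {
      if (length(sel) == best_k) consider(sel)
      return(invisible(NULL))
    }
    if (length(sel) >= best_k) return(invisible(NULL))
    max_gain <- max(vapply(cov, function(s) length(intersect(s, uncovered)), 0L))
    if (length(sel) + ceiling(length(uncovered) / max_gain) > best_k) {
      return(invisible(NULL))
    }
    e <- n_cover_of(uncovered)
    for (p in which(vapply(cov, function(s) e %in% s, logical(1)))) {
      if (p %in% sel) next
      enumerate(setdiff(uncovered, cov[[p]]), c(sel, p))
    }
    invisible(NULL)
  }
  enumerate(universe, integer(0))

  pathway_callset(sample_id, best$ids,
                  covered_ecs = observed[coverable],
                  orphan_ecs = observed[orphans])
}
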