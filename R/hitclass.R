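#' Read a blast-tabular hit table with an optional lineage map
#'
#' The hit table is the 12-column tabular dialect
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore`), headerless. The lineage TSV maps `sseqid` to
#' ranked labels (`phylum class order family genus`; header row). When
#' given, lineage columns are joined onto the hits.
#'
#' @param path hit table path.
#' @param lineage_path optional lineage TSV path.
#' @return data.frame of hits (plus lineage columns when joined).
#' @export
read_hit_table <- function(path, lineage_path = NULL) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  hits <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(hits) != 12) {
    stop(sprintf("expected 12 tab-separated columns, found %d", ncol(hits)),
         call. = FALSE)
  }
  names(hits) <- cols
  if (!is.null(lineage_path)) {
    lin <- read.delim(lineage_path, stringsAsFactors = FALSE)
    hits <- merge(hits, lin, by = "sseqid", all.x = TRUE, sort = FALSE)
    hits <- hits[, c(cols, setdiff(names(lin), "sseqid"))]
  }
  hits
}

check_single_query <- function(hits) {
  if (nrow(hits) == 0) stop("empty hit list", call. = FALSE)
  if (length(unique(hits$qseqid)) != 1) {
    stop("hits must share a single query", call. = FALSE)
  }
}

#' Rank hits of one query
#'
#' Total order: bit score descending, ties by E-value ascending, then
#' subject id lexicographic.
#'
#' @param hits data.frame of hits sharing one `qseqid`.
#' @return the same data.frame, reordered.
#' @export
rank_hits <- function(hits) {
  check_single_query(hits)
  hits[order(-hits$bitscore, hits$evalue, hits$sseqid), , drop = FALSE]
}

#' Vote a taxonomic call from ranked hits
#'
#' The rule: a phylum is assigned iff the top `min(10, n)` hits carry
#' one identical non-missing phylum and at least `min_hits` hits exist;
#' class, family and genus are each assignable iff a single non-missing
#' taxon strictly exceeds half of the top `min(30, n)` hits. The
#' deepest assignable rank is reported; queries with fewer than
#' `min_hits` hits are unassigned.
#'
#' @param ranked hits of one query, already ordered by [rank_hits()]
#'   (re-ranked defensively here).
#' @param min_hits minimum evidence (default 10).
#' @return list `taxonomy_call`: `query_id`, `rank`, `taxon` (or both
#'   `"unassigned"`), `n_considered`, `n_agreeing`.
#' @export
vote_taxonomy <- function(ranked, min_hits = 10L) {
  check_single_query(ranked)
  ranked <- rank_hits(ranked)
  q <- ranked$qseqid[1]
  n <- nrow(ranked)
  unassigned <- structure(
    list(query_id = q, rank = "unassigned", taxon = "unassigned",
         n_considered = n, n_agreeing = 0L),
    class = "taxonomy_call")
  if (n < min_hits) return(unassigned)
  present <- function(x) !is.na(x) & x != ""
  call_at <- NULL
  # deepest first: genus, family, class (strict majority of top 30)
  top30 <- head(ranked, 30L)
  for (rank in c("genus", "family", "class")) {
    if (!rank %in% names(ranked)) next
    vals <- top30[[rank]][present(top30[[rank]])]
    if (length(vals) == 0) next
    tab <- sort(table(vals), decreasing = TRUE)
    if (tab[1] > nrow(top30) / 2) {
      call_at <- structure(
        list(query_id = q, rank = rank, taxon = names(tab)[1],
             n_considered = nrow(top30), n_agreeing = as.integer(tab[1])),
        class = "taxonomy_call")
      break
    }
  }
  if (!is.null(call_at)) return(call_at)
  # phylum: unanimity of top 10
  if ("phylum" %in% names(ranked)) {
    top10 <- head(ranked, 10L)
    ph <- top10$phylum
    if (all(present(ph)) && length(unique(ph)) == 1) {
      return(structure(
        list(query_id = q, rank = "phylum", taxon = ph[1],
             n_considered = nrow(top10), n_agreeing = nrow(top10)),
        class = "taxonomy_call"))
    }
  }
  unassigned
}

#' @export
print.taxonomy_call <- function(x, ...) {
  cat(sprintf("<taxonomy_call %s> %s: %s (%d/%d)\n", x$query_id, x$rank,
              x$taxon, x$n_agreeing, x$n_considered))
  invisible(x)
}

#' Vote taxonomy for every query in a table
#'
#' @param hits hit data.frame with lineage columns (see
#'   [read_hit_table()]).
#' @param min_hits minimum evidence per query.
#' @return data.frame (query_id, rank, taxon, n_considered, n_agreeing).
#' @export
vote_taxonomy_all <- function(hits, min_hits = 10L) {
  do.call(rbind, lapply(split(hits, hits$qseqid), function(h) {
    v <- vote_taxonomy(h, min_hits = min_hits)
    data.frame(query_id = v$query_id, rank = v$rank, taxon = v$taxon,
               n_considered = v$n_considered, n_agreeing = v$n_agreeing,
               stringsAsFactors = FALSE)
  }))
}

#' Attach query coverage to a hit table
#'
#' Coverage is `100 * alignment span / query length` computed from
#' `qstart`/`qend` and a query-length map; a pre-existing `qcovs`
#' column is left untouched.
#'
#' @param hits hit data.frame.
#' @param query_lengths named vector of query lengths in bp.
#' @return hits with a `qcovs` column.
#' @export
add_query_coverage <- function(hits, query_lengths) {
  if ("qcovs" %in% names(hits)) return(hits)
  qlen <- query_lengths[hits$qseqid]
  if (any(is.na(qlen))) {
    stop("query_lengths is missing entries for some queries", call. = FALSE)
  }
  hits$qcovs <- 100 * (abs(hits$qend - hits$qstart) + 1) / as.numeric(qlen)
  hits
}

#' Best hit of one query under a coverage cutoff
#'
#' Filters hits to query coverage `>= coverage_cutoff` percent, then
#' takes the first under the [rank_hits()] ordering.
#'
#' @param hits hits of one query; must carry a `qcovs` column (see
#'   [add_query_coverage()]) unless `query_lengths` is given.
#' @param coverage_cutoff minimum query coverage percent (default 80).
#' @param query_lengths optional named length map used to compute
#'   coverage on the fly.
#' @return a one-row data.frame `bbh_record` (query_id, subject_id,
#'   pident, evalue, bitscore, qcovs), or `NULL` when no hit survives.
#' @export
best_hit <- function(hits, coverage_cutoff = 80, query_lengths = NULL) {
  check_single_query(hits)
  if (!"qcovs" %in% names(hits)) {
    if (is.null(query_lengths)) {
      stop("hits lack a qcovs column; pass query_lengths", call. = FALSE)
    }
    hits <- add_query_coverage(hits, query_lengths)
  }
  surv <- hits[hits$qcovs >= coverage_cutoff, , drop = FALSE]
  if (nrow(surv) == 0) return(NULL)
  top <- rank_hits(surv)[1, ]
  data.frame(query_id = top$qseqid, subject_id = top$sseqid,
             pident = top$pident, evalue = top$evalue,
             bitscore = top$bitscore, qcovs = top$qcovs,
             stringsAsFactors = FALSE)
}

#' Best hit per query over a whole table
#'
#' @inheritParams best_hit
#' @param hits hit data.frame over any number of queries.
#' @return data.frame of surviving best-hit records (possibly 0 rows).
#' @export
best_hit_all <- function(hits, coverage_cutoff = 80, query_lengths = NULL) {
  recs <- lapply(split(hits, hits$qseqid), best_hit,
                 coverage_cutoff = coverage_cutoff,
                 query_lengths = query_lengths)
  recs <- recs[!vapply(recs, is.null, TRUE)]
  if (length(recs) == 0) {
    return(data.frame(query_id = character(), subject_id = character(),
                      pident = numeric(), evalue = numeric(),
                      bitscore = numeric(), qcovs = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Per-reference summary of best-hit records
#'
#' Counts, per reference genome, the queries whose best hit maps to it,
#' with the unweighted mean percent identity rounded to integer.
#' References in the map with no record get an `n = 0` row with `NA`
#' identity.
#'
#' @param records best-hit records ([best_hit_all()] output).
#' @param reference_map named vector mapping subject id to reference
#'   genome id (must cover every subject in `records`).
#' @return data.frame (reference, n_queries, mean_identity).
#' @export
bbh_summary <- function(records, reference_map) {
  refs_all <- sort(unique(unname(reference_map)))
  if (nrow(records) > 0) {
    unmapped <- setdiff(records$subject_id, names(reference_map))
    if (length(unmapped) > 0) {
      stop(sprintf("mapping error: subject(s) not in reference map: %s",
                   paste(head(unmapped, 5), collapse = ", ")), call. = FALSE)
    }
    ref <- unname(reference_map[records$subject_id])
  } else ref <- character(0)
  do.call(rbind, lapply(refs_all, function(r) {
    i <- ref == r
    data.frame(reference = r, n_queries = sum(i),
               mean_identity = if (any(i)) round(mean(records$pident[i])) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
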