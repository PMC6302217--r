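# Global-alignment identity between two nucleotide strings:
# matches / alignment columns, under match +1, mismatch -1,
# gap open -5, gap extend -1.
align_identity_nt <- function(a, b) {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = m,
                                       gapOpening = 5, gapExtension = 1,
                                       type = "global")
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

# Vectorized over `bs`; best of forward and reverse-complement.
align_identity_best <- function(a, bs) {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                baseOnly = TRUE)
  pat <- Biostrings::DNAStringSet(bs)
  fwd <- Biostrings::pairwiseAlignment(pat, Biostrings::DNAString(a),
                                       substitutionMatrix = m,
                                       gapOpening = 5, gapExtension = 1,
                                       type = "global")
  rev <- Biostrings::pairwiseAlignment(Biostrings::reverseComplement(pat),
                                       Biostrings::DNAString(a),
                                       substitutionMatrix = m,
                                       gapOpening = 5, gapExtension = 1,
                                       type = "global")
  pmax(Biostrings::nmatch(fwd) / Biostrings::nchar(fwd),
       Biostrings::nmatch(rev) / Biostrings::nchar(rev))
}

#' Retain arrays found consistently by both detectors
#'
#' An array from `a` (by convention the seed-and-extend detections) is
#' retained iff some array from `b` on the same contig overlaps it
#' reciprocally by at least `overlap_frac` of each interval. The
#' retained record keeps the seed detector's repeat starts, consensus
#' and spacers; its interval is widened to the union of the two
#' intervals.
#'
#' @param a,b lists of `crispr_array` from the two detectors over the
#'   same contig set.
#' @param overlap_frac reciprocal overlap fraction (default 0.5).
#' @return list of consensus `crispr_array` records.
#' @export
consensus_arrays <- function(a, b, overlap_frac = 0.5) {
  out <- list()
  for (x in a) {
    for (y in b) {
      if (x$contig_id != y$contig_id) next
      ov <- min(x$end, y$end) - max(x$start, y$start)
      if (ov <= 0) next
      if (ov >= overlap_frac * (x$end - x$start) &&
          ov >= overlap_frac * (y$end - y$start)) {
        z <- x
        z$start <- min(x$start, y$start)
        z$end <- max(x$end, y$end)
        z$detector <- "consensus"
        out <- c(out, list(z))
        break
      }
    }
  }
  out
}

#' Majority-consensus repeat of an array
#'
#' Gapless per-column majority over the repeat copies cut at the
#' array's recorded starts; ties broken by fixed base order A < C < G < T.
#'
#' @param array a `crispr_array`.
#' @param x the [contig()] (or sequence) the array was called on.
#' @return nucleotide string of length `array$repeat_length`.
#' @export
consensus_repeat <- function(array, x) {
  seqstr <- as_sequence(x)
  ch <- seq_chars(seqstr)
  cp <- column_profile(ch, array$repeat_starts + 1L, array$repeat_length,
                       nchar(seqstr))
  consensus_from_profile(cp$profile)
}

#' Cluster arrays into unique repeat types
#'
#' Single-linkage clustering in which two arrays link iff the
#' global-alignment identity of their consensus repeats (best of
#' forward and reverse complement) reaches `identity_threshold`. The
#' representative of each type is the medoid consensus (maximal mean
#' identity to the other members).
#'
#' @param arrays list of `crispr_array` carrying consensus repeats.
#' @param identity_threshold linkage identity (default 0.9).
#' @param samples optional named vector mapping contig id to sample
#'   label, used for the per-sample array tallies.
#' @return list of `repeat_type` objects: `type_id`, `representative`,
#'   `member_ids` (indices into `arrays`), `sample_counts`.
#' @export
cluster_repeat_types <- function(arrays, identity_threshold = 0.9,
                                 samples = NULL) {
  if (length(arrays) == 0) return(list())
  cons <- vapply(arrays, `[[`, "", "consensus_repeat")
  n <- length(cons)
  # collapse exact duplicates first, then align distinct consensi
  uniq <- unique(cons)
  u <- length(uniq)
  idmat <- diag(1, u)
  if (u > 1) {
    for (i in 1:(u - 1)) {
      ids <- align_identity_best(uniq[i], uniq[(i + 1):u])
      idmat[i, (i + 1):u] <- ids
      idmat[(i + 1):u, i] <- ids
    }
  }
  g <- igraph::graph_from_adjacency_matrix(idmat >= identity_threshold,
                                           mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  member_of <- comp[match(cons, uniq)]
  lapply(sort(unique(member_of)), function(cl) {
    idx <- which(member_of == cl)
    ucl <- which(comp == cl)
    rep_seq <- if (length(ucl) == 1) uniq[ucl] else {
      sub <- idmat[ucl, ucl, drop = FALSE]
      uniq[ucl[which.max(rowMeans(sub))]]
    }
    counts <- NULL
    if (!is.null(samples)) {
      smp <- vapply(arrays[idx], function(a) {
        s <- samples[[a$contig_id]]
        if (is.null(s)) NA_character_ else s
      }, "")
      counts <- table(smp)
    }
    structure(list(type_id = sprintf("RT%03d", cl),
                   representative = rep_seq,
                   member_ids = idx,
                   sample_counts = counts),
              class = "repeat_type")
  })
}

#' @export
print.repeat_type <- function(x, ...) {
  cat(sprintf("<repeat_type %s> %d member array(s), representative %s\n",
              x$type_id, length(x$member_ids), x$representative))
  invisible(x)
}

#' Tally arrays and unique repeat types per sample
#'
#' @param arrays list of `crispr_array`.
#' @param types list of `repeat_type` from [cluster_repeat_types()].
#' @param samples named vector mapping contig id to sample label.
#' @return data.frame (sample, n_arrays, n_types).
#' @export
tally_arrays <- function(arrays, types, samples) {
  smp <- vapply(arrays, function(a) {
    s <- samples[[a$contig_id]]
    if (is.null(s)) NA_character_ else s
  }, "")
  all_samples <- sort(unique(smp))
  type_samples <- lapply(types, function(t) unique(smp[t$member_ids]))
  do.call(rbind, lapply(all_samples, function(s) {
    data.frame(sample = s,
               n_arrays = sum(smp == s),
               n_types = sum(vapply(type_samples, function(ts) s %in% ts, TRUE)),
               stringsAsFactors = FALSE)
  }))
}

#' Read a motif consensus database
#'
#' TSV with columns `motif_id`, `consensus`. A synthetic 33-entry
#' database is shipped in `extdata` for demonstrations and tests.
#'
#' @param path TSV path; default the shipped synthetic database.
#' @return data.frame (motif_id, consensus).
#' @export
read_motif_db <- function(path = system.file("extdata",
                                             "motif_db_synthetic.tsv",
                                             package = "thermavir")) {
  db <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("motif_id", "consensus") %in% names(db)))
  db
}

#' Assign a repeat type to a motif consensus
#'
#' Scores the type's representative repeat against every database
#' consensus by global-alignment identity (best of both orientations)
#' and assigns the arg-max motif iff its identity reaches `threshold`,
#' else `"novel"`. Identity ties go to the lowest motif id.
#'
#' @param rt a `repeat_type` (or a bare consensus string).
#' @param motif_db data.frame (motif_id, consensus), see
#'   [read_motif_db()].
#' @param threshold assignment identity (default 0.8).
#' @return list `motif_assignment`: `type_id`, `motif_id` (or
#'   `"novel"`), `identity`.
#' @export
assign_motif <- function(rt, motif_db, threshold = 0.8) {
  if (is.null(motif_db) || nrow(motif_db) == 0) {
    stop_field("motif_db", "must be non-empty")
  }
  rep_seq <- if (inherits(rt, "repeat_type")) rt$representative else rt
  type_id <- if (inherits(rt, "repeat_type")) rt$type_id else NA_character_
  ord <- order(motif_db$motif_id)
  db <- motif_db[ord, ]
  ids <- align_identity_best(rep_seq, db$consensus)
  best <- which.max(ids) # first max = lowest motif id after ordering
  structure(list(
    type_id = type_id,
    motif_id = if (ids[best] >= threshold) db$motif_id[best] else "novel",
    identity = ids[best]
  ), class = "motif_assignment")
}

#' Write detected arrays as GFF3 plus a spacer FASTA
#'
#' Emits one `repeat_region` feature per array and one `direct_repeat`
#' child per copy, converting the internal 0-based half-open
#' coordinates to GFF3 1-based inclusive.
#'
#' @param arrays list of `crispr_array`.
#' @param gff_path GFF3 output path.
#' @param spacer_fasta optional spacer FASTA output path.
#' @return invisibly, `gff_path`.
#' @export
write_crispr_gff3 <- function(arrays, gff_path, spacer_fasta = NULL) {
  lines <- "##gff-version 3"
  for (i in seq_along(arrays)) {
    a <- arrays[[i]]
    aid <- sprintf("array%03d", i)
    lines <- c(lines, sprintf(
      "%s\tthermavir\trepeat_region\t%d\t%d\t.\t+\t.\tID=%s;copies=%d;consensus=%s",
      a$contig_id, a$start + 1L, a$end, aid, a$copies, a$consensus_repeat))
    for (j in seq_along(a$repeat_starts)) {
      s <- a$repeat_starts[j]
      lines <- c(lines, sprintf(
        "%s\tthermavir\tdirect_repeat\t%d\t%d\t.\t+\t.\tID=%s.dr%d;Parent=%s",
        a$contig_id, s + 1L, s + a$repeat_length, aid, j, aid))
    }
  }
  writeLines(lines, gff_path)
  if (!is.null(spacer_fasta)) {
    sp <- unlist(lapply(seq_along(arrays), function(i) {
      setNames(arrays[[i]]$spacers,
               sprintf("array%03d_spacer%02d", i,
                       seq_along(arrays[[i]]$spacers)))
    }))
    if (length(sp) > 0) {
      ss <- Biostrings::DNAStringSet(sp)
      Biostrings::writeXStringSet(ss, spacer_fasta, width = 60L)
    } else writeLines(character(0), spacer_fasta)
  }
  invisible(gff_path)
}
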