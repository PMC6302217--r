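#' Bin contigs by composition and coverage
#'
#' Contigs of at least `min_length` bp are clustered by average-linkage
#' hierarchical clustering on [feature_distance_matrix()] (tetranucleotide
#' frequency, standardized log coverage, GC) and the dendrogram is cut to
#' `k` bins. `k = "auto"` picks the `k` in 2..10 with the largest mean
#' silhouette width. Shorter contigs are excluded and reported.
#'
#' @param contigs list of [contig()] objects.
#' @param min_length minimum contig length in bp (default 10 kb).
#' @param k bin count, or `"auto"`.
#' @param weights feature weights passed to [feature_distance_matrix()].
#' @return object of class `bin_assignment`: `assignments` (data.frame
#'   contig_id, bin), `excluded` (ids below the length filter),
#'   `summary` (per-bin n, total bp, mean GC, mean coverage).
#' @export
bin_contigs <- function(contigs, min_length = 10000L, k = "auto",
                        weights = c(1, 1, 1)) {
  lens <- vapply(contigs, `[[`, 0, "length")
  ids <- vapply(contigs, `[[`, "", "id")
  keep <- lens >= min_length
  excluded <- ids[!keep]
  eligible <- contigs[keep]
  if (length(eligible) < 2) {
    stop(sprintf("insufficient input: %d contig(s) pass the %d bp filter, need >= 2",
                 length(eligible), min_length), call. = FALSE)
  }
  d <- feature_distance_matrix(eligible, weights = weights)
  hc <- hclust(as.dist(d), method = "average")
  n <- length(eligible)
  if (identical(k, "auto")) {
    ks <- 2:min(10L, n - 1L)
    if (length(ks) == 0) {
      k <- 1L
    } else {
      widths <- vapply(ks, function(kk) {
        cl <- cutree(hc, k = kk)
        mean(cluster::silhouette(cl, dmatrix = d)[, "sil_width"])
      }, 0)
      k <- ks[which.max(widths)]
    }
  }
  k <- as.integer(k)
  if (k < 1 || k > n) stop_field("k", sprintf("must be in [1, %d]", n))
  cl <- if (k == 1L) rep(1L, n) else cutree(hc, k = k)
  eids <- vapply(eligible, `[[`, "", "id")
  assignments <- data.frame(contig_id = eids,
                            bin = sprintf("bin%02d", cl),
                            stringsAsFactors = FALSE)
  gc <- vapply(eligible, gc_content, 0)
  cov <- vapply(eligible, `[[`, 0, "coverage")
  len <- vapply(eligible, `[[`, 0, "length")
  summary <- do.call(rbind, lapply(sort(unique(assignments$bin)), function(b) {
    i <- assignments$bin == b
    data.frame(bin = b, n_contigs = sum(i), total_bp = sum(len[i]),
               mean_gc = mean(gc[i]), mean_coverage = mean(cov[i]),
               stringsAsFactors = FALSE)
  }))
  structure(list(assignments = assignments, excluded = excluded,
                 summary = summary, k = k),
            class = "bin_assignment")
}

#' @export
print.bin_assignment <- function(x, ...) {
  cat(sprintf("<bin_assignment> %d contigs in %d bins (%d excluded by length)\n",
              nrow(x$assignments), x$k, length(x$excluded)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Score bin completeness against marker-gene lists
#'
#' Counts the distinct single-copy and essential markers present in a
#' bin's annotation table. Duplicated markers count once toward
#' completeness and are reported separately. Completeness is the
#' fraction of the essential list recovered. Marker ids on neither list
#' raise a warning and are ignored.
#'
#' @param bin_annotations data.frame with columns `contig_id`,
#'   `marker_id` (one row per marker occurrence in the bin).
#' @param single_copy_list character vector of single-copy marker ids
#'   (the shipped default has 31).
#' @param essential_list character vector of essential marker ids (the
#'   shipped default has 107).
#' @return object of class `marker_report` with fields
#'   `single_copy_found`, `essential_found`, `completeness`,
#'   `duplicated_markers`.
#' @export
score_completeness <- function(bin_annotations,
                               single_copy_list = default_marker_list("single_copy"),
                               essential_list = default_marker_list("essential")) {
  if (length(single_copy_list) == 0 || length(essential_list) == 0) {
    stop_field("marker lists", "must be non-empty")
  }
  markers <- character(0)
  if (nrow(bin_annotations) > 0) {
    stopifnot(all(c("contig_id", "marker_id") %in% names(bin_annotations)))
    markers <- as.character(bin_annotations$marker_id)
  }
  known <- markers[markers %in% c(single_copy_list, essential_list)]
  unknown <- setdiff(markers, c(single_copy_list, essential_list))
  if (length(unknown) > 0) {
    warning(sprintf("unknown marker id(s) ignored: %s",
                    paste(head(unknown, 5), collapse = ", ")), call. = FALSE)
  }
  tab <- table(known)
  structure(list(
    single_copy_found = sum(unique(known) %in% single_copy_list),
    essential_found = sum(unique(known) %in% essential_list),
    completeness = sum(unique(known) %in% essential_list) / length(essential_list),
    duplicated_markers = sum(tab > 1)
  ), class = "marker_report")
}

#' @export
print.marker_report <- function(x, ...) {
  cat(sprintf("<marker_report> essential %d, single-copy %d, completeness %.1f%%, duplicated %d\n",
              x$essential_found, x$single_copy_found,
              100 * x$completeness, x$duplicated_markers))
  invisible(x)
}

#' Default marker-gene id lists
#'
#' Synthetic placeholder lists shipped with the package: 31 single-copy
#' ids and 107 essential ids. They exercise the counting logic; users
#' supply their own curated lists for real data.
#'
#' @param which `"single_copy"` or `"essential"`.
#' @return character vector of marker ids.
#' @export
default_marker_list <- function(which = c("single_copy", "essential")) {
  which <- match.arg(which)
  file <- system.file("extdata",
                      paste0(which, "_markers_synthetic.tsv"),
                      package = "thermavir")
  read.delim(file, stringsAsFactors = FALSE)$marker_id
}

#' Write bin membership and per-bin report TSVs
#'
#' @param bins a `bin_assignment`.
#' @param membership_path,report_path output paths.
#' @return invisibly, `membership_path`.
#' @export
write_bins <- function(bins, membership_path, report_path = NULL) {
  write.table(bins$assignments, membership_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(report_path)) {
    write.table(bins$summary, report_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(membership_path)
}
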