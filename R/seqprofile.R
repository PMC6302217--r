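#' G+C content of a sequence
#'
#' Fraction (G+C)/(A+C+G+T); `N` positions are excluded from both
#' numerator and denominator. Case-insensitive.
#'
#' @param x a [contig()] or a single sequence string.
#' @return fraction in `[0, 1]`.
#' @export
gc_content <- function(x) {
  s <- Biostrings::DNAString(as_sequence(x))
  counts <- Biostrings::letterFrequency(s, c("A", "C", "G", "T"))
  denom <- sum(counts)
  if (denom == 0) {
    stop("undefined composition: sequence contains no unambiguous base",
         call. = FALSE)
  }
  unname((counts[["C"]] + counts[["G"]]) / denom)
}

#' Tetranucleotide frequency vector
#'
#' Counts every overlapping 4-mer window that contains no `N`, on the
#' given strand only (no reverse-complement canonicalization), and
#' normalizes by the number of counted windows. The result is the
#' 256-vector over all 4-mers in lexicographic order.
#'
#' @param x a [contig()] or a single sequence string.
#' @return named numeric vector of length 256 summing to 1.
#' @export
tnf_vector <- function(x) {
  s <- Biostrings::DNAString(as_sequence(x))
  counts <- Biostrings::oligonucleotideFrequency(s, width = 4L)
  total <- sum(counts)
  if (total == 0) {
    stop("insufficient sequence: no window of 4 unambiguous bases",
         call. = FALSE)
  }
  counts / total
}

#' Pearson correlation matrix of tetranucleotide profiles
#'
#' @param vectors list of [tnf_vector()] results (or any equal-length
#'   numeric vectors), optionally named.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(vectors) {
  if (length(vectors) < 2) stop("need at least 2 vectors", call. = FALSE)
  ids <- names(vectors)
  if (is.null(ids)) ids <- paste0("v", seq_along(vectors))
  mat <- do.call(cbind, vectors)
  colnames(mat) <- ids
  sds <- apply(mat, 2, sd)
  if (any(sds == 0)) {
    stop(sprintf("degenerate variance: constant profile for %s",
                 paste(ids[sds == 0], collapse = ", ")), call. = FALSE)
  }
  cor(mat)
}

#' Composition + coverage feature distance matrix
#'
#' Weighted Euclidean distance over the concatenation of the
#' tetranucleotide profile, standardized `log10(coverage + 1)`, and GC
#' fraction. This is the metric contig binning clusters on.
#'
#' @param contigs list of [contig()] objects.
#' @param weights numeric weights for the three feature blocks, in the
#'   order (tnf, coverage, gc).
#' @return symmetric distance matrix with contig ids as dimnames.
#' @export
feature_distance_matrix <- function(contigs, weights = c(1, 1, 1)) {
  if (length(contigs) < 2) stop("need at least 2 contigs", call. = FALSE)
  stopifnot(length(weights) == 3, all(weights >= 0))
  ids <- vapply(contigs, `[[`, "", "id")
  tnf <- t(vapply(contigs, function(x) as.numeric(tnf_vector(x)),
                  numeric(256)))
  gc <- vapply(contigs, gc_content, 0)
  logcov <- log10(vapply(contigs, `[[`, 0, "coverage") + 1)
  s <- sd(logcov)
  covz <- if (s > 0) (logcov - mean(logcov)) / s else rep(0, length(logcov))
  feats <- cbind(sqrt(weights[1]) * tnf,
                 sqrt(weights[2]) * covz,
                 sqrt(weights[3]) * gc)
  d <- as.matrix(stats::dist(feats))
  dimnames(d) <- list(ids, ids)
  d
}

#' Write a square matrix as TSV with id header row and column
#'
#' @param mat matrix with dimnames.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
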