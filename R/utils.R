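#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cutree hclust as.dist rnorm runif t.test sd var
#   pt setNames aggregate
#' @importFrom methods as
#' @importFrom utils read.delim write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Derive a stage-local seed from a master seed and a label
#'
#' All randomness in the package flows from one master seed. Each stage
#' draws from its own generator seeded by a stable hash of
#' (master seed, label), so adding a new stage never perturbs the draws
#' of existing ones.
#'
#' @param master master seed, a non-negative integer.
#' @param label character scalar naming the stage (and, if needed, the
#'   object it applies to, e.g. `"fragment:genome1"`).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, master >= 0)
  p <- 2147483647 # 2^31 - 1, prime
  h <- master %% p
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% p
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}

# Split a sequence string into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Construct a contig
#'
#' The atom of every stage: a nucleotide sequence with an id, the sample
#' it came from, and an assembly coverage.
#'
#' @param id unique contig identifier.
#' @param sequence nucleotide string over `A,C,G,T,N` (case-insensitive).
#' @param sample sample label.
#' @param coverage fold coverage, `>= 0`.
#' @return an object of class `contig` with fields `id`, `sample`,
#'   `sequence`, `length`, `coverage`.
#' @export
contig <- function(id, sequence, sample = "S1", coverage = 1) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0L) stop_field("sequence", "must be non-empty")
  if (grepl("[^ACGTN]", sequence)) {
    stop_field("sequence", "contains characters outside {A,C,G,T,N}")
  }
  if (coverage < 0) stop_field("coverage", "must be >= 0")
  structure(
    list(id = as.character(id), sample = as.character(sample),
         sequence = sequence, length = nchar(sequence),
         coverage = as.numeric(coverage)),
    class = "contig"
  )
}

#' @export
print.contig <- function(x, ...) {
  cat(sprintf("<contig %s> sample=%s length=%d coverage=%.1fx\n",
              x$id, x$sample, x$length, x$coverage))
  invisible(x)
}

as_sequence <- function(x) {
  if (inherits(x, "contig")) x$sequence
  else if (is.character(x) && length(x) == 1L) toupper(x)
  else stop("expected a contig or a single sequence string", call. = FALSE)
}

#' Read contigs from a FASTA file
#'
#' @param path FASTA file path.
#' @param metadata optional path to a contig metadata TSV with columns
#'   `id`, `sample`, `coverage` (as written by [write_contigs()]).
#' @return a list of [contig()] objects.
#' @export
read_contigs <- function(path, metadata = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  meta <- NULL
  if (!is.null(metadata)) {
    meta <- read.delim(metadata, stringsAsFactors = FALSE)
  }
  lapply(seq_along(ss), function(i) {
    id <- sub("\\s.*$", "", names(ss)[i])
    sample <- "S1"; coverage <- 1
    if (!is.null(meta) && id %in% meta$id) {
      row <- meta[meta$id == id, , drop = FALSE][1, ]
      if ("sample" %in% names(row)) sample <- row$sample
      if ("coverage" %in% names(row)) coverage <- row$coverage
    }
    contig(id, as.character(ss[[i]]), sample = sample, coverage = coverage)
  })
}

#' Write contigs as FASTA (60-column wrap) plus a metadata TSV
#'
#' @param contigs list of [contig()] objects.
#' @param fasta output FASTA path.
#' @param metadata optional output TSV path (id, sample, length, gc,
#'   coverage); skipped when `NULL`.
#' @return invisibly, the FASTA path.
#' @export
write_contigs <- function(contigs, fasta, metadata = NULL) {
  ss <- Biostrings::DNAStringSet(vapply(contigs, `[[`, "", "sequence"))
  names(ss) <- vapply(contigs, `[[`, "", "id")
  Biostrings::writeXStringSet(ss, fasta, width = 60L)
  if (!is.null(metadata)) {
    df <- data.frame(
      id = vapply(contigs, `[[`, "", "id"),
      sample = vapply(contigs, `[[`, "", "sample"),
      length = vapply(contigs, `[[`, 0, "length"),
      gc = vapply(contigs, function(x) gc_content(x), 0),
      coverage = vapply(contigs, `[[`, 0, "coverage"),
      stringsAsFactors = FALSE
    )
    write.table(df, metadata, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta)
}
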