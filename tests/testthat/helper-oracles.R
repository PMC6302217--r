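# Independent brute-force oracles used across the suite. These are
# deliberately naive re-derivations, kept free of the package's own
# code paths.

rand_seq <- function(n, gc = 0.5) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

# sliding-window 4-mer tally, N windows skipped
brute_tnf <- function(s) {
  kmers <- sort(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                  c("A","C","G","T"), c("A","C","G","T"))[, 4:1],
                      1, paste0, collapse = ""))
  counts <- setNames(numeric(256), kmers)
  n <- nchar(s)
  for (i in 1:(n - 3)) {
    w <- substr(s, i, i + 3)
    if (!grepl("N", w, fixed = TRUE)) counts[w] <- counts[w] + 1
  }
  counts / sum(counts)
}

brute_revcomp <- function(s) {
  paste0(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
}

# exhaustive word-pair enumeration for dot plots (0-based starts)
brute_dotplot <- function(a, b, word) {
  out <- list()
  rcb <- brute_revcomp(b)
  nb <- nchar(b)
  for (i in 0:(nchar(a) - word)) {
    wa <- substr(a, i + 1, i + word)
    for (j in 0:(nb - word)) {
      if (wa == substr(b, j + 1, j + word)) {
        out <- c(out, list(c(i, j, 1L)))
      }
      if (wa == substr(rcb, j + 1, j + word)) {
        out <- c(out, list(c(i, nb - word - j, 2L)))
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(x = integer(), y = integer(), strand = character()))
  }
  m <- do.call(rbind, out)
  df <- data.frame(x = m[, 1], y = m[, 2], strand = c("+", "-")[m[, 3]],
                   stringsAsFactors = FALSE)
  df[order(df$x, df$y, df$strand), ]
}

# Gotoh global affine alignment: match +1, mismatch -1, gap open -5,
# gap extend -1 (a gap of length L costs 5 + L). Returns the optimal
# score only (which is unique, unlike any particular traceback).
gotoh_score <- function(a, b, match = 1, mismatch = -1, open = 5, ext = 1) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); E <- M; F <- M
  M[1, 1] <- 0
  for (j in 2:(m + 1)) E[1, j] <- -open - (j - 1) * ext
  for (i in 2:(n + 1)) F[i, 1] <- -open - (i - 1) * ext
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], E[i - 1, j - 1], F[i - 1, j - 1]) + s
      E[i, j] <- max(E[i, j - 1] - ext, M[i, j - 1] - open - ext,
                     F[i, j - 1] - open - ext)
      F[i, j] <- max(F[i - 1, j] - ext, M[i - 1, j] - open - ext,
                     E[i - 1, j] - open - ext)
    }
  }
  max(M[n + 1, m + 1], E[n + 1, m + 1], F[n + 1, m + 1])
}

# point-mutate a sequence at a per-base rate (test-side twin of the
# generator's model)
mutate_at <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A","C","G","T"), ch[i]), 1)
  paste0(ch, collapse = "")
}

# build a contig with one planted array and return truth coordinates
planted_contig <- function(id = "c1", clen = 8000, rep_len = 35,
                           sp_len = 34, copies = 6, mut = 0.01, gc = 0.5) {
  backbone <- rand_seq(clen, gc)
  consensus <- rand_seq(rep_len)
  copies_seq <- vapply(seq_len(copies), function(i) mutate_at(consensus, mut), "")
  spacers <- vapply(seq_len(copies - 1), function(i) rand_seq(sp_len), "")
  segment <- paste0(copies_seq, c(spacers, ""), collapse = "")
  foot <- nchar(segment)
  start0 <- sample.int(clen - foot + 1, 1) - 1
  s <- paste0(substr(backbone, 1, start0), segment,
              substr(backbone, start0 + foot + 1, clen))
  list(contig = contig(id, s), start = start0, end = start0 + foot,
       consensus = consensus, copies = copies)
}

interval_overlap_frac <- function(s1, e1, s2, e2) {
  ov <- max(0, min(e1, e2) - max(s1, s2))
  ov / min(e1 - s1, e2 - s2)
}
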