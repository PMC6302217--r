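#' Exact shared-word matches for a dot plot
#'
#' All exact shared words of size `word` between two sequences, forward
#' and reverse-complement, as 0-based start coordinate pairs. This is
#' the match set a genome dot plot draws.
#'
#' @param a,b nucleotide sequences (strings or [contig()]s).
#' @param word word size in nt (default 10).
#' @return data.frame (x, y, strand) with strand `"+"` or `"-"`; `y` is
#'   the 0-based start of the word on the forward strand of `b` in both
#'   cases.
#' @export
dotplot_matches <- function(a, b, word = 10L) {
  if (word < 4) stop_field("word", "must be >= 4")
  a <- as_sequence(a); b <- as_sequence(b)
  if (nchar(a) < word || nchar(b) < word) {
    stop("both sequences must be at least `word` long", call. = FALSE)
  }
  words_of <- function(s) {
    n <- nchar(s)
    w <- substring(s, 1:(n - word + 1L), word:n)
    split(0:(n - word), w) # 0-based starts keyed by word
  }
  wa <- words_of(a)
  join <- function(wb, strand, map_y) {
    shared <- intersect(names(wa), names(wb))
    if (length(shared) == 0) {
      return(data.frame(x = integer(), y = integer(),
                        strand = character(), stringsAsFactors = FALSE))
    }
    do.call(rbind, lapply(shared, function(w) {
      g <- expand.grid(x = wa[[w]], y = wb[[w]])
      data.frame(x = g$x, y = map_y(g$y), strand = strand,
                 stringsAsFactors = FALSE)
    }))
  }
  fwd <- join(words_of(b), "+", identity)
  nb <- nchar(b)
  rev <- join(words_of(revcomp(b)), "-", function(y) nb - word - y)
  out <- rbind(fwd, rev)
  out[order(out$x, out$y, out$strand), , drop = FALSE]
}

#' Global percent identity of two sequences
#'
#' Needleman-Wunsch with affine gaps (match +1, mismatch -1, gap open
#' -5, gap extend -1); identity is `100 * matches / alignment columns`.
#'
#' @param a,b nucleotide sequences.
#' @return percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b) {
  a <- as_sequence(a); b <- as_sequence(b)
  100 * align_identity_nt(a, b)
}

#' Within-group mean pairwise identity
#'
#' Mean and standard deviation of [pairwise_identity()] over all
#' within-group genome pairs. This is the package's group-conservation
#' statistic (the score formula of whole-genome aligner suites is not
#' reproduced).
#'
#' @param genomes named list/vector of sequences (or [contig()]s).
#' @param groups named vector mapping genome id to group label.
#' @return data.frame (group, n_genomes, n_pairs, mean_identity,
#'   sd_identity).
#' @export
group_similarity <- function(genomes, groups) {
  ids <- names(genomes)
  stopifnot(!is.null(ids), all(ids %in% names(groups)))
  do.call(rbind, lapply(sort(unique(unname(groups[ids]))), function(g) {
    members <- ids[groups[ids] == g]
    if (length(members) < 2) {
      stop(sprintf("insufficient group: '%s' has %d genome(s), need >= 2",
                   g, length(members)), call. = FALSE)
    }
    cmb <- utils::combn(members, 2)
    pid <- vapply(seq_len(ncol(cmb)), function(i) {
      pairwise_identity(genomes[[cmb[1, i]]], genomes[[cmb[2, i]]])
    }, 0)
    data.frame(group = g, n_genomes = length(members), n_pairs = ncol(cmb),
               mean_identity = mean(pid), sd_identity = sd(pid),
               stringsAsFactors = FALSE)
  }))
}

#' Tetranucleotide correlation network of genomes
#'
#' Nodes are genomes; an undirected edge joins two genomes whose
#' tetranucleotide profiles correlate (Pearson) at or above
#' `edge_threshold`, weighted by the correlation. Node weight is the
#' sum of incident edge weights. Set the threshold to 0 (or below) for
#' the complete correlation graph.
#'
#' @param genomes named list of sequences or [contig()]s (>= 2).
#' @param edge_threshold minimum correlation for an edge (default 0.5).
#' @return an `igraph` graph with edge attribute `weight` and vertex
#'   attribute `weight`.
#' @export
tnf_network <- function(genomes, edge_threshold = 0.5) {
  if (length(genomes) < 2) stop("need at least 2 genomes", call. = FALSE)
  ids <- names(genomes)
  if (is.null(ids)) ids <- paste0("g", seq_along(genomes))
  vecs <- lapply(genomes, tnf_vector)
  names(vecs) <- ids
  cm <- correlation_matrix(vecs)
  adj <- cm
  adj[adj < edge_threshold] <- 0
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$weight <- igraph::strength(g)
  g
}

#' Write a network as an edge-list TSV
#'
#' @param g an `igraph` graph from [tnf_network()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_network_tsv <- function(g, path) {
  df <- igraph::as_data_frame(g, what = "edges")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- reciprocal smallest distance ---------------------------------------

# Karlin-Altschul-style E-value for a gapped BLOSUM62 local alignment:
# E = K * m * n * exp(-lambda * S), with the fixed parameterization
# lambda = 0.267, K = 0.041 (the standard gapped BLOSUM62/11,1 values).
# The RSD screen needs a consistent threshold, not database-calibrated
# significance.
ka_evalue <- function(score, m, n, lambda = 0.267, K = 0.041) {
  K * m * n * exp(-lambda * score)
}

# All-vs-all local alignment of one query against a proteome:
# Smith-Waterman, BLOSUM62, gap open 11 / extend 1.
local_hits <- function(query_seq, subject_seqs, db_residues) {
  subj <- Biostrings::AAStringSet(subject_seqs)
  aln <- Biostrings::pairwiseAlignment(
    subj, Biostrings::AAString(query_seq),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = "local")
  score <- Biostrings::score(aln)
  data.frame(
    subject = names(subject_seqs),
    score = score,
    evalue = ka_evalue(score, nchar(query_seq), db_residues),
    distance = 1 - Biostrings::nmatch(aln) / Biostrings::nchar(aln),
    stringsAsFactors = FALSE)
}

#' Reciprocal-smallest-distance orthologs between two proteomes
#'
#' For each protein the smallest-distance hit in the other proteome is
#' found under the E-value cutoff (distance is 1 minus the fractional
#' identity of the BLOSUM62 local alignment); a pair is an ortholog iff
#' the relation holds in both directions and the distance does not
#' exceed `divergence_cutoff`.
#'
#' @param proteome_a,proteome_b named character vectors of protein
#'   sequences.
#' @param evalue_cutoff maximum E-value in both directions (default
#'   1e-15).
#' @param divergence_cutoff maximum distance (default 0.5).
#' @return data.frame (protein_a, protein_b, distance, evalue_forward,
#'   evalue_reverse), possibly 0 rows.
#' @export
rsd_orthologs <- function(proteome_a, proteome_b,
                          evalue_cutoff = 1e-15, divergence_cutoff = 0.5) {
  if (length(proteome_a) == 0 || length(proteome_b) == 0) {
    stop("empty proteome", call. = FALSE)
  }
  stopifnot(!is.null(names(proteome_a)), !is.null(names(proteome_b)))
  db_a <- sum(nchar(proteome_a)); db_b <- sum(nchar(proteome_b))
  best_in <- function(qname, qseq, subjects, db_res) {
    h <- local_hits(qseq, subjects, db_res)
    h <- h[h$evalue <= evalue_cutoff, , drop = FALSE]
    if (nrow(h) == 0) return(NULL)
    h <- h[order(h$distance, h$evalue, h$subject), , drop = FALSE]
    h[1, ]
  }
  fwd <- lapply(names(proteome_a), function(qa) {
    best_in(qa, proteome_a[[qa]], proteome_b, db_b)
  })
  names(fwd) <- names(proteome_a)
  # reverse searches only for proteins named as someone's best hit
  needed <- unique(unlist(lapply(fwd, function(h) if (is.null(h)) NULL else h$subject)))
  rev <- lapply(needed, function(qb) {
    best_in(qb, proteome_b[[qb]], proteome_a, db_a)
  })
  names(rev) <- needed
  out <- list()
  for (qa in names(proteome_a)) {
    hf <- fwd[[qa]]
    if (is.null(hf)) next
    qb <- hf$subject
    hr <- rev[[qb]]
    if (is.null(hr) || hr$subject != qa) next
    if (hf$distance > divergence_cutoff) next
    out <- c(out, list(data.frame(
      protein_a = qa, protein_b = qb, distance = hf$distance,
      evalue_forward = hf$evalue, evalue_reverse = hr$evalue,
      stringsAsFactors = FALSE)))
  }
  if (length(out) == 0) {
    return(data.frame(protein_a = character(), protein_b = character(),
                      distance = numeric(), evalue_forward = numeric(),
                      evalue_reverse = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ortholog groups present in every genome
#'
#' Single-linkage grouping of reciprocal-smallest-distance pairs
#' (pooled over all genome pairs) into connected components; a
#' component is core iff it contains at least one protein from every
#' genome.
#'
#' @param pair_tables list of [rsd_orthologs()] outputs covering all
#'   genome pairs.
#' @param protein_genome named vector mapping protein id to genome id.
#' @return list of core groups, each a character vector of protein ids.
#' @export
shared_core <- function(pair_tables, protein_genome) {
  pairs <- do.call(rbind, pair_tables)
  genomes <- sort(unique(unname(protein_genome)))
  if (is.null(pairs) || nrow(pairs) == 0) return(list())
  g <- igraph::graph_from_data_frame(
    pairs[, c("protein_a", "protein_b")], directed = FALSE)
  comp <- igraph::components(g)$membership
  groups <- split(names(comp), comp)
  Filter(function(grp) {
    all(genomes %in% unique(unname(protein_genome[grp])))
  }, unname(groups))
}

#' Welch's t-test per functional category
#'
#' Unequal-variance two-sample t-test (Welch-Satterthwaite degrees of
#' freedom, two-sided) on per-genome category relative abundances
#' between two groups. Raw p-values drive the significance flag at
#' `alpha`; a Benjamini-Hochberg column is added when `adjust = TRUE`.
#' Categories with zero variance in both groups are flagged degenerate:
#' non-significant when the means agree, p = 0 when they differ.
#'
#' @param profiles matrix of relative abundances, genomes in rows
#'   (rownames), categories in columns.
#' @param groups named vector mapping genome id to one of exactly two
#'   group labels; each group needs >= 2 genomes.
#' @param alpha significance threshold on the raw p-value (default
#'   0.05, uncorrected by design).
#' @param adjust add a BH-adjusted p-value column.
#' @return data.frame (category, t, df, p, [p_adj,] significant,
#'   degenerate).
#' @export
welch_category_test <- function(profiles, groups, alpha = 0.05,
                                adjust = FALSE) {
  profiles <- as.matrix(profiles)
  ids <- rownames(profiles)
  stopifnot(!is.null(ids), all(ids %in% names(groups)))
  lab <- unname(groups[ids])
  lv <- sort(unique(lab))
  if (length(lv) != 2) stop("exactly two groups required", call. = FALSE)
  if (any(table(lab) < 2)) {
    stop("each group needs at least 2 profiles", call. = FALSE)
  }
  res <- do.call(rbind, lapply(colnames(profiles), function(cat) {
    x <- profiles[lab == lv[1], cat]
    y <- profiles[lab == lv[2], cat]
    if (var(x) == 0 && var(y) == 0) {
      if (mean(x) == mean(y)) {
        return(data.frame(category = cat, t = NA_real_, df = NA_real_,
                          p = NA_real_, significant = FALSE,
                          degenerate = TRUE, stringsAsFactors = FALSE))
      }
      return(data.frame(category = cat, t = Inf * sign(mean(x) - mean(y)),
                        df = NA_real_, p = 0, significant = TRUE,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    tt <- t.test(x, y, var.equal = FALSE)
    data.frame(category = cat, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               significant = tt$p.value < alpha, degenerate = FALSE,
               stringsAsFactors = FALSE)
  }))
  if (adjust) {
    res$p_adj <- stats::p.adjust(res$p, method = "BH")
    res <- res[, c("category", "t", "df", "p", "p_adj", "significant",
                   "degenerate")]
  }
  res
}

#' Neighbor-joining tree from shared-ortholog distances
#'
#' Genome distance is `1 - shared ortholog pairs / size of the smaller
#' proteome`; the tree is neighbor-joining with negative branch lengths
#' clamped to 0.
#'
#' @param pair_counts symmetric matrix (genome x genome) of
#'   reciprocal-smallest-distance pair counts, or a named list of
#'   [rsd_orthologs()] outputs with names `"gA|gB"`.
#' @param proteome_sizes named vector of proteome sizes.
#' @return an `ape` `phylo` tree.
#' @export
proteome_tree <- function(pair_counts, proteome_sizes) {
  ids <- names(proteome_sizes)
  if (length(ids) < 3) stop("need at least 3 genomes", call. = FALSE)
  if (is.list(pair_counts) && !is.matrix(pair_counts)) {
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    for (nm in names(pair_counts)) {
      gg <- strsplit(nm, "|", fixed = TRUE)[[1]]
      m[gg[1], gg[2]] <- nrow(pair_counts[[nm]])
      m[gg[2], gg[1]] <- nrow(pair_counts[[nm]])
    }
    pair_counts <- m
  }
  d <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i == j) next
    d[i, j] <- 1 - pair_counts[ids[i], ids[j]] /
      min(proteome_sizes[ids[i]], proteome_sizes[ids[j]])
  }
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
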