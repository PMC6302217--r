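#' Parameters for the synthetic-community generator
#'
#' Collects every knob of the generator with validation. Defaults encode
#' the repeat/spacer geometry the detectors are built for (~35 nt direct
#' repeats separated by ~34 nt spacers) and community-scale values chosen
#' for testability: sequences are i.i.d. bases at a target GC, coverage
#' is truncated-normal.
#'
#' @param seed master seed; stage seeds are derived with [derive_seed()].
#' @param genome_length genome size in bp.
#' @param gc_target target G+C fraction in `[0, 1]`.
#' @param contig_length_mean,contig_length_sd fragment length model (bp).
#' @param coverage_mean,coverage_sd fold-coverage model, truncated at 0.
#' @param repeat_length direct-repeat length (nt).
#' @param spacer_length spacer length (nt).
#' @param array_copies repeat copies per planted array.
#' @param repeat_mutation_rate per-base substitution probability applied
#'   independently to each planted repeat copy.
#' @param hit_noise_rate fraction of synthetic homology hits whose
#'   lineage is resampled from a decoy pool.
#' @return a validated list of class `generator_params`.
#' @export
generator_params <- function(seed = 1L,
                             genome_length = 100000L,
                             gc_target = 0.5,
                             contig_length_mean = 10000L,
                             contig_length_sd = 2000L,
                             coverage_mean = 20,
                             coverage_sd = 5,
                             repeat_length = 35L,
                             spacer_length = 34L,
                             array_copies = 10L,
                             repeat_mutation_rate = 0.01,
                             hit_noise_rate = 0.1) {
  p <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
            gc_target = gc_target,
            contig_length_mean = as.integer(contig_length_mean),
            contig_length_sd = as.numeric(contig_length_sd),
            coverage_mean = as.numeric(coverage_mean),
            coverage_sd = as.numeric(coverage_sd),
            repeat_length = as.integer(repeat_length),
            spacer_length = as.integer(spacer_length),
            array_copies = as.integer(array_copies),
            repeat_mutation_rate = repeat_mutation_rate,
            hit_noise_rate = hit_noise_rate)
  for (f in c("genome_length", "contig_length_mean", "repeat_length",
              "spacer_length", "array_copies")) {
    if (is.na(p[[f]]) || p[[f]] <= 0) stop_field(f, "must be > 0")
  }
  for (f in c("gc_target", "repeat_mutation_rate", "hit_noise_rate")) {
    if (is.na(p[[f]]) || p[[f]] < 0 || p[[f]] > 1) {
      stop_field(f, "must lie in [0, 1]")
    }
  }
  if (p$contig_length_sd < 0) stop_field("contig_length_sd", "must be >= 0")
  if (p$coverage_sd < 0) stop_field("coverage_sd", "must be >= 0")
  if (p$coverage_mean < 0) stop_field("coverage_mean", "must be >= 0")
  foot <- array_footprint(p)
  if (foot >= p$genome_length) {
    stop_field("array_copies",
               sprintf("array footprint (%d bp) must be < genome_length (%d bp)",
                       foot, p$genome_length))
  }
  structure(p, class = "generator_params")
}

array_footprint <- function(params) {
  params$array_copies * params$repeat_length +
    (params$array_copies - 1L) * params$spacer_length
}

random_dna <- function(n, gc) {
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste0(sample(DNA_BASES, n, replace = TRUE, prob = prob), collapse = "")
}

# Substitute each base independently with probability `rate`, always to a
# different base.
mutate_seq <- function(x, rate) {
  if (rate <= 0) return(x)
  ch <- seq_chars(x)
  hit <- runif(length(ch)) < rate
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(DNA_BASES, b), 1L),
                      "", USE.NAMES = FALSE)
  }
  paste0(ch, collapse = "")
}

#' An empty ground-truth manifest
#'
#' The manifest records every planted feature of a synthetic community:
#' array coordinates (0-based half-open) and unmutated repeat consensus,
#' prophage coordinates, the source genome and true lineage of every
#' contig, and true ortholog pairs. It is the oracle all recovery tests
#' are scored against.
#'
#' @return an object of class `ground_truth_manifest`.
#' @export
empty_manifest <- function() {
  structure(list(
    planted_arrays = data.frame(
      contig_id = character(), start = integer(), end = integer(),
      repeat_consensus = character(), copies = integer(),
      repeat_starts = character(), stringsAsFactors = FALSE),
    planted_prophages = data.frame(
      contig_id = character(), start = integer(), end = integer(),
      stringsAsFactors = FALSE),
    genome_origin = data.frame(
      contig_id = character(), genome_id = character(),
      lineage = character(), stringsAsFactors = FALSE),
    true_orthologs = data.frame(
      protein_a = character(), protein_b = character(),
      stringsAsFactors = FALSE)
  ), class = "ground_truth_manifest")
}

merge_manifests <- function(a, b) {
  out <- empty_manifest()
  for (f in names(out)) out[[f]] <- rbind(a[[f]], b[[f]])
  out
}

#' Serialize / restore a ground-truth manifest
#'
#' Plain-text hierarchical (YAML) representation; `read_manifest()`
#' restores a manifest byte-equivalent to the one written.
#'
#' @param manifest a `ground_truth_manifest`.
#' @param path file path.
#' @return `read_manifest()` returns the manifest; `write_manifest()`
#'   returns the path invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "ground_truth_manifest"))
  obj <- lapply(unclass(manifest), function(df) {
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  })
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  obj <- yaml::read_yaml(path)
  out <- empty_manifest()
  for (f in names(out)) {
    rows <- obj[[f]]
    if (length(rows) > 0) {
      df <- do.call(rbind, lapply(rows, function(r) {
        as.data.frame(r, stringsAsFactors = FALSE)
      }))
      # restore column types of the empty template
      for (col in names(out[[f]])) {
        df[[col]] <- methods::as(df[[col]], class(out[[f]][[col]]))
      }
      rownames(df) <- NULL
      out[[f]] <- df[, names(out[[f]])]
    }
  }
  out
}

#' Generate a host genome
#'
#' An i.i.d. random genome at the target GC, deterministic under the
#' master seed. Realized GC converges on the target (within about 0.02
#' for genomes of 50 kb and larger).
#'
#' @param params a [generator_params()] object.
#' @param id contig id for the genome.
#' @param sample sample label.
#' @param lineage true lineage recorded in the manifest.
#' @return `list(contig =, manifest =)`.
#' @export
generate_host_genome <- function(params, id = "host1", sample = "S1",
                                 lineage = "Proteobacteria") {
  stopifnot(inherits(params, "generator_params"))
  seq <- with_seed(derive_seed(params$seed, paste0("host_genome:", id)),
                  random_dna(params$genome_length, params$gc_target))
  man <- empty_manifest()
  man$genome_origin <- data.frame(contig_id = id, genome_id = id,
                                  lineage = lineage, stringsAsFactors = FALSE)
  list(contig = contig(id, seq, sample = sample,
                       coverage = params$coverage_mean),
       manifest = man)
}

#' Plant a CRISPR array into a genome
#'
#' Overwrites a seeded-random location of the genome with
#' `array_copies` near-identical copies of a random direct repeat
#' (each copy independently mutated at `repeat_mutation_rate`),
#' separated by independent uniform-random spacers. Genome length is
#' unchanged. The manifest records the exact 0-based half-open
#' interval, the per-copy repeat start positions and the unmutated
#' repeat consensus.
#'
#' @param genome a [contig()].
#' @param params a [generator_params()].
#' @param label distinguishes multiple plants in one genome (enters the
#'   derived seed).
#' @return `list(contig =, manifest =)`.
#' @export
plant_crispr_array <- function(genome, params, label = "array1") {
  stopifnot(inherits(genome, "contig"), inherits(params, "generator_params"))
  foot <- array_footprint(params)
  if (foot > genome$length) {
    stop(sprintf("array footprint (%d bp) exceeds genome length (%d bp)",
                 foot, genome$length), call. = FALSE)
  }
  seed <- derive_seed(params$seed, paste0("plant_array:", genome$id, ":", label))
  res <- with_seed(seed, {
    start0 <- sample.int(genome$length - foot + 1L, 1L) - 1L # 0-based
    consensus <- random_dna(params$repeat_length, 0.5)
    copies <- vapply(seq_len(params$array_copies), function(i) {
      mutate_seq(consensus, params$repeat_mutation_rate)
    }, "")
    spacers <- vapply(seq_len(params$array_copies - 1L), function(i) {
      random_dna(params$spacer_length, 0.5)
    }, "")
    segment <- paste0(copies, c(spacers, ""), collapse = "")
    list(start0 = start0, consensus = consensus, segment = segment)
  })
  period <- params$repeat_length + params$spacer_length
  starts <- res$start0 + period * (seq_len(params$array_copies) - 1L)
  seq <- genome$sequence
  substr(seq, res$start0 + 1L, res$start0 + foot) <- res$segment
  man <- empty_manifest()
  man$planted_arrays <- data.frame(
    contig_id = genome$id, start = res$start0, end = res$start0 + foot,
    repeat_consensus = res$consensus, copies = params$array_copies,
    repeat_starts = paste(starts, collapse = ","), stringsAsFactors = FALSE)
  list(contig = contig(genome$id, seq, sample = genome$sample,
                       coverage = genome$coverage),
       manifest = man)
}

#' Generate a set of phage genomes
#'
#' Per-genome GC targets are assigned round-robin from `gc_targets`, so
#' genomes sharing a target form a compositional group with a common
#' tetranucleotide signature; lengths are uniform over `length_range`
#' (default the 24-200 kb genome-size range the pipeline targets).
#'
#' @param n number of genomes (`>= 1`).
#' @param gc_targets vector of GC fractions, one compositional group per
#'   distinct value.
#' @param length_range genome length interval in bp.
#' @param seed master seed.
#' @param sample sample label.
#' @return `list(contigs = list of contig, manifest =)`; the manifest's
#'   `genome_origin$lineage` carries the GC-group label `gc=<target>`.
#' @export
generate_phage_set <- function(n, gc_targets, length_range = c(24000L, 200000L),
                               seed = 1L, sample = "S1") {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop_field("n", "must be >= 1")
  }
  if (length(gc_targets) == 0) stop_field("gc_targets", "must be non-empty")
  if (any(gc_targets < 0 | gc_targets > 1)) {
    stop_field("gc_targets", "entries must lie in [0, 1]")
  }
  n <- as.integer(n)
  gcs <- rep_len(gc_targets, n)
  man <- empty_manifest()
  contigs <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("phage%02d", i)
    len <- with_seed(derive_seed(seed, paste0("phage_len:", id)), {
      as.integer(round(runif(1, length_range[1], length_range[2])))
    })
    seq <- with_seed(derive_seed(seed, paste0("phage_seq:", id)),
                     random_dna(len, gcs[i]))
    contigs[[i]] <- contig(id, seq, sample = sample)
    man$genome_origin <- rbind(man$genome_origin, data.frame(
      contig_id = id, genome_id = id,
      lineage = sprintf("gc=%.2f", gcs[i]), stringsAsFactors = FALSE))
  }
  list(contigs = contigs, manifest = man)
}

#' Fragment a genome into contigs
#'
#' Draws fragment lengths from `N(contig_length_mean, contig_length_sd)`
#' (rounded, floored at 200 bp) until the genome is exhausted; the last
#' fragment takes the remainder. Fragments are non-overlapping and
#' concatenate, in order, to the parent sequence. Each fragment gets a
#' coverage from `N(coverage_mean, coverage_sd)` truncated at 0.
#'
#' @param genome a [contig()].
#' @param params a [generator_params()].
#' @param manifest optional parent manifest whose `genome_origin` row for
#'   the genome supplies the fragments' true lineage.
#' @return `list(contigs = list of contig, manifest =)`; fragment origin
#'   (parent genome, lineage) is recorded in the manifest.
#' @export
fragment_to_contigs <- function(genome, params, manifest = NULL) {
  stopifnot(inherits(genome, "contig"), inherits(params, "generator_params"))
  if (params$contig_length_mean >= genome$length) {
    stop_field("contig_length_mean", "must be < genome length")
  }
  seed <- derive_seed(params$seed, paste0("fragment:", genome$id))
  lens <- with_seed(seed, {
    draw_fragment_lengths(genome$length, params$contig_length_mean,
                          params$contig_length_sd)
  })
  covs <- with_seed(derive_seed(params$seed, paste0("coverage:", genome$id)), {
    vapply(seq_along(lens), function(i) {
      if (params$coverage_sd == 0) return(params$coverage_mean)
      repeat {
        v <- rnorm(1, params$coverage_mean, params$coverage_sd)
        if (v >= 0) return(v)
      }
    }, 0)
  })
  lineage <- NA_character_
  if (!is.null(manifest)) {
    hit <- manifest$genome_origin$contig_id == genome$id
    if (any(hit)) lineage <- manifest$genome_origin$lineage[which(hit)[1]]
  }
  starts <- cumsum(c(0L, lens[-length(lens)]))
  man <- empty_manifest()
  contigs <- vector("list", length(lens))
  for (i in seq_along(lens)) {
    id <- sprintf("%s_c%03d", genome$id, i)
    contigs[[i]] <- contig(
      id, substr(genome$sequence, starts[i] + 1L, starts[i] + lens[i]),
      sample = genome$sample, coverage = covs[i])
    man$genome_origin <- rbind(man$genome_origin, data.frame(
      contig_id = id, genome_id = genome$id, lineage = lineage,
      stringsAsFactors = FALSE))
  }
  list(contigs = contigs, manifest = man)
}

# The replayable RNG schedule for fragmentation: one rnorm per fragment,
# in order, until the genome is exhausted.
draw_fragment_lengths <- function(total, mean, sd) {
  lens <- integer(0)
  left <- total
  while (left > 0) {
    l <- if (sd == 0) mean else max(200L, as.integer(round(rnorm(1, mean, sd))))
    if (l >= left) l <- left
    lens <- c(lens, as.integer(l))
    left <- left - l
  }
  lens
}

#' Synthesize a ranked homology-hit table with lineages
#'
#' For every query in the manifest's `genome_origin`, emits `n` ranked
#' hits in the 12-column blast-tabular dialect with strictly decreasing
#' bit scores, non-decreasing E-values, identities in `[30, 100]` and
#' query coverages in `[50, 100]`. Each hit carries the query's true
#' lineage except with probability `hit_noise_rate`, when the lineage is
#' resampled from `decoy_lineages`.
#'
#' @param truth a `ground_truth_manifest`.
#' @param n_hits_per_query hits per query.
#' @param params a [generator_params()] (seed and `hit_noise_rate`).
#' @param decoy_lineages character pool of wrong lineages.
#' @param query_lengths named vector of query lengths (bp) used to place
#'   alignment coordinates; defaults to 10 kb per query.
#' @return `list(hits =, lineage =)`: a hit data.frame with blast-dialect
#'   columns (`qseqid sseqid pident length mismatch gapopen qstart qend
#'   sstart send evalue bitscore`) and a lineage table
#'   (`sseqid phylum class order family genus`).
#' @export
synthesize_hit_table <- function(truth, n_hits_per_query, params,
                                 decoy_lineages = c("Decoyphyla"),
                                 query_lengths = NULL) {
  stopifnot(inherits(truth, "ground_truth_manifest"),
            inherits(params, "generator_params"))
  queries <- truth$genome_origin$contig_id
  if (length(queries) == 0) stop("manifest contains no queries", call. = FALSE)
  n <- as.integer(n_hits_per_query)
  hits_list <- vector("list", length(queries))
  lin_list <- vector("list", length(queries))
  for (qi in seq_along(queries)) {
    q <- queries[qi]
    true_lin <- truth$genome_origin$lineage[qi]
    qlen <- if (!is.null(query_lengths) && q %in% names(query_lengths)) {
      as.integer(query_lengths[[q]])
    } else 10000L
    row <- with_seed(derive_seed(params$seed, paste0("hits:", q)), {
      bit0 <- runif(1, 200, 500)
      bits <- bit0 - cumsum(c(0, runif(n - 1, 0.5, 5)))
      eval <- 10 ^ (-bits / 10)
      pid <- runif(n, 30, 100)
      cov <- runif(n, 50, 100)
      noisy <- runif(n) < params$hit_noise_rate
      lins <- rep(true_lin, n)
      if (any(noisy)) {
        lins[noisy] <- sample(decoy_lineages, sum(noisy), replace = TRUE)
      }
      span <- pmax(1L, as.integer(round(cov / 100 * qlen)))
      qstart <- vapply(span, function(s) sample.int(max(1L, qlen - s + 1L), 1L),
                       1L)
      list(bits = bits, eval = eval, pid = pid, span = span,
           qstart = qstart, lins = lins)
    })
    sids <- sprintf("%s_s%03d", q, seq_len(n))
    hits_list[[qi]] <- data.frame(
      qseqid = q, sseqid = sids, pident = round(row$pid, 2),
      length = row$span, mismatch = as.integer(round(row$span * (100 - row$pid) / 100)),
      gapopen = 0L, qstart = row$qstart, qend = row$qstart + row$span - 1L,
      sstart = 1L, send = row$span,
      evalue = signif(row$eval, 4), bitscore = round(row$bits, 1),
      stringsAsFactors = FALSE)
    lin_list[[qi]] <- data.frame(
      sseqid = sids, phylum = row$lins,
      class = paste0(row$lins, "_c"), order = paste0(row$lins, "_o"),
      family = paste0(row$lins, "_f"), genus = paste0(row$lins, "_g"),
      stringsAsFactors = FALSE)
  }
  list(hits = do.call(rbind, hits_list), lineage = do.call(rbind, lin_list))
}

#' Write a hit table and lineage map to disk
#'
#' The hit table is written headerless (blast tabular convention), the
#' lineage TSV with a header row.
#'
#' @param tab the list returned by [synthesize_hit_table()].
#' @param hits_path,lineage_path output paths.
#' @return invisibly, `hits_path`.
#' @export
write_hit_table <- function(tab, hits_path, lineage_path) {
  write.table(tab$hits, hits_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(tab$lineage, lineage_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(hits_path)
}

#' Generate proteome sets with planted orthologs
#'
#' Each genome gets a copy of every core ancestor protein, mutated at
#' `mutation_rate` per residue, plus its own unrelated accessory
#' proteins. True ortholog pairs (all cross-genome pairs of copies of
#' one ancestor) are recorded in the manifest.
#'
#' @param n_genomes number of genomes (`>= 2`).
#' @param n_core ancestor proteins shared by every genome.
#' @param n_accessory genome-private proteins each.
#' @param protein_length residues per protein.
#' @param mutation_rate per-residue substitution probability per copy.
#' @param seed master seed.
#' @return `list(proteomes = named list of named character vectors,
#'   manifest =)`.
#' @export
generate_proteome_set <- function(n_genomes = 2L, n_core = 10L,
                                  n_accessory = 5L, protein_length = 120L,
                                  mutation_rate = 0.05, seed = 1L) {
  stopifnot(n_genomes >= 2, n_core >= 0, protein_length > 0)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rand_prot <- function(n) paste0(sample(aa, n, replace = TRUE), collapse = "")
  mut_prot <- function(x, rate) {
    ch <- seq_chars(x)
    hit <- runif(length(ch)) < rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(aa, b), 1L), "",
                        USE.NAMES = FALSE)
    }
    paste0(ch, collapse = "")
  }
  with_seed(derive_seed(seed, "proteomes"), {
    ancestors <- vapply(seq_len(n_core), function(i) rand_prot(protein_length), "")
    proteomes <- list()
    ids_by_core <- vector("list", n_core)
    for (g in seq_len(n_genomes)) {
      gname <- sprintf("genome%02d", g)
      core_ids <- sprintf("%s_core%02d", gname, seq_len(n_core))
      core_seqs <- vapply(ancestors, mut_prot, "", rate = mutation_rate,
                          USE.NAMES = FALSE)
      acc_ids <- if (n_accessory > 0) {
        sprintf("%s_acc%02d", gname, seq_len(n_accessory))
      } else character(0)
      acc_seqs <- vapply(seq_len(n_accessory), function(i) {
        rand_prot(protein_length)
      }, "")
      proteomes[[gname]] <- setNames(c(core_seqs, acc_seqs),
                                     c(core_ids, acc_ids))
      for (k in seq_len(n_core)) {
        ids_by_core[[k]] <- c(ids_by_core[[k]], core_ids[k])
      }
    }
    man <- empty_manifest()
    pairs <- do.call(rbind, lapply(ids_by_core, function(ids) {
      if (length(ids) < 2) return(NULL)
      cmb <- utils::combn(ids, 2)
      data.frame(protein_a = cmb[1, ], protein_b = cmb[2, ],
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(pairs)) man$true_orthologs <- pairs
    list(proteomes = proteomes, manifest = man)
  })
}
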