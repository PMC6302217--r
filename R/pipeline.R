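#' Default pipeline configuration
#'
#' A single hierarchical configuration drives the whole analysis; every
#' cutoff the stages use (length filter, coverage cutoff, detector
#' brackets, identity thresholds, edge threshold) lives here so a run
#' is auditable from its echoed log. Values given in `...` (or loaded
#' from YAML) override the defaults block-wise.
#'
#' @param ... named overrides, e.g. `seed = 7`,
#'   `stages = c("simulate", "crispr")`.
#' @return a nested list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    stages = c("simulate", "profile", "bin", "crispr", "classify", "compare"),
    simulate = list(
      hosts = list(
        list(id = "hostA", sample = "MM1", gc = 0.35, length = 40000L,
             n_arrays = 2L),
        list(id = "hostB", sample = "MnS1", gc = 0.65, length = 40000L,
             n_arrays = 1L)
      ),
      array = list(repeat_length = 35L, spacer_length = 34L,
                   copies = 8L, mutation_rate = 0.01),
      fragment = list(length_mean = 14000L, length_sd = 1500L,
                      coverage_mean = 20, coverage_sd = 5),
      phages = list(n = 4L, gc_targets = c(0.38, 0.62),
                    length_range = c(24000L, 30000L), sample = "MM1"),
      hits = list(n_per_query = 30L, noise_rate = 0.1,
                  decoys = c("Decoyphyla", "Shadowbacteria"))
    ),
    bin = list(min_length = 10000L, k = "auto"),
    crispr = list(min_copies = 3L, repeat_range = c(21L, 48L),
                  spacer_range = c(20L, 60L), type_identity = 0.9,
                  motif_threshold = 0.8, overlap_frac = 0.5,
                  motif_db = NULL),
    classify = list(coverage_cutoff = 80, min_hits = 10L),
    compare = list(edge_threshold = 0.5)
  )
  dots <- list(...)
  modifyList(structure(cfg, class = "run_config"), dots)
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the end-to-end analysis
#'
#' Executes the enabled stages in dependency order
#' (simulate, profile, bin, crispr, classify, compare) on a
#' seeded synthetic community, writing per-stage artifacts under
#' `outdir` and a per-sample summary table (contig, CRISPR-cassette and
#' phage-genome counts). Every effective parameter and derived seed is
#' echoed to `run.log`. Identical configuration and seed give
#' byte-identical artifacts.
#'
#' @param config a [run_config()] (or a YAML path).
#' @param outdir output directory, created if missing.
#' @return a run report: `summary` (per-sample data.frame), `artifacts`
#'   (named paths), `manifest` (the ground truth), and stage results.
#' @export
run_pipeline <- function(config = run_config(), outdir = tempfile("thermavir_")) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outdir, "run.log")
  logcon <- file(logf, open = "wt")
  on.exit(close(logcon), add = TRUE)
  say <- function(...) writeLines(sprintf(...), logcon)
  say("thermavir pipeline")
  say("seed: %d", config$seed)
  say("stages: %s", paste(config$stages, collapse = ", "))
  say("config: %s", paste(utils::capture.output(utils::str(unclass(config))),
                          collapse = " | "))
  stages <- config$stages
  art <- list()
  report <- list(artifacts = art, config = config)

  run_stage <- function(name, fn) {
    if (!name %in% stages) return(NULL)
    say("stage %s: start", name)
    res <- tryCatch(fn(), error = function(e) {
      say("stage %s: FAILED: %s", name, conditionMessage(e))
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 file.path(outdir, "FAILED"))
      stop(sprintf("pipeline aborted at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    say("stage %s: done", name)
    res
  }

  # --- simulate ---
  sim <- run_stage("simulate", function() {
    sc <- config$simulate
    man <- empty_manifest()
    hosts <- list()
    frags <- list()
    for (h in sc$hosts) {
      gp <- generator_params(
        seed = config$seed, genome_length = h$length, gc_target = h$gc,
        contig_length_mean = sc$fragment$length_mean,
        contig_length_sd = sc$fragment$length_sd,
        coverage_mean = sc$fragment$coverage_mean,
        coverage_sd = sc$fragment$coverage_sd,
        repeat_length = sc$array$repeat_length,
        spacer_length = sc$array$spacer_length,
        array_copies = sc$array$copies,
        repeat_mutation_rate = sc$array$mutation_rate,
        hit_noise_rate = sc$hits$noise_rate)
      g <- generate_host_genome(gp, id = h$id, sample = h$sample,
                                lineage = if (!is.null(h$lineage)) h$lineage
                                          else "Proteobacteria")
      man <- merge_manifests(man, g$manifest)
      gen <- g$contig
      n_arrays <- if (is.null(h$n_arrays)) 1L else h$n_arrays
      for (ai in seq_len(n_arrays)) {
        pl <- plant_crispr_array(gen, gp, label = sprintf("array%d", ai))
        gen <- pl$contig
        man <- merge_manifests(man, pl$manifest)
      }
      hosts[[h$id]] <- gen
      fr <- fragment_to_contigs(gen, gp, manifest = man)
      man <- merge_manifests(man, fr$manifest)
      frags <- c(frags, fr$contigs)
    }
    ph <- generate_phage_set(sc$phages$n, sc$phages$gc_targets,
                             length_range = sc$phages$length_range,
                             seed = config$seed, sample = sc$phages$sample)
    man <- merge_manifests(man, ph$manifest)
    gp0 <- generator_params(seed = config$seed,
                            hit_noise_rate = sc$hits$noise_rate)
    frag_lengths <- setNames(vapply(frags, `[[`, 0, "length"),
                             vapply(frags, `[[`, "", "id"))
    frag_man <- empty_manifest()
    frag_man$genome_origin <- man$genome_origin[
      man$genome_origin$contig_id %in% names(frag_lengths), , drop = FALSE]
    tab <- synthesize_hit_table(frag_man, sc$hits$n_per_query, gp0,
                                decoy_lineages = sc$hits$decoys,
                                query_lengths = frag_lengths)
    art$host_fasta <<- file.path(outdir, "hosts.fasta")
    art$contig_fasta <<- file.path(outdir, "contigs.fasta")
    art$contig_meta <<- file.path(outdir, "contigs.tsv")
    art$hits <<- file.path(outdir, "hits.tsv")
    art$lineage <<- file.path(outdir, "lineage.tsv")
    art$manifest <<- file.path(outdir, "manifest.yml")
    write_contigs(hosts, art$host_fasta)
    write_contigs(frags, art$contig_fasta, metadata = art$contig_meta)
    write_hit_table(tab, art$hits, art$lineage)
    write_manifest(man, art$manifest)
    list(hosts = hosts, fragments = frags, phages = ph$contigs,
         manifest = man, hits = tab)
  })
  if (is.null(sim) && any(stages != "simulate")) {
    stop("downstream stages require the simulate stage in this run",
         call. = FALSE)
  }

  # --- profile ---
  run_stage("profile", function() {
    vecs <- lapply(sim$phages, tnf_vector)
    names(vecs) <- vapply(sim$phages, `[[`, "", "id")
    cm <- correlation_matrix(vecs)
    art$tnf_correlation <<- file.path(outdir, "phage_tnf_correlation.tsv")
    write_matrix_tsv(round(cm, 6), art$tnf_correlation)
    cm
  })

  # --- bin ---
  bins <- run_stage("bin", function() {
    b <- bin_contigs(sim$fragments, min_length = config$bin$min_length,
                     k = config$bin$k)
    art$bins <<- file.path(outdir, "bins.tsv")
    art$bin_report <<- file.path(outdir, "bin_report.tsv")
    write_bins(b, art$bins, art$bin_report)
    b
  })

  # --- crispr ---
  cr <- run_stage("crispr", function() {
    cp <- crispr_params(
      repeat_min = config$crispr$repeat_range[1],
      repeat_max = config$crispr$repeat_range[2],
      spacer_min = config$crispr$spacer_range[1],
      spacer_max = config$crispr$spacer_range[2],
      min_copies = config$crispr$min_copies)
    arrays <- list()
    for (h in sim$hosts) {
      a <- detect_arrays_seed(h, cp)
      b <- detect_arrays_periodic(h, cp)
      arrays <- c(arrays, consensus_arrays(a, b,
                                           overlap_frac = config$crispr$overlap_frac))
    }
    samples <- setNames(vapply(sim$hosts, `[[`, "", "sample"),
                        vapply(sim$hosts, `[[`, "", "id"))
    types <- cluster_repeat_types(arrays,
                                  identity_threshold = config$crispr$type_identity,
                                  samples = samples)
    db <- if (is.null(config$crispr$motif_db)) read_motif_db()
          else read_motif_db(config$crispr$motif_db)
    motifs <- lapply(types, assign_motif, motif_db = db,
                     threshold = config$crispr$motif_threshold)
    art$crispr_gff <<- file.path(outdir, "crispr.gff3")
    art$spacers <<- file.path(outdir, "spacers.fasta")
    art$repeat_types <<- file.path(outdir, "repeat_types.tsv")
    write_crispr_gff3(arrays, art$crispr_gff, art$spacers)
    rt_df <- do.call(rbind, lapply(seq_along(types), function(i) {
      data.frame(type_id = types[[i]]$type_id,
                 representative = types[[i]]$representative,
                 n_arrays = length(types[[i]]$member_ids),
                 motif_id = as.character(motifs[[i]]$motif_id),
                 motif_identity = round(motifs[[i]]$identity, 4),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(rt_df)) {
      rt_df <- data.frame(type_id = character(), representative = character(),
                          n_arrays = integer(), motif_id = character(),
                          motif_identity = numeric())
    }
    write.table(rt_df, art$repeat_types, sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(arrays = arrays, types = types, motifs = motifs, samples = samples)
  })

  # --- classify ---
  cls <- run_stage("classify", function() {
    hits <- merge(sim$hits$hits, sim$hits$lineage, by = "sseqid",
                  all.x = TRUE, sort = FALSE)
    calls <- vote_taxonomy_all(hits, min_hits = config$classify$min_hits)
    frag_lengths <- setNames(vapply(sim$fragments, `[[`, 0, "length"),
                             vapply(sim$fragments, `[[`, "", "id"))
    bbh <- best_hit_all(sim$hits$hits,
                        coverage_cutoff = config$classify$coverage_cutoff,
                        query_lengths = frag_lengths)
    art$taxonomy <<- file.path(outdir, "taxonomy_calls.tsv")
    art$bbh <<- file.path(outdir, "best_hits.tsv")
    write.table(calls, art$taxonomy, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(bbh, art$bbh, sep = "\t", quote = FALSE, row.names = FALSE)
    list(calls = calls, bbh = bbh)
  })

  # --- compare ---
  cmp <- run_stage("compare", function() {
    phage_seqs <- lapply(sim$phages, `[[`, "sequence")
    names(phage_seqs) <- vapply(sim$phages, `[[`, "", "id")
    net <- tnf_network(phage_seqs,
                       edge_threshold = config$compare$edge_threshold)
    art$network <<- file.path(outdir, "phage_network.tsv")
    write_network_tsv(net, art$network)
    net
  })

  # --- summary ---
  man <- sim$manifest
  frag_samples <- setNames(vapply(sim$fragments, `[[`, "", "sample"),
                           vapply(sim$fragments, `[[`, "", "id"))
  phage_samples <- setNames(vapply(sim$phages, `[[`, "", "sample"),
                            vapply(sim$phages, `[[`, "", "id"))
  crispr_samples <- if (!is.null(cr)) {
    vapply(cr$arrays, function(a) unname(cr$samples[[a$contig_id]]), "")
  } else character(0)
  all_samples <- sort(unique(c(frag_samples, phage_samples)))
  summary <- do.call(rbind, lapply(all_samples, function(s) {
    data.frame(sample = s,
               n_contigs = sum(frag_samples == s),
               n_crispr_cassettes = sum(crispr_samples == s),
               n_phage_genomes = sum(phage_samples == s),
               stringsAsFactors = FALSE)
  }))
  art$summary <- file.path(outdir, "summary.tsv")
  write.table(summary, art$summary, sep = "\t", quote = FALSE,
              row.names = FALSE)
  say("summary written: %s", art$summary)
  structure(list(summary = summary, artifacts = art, manifest = man,
                 bins = bins, crispr = cr, classify = cls, compare = cmp,
                 config = config, outdir = outdir),
            class = "thermavir_run")
}

#' @export
print.thermavir_run <- function(x, ...) {
  cat("<thermavir run>\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("artifacts in %s\n", x$outdir))
  invisible(x)
}
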