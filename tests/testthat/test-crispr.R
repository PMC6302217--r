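test_that("both detectors recover a planted repeat-spacer array", {
  set.seed(1001)
  pc <- planted_contig(clen = 8000, copies = 10, mut = 0.01)
  for (detect in list(detect_arrays_seed, detect_arrays_periodic)) {
    found <- detect(pc$contig)
    expect_length(found, 1)
    a <- found[[1]]
    expect_gte(interval_overlap_frac(a$start, a$end, pc$start, pc$end), 0.9)
    expect_true(isTRUE(validate_crispr_array(a)))
  }
})

test_that("arrays below min_copies are not called", {
  set.seed(1002)
  pc <- planted_contig(clen = 6000, copies = 2, mut = 0)
  expect_length(detect_arrays_seed(pc$contig), 0)
  expect_length(detect_arrays_periodic(pc$contig), 0)
})

test_that("degenerate periodicity is suppressed", {
  homo <- contig("h", strrep("A", 3000))
  expect_length(detect_arrays_periodic(homo), 0)
  expect_length(detect_arrays_seed(homo), 0)
  dinuc <- contig("d", strrep("AC", 1500))
  expect_length(detect_arrays_periodic(dinuc), 0)
  expect_length(detect_arrays_seed(dinuc), 0)
})

test_that("false-positive rate on random contigs is low", {
  set.seed(1003)
  n_false_seed <- sum(vapply(1:100, function(i) {
    length(detect_arrays_seed(rand_seq(10000)))
  }, 0))
  expect_lt(n_false_seed / 100, 0.05)
  n_false_per <- sum(vapply(1:30, function(i) {
    length(detect_arrays_periodic(rand_seq(10000)))
  }, 0))
  expect_lt(n_false_per / 30, 0.1)
})

test_that("consensus retention keeps reciprocally overlapping arrays", {
  set.seed(1004)
  pc <- planted_contig(clen = 8000, copies = 8, mut = 0.01)
  a <- detect_arrays_seed(pc$contig)
  b <- detect_arrays_periodic(pc$contig)
  cons <- consensus_arrays(a, b)
  expect_length(cons, 1)
  expect_equal(cons[[1]]$detector, "consensus")

  # idempotence on identical lists
  same <- consensus_arrays(a, a)
  expect_equal(same[[1]]$repeat_starts, a[[1]]$repeat_starts)
  expect_equal(same[[1]]$start, a[[1]]$start)

  # disjoint detections are dropped
  shifted <- a
  shifted[[1]]$start <- a[[1]]$start + 5000
  shifted[[1]]$end <- a[[1]]$end + 5000
  expect_length(consensus_arrays(a, shifted), 0)

  # 80% overlap: retained, interval widened to the union
  wide <- a
  wide[[1]]$start <- a[[1]]$start - 40L
  wide[[1]]$end <- a[[1]]$end - 40L
  kept <- consensus_arrays(a, wide)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$start, a[[1]]$start - 40L)
  expect_equal(kept[[1]]$end, a[[1]]$end)

  # no invented loci: every consensus interval overlaps an input locus
  for (z in cons) {
    expect_true(any(vapply(a, function(x) {
      min(z$end, x$end) > max(z$start, x$start)
    }, TRUE)))
  }
})

test_that("consensus_repeat is the per-column majority with A<C<G<T ties", {
  # three identical copies: the consensus is that copy
  unit <- "ACGTACGTACGTACGTACGTACGTACGTACGTACG"
  sp <- vapply(1:2, function(i) rand_seq(34), "")
  s <- paste0(unit, sp[1], unit, sp[2], unit)
  arr <- structure(list(contig_id = "c", start = 0L,
                        end = nchar(s), repeat_starts = c(0L, 69L, 138L),
                        repeat_length = 35L, consensus_repeat = "",
                        spacers = sp, copies = 3L, detector = "seed"),
                   class = "crispr_array")
  expect_equal(consensus_repeat(arr, s), unit)

  # one copy differing at one column: majority wins
  unit2 <- unit
  substr(unit2, 5, 5) <- "T"
  s2 <- paste0(unit, sp[1], unit, sp[2], unit2)
  expect_equal(consensus_repeat(arr, s2), unit)

  # 2-2 tie at a column: first base in A<C<G<T order wins
  uA <- paste0("A", substr(unit, 2, 35))
  uG <- paste0("G", substr(unit, 2, 35))
  s3 <- paste0(uA, sp[1], uA, sp[2], uG, sp[1], uG)
  arr4 <- arr
  arr4$repeat_starts <- c(0L, 69L, 138L, 207L)
  arr4$copies <- 4L
  arr4$spacers <- c(sp, sp[1])
  expect_equal(substr(consensus_repeat(arr4, s3), 1, 1), "A")
})

test_that("repeat types cluster by consensus identity in either orientation", {
  set.seed(1005)
  mk_array <- function(id, consensus) {
    structure(list(contig_id = id, start = 0L, end = 300L,
                   repeat_starts = c(0L, 69L, 138L), repeat_length = 35L,
                   consensus_repeat = consensus, spacers = c("A", "A"),
                   copies = 3L, detector = "consensus"),
              class = "crispr_array")
  }
  base <- rand_seq(35)
  t1 <- cluster_repeat_types(list(mk_array("c1", base), mk_array("c2", base)))
  expect_length(t1, 1)

  other <- rand_seq(35)
  t2 <- cluster_repeat_types(list(mk_array("c1", base), mk_array("c2", other)),
                             identity_threshold = 0.9)
  expect_length(t2, 2)

  # reverse-complemented consensus joins the same type
  t3 <- cluster_repeat_types(list(mk_array("c1", base),
                                  mk_array("c2", brute_revcomp(base))))
  expect_length(t3, 1)

  # 10 arrays from 3 well-separated consensi give exactly 3 types
  sources <- replicate(3, rand_seq(35))
  arrays <- lapply(1:10, function(i) {
    src <- sources[(i %% 3) + 1]
    mk_array(paste0("c", i), mutate_at(src, 0.02))
  })
  t4 <- cluster_repeat_types(arrays, identity_threshold = 0.9)
  expect_length(t4, 3)
  # every array in exactly one type
  members <- sort(unlist(lapply(t4, `[[`, "member_ids")))
  expect_equal(members, 1:10)

  # per-sample counts flow through the sample map
  smp <- setNames(rep(c("MM1", "MnS1"), 5), paste0("c", 1:10))
  t5 <- cluster_repeat_types(arrays, samples = smp)
  tal <- tally_arrays(arrays, t5, smp)
  expect_equal(sum(tal$n_arrays), 10)
})

test_that("motif assignment picks the best database consensus or novel", {
  set.seed(1006)
  db <- data.frame(motif_id = 1:5,
                   consensus = replicate(5, rand_seq(35)),
                   stringsAsFactors = FALSE)
  exact <- assign_motif(db$consensus[3], db, threshold = 0.8)
  expect_equal(exact$motif_id, 3)
  expect_equal(exact$identity, 1.0)

  novel <- assign_motif(rand_seq(35), db, threshold = 0.8)
  expect_equal(novel$motif_id, "novel")

  # 20 repeats derived from two database entries all map home
  for (i in 1:20) {
    src <- c(2, 5)[(i %% 2) + 1]
    got <- assign_motif(mutate_at(db$consensus[src], 0.02), db,
                        threshold = 0.8)
    expect_equal(got$motif_id, src)
  }

  # identity tie goes to the lowest motif id
  dup_db <- data.frame(motif_id = c(4, 2), consensus = rep(db$consensus[1], 2),
                       stringsAsFactors = FALSE)
  expect_equal(assign_motif(db$consensus[1], dup_db)$motif_id, 2)

  expect_error(assign_motif("ACGT", db[0, ]), "motif_db")
})

test_that("emitted arrays satisfy the structural invariants on random inputs", {
  set.seed(1007)
  params <- crispr_params()
  for (i in 1:12) {
    copies <- sample(3:8, 1)
    rep_len <- sample(25:45, 1)
    sp_len <- sample(c(25, 34, 45), 1)
    pc <- planted_contig(clen = 5000, rep_len = rep_len, sp_len = sp_len,
                         copies = copies, mut = 0.01)
    for (found in list(detect_arrays_seed(pc$contig, params),
                       detect_arrays_periodic(pc$contig, params))) {
      for (a in found) expect_true(isTRUE(validate_crispr_array(a, params)))
    }
  }
})

test_that("detection is strand-agnostic up to mirrored coordinates", {
  set.seed(1008)
  pc <- planted_contig(clen = 6000, copies = 8, mut = 0)
  fwd <- detect_arrays_seed(pc$contig)
  rc <- contig("rc", brute_revcomp(pc$contig$sequence))
  rev <- detect_arrays_seed(rc)
  expect_length(fwd, 1)
  expect_length(rev, 1)
  n <- pc$contig$length
  mirrored_start <- n - rev[[1]]$end
  mirrored_end <- n - rev[[1]]$start
  expect_gte(interval_overlap_frac(fwd[[1]]$start, fwd[[1]]$end,
                                   mirrored_start, mirrored_end), 0.95)
})

test_that("GFF3 output is 1-based inclusive with spacers alongside", {
  set.seed(1009)
  pc <- planted_contig(clen = 5000, copies = 5, mut = 0)
  arrays <- detect_arrays_seed(pc$contig)
  gff <- tempfile(fileext = ".gff3")
  spa <- tempfile(fileext = ".fasta")
  write_crispr_gff3(arrays, gff, spa)
  lines <- readLines(gff)
  expect_equal(lines[1], "##gff-version 3")
  fields <- strsplit(grep("repeat_region", lines, value = TRUE)[1], "\t")[[1]]
  expect_equal(as.integer(fields[4]), arrays[[1]]$start + 1L)
  expect_equal(as.integer(fields[5]), arrays[[1]]$end)
  expect_equal(sum(grepl("direct_repeat", lines)), arrays[[1]]$copies)
  sp <- Biostrings::readDNAStringSet(spa)
  expect_length(sp, arrays[[1]]$copies - 1L)
})
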