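test_that("dot-plot matches equal the exhaustive word-pair enumeration", {
  set.seed(301)
  a <- rand_seq(300)
  b <- rand_seq(300)
  got <- dotplot_matches(a, b, word = 5)
  oracle <- brute_dotplot(a, b, word = 5)
  rownames(got) <- rownames(oracle) <- NULL
  expect_equal(got, oracle)
  expect_error(dotplot_matches(a, b, word = 3), "word")
})

test_that("self and reverse-complement dot plots show the expected diagonals", {
  set.seed(302)
  a <- rand_seq(200)
  self <- dotplot_matches(a, a, word = 10)
  diag_fwd <- self[self$strand == "+", ]
  expect_true(all(0:(200 - 10) %in% diag_fwd$x[diag_fwd$x == diag_fwd$y]))

  rc <- dotplot_matches(a, brute_revcomp(a), word = 10)
  anti <- rc[rc$strand == "-", ]
  # every word of a matches the mirrored position on the minus strand
  expect_gte(nrow(anti), 200 - 10 + 1)
})

test_that("pairwise identity agrees with an independent affine-gap DP", {
  expect_equal(pairwise_identity("ACGTACGTAC", "ACGTACGTAC"), 100)
  expect_equal(pairwise_identity("AAAA", "TTTT"), 0)

  set.seed(303)
  anc <- rand_seq(300)
  div <- mutate_at(anc, 0.1)
  pid <- pairwise_identity(anc, div)
  expect_gte(pid, 85)
  expect_lte(pid, 95)

  # the optimal affine score is unique: cross-check engine vs oracle on
  # short sequences (identity can differ between co-optimal alignments,
  # the score cannot)
  for (i in 1:5) {
    x <- rand_seq(60)
    y <- mutate_at(x, 0.15)
    if (i > 3) y <- paste0(substr(y, 1, 25), substr(y, 31, 60)) # indel
    m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
    engine <- Biostrings::score(Biostrings::pairwiseAlignment(
      x, y, substitutionMatrix = m, gapOpening = 5, gapExtension = 1,
      type = "global"))
    expect_equal(engine, gotoh_score(x, y))
  }

  # symmetry
  expect_equal(pairwise_identity(anc, div), pairwise_identity(div, anc))
})

test_that("group similarity summarizes within-group pairs", {
  g <- "ACGTACGTACGTACGTACGTACGTACGTAC"
  out <- group_similarity(list(a = g, b = g, c = g),
                          c(a = "x", b = "x", c = "x"))
  expect_equal(out$mean_identity, 100)
  expect_equal(out$sd_identity, 0)
  expect_equal(out$n_pairs, 3)

  set.seed(304)
  anc1 <- rand_seq(600); anc2 <- rand_seq(600)
  genomes <- list(m1 = mutate_at(anc1, 0.025), m2 = mutate_at(anc1, 0.025),
                  s1 = mutate_at(anc2, 0.15), s2 = mutate_at(anc2, 0.15))
  groups <- c(m1 = "tight", m2 = "tight", s1 = "loose", s2 = "loose")
  out2 <- group_similarity(genomes, groups)
  expect_gt(out2$mean_identity[out2$group == "tight"],
            out2$mean_identity[out2$group == "loose"])

  # hand enumeration over the three pairs of a triple
  tri <- list(a = anc1, b = mutate_at(anc1, 0.05), c = mutate_at(anc1, 0.1))
  out3 <- group_similarity(tri, c(a = "g", b = "g", c = "g"))
  manual <- mean(c(pairwise_identity(tri$a, tri$b),
                   pairwise_identity(tri$a, tri$c),
                   pairwise_identity(tri$b, tri$c)))
  expect_equal(out3$mean_identity, manual)

  expect_error(group_similarity(list(a = g, b = g),
                                c(a = "x", b = "y")), "insufficient group")
})

test_that("tnf networks carry correlation edges with consistent node weights", {
  set.seed(305)
  s <- rand_seq(5000)
  g <- tnf_network(list(g1 = s, g2 = s), edge_threshold = 0.5)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(unname(igraph::E(g)$weight), 1)
  expect_equal(unname(igraph::V(g)$weight), c(1, 1))

  g0 <- tnf_network(list(g1 = s, g2 = rand_seq(5000)), edge_threshold = 1.01)
  expect_equal(igraph::ecount(g0), 0)

  ph <- generate_phage_set(6, c(0.35, 0.60), length_range = c(24000, 28000),
                           seed = 31)
  seqs <- setNames(lapply(ph$contigs, `[[`, "sequence"),
                   vapply(ph$contigs, `[[`, "", "id"))
  grp <- rep(c(1, 2), 3) # round-robin gc groups
  net <- tnf_network(seqs, edge_threshold = 0.6)
  el <- igraph::as_data_frame(net)
  gm <- setNames(grp, names(seqs))
  within <- sum(gm[el$from] == gm[el$to])
  cross <- sum(gm[el$from] != gm[el$to])
  expect_gt(within, cross)

  # node weight stays the sum of incident edge weights after filtering
  str_manual <- vapply(names(seqs), function(v) {
    sum(el$weight[el$from == v | el$to == v])
  }, 0)
  expect_equal(unname(igraph::V(net)$weight[match(names(seqs),
                                                  igraph::V(net)$name)]),
               unname(str_manual))
})

test_that("reciprocal-smallest-distance orthologs recover planted pairs", {
  set.seed(306)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rand_prot <- function(n) paste0(sample(aa, n, TRUE), collapse = "")

  # identical proteomes of distinct proteins
  pro <- setNames(vapply(1:5, function(i) rand_prot(120), ""),
                  paste0("p", 1:5))
  pro_b <- setNames(pro, paste0("q", 1:5))
  out <- rsd_orthologs(pro, pro_b)
  expect_equal(nrow(out), 5)
  expect_true(all(out$distance == 0))
  expect_equal(sort(paste(out$protein_a, sub("q", "p", out$protein_b))),
               sort(paste(names(pro), names(pro))))

  # unrelated random proteins yield nothing under the E-value cutoff
  junk_a <- setNames(vapply(1:4, function(i) rand_prot(100), ""),
                     paste0("a", 1:4))
  junk_b <- setNames(vapply(1:4, function(i) rand_prot(100), ""),
                     paste0("b", 1:4))
  expect_equal(nrow(rsd_orthologs(junk_a, junk_b)), 0)

  # planted orthologs from the generator are recovered exactly
  ps <- generate_proteome_set(n_genomes = 2, n_core = 8, n_accessory = 4,
                              mutation_rate = 0.08, seed = 7)
  got <- rsd_orthologs(ps$proteomes$genome01, ps$proteomes$genome02)
  truth <- ps$manifest$true_orthologs
  expect_equal(sort(paste(got$protein_a, got$protein_b)),
               sort(paste(truth$protein_a, truth$protein_b)))

  # symmetric in its arguments
  swapped <- rsd_orthologs(ps$proteomes$genome02, ps$proteomes$genome01)
  expect_equal(sort(paste(swapped$protein_b, swapped$protein_a)),
               sort(paste(got$protein_a, got$protein_b)))

  expect_error(rsd_orthologs(character(0), pro), "empty proteome")
})

test_that("shared cores require a member from every genome", {
  ps <- generate_proteome_set(n_genomes = 4, n_core = 10, n_accessory = 3,
                              mutation_rate = 0.05, seed = 11)
  genomes <- names(ps$proteomes)
  prot_genome <- unlist(lapply(genomes, function(g) {
    setNames(rep(g, length(ps$proteomes[[g]])), names(ps$proteomes[[g]]))
  }))
  pairs <- list()
  for (i in 1:3) for (j in (i + 1):4) {
    pairs[[paste(genomes[i], genomes[j], sep = "|")]] <-
      rsd_orthologs(ps$proteomes[[i]], ps$proteomes[[j]])
  }
  core <- shared_core(pairs, prot_genome)
  expect_length(core, 10)
  # dropping one genome's copy of a gene removes that core group
  drop <- ps$proteomes
  drop$genome01 <- drop$genome01[names(drop$genome01) != "genome01_core01"]
  pairs2 <- pairs
  for (j in 2:4) {
    key <- paste("genome01", genomes[j], sep = "|")
    pairs2[[key]] <- rsd_orthologs(drop$genome01, ps$proteomes[[j]])
  }
  core2 <- shared_core(pairs2, prot_genome)
  expect_length(core2, 9)
})

test_that("Welch tests match the closed-form statistic and handle degeneracy", {
  prof <- rbind(matrix(rep(c(0.5, 0.5), 4), 4, 2, byrow = TRUE),
                matrix(rep(c(0.5, 0.5), 4), 4, 2, byrow = TRUE))
  prof <- prof + rep(c(-0.01, 0.01), each = 4) # equal group means? no:
  # build explicitly: equal means and variances across groups
  prof <- matrix(c(0.4, 0.6,
                   0.5, 0.5,
                   0.4, 0.6,
                   0.5, 0.5), 4, 2, byrow = TRUE)
  rownames(prof) <- paste0("g", 1:4)
  colnames(prof) <- c("catA", "catB")
  grp <- c(g1 = "mat", g2 = "mat", g3 = "sed", g4 = "sed")
  out <- welch_category_test(prof, grp)
  expect_equal(out$t, c(0, 0))
  expect_equal(out$p, c(1, 1))

  # extreme separation is significant
  prof2 <- matrix(c(0.9, 0.1, 0.91, 0.09, 0.89, 0.11, 0.9, 0.1,
                    0.1, 0.9, 0.11, 0.89, 0.09, 0.91, 0.1, 0.9),
                  8, 2, byrow = TRUE)
  rownames(prof2) <- paste0("g", 1:8)
  colnames(prof2) <- c("catA", "catB")
  grp2 <- setNames(rep(c("mat", "sed"), each = 4), paste0("g", 1:8))
  out2 <- welch_category_test(prof2, grp2)
  expect_true(all(out2$significant))

  # closed-form Welch formulas on random profiles
  set.seed(307)
  prof3 <- matrix(runif(8 * 3), 8, 3,
                  dimnames = list(paste0("g", 1:8), paste0("cat", 1:3)))
  out3 <- welch_category_test(prof3, grp2)
  x <- prof3[1:4, 2]; y <- prof3[5:8, 2]
  se2x <- var(x) / 4; se2y <- var(y) / 4
  t_manual <- (mean(x) - mean(y)) / sqrt(se2x + se2y)
  df_manual <- (se2x + se2y)^2 /
    (se2x^2 / 3 + se2y^2 / 3)
  p_manual <- 2 * pt(-abs(t_manual), df_manual)
  expect_equal(out3$t[2], t_manual)
  expect_equal(out3$df[2], df_manual)
  expect_equal(out3$p[2], p_manual)

  # zero variance in both groups
  prof4 <- matrix(c(rep(0.3, 8), rep(c(0.2, 0.8), each = 4)), 8, 2,
                  dimnames = list(paste0("g", 1:8), c("flat", "split")))
  out4 <- welch_category_test(prof4, grp2)
  expect_true(out4$degenerate[1])
  expect_false(out4$significant[1])
  expect_true(out4$degenerate[2])
  expect_true(out4$significant[2])
})

test_that("proteome trees reflect shared-ortholog distances", {
  sizes <- c(gA = 10, gB = 10, gC = 10)
  counts <- matrix(c(0, 10, 2,
                     10, 0, 2,
                     2, 2, 0), 3, 3, byrow = TRUE,
                   dimnames = list(names(sizes), names(sizes)))
  tr <- proteome_tree(counts, sizes)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, names(sizes))
  co <- ape::cophenetic.phylo(tr)
  expect_equal(co["gA", "gB"], 0) # identical pair sits at distance zero
  expect_true(all(tr$edge.length >= 0))

  # four genomes with additive distances: NJ recovers the topology
  sizes4 <- c(a = 20, b = 20, c = 20, d = 20)
  d4 <- matrix(0, 4, 4, dimnames = list(names(sizes4), names(sizes4)))
  # pairs: (a,b) close, (c,d) close, cross pairs far
  counts4 <- matrix(c(0, 18, 6, 6,
                      18, 0, 6, 6,
                      6, 6, 0, 18,
                      6, 6, 18, 0), 4, 4, byrow = TRUE,
                    dimnames = list(names(sizes4), names(sizes4)))
  tr4 <- ape::unroot(proteome_tree(counts4, sizes4))
  # a-b form a cherry: their shared internal node has no other tips
  co4 <- ape::cophenetic.phylo(tr4)
  expect_lt(co4["a", "b"], co4["a", "c"])
  expect_lt(co4["c", "d"], co4["a", "c"])

  expect_error(proteome_tree(counts[1:2, 1:2], sizes[1:2]), "at least 3")

  # newick round trip
  nwk <- tempfile(fileext = ".nwk")
  ape::write.tree(tr4, nwk)
  back <- ape::read.tree(nwk)
  expect_setequal(back$tip.label, names(sizes4))
})
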