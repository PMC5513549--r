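make_reads <- function(seqs, prefix = "r") {
  data.frame(read_id = sprintf("%s%03d", prefix, seq_along(seqs)),
             sequence = seqs, stringsAsFactors = FALSE)
}

test_that("degenerate clustering cases behave as contracted", {
  reads <- make_reads(rep("ACGTACGTACGT", 5))
  cs <- greedy_cluster(reads, 0.97)
  expect_equal(nrow(cs$centroids), 1L)
  expect_setequal(cs$members$read_id, reads$read_id)

  set.seed(1)
  seqs <- replicate(6, oracle_random_dna(30))
  cs <- greedy_cluster(make_reads(c(seqs, seqs[1:2])), 1.0)
  expect_equal(nrow(cs$centroids), length(unique(seqs)))

  expect_error(greedy_cluster(make_reads("ACGT"), 0),
               class = "gutswap_config_error")
  expect_error(greedy_cluster(make_reads("ACNT"), 0.9),
               class = "gutswap_error")
})

test_that("well-separated taxa partition into one cluster each", {
  set.seed(7)
  # three taxa with cross identity well below 0.9, reads within 1%
  taxa <- c(oracle_random_dna(120), oracle_random_dna(120), oracle_random_dna(120))
  reads <- make_reads(unlist(lapply(taxa, function(t)
    c(t, replicate(6, oracle_mutate(t, 1))))))
  truth_taxon <- rep(1:3, each = 7)
  cs <- greedy_cluster(reads, 0.97)
  expect_equal(nrow(cs$centroids), 3L)
  # members partition exactly by taxon, confirmed by the full identity matrix
  idm <- sapply(taxa, function(t) sapply(reads$sequence, function(s)
    oracle_nw(s, t)$identity))
  expect_true(all(apply(idm, 1, which.max) == truth_taxon))
  cl_of_taxon <- tapply(cs$members$cluster_id, truth_taxon, unique)
  expect_true(all(lengths(cl_of_taxon) == 1))
  expect_equal(length(unique(unlist(cl_of_taxon))), 3L)
})

test_that("every read is in exactly one cluster and meets the centroid bound", {
  set.seed(17)
  for (i in 1:6) {
    taxa <- replicate(sample(2:4, 1), oracle_random_dna(sample(40:60, 1)))
    reads <- make_reads(unlist(lapply(taxa, function(t)
      replicate(sample(3:8, 1), oracle_mutate(t, sample(0:2, 1))))))
    th <- sample(c(0.8, 0.9, 0.97), 1)
    cs <- greedy_cluster(reads, th)
    expect_setequal(cs$members$read_id, reads$read_id)
    expect_false(anyDuplicated(cs$members$read_id) > 0)
    expect_setequal(unique(cs$members$cluster_id), cs$centroids$cluster_id)
    cent <- stats::setNames(cs$centroids$centroid_sequence,
                            cs$centroids$cluster_id)
    seq_of <- stats::setNames(reads$sequence, reads$read_id)
    for (k in seq_len(nrow(cs$members))) {
      o <- oracle_nw(seq_of[[cs$members$read_id[k]]],
                     cent[[cs$members$cluster_id[k]]])
      expect_gte(o$identity, th - 1e-9)
      expect_equal(o$identity, cs$members$identity_to_centroid[k])
    }
  }
})

test_that("cluster count is non-decreasing in the threshold", {
  set.seed(23)
  taxa <- replicate(3, oracle_random_dna(50))
  reads <- make_reads(unlist(lapply(taxa, function(t)
    replicate(6, oracle_mutate(t, sample(0:3, 1))))))
  ns <- vapply(c(0.7, 0.8, 0.9, 0.97, 1.0), function(th)
    nrow(greedy_cluster(reads, th)$centroids), numeric(1))
  expect_true(all(diff(ns) >= 0))
})

test_that("clustering is invariant to input read order", {
  set.seed(31)
  taxa <- replicate(3, oracle_random_dna(60))
  reads <- make_reads(unlist(lapply(taxa, function(t)
    replicate(5, oracle_mutate(t, sample(0:2, 1))))))
  cs1 <- greedy_cluster(reads, 0.9)
  perm <- sample(nrow(reads))
  cs2 <- greedy_cluster(reads[perm, ], 0.9)
  expect_identical(cs1$centroids, cs2$centroids)
  m1 <- cs1$members[order(cs1$members$read_id), ]
  m2 <- cs2$members[order(cs2$members$read_id), ]
  rownames(m1) <- rownames(m2) <- NULL
  expect_identical(m1, m2)
})

test_that("OTU tables conserve counts and ignore read order", {
  set.seed(41)
  taxa <- replicate(2, oracle_random_dna(50))
  seqs <- unlist(lapply(taxa, function(t) replicate(5, oracle_mutate(t, 1))))
  reads <- make_reads(seqs)
  samples <- stats::setNames(rep(c("sA", "sB"), 5), reads$read_id)
  cs <- greedy_cluster(reads, 0.9)
  tbl <- build_otu_table(cs, samples)
  expect_equal(unname(colSums(tbl$counts)), c(5L, 5L))
  expect_equal(sum(tbl$counts), nrow(reads))

  cs2 <- greedy_cluster(reads[sample(nrow(reads)), ], 0.9)
  tbl2 <- build_otu_table(cs2, samples)
  expect_identical(tbl$counts, tbl2$counts)

  expect_error(build_otu_table(cs, samples[-1]), class = "gutswap_error")

  one <- greedy_cluster(make_reads(rep("ACGTACGTAC", 5)), 0.97)
  t1 <- build_otu_table(one, stats::setNames(c("a", "a", "a", "b", "b"),
                                             sprintf("r%03d", 1:5)))
  expect_equal(unname(t1$counts[1, ]), c(3L, 2L))
})

test_that("taxonomy assignment picks the deterministic best hit", {
  pool <- build_reference_pool(n_families = 4L, taxa_per_family = 2L, seed = 3L)
  ref <- pool$taxa
  # a centroid equal to a reference sequence inherits its lineage
  cents <- data.frame(cluster_id = c("OTU_0001", "OTU_0002"),
                      centroid_sequence = c(ref$sequence[5],
                                            oracle_random_dna(300)))
  tax <- assign_taxonomy(cents, ref, min_identity = 0.80)
  expect_equal(tax$best_taxon_id[1], ref$taxon_id[5])
  expect_equal(tax$family[1], ref$family[5])
  # a random sequence stays unclassified below the floor
  expect_equal(tax$family[2], "unclassified")
  expect_true(is.na(tax$best_taxon_id[2]))

  # equal-identity ties resolve to the lexicographically smaller taxon id,
  # verified against an exhaustive best-hit scan
  ref2 <- ref[c(1, 1, 2), ]
  ref2$taxon_id <- c("T_b", "T_a", "T_z")
  cents2 <- data.frame(cluster_id = "OTU_0001",
                       centroid_sequence = ref$sequence[1])
  tax2 <- assign_taxonomy(cents2, ref2)
  idm <- sapply(ref2$sequence, function(s)
    oracle_nw(ref$sequence[1], s)$identity)
  best <- max(idm)
  expect_equal(tax2$best_taxon_id,
               min(ref2$taxon_id[abs(idm - best) < 1e-12]))
  expect_equal(tax2$best_taxon_id, "T_a")
})
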