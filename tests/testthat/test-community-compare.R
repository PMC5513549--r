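toy_table <- function() {
  counts <- matrix(c(4L, 6L, 0L, 2L,
                     1L, 0L, 5L, 4L,
                     3L, 3L, 3L, 1L), nrow = 4,
                   dimnames = list(c("OTU_1", "OTU_2", "OTU_3", "OTU_4"),
                                   c("s1", "s2", "s3")))
  tax <- data.frame(otu_id = rownames(counts),
                    phylum = "P1", class = "C1",
                    order = c("O1", "O1", "O2", "O2"),
                    family = c("F1", "F1", "F2", "unclassified"),
                    genus = "unclassified")
  otu_table(counts, tax)
}

test_that("rank aggregation sums by label, pools unclassified, conserves totals", {
  tbl <- toy_table()
  fam <- aggregate_to_rank(tbl, "family")
  expect_setequal(rownames(fam$counts), c("F1", "F2", "O2_unclassified"))
  # brute-force groupby oracle
  lab <- c("F1", "F1", "F2", "O2_unclassified")
  for (s in colnames(tbl$counts)) {
    oracle <- tapply(tbl$counts[, s], lab, sum)
    expect_equal(as.vector(fam$counts[, s]),
                 as.vector(oracle[rownames(fam$counts)]))
  }
  expect_equal(colSums(fam$counts), colSums(tbl$counts))
  expect_error(aggregate_to_rank(tbl, "kingdom"), class = "gutswap_error")

  one <- tbl; one$taxonomy$family <- "F9"
  agg <- aggregate_to_rank(one, "family")
  expect_equal(nrow(agg$counts), 1L)
  expect_equal(agg$counts["F9", ], colSums(tbl$counts))
})

test_that("relative abundance columns sum to one and reject empty samples", {
  p <- relative_abundance(toy_table())
  expect_equal(unname(colSums(p)), rep(1, 3), tolerance = 1e-9)
  single <- matrix(c(5L), 1, dimnames = list("f", "s"))
  expect_equal(unname(relative_abundance(single)[1, 1]), 1)
  m <- toy_table()$counts; m[, 2] <- 0L
  expect_error(relative_abundance(m), "s2")
  # proportional scaling of one sample leaves its column unchanged
  m2 <- toy_table()$counts
  m3 <- m2; m3[, 1] <- m3[, 1] * 5L
  expect_equal(relative_abundance(m3)[, 1], relative_abundance(m2)[, 1])
})

test_that("Venn regions match brute-force set algebra", {
  a <- c("x", "y", "z"); b <- c("u", "v")
  r <- shared_membership(list(A = a, B = b))
  expect_equal(r$count[r$region == "A"], 3L)
  expect_equal(r$count[r$region == "B"], 2L)
  expect_equal(r$count[r$region == "A&B"], 0L)

  r2 <- shared_membership(list(A = a, B = a))
  expect_equal(r2$count[r2$region == "A&B"], 3L)
  expect_equal(sum(r2$count), 3L)

  set.seed(8)
  sets <- lapply(1:4, function(i) sample(letters[1:20], sample(3:15, 1)))
  names(sets) <- c("P", "Q", "R", "S")
  r4 <- shared_membership(sets)
  # independent region oracle via explicit intersections and differences
  univ <- unique(unlist(sets))
  for (k in seq_len(nrow(r4))) {
    inc <- strsplit(r4$region[k], "&", fixed = TRUE)[[1]]
    exc <- setdiff(names(sets), inc)
    members <- Reduce(intersect, sets[inc], accumulate = FALSE)
    for (e in exc) members <- setdiff(members, sets[[e]])
    expect_equal(r4$count[k], length(members))
  }
  expect_equal(sum(r4$count), length(univ))
  expect_error(shared_membership(list(A = a)), class = "gutswap_error")
})

test_that("Spearman/UPGMA dendrogram matches a hand-computed merge", {
  props <- cbind(s1 = c(1, 2, 3, 4), s2 = c(1, 2, 4, 3), s3 = c(4, 3, 2, 1))
  # rho(s1,s2) = 0.8, rho(s1,s3) = -1, rho(s2,s3) = -0.8
  hc <- correlation_dendrogram(props)
  expect_equal(hc$height, c(0.2, 1.9), tolerance = 1e-12)
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first, c("s1", "s2"))

  dup <- cbind(s1 = c(1, 2, 3), s2 = c(1, 2, 3), s3 = c(5, 1, 2))
  hcd <- correlation_dendrogram(dup)
  expect_equal(hcd$height[1], 0)
  expect_error(correlation_dendrogram(cbind(s1 = c(1, 1, 1), s2 = c(1, 2, 3))),
               "s1")
})

test_that("Bray-Curtis matches the formula and its boundary values", {
  m <- cbind(a = c(2, 0, 1), b = c(1, 1, 0))
  expect_equal(bray_curtis(m)["a", "b"], 0.6)
  eq <- cbind(a = c(1, 2), b = c(1, 2))
  expect_equal(bray_curtis(eq)["a", "b"], 0)
  dis <- cbind(a = c(1, 0), b = c(0, 1))
  expect_equal(bray_curtis(dis)["a", "b"], 1)
  bc <- bray_curtis(cbind(a = c(2, 0, 1), b = c(1, 1, 0), c = c(5, 5, 5)))
  expect_true(isSymmetric(bc))
  expect_true(all(diag(bc) == 0))
  expect_true(all(bc >= 0 & bc <= 1))
})

test_that("NMDS satisfies its stress contracts", {
  # perfectly embeddable three points
  pts <- rbind(c(0, 0), c(3, 0), c(0, 4))
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- c("p", "q", "r")
  fit <- nmds(d, k = 2)
  expect_lt(fit$stress, 1e-6)
  # accepted-iteration stress never increases
  expect_true(all(diff(fit$stress_trace) <= 1e-12))
  # self-consistency: reported stress equals stress recomputed from the output
  dvec <- as.vector(as.dist(d))
  st <- gutswap:::nmds_stress(order(dvec), fit$points)
  expect_equal(fit$stress, st$stress, tolerance = 1e-12)
  # configuration is mean-centred
  expect_equal(unname(colMeans(fit$points)), c(0, 0), tolerance = 1e-9)
  expect_error(nmds(d, k = 3), class = "gutswap_error")
})

test_that("NMDS stress depends only on dissimilarity ranks", {
  set.seed(14)
  x <- matrix(rnorm(14), 7, 2)
  d <- as.matrix(dist(x)) + 0.05
  diag(d) <- 0
  init <- cmdscale(d, k = 2)
  f1 <- nmds(d, k = 2, init = init)
  f2 <- nmds(sqrt(d), k = 2, init = init)    # strictly monotone transform
  f3 <- nmds(d^2 + 2 * d, k = 2, init = init)
  expect_equal(f1$stress, f2$stress, tolerance = 1e-6)
  expect_equal(f1$stress, f3$stress, tolerance = 1e-6)
})

test_that("heatmap selection applies the abundance and fold filters", {
  gm <- rbind(low = c(C = 0.005, CK = 0.004, K = 0.005, KC = 0.002),
              big = c(C = 0.02, CK = 0.06, K = 0.02, KC = 0.02),
              flat = c(C = 0.02, CK = 0.03, K = 0.02, KC = 0.02),
              gone = c(C = 0.05, CK = 0, K = 0.05, KC = 0.05))
  sel <- heatmap_select(gm)
  expect_setequal(sel$selected$family, c("big", "gone"))
  expect_setequal(sel$others, c("low", "flat"))
  expect_error(heatmap_select(gm[, c("C", "K")]), class = "gutswap_error")
})
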