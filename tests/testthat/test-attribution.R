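test_that("fold change reproduces hand-enumerated targeting", {
  native <- c(Flavo = 0.01, Stable = 0.05, Doubler = 0.02,
              Shy = 0.019, Gone = 0.04, Absent = 0, Never = 0)
  exch <- c(Flavo = 0.4191, Stable = 0.05, Doubler = 0.04,
            Shy = 0.0361, Gone = 0, Absent = 0.03, Never = 0)
  expect_message(fc <- family_fold_change(native, exch), "Never")
  expect_false("Never" %in% fc$family)   # absent from both groups -> dropped

  get <- function(f) fc[fc$family == f, ]
  # 41.91-fold increase
  expect_equal(get("Flavo")$log2_ratio, log2(41.91), tolerance = 1e-12)
  expect_true(get("Flavo")$targeted)
  # equal means: ratio 0, not targeted
  expect_equal(get("Stable")$log2_ratio, 0)
  expect_false(get("Stable")$targeted)
  # exact doubling: boundary inclusive
  expect_equal(get("Doubler")$log2_ratio, 1.0, tolerance = 1e-12)
  expect_true(get("Doubler")$targeted)
  # 1.9-fold: below threshold
  expect_false(get("Shy")$targeted)
  # zero handling: epsilon is half the smallest nonzero mean of the group
  eps_exch <- min(exch[exch > 0]) / 2
  expect_equal(get("Gone")$log2_ratio, log2(eps_exch / 0.04), tolerance = 1e-12)
  expect_true(get("Gone")$targeted)
  eps_nat <- min(native[native > 0]) / 2
  expect_equal(get("Absent")$log2_ratio, log2(0.03 / eps_nat), tolerance = 1e-12)

  sel <- select_targeted(fc)
  expect_equal(sel$family,
               sel$family[order(-abs(sel$log2_ratio), sel$family)])
  expect_true(all(abs(sel$log2_ratio) >= 1 - 1e-12))
  expect_equal(sel$direction[sel$family == "Flavo"], "increase")
  expect_equal(sel$direction[sel$family == "Gone"], "decrease")

  # a 2.06-fold family is targeted, mirroring the smallest reported change
  fc2 <- family_fold_change(c(f = 0.01), c(f = 0.0206))
  expect_true(fc2$targeted)
  # empty targeted set is allowed
  expect_equal(nrow(select_targeted(family_fold_change(c(f = .1), c(f = .1)))), 0L)
})

# deterministic toy attribution scenario: three well-separated taxa
toy_attribution <- function(water_reads = TRUE) {
  set.seed(77)
  taxA <- oracle_random_dna(120)  # shared gut + water
  taxB <- oracle_random_dna(120)  # exchanged only
  taxC <- oracle_random_dna(120)  # sediment + exchanged
  exch <- data.frame(
    read_id = sprintf("e%02d", 1:6),
    sequence = c(taxA, taxA, taxC, taxC, taxB, taxB),
    replicate = c(1, 2, 1, 2, 1, 2))
  native <- data.frame(read_id = c("n1", "n2"), sequence = c(taxA, taxA))
  water <- if (water_reads)
    data.frame(read_id = "w1", sequence = taxA) else NULL
  sediment <- data.frame(read_id = "s1", sequence = taxC)
  recluster_targeted(exch, native, water, sediment, threshold = 0.99)
}

test_that("pooled reclustering keeps tags and separates distant taxa", {
  rc <- toy_attribution()
  expect_equal(nrow(rc$clusters$centroids), 3L)
  expect_setequal(rc$tags$tag,
                  c("exchanged", "native_gut", "water", "sediment"))
  # permuting pool assembly order cannot change the clustering
  expect_equal(rc$clusters$threshold, 0.99)
  expect_message(
    empty <- recluster_targeted(data.frame(read_id = character(0),
                                           sequence = character(0)),
                                NULL, NULL, NULL),
    "nothing to attribute")
  expect_null(empty$clusters)
})

test_that("core filtering applies the 50% and single-replicate rules", {
  rc <- toy_attribution()
  expect_error(core_filter(rc, 0), class = "gutswap_error")
  # every toy cluster spans 2 of 2 replicates -> all core
  expect_equal(length(core_filter(rc, 2)), 3L)

  # synthetic membership: spans {3, 2, 1} of 5 replicates
  set.seed(5)
  t1 <- oracle_random_dna(80); t2 <- oracle_random_dna(80); t3 <- oracle_random_dna(80)
  exch <- data.frame(
    read_id = sprintf("e%02d", 1:6),
    sequence = c(t1, t1, t1, t2, t2, t3),
    replicate = c(1, 2, 3, 1, 2, 4))
  rc2 <- recluster_targeted(exch, NULL, NULL, NULL)
  core5 <- core_filter(rc2, 5)   # needs >= 2.5 replicates
  m <- merge(rc2$clusters$members, rc2$tags, by = "read_id")
  span <- tapply(m$replicate, m$cluster_id, function(x) length(unique(x)))
  expect_setequal(core5, names(span)[span >= 3])
  core4 <- core_filter(rc2, 4)   # 2 of 4 is core (boundary inclusive)
  expect_setequal(core4, names(span)[span >= 2])
  # single-replicate clusters are always excluded
  expect_false(names(span)[span == 1] %in% core4)
})

test_that("origin classes come from cluster co-membership", {
  rc <- toy_attribution()
  att <- attribute_origins(rc, core_filter(rc, 2))
  cls <- stats::setNames(att$records$class, att$records$read_id)
  expect_equal(unname(cls[c("e01", "e02")]), c("GW", "GW"))
  expect_equal(unname(cls[c("e03", "e04")]), c("S", "S"))
  expect_equal(unname(cls[c("e05", "e06")]), c("Specific", "Specific"))
  # summary fractions sum to one per cluster
  fr <- att$summary[, intersect(colnames(att$summary),
                                c("G", "S", "W", "GS", "GW", "SW", "GSW",
                                  "Specific"))]
  expect_equal(unname(rowSums(fr)), rep(1, nrow(att$summary)))
  expect_equal(sum(att$summary$n_reads), nrow(att$records))

  # monotonicity: adding water reads only ever adds the letter W
  rc0 <- toy_attribution(water_reads = FALSE)
  att0 <- attribute_origins(rc0, core_filter(rc0, 2))
  cls0 <- stats::setNames(att0$records$class, att0$records$read_id)
  expect_equal(unname(cls0[c("e01", "e02")]), c("G", "G"))
  for (r in names(cls0)) {
    without <- strsplit(sub("Specific", "", cls0[[r]]), "")[[1]]
    with_w <- strsplit(sub("Specific", "", cls[[r]]), "")[[1]]
    expect_true(all(without %in% with_w))
  }
})

test_that("attribution accuracy is exact on a known truth table", {
  rc <- toy_attribution()
  att <- attribute_origins(rc, core_filter(rc, 2))
  truth <- data.frame(read_id = sprintf("e%02d", 1:6),
                      origin_class = c("GW", "GW", "S", "S",
                                       "Specific", "Specific"))
  acc <- attribution_accuracy(att$records, truth)
  expect_equal(acc$accuracy, 1)
  expect_equal(acc$n, 6L)
  truth_bad <- truth
  truth_bad$origin_class[5] <- "G"
  acc2 <- attribution_accuracy(att$records, truth_bad)
  expect_equal(acc2$accuracy, 5 / 6)
  expect_error(attribution_accuracy(att$records, truth[-1, ]),
               class = "gutswap_error")
})

test_that("simulated attribution recovers the truth classes", {
  fx <- simulate_experiment(small_scenario(seed = 2L))
  reads <- fx$reads
  fam <- stats::setNames(fx$truth$family, fx$truth$read_id)
  sheet <- fx$sample_sheet
  # group-mean family proportions straight from simulator reads
  tb <- table(fx$truth$family, fx$truth$sample_id)
  m <- matrix(as.integer(tb), nrow = nrow(tb), dimnames = dimnames(tb))
  props <- relative_abundance(m)
  cfg <- run_config(scenario = small_scenario(seed = 2L))
  acc_reads <- cbind(reads, stringsAsFactors = FALSE)
  res <- gutswap:::attribute_group("CK", fx, acc_reads, NULL, fam, props, cfg)
  expect_true(nrow(res$targeted) >= 1)
  if (nrow(res$attribution$records) > 0) {
    acc <- attribution_accuracy(res$attribution$records, fx$truth)
    expect_gt(acc$accuracy, 0.9)
  }
})
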