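test_that("reference pools are deterministic per seed with valid lineages", {
  p1 <- build_reference_pool(n_families = 4L, taxa_per_family = 2L, seed = 7L)
  p2 <- build_reference_pool(n_families = 4L, taxa_per_family = 2L, seed = 7L)
  expect_identical(p1, p2)
  p3 <- build_reference_pool(n_families = 4L, taxa_per_family = 2L, seed = 8L)
  expect_false(identical(p1$taxa$sequence, p3$taxa$sequence))

  expect_equal(nrow(p1$taxa), 8L)
  expect_false(anyDuplicated(p1$taxa$taxon_id) > 0)
  for (rk in c("phylum", "class", "order", "family", "genus"))
    expect_true(all(nzchar(p1$taxa[[rk]])))
  expect_true(all(nchar(p1$taxa$sequence) >= 295 &
                  nchar(p1$taxa$sequence) <= 311))

  p <- build_reference_pool(n_families = 2L, taxa_per_family = 1L, seed = 1L)
  expect_equal(nrow(p$taxa), 2L)
  expect_false(p$taxa$family[1] == p$taxa$family[2])
})

test_that("configured cross-family identity lands in the expected band", {
  p <- build_reference_pool(seed = 3L)  # between-family target 0.85
  set.seed(5)
  i <- sample(nrow(p$taxa), 24)
  idm <- identity_matrix(p$taxa$sequence[i[1:12]], p$taxa$sequence[i[13:24]])
  cross <- idm[outer(p$taxa$family[i[1:12]], p$taxa$family[i[13:24]], "!=")]
  expect_gt(mean(cross), 0.80)
  expect_lt(mean(cross), 0.90)
  expect_true(all(cross < 0.97))  # below the community clustering threshold
})

test_that("pool construction rejects invalid configurations", {
  expect_error(build_reference_pool(n_families = 1L),
               class = "gutswap_config_error")
  expect_error(build_reference_pool(between_family_identity = 0.95,
                                    within_family_identity = 0.93),
               class = "gutswap_config_error")
})

test_that("community profiles follow the log-normal ranked-abundance model", {
  pool <- build_reference_pool(n_families = 5L, taxa_per_family = 4L, seed = 2L)
  pr <- sample_community_profile(pool, "X", richness = 10L, sigma = 1, seed = 9L)
  expect_length(pr$weights, 10L)
  expect_true(all(pr$weights > 0))
  expect_equal(sum(pr$weights), 1, tolerance = 1e-12)
  expect_true(all(diff(sort(pr$weights, decreasing = TRUE)) <= 0))

  # sigma = 0 degenerates to the uniform profile
  u <- sample_community_profile(pool, "U", richness = 8L, sigma = 0, seed = 1L)
  expect_equal(unname(u$weights), rep(1 / 8, 8))

  full <- sample_community_profile(pool, "F", richness = nrow(pool$taxa))
  expect_setequal(names(full$weights), pool$taxa$taxon_id)
  expect_error(sample_community_profile(pool, "E", richness = 99L),
               class = "gutswap_error")
})

test_that("simulated experiments have exact read counts and seed determinism", {
  cfg <- small_scenario(seed = 5L)
  fx <- simulate_experiment(cfg)
  counts <- table(fx$reads$sample_id)
  expect_true(all(counts == cfg$reads_per_sample))
  expect_equal(nrow(fx$truth), nrow(fx$reads))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir(); d3 <- withr::local_tempdir()
  f1 <- simulate_experiment(cfg, d1)
  f2 <- simulate_experiment(cfg, d2)
  for (s in names(f1$paths$fastq))
    expect_identical(readLines(f1$paths$fastq[[s]]),
                     readLines(f2$paths$fastq[[s]]))
  f3 <- simulate_experiment(small_scenario(seed = 6L), d3)
  expect_false(identical(readLines(f1$paths$fastq[[1]]),
                         readLines(f3$paths$fastq[[1]])))
})

test_that("truth origin classes match source-community membership exactly", {
  fx <- simulate_experiment(small_scenario(seed = 11L))
  tr <- fx$truth[fx$truth$sample_id %in%
                   fx$sample_sheet$sample_id[fx$sample_sheet$group %in%
                                               c("CK", "KC")], ]
  grp <- sub("_[0-9]+$", "", tr$sample_id)
  for (g in c("CK", "KC")) {
    ss <- fx$source_sets[[g]]
    sub <- tr[grp == g, ]
    expected <- paste0(ifelse(sub$taxon_id %in% ss$g, "G", ""),
                       ifelse(sub$taxon_id %in% ss$s, "S", ""),
                       ifelse(sub$taxon_id %in% ss$w, "W", ""))
    expected[expected == ""] <- "Specific"
    expect_identical(sub$origin_class, expected)
  }
  # reads drawn from the indigenous pool always share with the native gut
  ind <- tr[tr$source_pool == "indigenous", ]
  expect_true(all(grepl("G", ind$origin_class)))
  # native samples carry no origin class
  expect_true(all(is.na(fx$truth$origin_class[!fx$truth$sample_id %in%
                                                tr$sample_id])))
})

test_that("degenerate mixing weights behave as contracted", {
  no_specific <- c(indigenous = 0.6, water = 0.25, sediment = 0.15, specific = 0)
  fx <- simulate_experiment(small_scenario(seed = 3L, mixing = no_specific))
  ex <- fx$truth[!is.na(fx$truth$origin_class), ]
  expect_false(any(ex$source_pool == "specific"))
  expect_false(any(ex$origin_class == "Specific"))

  all_ind <- c(indigenous = 1, water = 0, sediment = 0, specific = 0)
  fx2 <- simulate_experiment(small_scenario(seed = 3L, mixing = all_ind))
  ex2 <- fx2$truth[!is.na(fx2$truth$origin_class), ]
  expect_true(all(grepl("G", ex2$origin_class)))

  bad <- c(indigenous = 0.9, water = 0.2, sediment = 0, specific = 0)
  expect_error(simulate_experiment(small_scenario(mixing = bad)),
               class = "gutswap_config_error")
})

test_that("read mutation rate matches the configured divergence", {
  cfg <- small_scenario(seed = 21L)
  fx <- simulate_experiment(cfg)
  seqs <- stats::setNames(fx$pool$taxa$sequence, fx$pool$taxa$taxon_id)
  source_seq <- seqs[fx$reads$taxon_id]
  n_mm <- mapply(function(r, s) {
    sum(utf8ToInt(r) != utf8ToInt(s))
  }, fx$reads$sequence, source_seq, USE.NAMES = FALSE)
  total_bases <- sum(nchar(fx$reads$sequence))
  p <- cfg$within_taxon_read_divergence
  se <- sqrt(p * (1 - p) / total_bases)
  expect_lt(abs(sum(n_mm) / total_bases - p), 3 * se)
})
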