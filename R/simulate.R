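# Simulation of the habitat-exchange experiment: two habitats (lake "C",
# river "K"), native gut groups C and K, exchanged groups CK (lake-to-river)
# and KC (river-to-lake), plus water and sediment source communities per
# habitat. Every emitted read records its true taxon, the pool it was drawn
# from, and (for exchanged guts) the origin class implied by which source
# communities carry its taxon.

ORIGIN_CLASSES <- c("G", "S", "W", "GS", "GW", "SW", "GSW", "Specific")

FORWARD_PRIMER <- "AGAGTTTGATCMTGGCTCAG"   # 27F, IUPAC M = A or C
REVERSE_PRIMER <- "GCTGCCTCCCGAGGAGT"      # 355R, applied at the 3' end as given

#' Scenario configuration for the habitat-exchange simulator
#'
#' Defaults encode the study design being emulated: V1-V2-like amplicons of
#' about 303 bp, gut groups C (3 replicates), K (6), CK (5), KC (5), river
#' source communities twice as rich as lake ones, and exchanged-gut reads drawn
#' from indigenous-gut / new-water / new-sediment / group-specific pools.
#'
#' @param n_families,taxa_per_family,seq_len_range,between_family_identity,
#'   within_family_identity reference-pool parameters, see
#'   [build_reference_pool()].
#' @param within_taxon_read_divergence per-base substitution probability applied
#'   independently to every emitted read.
#' @param richness named integer vector of master-community richness for
#'   C_gut, K_gut, CW, CS, KW, KS (river sources default to 2x lake).
#' @param specific_richness taxa in each exchanged group's group-specific pool.
#' @param replicates named integer vector of gut replicate counts (all >= 3).
#' @param env_replicates replicate samples per environmental community.
#' @param reads_per_sample reads emitted per sample.
#' @param mixing mixing weights (indigenous, water, sediment, specific) for
#'   exchanged-gut reads, each set summing to 1: either one named numeric
#'   vector applied to both exchanged groups, or a list with elements `CK` and
#'   `KC`. The default gives the group moved to the richer river habitat a
#'   larger environmental share than the group moved to the poorer lake,
#'   reflecting colonization pressure scaling with habitat diversity.
#' @param abundance_sigma log-normal shape of master community profiles.
#' @param gut_capacity taxa an individual gut realizes from its source
#'   community (the colonization bottleneck: richer sources yield more
#'   divergent individuals).
#' @param acquisition_capacity taxa an exchanged individual acquires from each
#'   of the new habitat's water and sediment communities.
#' @param env_subsample fraction of master taxa a bulk water/sediment sample
#'   retains (environmental samples aggregate far more material than a gut).
#' @param indiv_sigma log-normal jitter applied to retained weights.
#' @param barcode_length sample barcode length in nt.
#' @param quality_phred constant per-base Phred score of emitted reads.
#' @param seed integer seed governing the whole simulation.
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(n_families = 20L, taxa_per_family = 5L,
                            seq_len_range = c(295L, 311L),
                            between_family_identity = 0.85,
                            within_family_identity = 0.93,
                            within_taxon_read_divergence = 0.005,
                            richness = c(C_gut = 25L, K_gut = 50L, CW = 20L,
                                         CS = 25L, KW = 40L, KS = 50L),
                            specific_richness = 8L,
                            replicates = c(C = 3L, K = 6L, CK = 5L, KC = 5L),
                            env_replicates = 3L,
                            reads_per_sample = 2000L,
                            mixing = list(
                              CK = c(indigenous = 0.50, water = 0.25,
                                     sediment = 0.15, specific = 0.10),
                              KC = c(indigenous = 0.75, water = 0.08,
                                     sediment = 0.07, specific = 0.10)),
                            abundance_sigma = 1,
                            gut_capacity = 20L, acquisition_capacity = 8L,
                            env_subsample = 0.9, indiv_sigma = 0.5,
                            barcode_length = 10L,
                            quality_phred = 38L,
                            seed = 1L) {
  cfg <- list(n_families = as.integer(n_families),
              taxa_per_family = as.integer(taxa_per_family),
              seq_len_range = as.integer(seq_len_range),
              between_family_identity = between_family_identity,
              within_family_identity = within_family_identity,
              within_taxon_read_divergence = within_taxon_read_divergence,
              richness = richness, specific_richness = as.integer(specific_richness),
              replicates = replicates, env_replicates = as.integer(env_replicates),
              reads_per_sample = as.integer(reads_per_sample),
              mixing = if (is.list(mixing)) mixing else
                list(CK = mixing, KC = mixing),
              abundance_sigma = abundance_sigma,
              gut_capacity = as.integer(gut_capacity),
              acquisition_capacity = as.integer(acquisition_capacity),
              env_subsample = env_subsample, indiv_sigma = indiv_sigma,
              barcode_length = as.integer(barcode_length),
              quality_phred = as.integer(quality_phred),
              seed = as.integer(seed))
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  probs <- c(cfg$within_taxon_read_divergence, unlist(cfg$mixing),
             cfg$env_subsample)
  if (any(probs < 0 | probs > 1))
    gs_config_error("all probabilities must be in [0, 1]")
  if (cfg$gut_capacity < 1L || cfg$acquisition_capacity < 1L)
    gs_config_error("capacities must be >= 1")
  if (!setequal(names(cfg$mixing), c("CK", "KC")))
    gs_config_error("mixing must be one weight set or a list for CK and KC")
  for (g in names(cfg$mixing)) {
    mx <- cfg$mixing[[g]]
    if (abs(sum(mx) - 1) > 1e-9)
      gs_config_error("mixing weights must sum to 1")
    if (!setequal(names(mx), c("indigenous", "water", "sediment", "specific")))
      gs_config_error("mixing must name indigenous, water, sediment, specific")
  }
  if (!setequal(names(cfg$replicates), c("C", "K", "CK", "KC")))
    gs_config_error("replicates must name the four gut groups C, K, CK, KC")
  if (any(cfg$replicates < 3L))
    gs_config_error("gut replicate counts must all be >= 3")
  need <- c("C_gut", "K_gut", "CW", "CS", "KW", "KS")
  if (!all(need %in% names(cfg$richness)))
    gs_config_error("richness must name C_gut, K_gut, CW, CS, KW, KS")
  if (cfg$reads_per_sample < 1L) gs_config_error("reads_per_sample must be >= 1")
  if (cfg$env_replicates < 1L) gs_config_error("env_replicates must be >= 1")
  invisible(cfg)
}

# barcodes by rejection sampling: pairwise Hamming distance >= 4 so one-error
# assignment is never ambiguous (needs > 2 * max_barcode_mismatch)
generate_barcodes <- function(n, len = 10L, min_dist = 4L) {
  codes <- character(0)
  mat <- NULL
  tries <- 0L
  while (length(codes) < n) {
    tries <- tries + 1L
    if (tries > 10000L) gs_stop("failed to generate distinct barcodes")
    cand <- sample(BASES, len, replace = TRUE)
    if (!is.null(mat) && any(colSums(mat != cand) < min_dist)) next
    mat <- cbind(mat, cand)
    codes <- c(codes, paste(cand, collapse = ""))
  }
  codes
}

hamming_identity_sites <- function(a, b) {
  # site identity of equal-length strings (simulator internals only)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  mean(av == bv)
}

group_design <- function(cfg) {
  g <- list(
    C  = list(type = "gut", habitat = "lake",  n = cfg$replicates[["C"]],
              components = c(indigenous = "C_gut")),
    K  = list(type = "gut", habitat = "river", n = cfg$replicates[["K"]],
              components = c(indigenous = "K_gut")),
    CK = list(type = "gut", habitat = "river", n = cfg$replicates[["CK"]],
              exchanged = TRUE, native_gut_group = "C",
              env_groups = c(water = "KW", sediment = "KS"),
              components = c(indigenous = "C_gut", water = "KW",
                             sediment = "KS", specific = "CK_specific")),
    KC = list(type = "gut", habitat = "lake", n = cfg$replicates[["KC"]],
              exchanged = TRUE, native_gut_group = "K",
              env_groups = c(water = "CW", sediment = "CS"),
              components = c(indigenous = "K_gut", water = "CW",
                             sediment = "CS", specific = "KC_specific")),
    CW = list(type = "water",    habitat = "lake",  n = cfg$env_replicates,
              components = c(indigenous = "CW")),
    CS = list(type = "sediment", habitat = "lake",  n = cfg$env_replicates,
              components = c(indigenous = "CS")),
    KW = list(type = "water",    habitat = "river", n = cfg$env_replicates,
              components = c(indigenous = "KW")),
    KS = list(type = "sediment", habitat = "river", n = cfg$env_replicates,
              components = c(indigenous = "KS")))
  g
}

# origin class of exchanged-gut reads, from the taxon sets the three source
# communities realize in the experiment (union over the native group's
# individual gut profiles, and over the new habitat's water/sediment samples)
origin_class_for <- function(taxon_ids, g_set, s_set, w_set) {
  inG <- taxon_ids %in% g_set
  inS <- taxon_ids %in% s_set
  inW <- taxon_ids %in% w_set
  cls <- paste0(ifelse(inG, "G", ""), ifelse(inS, "S", ""), ifelse(inW, "W", ""))
  cls[cls == ""] <- "Specific"
  cls
}

#' Simulate a habitat-exchange amplicon experiment
#'
#' Builds the reference pool and the six source-community master profiles,
#' realizes per-individual profiles, emits reads (taxon sequence mutated i.i.d.
#' per base), and records per-read ground truth: true taxon, generating pool,
#' and for exchanged-gut reads the origin class (G/S/W combinations or
#' Specific) implied by master-community membership. Optionally writes the
#' whole fixture set (per-sample FASTQ with barcode and primers, sample sheet,
#' truth table, lineage map, reference FASTA, manifest) under `out_dir`.
#'
#' @param config a [scenario_config()].
#' @param out_dir optional directory to write the fixture files into.
#' @return A `fixture_set` list: `pool`, `masters`, `sample_sheet`, `reads`
#'   (read_id, sample_id, taxon_id, sequence), `truth` (adds source_pool,
#'   origin_class, family), `barcode_map`, `config`, and `paths` when written.
#' @export
simulate_experiment <- function(config = scenario_config(), out_dir = NULL) {
  validate_scenario_config(config)
  set.seed(config$seed)

  pool <- build_reference_pool(config$n_families, config$taxa_per_family,
                               config$seq_len_range,
                               config$between_family_identity,
                               config$within_family_identity, seed = NULL)
  taxa_seq <- stats::setNames(pool$taxa$sequence, pool$taxa$taxon_id)
  taxa_family <- stats::setNames(pool$taxa$family, pool$taxa$taxon_id)

  masters <- list()
  for (cm in c("C_gut", "K_gut", "CW", "CS", "KW", "KS")) {
    masters[[cm]] <- sample_community_profile(
      pool, cm, richness = config$richness[[cm]],
      sigma = config$abundance_sigma, seed = NULL)
  }
  # group-specific pools: taxa absent from native gut and both new-habitat
  # source communities, so their reads are Specific by construction
  for (sp in list(c("CK_specific", "C_gut", "KW", "KS"),
                  c("KC_specific", "K_gut", "CW", "CS"))) {
    used <- unique(unlist(lapply(masters[sp[2:4]], function(m) names(m$weights))))
    free <- setdiff(pool$taxa$taxon_id, used)
    if (length(free) < config$specific_richness)
      gs_config_error("pool too small for the configured specific_richness")
    ids <- sample(free, config$specific_richness)
    w <- rlnorm(length(ids), 0, config$abundance_sigma)
    w <- w / sum(w); names(w) <- ids
    masters[[sp[1]]] <- structure(list(community_id = sp[1], weights = w),
                                  class = "community_profile")
  }

  design <- group_design(config)
  sample_ids <- unlist(lapply(names(design), function(g)
    sprintf("%s_%d", g, seq_len(design[[g]]$n))))
  barcodes <- generate_barcodes(length(sample_ids), config$barcode_length)
  names(barcodes) <- sample_ids

  # --- phase 1: realize individual profiles, source communities first -------
  # (native guts and environments are drawn before the exchanged groups, whose
  # indigenous and acquired components come from those REALIZED communities)
  profiles <- list()
  draw_order <- c("C", "K", "CW", "CS", "KW", "KS", "CK", "KC")
  realized_community <- function(group) {
    # the community a group realizes in the experiment: mean of its
    # individuals' profiles over the union of their taxa
    ps <- lapply(profiles[sprintf("%s_%d", group, seq_len(design[[group]]$n))],
                 `[[`, "indigenous")
    ids <- unique(unlist(lapply(ps, function(p) names(p$weights))))
    w <- rowMeans(vapply(ps, function(p) {
      v <- stats::setNames(numeric(length(ids)), ids)
      v[names(p$weights)] <- p$weights
      v
    }, numeric(length(ids))))
    structure(list(community_id = paste0(group, "_realized"), weights = w / sum(w)),
              class = "community_profile")
  }
  realized <- list()
  for (g in draw_order) {
    d <- design[[g]]
    for (rep_i in seq_len(d$n)) {
      sid <- sprintf("%s_%d", g, rep_i)
      if (isTRUE(d$exchanged)) {
        src <- list(indigenous = realized[[d$native_gut_group]],
                    water = realized[[d$env_groups[["water"]]]],
                    sediment = realized[[d$env_groups[["sediment"]]]],
                    specific = masters[[d$components[["specific"]]]])
        profiles[[sid]] <- list(
          indigenous = draw_individual_profile(
            src$indigenous, capacity = config$gut_capacity,
            jitter_sigma = config$indiv_sigma),
          water = draw_individual_profile(
            src$water, capacity = config$acquisition_capacity,
            jitter_sigma = config$abundance_sigma, colonize = TRUE),
          sediment = draw_individual_profile(
            src$sediment, capacity = config$acquisition_capacity,
            jitter_sigma = config$abundance_sigma, colonize = TRUE),
          specific = draw_individual_profile(
            src$specific, subsample = 1, jitter_sigma = config$indiv_sigma))
      } else if (d$type == "gut") {
        profiles[[sid]] <- list(indigenous = draw_individual_profile(
          masters[[d$components[["indigenous"]]]],
          capacity = config$gut_capacity, jitter_sigma = config$indiv_sigma))
      } else {
        profiles[[sid]] <- list(indigenous = draw_individual_profile(
          masters[[d$components[["indigenous"]]]],
          subsample = config$env_subsample, jitter_sigma = config$indiv_sigma))
      }
    }
    if (!isTRUE(d$exchanged)) realized[[g]] <- realized_community(g)
  }

  # taxon sets carried by each exchanged group's three source communities
  source_sets <- lapply(design[c("CK", "KC")], function(d) list(
    g = names(realized[[d$native_gut_group]]$weights),
    s = names(realized[[d$env_groups[["sediment"]]]]$weights),
    w = names(realized[[d$env_groups[["water"]]]]$weights)))

  # --- phase 2: emit reads ---------------------------------------------------
  sheet_rows <- list(); read_rows <- list()
  ri <- 0L
  for (g in names(design)) {
    d <- design[[g]]
    exchanged <- isTRUE(d$exchanged)
    for (rep_i in seq_len(d$n)) {
      sid <- sprintf("%s_%d", g, rep_i)
      indiv <- profiles[[sid]]
      n <- config$reads_per_sample
      if (exchanged) {
        mx <- config$mixing[[g]]
        pool_of_read <- sample(names(mx), n, replace = TRUE, prob = mx)
      } else {
        pool_of_read <- rep("indigenous", n)
      }
      taxon <- character(n)
      for (comp in unique(pool_of_read)) {
        idx <- which(pool_of_read == comp)
        w <- indiv[[comp]]$weights
        taxon[idx] <- sample(names(w), length(idx), replace = TRUE, prob = w)
      }
      seqs <- vapply(taxa_seq[taxon], mutate_sequence, character(1),
                     rate = config$within_taxon_read_divergence,
                     USE.NAMES = FALSE)
      cls <- if (exchanged) {
        ss <- source_sets[[g]]
        origin_class_for(taxon, ss$g, ss$s, ss$w)
      } else rep(NA_character_, n)
      ri <- ri + 1L
      read_rows[[ri]] <- data.frame(
        read_id = sprintf("%s_r%06d", sid, seq_len(n)),
        sample_id = sid, taxon_id = taxon,
        family = unname(taxa_family[taxon]),
        source_pool = pool_of_read, origin_class = cls,
        sequence = seqs, stringsAsFactors = FALSE)
      sheet_rows[[ri]] <- data.frame(
        sample_id = sid, group = g, type = d$type, habitat = d$habitat,
        replicate = rep_i, barcode = barcodes[[sid]],
        stringsAsFactors = FALSE)
    }
  }
  reads <- do.call(rbind, read_rows)
  rownames(reads) <- NULL
  sheet <- do.call(rbind, sheet_rows)
  rownames(sheet) <- NULL

  fx <- structure(list(pool = pool, masters = masters, profiles = profiles,
                       realized = realized, source_sets = source_sets,
                       sample_sheet = sheet,
                       reads = reads[c("read_id", "sample_id", "taxon_id", "sequence")],
                       truth = reads[c("read_id", "sample_id", "taxon_id",
                                       "family", "source_pool", "origin_class")],
                       barcode_map = barcodes, config = config),
                  class = "fixture_set")
  if (!is.null(out_dir)) fx$paths <- write_fixture_set(fx, out_dir)
  fx
}

# barcoded, primer-flanked FASTQ record sequences (forward primer M resolved
# to A or C at random, as a real degenerate primer batch would be)
barcoded_read_sequences <- function(fx) {
  n <- nrow(fx$reads)
  fwd <- rep(FORWARD_PRIMER, n)
  m_pos <- regexpr("M", FORWARD_PRIMER, fixed = TRUE)
  substr(fwd, m_pos, m_pos) <- sample(c("A", "C"), n, replace = TRUE)
  paste0(fx$barcode_map[fx$reads$sample_id], fwd, fx$reads$sequence,
         REVERSE_PRIMER)
}

write_fixture_set <- function(fx, out_dir) {
  dir.create(file.path(out_dir, "fastq"), recursive = TRUE, showWarnings = FALSE)
  qchar <- rawToChar(as.raw(fx$config$quality_phred + 33L))
  full_seq <- barcoded_read_sequences(fx)
  fastq_paths <- character(0)
  for (sid in fx$sample_sheet$sample_id) {
    idx <- which(fx$reads$sample_id == sid)
    path <- file.path(out_dir, "fastq", paste0(sid, ".fastq"))
    lines <- as.vector(rbind(paste0("@", fx$reads$read_id[idx]),
                             full_seq[idx], "+",
                             vapply(nchar(full_seq[idx]),
                                    function(k) strrep(qchar, k), character(1))))
    writeLines(lines, path)
    fastq_paths[sid] <- path
  }
  sheet <- fx$sample_sheet
  sheet$fastq <- basename(fastq_paths[sheet$sample_id])
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- list(fastq = fastq_paths,
                sample_sheet = tsv(sheet, "sample_sheet.tsv"),
                truth = tsv(fx$truth, "truth.tsv"),
                lineage = tsv(fx$pool$taxa[c("taxon_id", LINEAGE_RANKS)],
                              "lineage.tsv"))
  ref <- Biostrings::DNAStringSet(stats::setNames(fx$pool$taxa$sequence,
                                                  fx$pool$taxa$taxon_id))
  paths$reference <- file.path(out_dir, "reference.fasta")
  Biostrings::writeXStringSet(ref, paths$reference)
  manifest <- list(seed = fx$config$seed,
                   config = unclass(fx$config),
                   n_samples = nrow(fx$sample_sheet),
                   n_reads = nrow(fx$reads),
                   files = lapply(paths, function(p) unname(basename(p))))
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}
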