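# End-to-end orchestration: simulate -> demultiplex/QC -> cluster -> diversity
# -> community comparison -> source attribution, with a manifest recording the
# configuration hash, seed and per-stage row counts. Reruns with the same
# configuration and seed reproduce every tabular output byte for byte.

PIPELINE_STAGES <- c("simulate", "demux", "cluster", "diversity", "compare",
                     "attribute")

#' Run configuration for the full pipeline
#'
#' @param scenario a [scenario_config()] describing the simulated experiment.
#' @param qc a [qc_policy()].
#' @param community_threshold OTU clustering identity (default 0.97).
#' @param attribution_threshold re-clustering identity (default 0.99).
#' @param fold_threshold |log2 ratio| above which a family is targeted
#'   (default 1, i.e. 2-fold).
#' @param core_fraction fraction of exchanged replicates a core cluster must
#'   span (default 0.5).
#' @param min_taxonomy_identity best-hit classification floor (default 0.80).
#' @param scoring an [alignment_scoring()].
#' @return A validated `run_config`.
#' @export
run_config <- function(scenario = scenario_config(), qc = qc_policy(),
                       community_threshold = 0.97,
                       attribution_threshold = 0.99,
                       fold_threshold = 1, core_fraction = 0.5,
                       min_taxonomy_identity = 0.80,
                       scoring = alignment_scoring()) {
  cfg <- structure(list(scenario = scenario, qc = qc,
                        community_threshold = community_threshold,
                        attribution_threshold = attribution_threshold,
                        fold_threshold = fold_threshold,
                        core_fraction = core_fraction,
                        min_taxonomy_identity = min_taxonomy_identity,
                        scoring = scoring),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  for (th in c("community_threshold", "attribution_threshold",
               "min_taxonomy_identity", "core_fraction")) {
    v <- cfg[[th]]
    if (!is.numeric(v) || length(v) != 1 || !(v > 0 && v <= 1))
      gs_config_error(sprintf("%s must be in (0, 1]", th))
  }
  if (!(cfg$fold_threshold > 0)) gs_config_error("fold_threshold must be > 0")
  validate_scenario_config(cfg$scenario)
  if (cfg$qc$barcode_length != cfg$scenario$barcode_length)
    gs_config_error("qc and scenario barcode lengths disagree")
  invisible(cfg)
}

config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  jsonlite::write_json(rapply(unclass(cfg), unclass, how = "replace"), tf,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

tsv_out <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# group-mean relative abundances, features x groups
group_mean_props <- function(props, metadata) {
  groups <- sort(unique(metadata$group))
  out <- vapply(groups, function(g) {
    ids <- metadata$sample_id[metadata$group == g]
    rowMeans(props[, ids, drop = FALSE])
  }, numeric(nrow(props)))
  matrix(out, nrow = nrow(props), dimnames = list(rownames(props), groups))
}

# attribution for one exchanged group; used by run_pipeline and the
# acceptance/analysis drivers
attribute_group <- function(group, fx, accepted, members, fam_of_read,
                            props_fam, cfg) {
  sheet <- fx$sample_sheet
  design <- list(CK = list(native = "C", water = "KW", sediment = "KS"),
                 KC = list(native = "K", water = "CW", sediment = "CS"))[[group]]
  meta <- data.frame(sample_id = sheet$sample_id, group = sheet$group)
  gm <- group_mean_props(props_fam, meta)
  fc <- family_fold_change(gm[, design$native], gm[, group])
  fc$targeted <- abs(fc$log2_ratio) >= cfg$fold_threshold - 1e-12
  targeted <- select_targeted(fc)

  samples_of <- function(g) sheet$sample_id[sheet$group == g]
  reads_of <- function(g, fams = NULL) {
    r <- accepted[accepted$sample_id %in% samples_of(g), , drop = FALSE]
    if (!is.null(fams)) r <- r[fam_of_read[r$read_id] %in% fams, , drop = FALSE]
    r
  }
  ex <- reads_of(group, targeted$family)
  if (nrow(ex) > 0) {
    rep_of <- stats::setNames(sheet$replicate, sheet$sample_id)
    ex$replicate <- rep_of[ex$sample_id]
  }
  rc <- recluster_targeted(ex,
                           reads_of(design$native, targeted$family),
                           reads_of(design$water, targeted$family),
                           reads_of(design$sediment, targeted$family),
                           threshold = cfg$attribution_threshold,
                           scoring = cfg$scoring)
  n_rep <- sum(sheet$group == group)
  core <- core_filter(rc, n_rep * cfg$core_fraction / 0.5)
  att <- attribute_origins(rc, core, fam_of_read)
  acc <- if (nrow(att$records) > 0)
    attribution_accuracy(att$records, fx$truth) else NULL
  list(fold_change = fc, targeted = targeted, reclustered = rc,
       core = core, attribution = att, accuracy = acc)
}

#' Run the full habitat-exchange analysis pipeline
#'
#' Executes all six stages on a simulated experiment and writes their tabular
#' outputs plus a JSON manifest under `out_dir`. A failing stage leaves a
#' FAILED marker naming the stage and rethrows. Reruns with an identical
#' configuration reproduce all tabular outputs byte-identically.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and `paths`.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$scenario$seed, config_hash = config_hash(config),
                   stages = list())
  state <- new.env(parent = emptyenv())
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      writeLines(c(name, conditionMessage(e)), file.path(out_dir, "FAILED"))
      stop(e)
    })
    res
  }

  ## 1. simulate ------------------------------------------------------------
  fx <- run_stage("simulate", function()
    simulate_experiment(config$scenario, file.path(out_dir, "sim")))
  manifest$stages$simulate <- list(n_samples = nrow(fx$sample_sheet),
                                   n_reads = nrow(fx$reads))

  ## 2. demultiplex + QC -----------------------------------------------------
  demux <- run_stage("demux", function() {
    raw <- do.call(rbind, lapply(unname(fx$paths$fastq), read_sequences))
    demultiplex_filter(raw, fx$barcode_map, config$qc)
  })
  qcdir <- file.path(out_dir, "qc"); dir.create(qcdir, showWarnings = FALSE)
  tsv_out(demux$accepted[c("sample_id", "read_id")], qcdir, "accepted.tsv")
  tsv_out(demux$rejected, qcdir, "rejections.tsv")
  manifest$stages$demux <- list(n_in = nrow(demux$accepted) + nrow(demux$rejected),
                                n_accepted = nrow(demux$accepted),
                                n_rejected = nrow(demux$rejected))

  ## 3. OTU clustering + taxonomy -------------------------------------------
  otudir <- file.path(out_dir, "otu"); dir.create(otudir, showWarnings = FALSE)
  clus <- run_stage("cluster", function() {
    cs <- greedy_cluster(demux$accepted[c("read_id", "sequence")],
                         config$community_threshold, config$scoring)
    tax <- assign_taxonomy(cs$centroids, fx$pool$taxa,
                           config$min_taxonomy_identity, config$scoring)
    read_samples <- stats::setNames(demux$accepted$sample_id,
                                    demux$accepted$read_id)
    tbl <- build_otu_table(cs, read_samples, metadata = fx$sample_sheet)
    tbl$taxonomy <- tax[c("otu_id", LINEAGE_RANKS)]
    list(cluster_set = cs, taxonomy = tax, table = tbl)
  })
  tsv_out(clus$cluster_set$members, otudir, "clusters.tsv")
  tsv_out(clus$taxonomy, otudir, "taxonomy.tsv")
  write_count_table(clus$table, file.path(otudir, "otu_table.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(
      clus$cluster_set$centroids$centroid_sequence,
      clus$cluster_set$centroids$cluster_id)),
    file.path(otudir, "centroids.fasta"))
  manifest$stages$cluster <- list(n_otus = nrow(clus$cluster_set$centroids),
                                  n_reads = nrow(clus$cluster_set$members))

  ## 4. diversity -------------------------------------------------------------
  divdir <- file.path(out_dir, "diversity"); dir.create(divdir, showWarnings = FALSE)
  divres <- run_stage("diversity", function() {
    alpha <- alpha_diversity(clus$table)
    min_depth <- min(colSums(clus$table$counts))
    depths <- unique(pmax(1, round(seq(1, min_depth, length.out = 10))))
    rare <- do.call(rbind, lapply(colnames(clus$table$counts), function(s)
      cbind(sample_id = s,
            rarefaction_curve(clus$table$counts[, s], depths))))
    sheet <- fx$sample_sheet
    tests <- do.call(rbind, lapply(list(c("C", "CK"), c("K", "KC")), function(p) {
      do.call(rbind, lapply(c("chao1", "shannon"), function(metric) {
        va <- alpha[[metric]][match(sheet$sample_id[sheet$group == p[1]],
                                    alpha$sample_id)]
        vb <- alpha[[metric]][match(sheet$sample_id[sheet$group == p[2]],
                                    alpha$sample_id)]
        w <- compare_alpha(va, vb)
        data.frame(native = p[1], exchanged = p[2], metric = metric,
                   statistic = w$statistic, p_value = w$p_value,
                   stringsAsFactors = FALSE)
      }))
    }))
    list(alpha = alpha, rarefaction = rare, tests = tests)
  })
  tsv_out(divres$alpha, divdir, "alpha.tsv")
  tsv_out(divres$rarefaction, divdir, "rarefaction.tsv")
  tsv_out(divres$tests, divdir, "alpha_tests.tsv")
  manifest$stages$diversity <- list(n_samples = nrow(divres$alpha))

  ## 5. community comparison ---------------------------------------------------
  cmpdir <- file.path(out_dir, "compare"); dir.create(cmpdir, showWarnings = FALSE)
  cmp <- run_stage("compare", function() {
    fam_tbl <- aggregate_to_rank(clus$table, "family")
    props <- relative_abundance(fam_tbl)
    bc <- bray_curtis(props)
    ord <- nmds(bc, k = 2)
    sheet <- fx$sample_sheet
    gut_ids <- sheet$sample_id[sheet$type == "gut"]
    dendro <- correlation_dendrogram(props[, gut_ids, drop = FALSE])
    groups <- stats::setNames(sheet$group, sheet$sample_id)
    disp <- within_group_dispersion(bc, groups)
    fam_sets <- lapply(split(sheet$sample_id[sheet$type == "gut"],
                             sheet$group[sheet$type == "gut"]), function(ids)
      rownames(props)[rowSums(props[, ids, drop = FALSE]) > 0])
    venn <- shared_membership(fam_sets)
    gm <- group_mean_props(props, data.frame(sample_id = sheet$sample_id,
                                             group = sheet$group))
    hm <- heatmap_select(gm)
    list(fam_tbl = fam_tbl, props = props, bray = bc, nmds = ord,
         dendro = dendro, dispersion = disp, venn = venn, group_means = gm,
         heatmap = hm)
  })
  tsv_out(data.frame(sample_id = rownames(cmp$bray), cmp$bray,
                     check.names = FALSE), cmpdir, "bray_curtis.tsv")
  nm <- data.frame(sample_id = rownames(cmp$nmds$points), cmp$nmds$points)
  names(nm) <- c("sample_id", paste0("axis", seq_len(ncol(cmp$nmds$points))))
  nmds_path <- file.path(cmpdir, "nmds.tsv")
  write.table(nm, nmds_path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("# stress\t%.10f\n", cmp$nmds$stress), file = nmds_path,
      append = TRUE)
  write_dendrogram(cmp$dendro, file.path(cmpdir, "gut_dendrogram.nwk"))
  tsv_out(cmp$dispersion, cmpdir, "within_group_dispersion.tsv")
  tsv_out(cmp$venn, cmpdir, "venn_gut_families.tsv")
  tsv_out(cmp$heatmap$selected, cmpdir, "heatmap_families.tsv")
  write_count_table(cmp$fam_tbl, file.path(cmpdir, "family_table.tsv"))
  manifest$stages$compare <- list(n_families = nrow(cmp$fam_tbl$counts),
                                  nmds_stress = cmp$nmds$stress)

  ## 6. source attribution -----------------------------------------------------
  attdir <- file.path(out_dir, "attribution"); dir.create(attdir, showWarnings = FALSE)
  att <- run_stage("attribute", function() {
    fam_map <- stats::setNames(clus$taxonomy$family, clus$taxonomy$otu_id)
    fam_of_read <- stats::setNames(
      unname(fam_map[clus$cluster_set$members$cluster_id]),
      clus$cluster_set$members$read_id)
    res <- lapply(c(CK = "CK", KC = "KC"), function(g)
      attribute_group(g, fx, demux$accepted, clus$cluster_set$members,
                      fam_of_read, cmp$props, config))
    res
  })
  for (g in names(att)) {
    tsv_out(att[[g]]$fold_change, attdir, sprintf("fold_change_%s.tsv", g))
    tsv_out(att[[g]]$targeted, attdir, sprintf("targeted_%s.tsv", g))
    if (nrow(att[[g]]$attribution$records) > 0) {
      tsv_out(att[[g]]$attribution$records, attdir,
              sprintf("attribution_%s.tsv", g))
      tsv_out(att[[g]]$attribution$summary, attdir,
              sprintf("attribution_summary_%s.tsv", g))
    }
  }
  acc_rows <- do.call(rbind, lapply(names(att), function(g) {
    a <- att[[g]]$accuracy
    data.frame(group = g,
               n_attributed = if (is.null(a)) 0L else a$n,
               accuracy = if (is.null(a)) NA_real_ else a$accuracy,
               stringsAsFactors = FALSE)
  }))
  tsv_out(acc_rows, attdir, "accuracy.tsv")
  manifest$stages$attribute <- list(
    n_targeted_CK = nrow(att$CK$targeted),
    n_targeted_KC = nrow(att$KC$targeted),
    n_core_CK = length(att$CK$core), n_core_KC = length(att$KC$core))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fixture = fx, demux = demux, cluster = clus,
                 diversity = divres, compare = cmp, attribution = att,
                 manifest = manifest, out_dir = out_dir))
}
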