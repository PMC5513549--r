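# Read-source attribution: family-level log2 fold change targeting, pooled
# 99%-identity re-clustering of targeted families across the exchanged gut and
# its source communities, core-OTU filtering, and per-read origin classes.

#' Family-level log2 fold change between native and exchanged group means
#'
#' Zero means are replaced by half the smallest nonzero family mean of the
#' same group before taking the ratio, so families absent from one group get a
#' finite fold change; families absent from both groups are dropped with a
#' message. A family is targeted when |log2 ratio| >= 1, i.e. fold change
#' >= 2.00 (boundary inclusive).
#'
#' @param native_means,exchanged_means named numeric vectors of group-mean
#'   relative abundances over the same family universe.
#' @param epsilon_policy only "half_min_nonzero" is implemented.
#' @return data.frame: family, native_mean, exchanged_mean, log2_ratio,
#'   targeted.
#' @export
family_fold_change <- function(native_means, exchanged_means,
                               epsilon_policy = "half_min_nonzero") {
  if (!identical(epsilon_policy, "half_min_nonzero"))
    gs_config_error("unknown epsilon_policy")
  if (!setequal(names(native_means), names(exchanged_means)))
    gs_stop("native and exchanged means must cover the same families")
  fams <- sort(names(native_means))
  a <- native_means[fams]; b <- exchanged_means[fams]
  both_zero <- a == 0 & b == 0
  if (any(both_zero)) {
    message(sprintf("dropping %d family(ies) absent from both groups: %s",
                    sum(both_zero), paste(fams[both_zero], collapse = ", ")))
    fams <- fams[!both_zero]; a <- a[fams]; b <- b[fams]
  }
  eps_a <- if (any(a > 0)) min(a[a > 0]) / 2 else NA_real_
  eps_b <- if (any(b > 0)) min(b[b > 0]) / 2 else NA_real_
  a2 <- ifelse(a == 0, eps_a, a)
  b2 <- ifelse(b == 0, eps_b, b)
  lr <- log2(b2 / a2)
  data.frame(family = fams, native_mean = unname(a), exchanged_mean = unname(b),
             log2_ratio = unname(lr),
             targeted = abs(unname(lr)) >= 1 - 1e-12,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select targeted families ordered by effect size
#'
#' @param records a [family_fold_change()] result.
#' @return the targeted records, ordered by decreasing |log2_ratio| with ties
#'   broken by family name, annotated with `direction` (increase/decrease).
#' @export
select_targeted <- function(records) {
  t <- records[records$targeted, , drop = FALSE]
  t <- t[order(-abs(t$log2_ratio), t$family), , drop = FALSE]
  t$direction <- ifelse(t$log2_ratio >= 0, "increase", "decrease")
  rownames(t) <- NULL
  t
}

#' Pooled 99% re-clustering of targeted-family reads
#'
#' Reads from the exchanged-gut group (targeted families), the native-gut
#' group, and the new habitat's water and sediment communities are pooled and
#' clustered once at the attribution threshold; every read keeps its
#' community tag (and, for exchanged reads, its replicate), so each cluster
#' carries the multiset of source communities it contains.
#'
#' @param exchanged,native,water,sediment data.frames with `read_id`,
#'   `sequence`; `exchanged` also needs `replicate`.
#' @param threshold attribution identity threshold, default 0.99.
#' @param scoring an [alignment_scoring()].
#' @return list with the underlying `cluster_set` and `tags` (read_id, tag in
#'   exchanged/native_gut/water/sediment, replicate), or `NULL` clusters with
#'   a message when there are no exchanged reads to attribute.
#' @export
recluster_targeted <- function(exchanged, native, water, sediment,
                               threshold = 0.99, scoring = alignment_scoring()) {
  if (is.null(exchanged) || nrow(exchanged) == 0) {
    message("no targeted exchanged-gut reads; nothing to attribute")
    return(list(clusters = NULL, tags = NULL))
  }
  tag_block <- function(df, tag) {
    if (is.null(df) || nrow(df) == 0) return(NULL)
    data.frame(read_id = df$read_id, sequence = df$sequence, tag = tag,
               replicate = if ("replicate" %in% names(df)) df$replicate else NA,
               stringsAsFactors = FALSE)
  }
  pooled <- rbind(tag_block(exchanged, "exchanged"),
                  tag_block(native, "native_gut"),
                  tag_block(water, "water"),
                  tag_block(sediment, "sediment"))
  if (anyDuplicated(pooled$read_id)) gs_stop("duplicate read ids across pools")
  cs <- greedy_cluster(pooled[c("read_id", "sequence")], threshold, scoring)
  list(clusters = cs,
       tags = pooled[c("read_id", "tag", "replicate")])
}

#' Core-OTU filter on attribution clusters
#'
#' Keeps clusters whose exchanged-gut reads come from at least 50% of the
#' exchanged replicates (inclusive at exactly 50%), and always drops clusters
#' whose exchanged-gut reads come from a single replicate.
#'
#' @param reclustered a [recluster_targeted()] result.
#' @param n_replicates number of exchanged-gut replicates (> 0).
#' @return character vector of core cluster ids.
#' @export
core_filter <- function(reclustered, n_replicates) {
  if (n_replicates <= 0) gs_stop("n_replicates must be > 0")
  if (is.null(reclustered$clusters)) return(character(0))
  m <- merge(reclustered$clusters$members, reclustered$tags, by = "read_id")
  ex <- m[m$tag == "exchanged", , drop = FALSE]
  reps <- tapply(ex$replicate, ex$cluster_id,
                 function(r) length(unique(r)))
  core <- names(reps)[reps >= n_replicates / 2 & reps >= 2]
  sort(core)
}

#' Per-read origin attribution for core clusters
#'
#' Every exchanged-gut read in a core cluster receives the origin letters of
#' the source communities present in the same cluster: G for native gut, S
#' for new-habitat sediment, W for new-habitat water (concatenated in that
#' order), or Specific when the cluster holds no source-community read.
#'
#' @param reclustered a [recluster_targeted()] result.
#' @param core_ids cluster ids from [core_filter()].
#' @param read_families optional named vector read_id -> family used to label
#'   clusters (majority family of their exchanged reads).
#' @return list with `records` (read_id, sample-replicate, cluster_id, family,
#'   class) and `summary` (per cluster: n_reads and the fraction of reads in
#'   each of the eight classes; fractions sum to 1 per cluster).
#' @export
attribute_origins <- function(reclustered, core_ids, read_families = NULL) {
  if (is.null(reclustered$clusters) || length(core_ids) == 0) {
    return(list(records = data.frame(read_id = character(0),
                                     replicate = character(0),
                                     cluster_id = character(0),
                                     family = character(0),
                                     class = character(0)),
                summary = NULL))
  }
  m <- merge(reclustered$clusters$members, reclustered$tags, by = "read_id")
  if (any(is.na(m$tag))) gs_stop("untagged read in attribution clustering")
  m <- m[m$cluster_id %in% core_ids, , drop = FALSE]
  cls_of_cluster <- vapply(split(m$tag, m$cluster_id), function(tags) {
    letters <- c(G = any(tags == "native_gut"),
                 S = any(tags == "sediment"),
                 W = any(tags == "water"))
    if (!any(letters)) "Specific" else
      paste(names(letters)[letters], collapse = "")
  }, character(1))
  ex <- m[m$tag == "exchanged", , drop = FALSE]
  fam <- if (is.null(read_families)) rep(NA_character_, nrow(ex)) else
    unname(read_families[ex$read_id])
  records <- data.frame(read_id = ex$read_id, replicate = ex$replicate,
                        cluster_id = ex$cluster_id, family = fam,
                        class = unname(cls_of_cluster[ex$cluster_id]),
                        stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(records, records$cluster_id), function(r) {
    frac <- table(factor(r$class, levels = ORIGIN_CLASSES)) / nrow(r)
    cluster_fam <- if (all(is.na(r$family))) NA_character_ else
      names(sort(table(r$family), decreasing = TRUE))[1]
    cbind(data.frame(cluster_id = r$cluster_id[1], family = cluster_fam,
                     n_reads = nrow(r), stringsAsFactors = FALSE),
          as.data.frame.matrix(t(as.matrix(frac))))
  }))
  rownames(summ) <- NULL
  list(records = records, summary = summ)
}

#' Attribution accuracy against simulator ground truth
#'
#' @param records attribution records from [attribute_origins()].
#' @param truth the simulator truth table (read_id, origin_class).
#' @return list with `accuracy`, `n`, `confusion` (truth x predicted), and
#'   `per_class` precision/recall.
#' @export
attribution_accuracy <- function(records, truth) {
  missing <- setdiff(records$read_id, truth$read_id)
  if (length(missing))
    gs_stop(sprintf("read ids not in truth table, e.g. %s", missing[1]))
  tr <- truth$origin_class[match(records$read_id, truth$read_id)]
  pred <- records$class
  conf <- table(truth = factor(tr, levels = ORIGIN_CLASSES),
                predicted = factor(pred, levels = ORIGIN_CLASSES))
  correct <- sum(diag(conf))
  per_class <- data.frame(
    class = ORIGIN_CLASSES,
    precision = vapply(ORIGIN_CLASSES, function(cl) {
      p <- sum(conf[, cl]); if (p == 0) NA_real_ else conf[cl, cl] / p
    }, numeric(1)),
    recall = vapply(ORIGIN_CLASSES, function(cl) {
      t <- sum(conf[cl, ]); if (t == 0) NA_real_ else conf[cl, cl] / t
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(accuracy = correct / nrow(records), n = nrow(records),
       confusion = conf, per_class = per_class)
}
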