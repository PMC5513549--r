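# Greedy centroid clustering at a fixed identity threshold (97% community
# OTUs, 99% attribution OTUs) over dereplicated reads, plus best-hit taxonomy
# assignment of centroids against a reference pool.

#' Greedy centroid clustering of reads
#'
#' Reads are dereplicated into identical-sequence groups, processed in
#' decreasing group abundance (ties broken lexicographically by sequence, then
#' by smallest read id), and each group joins the first existing centroid
#' (in centroid-creation order) whose global alignment identity meets the
#' threshold, else founds a new centroid. This canonical internal ordering
#' makes the result invariant to the order reads are supplied in.
#'
#' @param reads data.frame with `read_id` and `sequence` (A/C/G/T only).
#' @param threshold identity threshold in (0, 1].
#' @param scoring an [alignment_scoring()].
#' @return A `cluster_set`: list with `members` (read_id, cluster_id,
#'   identity_to_centroid), `centroids` (cluster_id, centroid_read_id,
#'   centroid_sequence), and `threshold`.
#' @export
greedy_cluster <- function(reads, threshold, scoring = alignment_scoring()) {
  if (!(threshold > 0 && threshold <= 1))
    gs_config_error("threshold must be in (0, 1]")
  if (nrow(reads) < 1L) gs_stop("need at least one read")
  if (any(grepl("[^ACGT]", reads$sequence)))
    gs_stop("sequences must be A/C/G/T only; resolve ambiguity codes upstream")

  grp <- split(reads$read_id, reads$sequence)  # names sorted lexicographically
  uniq_seq <- names(grp)
  abund <- lengths(grp)
  rep_id <- vapply(grp, function(ids) min(ids), character(1))
  ord <- order(-abund, uniq_seq, rep_id)
  uniq_seq <- uniq_seq[ord]; rep_id <- rep_id[ord]

  res <- .greedy_cluster_cpp(uniq_seq, threshold,
                             scoring$match, scoring$mismatch, scoring$gap)
  n_cl <- length(res$centroid_index)
  cluster_id <- sprintf("OTU_%04d", seq_len(n_cl))
  centroids <- data.frame(cluster_id = cluster_id,
                          centroid_read_id = rep_id[res$centroid_index],
                          centroid_sequence = uniq_seq[res$centroid_index],
                          stringsAsFactors = FALSE)
  seq_cluster <- stats::setNames(cluster_id[res$cluster], uniq_seq)
  seq_ident <- stats::setNames(res$identity, uniq_seq)
  members <- data.frame(read_id = reads$read_id,
                        cluster_id = unname(seq_cluster[reads$sequence]),
                        identity_to_centroid = unname(seq_ident[reads$sequence]),
                        stringsAsFactors = FALSE)
  structure(list(members = members, centroids = centroids,
                 threshold = threshold),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters over %d reads at %.0f%% identity\n",
              nrow(x$centroids), nrow(x$members), 100 * x$threshold))
  invisible(x)
}

#' Build an OTU count table from a cluster set
#'
#' @param cluster_set a [greedy_cluster()] result.
#' @param read_samples named character vector read_id -> sample_id covering
#'   every member read.
#' @param metadata optional per-sample metadata data.frame.
#' @return An [otu_table()] (without taxonomy); column sums equal per-sample
#'   read counts.
#' @export
build_otu_table <- function(cluster_set, read_samples, metadata = NULL) {
  stopifnot(inherits(cluster_set, "cluster_set"))
  m <- cluster_set$members
  sample <- read_samples[m$read_id]
  if (any(is.na(sample)))
    gs_stop(sprintf("reads without a sample mapping, e.g. %s",
                    m$read_id[which(is.na(sample))[1]]))
  samples <- sort(unique(unname(sample)))
  counts <- table(factor(m$cluster_id, levels = cluster_set$centroids$cluster_id),
                  factor(sample, levels = samples))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = list(cluster_set$centroids$cluster_id, samples))
  otu_table(counts, metadata = metadata)
}

unclassified_lineage <- function(otu_ids) {
  data.frame(otu_id = otu_ids, phylum = "unclassified", class = "unclassified",
             order = "unclassified", family = "unclassified",
             genus = "unclassified", stringsAsFactors = FALSE)
}

#' Assign taxonomy to cluster centroids by best-hit identity
#'
#' Each centroid receives the lineage of its highest-identity reference taxon
#' when that identity reaches `min_identity`, else "unclassified" at all
#' ranks. Identity ties are broken by lexicographically smallest taxon id, so
#' assignment is deterministic.
#'
#' @param centroids data.frame with `cluster_id` and `centroid_sequence`
#'   (the `centroids` element of a [greedy_cluster()] result).
#' @param reference data.frame with `taxon_id`, the five lineage ranks, and
#'   `sequence` (e.g. the `taxa` element of a [build_reference_pool()] pool).
#' @param min_identity minimum best-hit identity to classify; default 0.80.
#' @param scoring an [alignment_scoring()].
#' @return data.frame: otu_id, best_taxon_id, best_identity, and the five
#'   lineage ranks.
#' @export
assign_taxonomy <- function(centroids, reference, min_identity = 0.80,
                            scoring = alignment_scoring()) {
  if (nrow(reference) == 0) gs_stop("reference must be non-empty")
  ref <- reference[order(reference$taxon_id), , drop = FALSE]
  idm <- identity_matrix(centroids$centroid_sequence, ref$sequence, scoring)
  best <- max.col(idm, ties.method = "first")  # first = smallest taxon_id
  best_id <- idm[cbind(seq_len(nrow(idm)), best)]
  out <- data.frame(otu_id = centroids$cluster_id,
                    best_taxon_id = ref$taxon_id[best],
                    best_identity = best_id,
                    ref[best, LINEAGE_RANKS, drop = FALSE],
                    stringsAsFactors = FALSE, row.names = NULL)
  low <- best_id < min_identity
  if (any(low)) {
    out$best_taxon_id[low] <- NA_character_
    out[low, LINEAGE_RANKS] <- "unclassified"
  }
  out
}
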