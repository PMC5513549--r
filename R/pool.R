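# Synthetic reference pool: family-structured taxa with known lineages and
# representative sequences, the ground-truth universe every community draws
# from. Sequence evolution is substitution-only (no indels) so the identity
# bands used by clustering stay analytically predictable.

BASES <- c("A", "C", "G", "T")
LINEAGE_RANKS <- c("phylum", "class", "order", "family", "genus")

# One mutation round at rate q acts on each site as a 4-state Markov step with
# non-identity eigenvalue lambda = 1 - (4/3) q, so expected site identity
# between sequences separated by rounds q_1..q_m is 1/4 + (3/4) prod lambda_i.
# Inverting for a two-branch split (q on each side) gives the rate making two
# descendants hit a target pairwise identity.
divergence_rate_for_identity <- function(target) {
  if (target <= 0.25 || target >= 1)
    gs_config_error("target identity must be in (0.25, 1)")
  lambda2 <- (target - 0.25) / 0.75
  0.75 * (1 - sqrt(lambda2))
}

# family-branch rate such that cross-family TAXA (which also carry their own
# taxon-branch mutations at within-family identity I_w) have expected pairwise
# identity I_x: lambda_f^2 = (I_x - 1/4) / (I_w - 1/4)
family_rate_for_identities <- function(between, within) {
  if (between <= 0.25) gs_config_error("between-family identity must exceed 0.25")
  0.75 * (1 - sqrt((between - 0.25) / (within - 0.25)))
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# i.i.d. per-base substitution to a uniformly chosen different base
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1L)
  paste(ch, collapse = "")
}

#' Build a synthetic reference pool of taxa
#'
#' Generates `n_families * taxa_per_family` reference taxa. All family
#' ancestors descend from one root sequence at a substitution rate tuned so
#' cross-family pairs have expected identity `between_family_identity`; taxa
#' within a family descend from the family ancestor at a rate giving expected
#' within-family identity `within_family_identity`. Each family carries its own
#' sequence length drawn from `seq_len_range`, and each taxon a 5-rank lineage
#' (phylum, class, order, family, genus) nested deterministically.
#'
#' @param n_families number of families (>= 2).
#' @param taxa_per_family taxa per family (>= 1).
#' @param seq_len_range integer length-2 range for family sequence lengths.
#' @param between_family_identity expected pairwise identity of cross-family
#'   taxa; must be below `within_family_identity`.
#' @param within_family_identity expected pairwise identity of same-family taxa.
#' @param seed integer seed; if `NULL` the current RNG stream is used.
#' @return A `reference_pool`: list with `taxa` (data.frame: taxon_id, the five
#'   lineage ranks, sequence) and the generating parameters.
#' @export
build_reference_pool <- function(n_families = 20L, taxa_per_family = 5L,
                                 seq_len_range = c(295L, 311L),
                                 between_family_identity = 0.85,
                                 within_family_identity = 0.93,
                                 seed = NULL) {
  if (n_families < 2L) gs_config_error("n_families must be >= 2")
  if (taxa_per_family < 1L) gs_config_error("taxa_per_family must be >= 1")
  if (length(seq_len_range) != 2L || seq_len_range[1] > seq_len_range[2] ||
      seq_len_range[1] < 1L)
    gs_config_error("seq_len_range must be an increasing positive pair")
  if (!(between_family_identity > 0 && between_family_identity < within_family_identity &&
        within_family_identity < 1))
    gs_config_error("need 0 < between_family_identity < within_family_identity < 1")
  if (!is.null(seed)) set.seed(as.integer(seed))

  q_family <- family_rate_for_identities(between_family_identity,
                                         within_family_identity)
  q_taxon <- divergence_rate_for_identity(within_family_identity)
  root <- random_dna(max(seq_len_range))
  fam_len <- sample(seq(seq_len_range[1], seq_len_range[2]), n_families, replace = TRUE)

  rows <- vector("list", n_families * taxa_per_family)
  idx <- 0L
  for (f in seq_len(n_families)) {
    ancestor <- substr(mutate_sequence(root, q_family), 1L, fam_len[f])
    phylum <- sprintf("Phylum_%02d", (f - 1L) %/% 8L + 1L)
    class_ <- sprintf("Class_%02d", (f - 1L) %/% 4L + 1L)
    order_ <- sprintf("Order_%02d", (f - 1L) %/% 2L + 1L)
    family <- sprintf("Family_%02d", f)
    for (t in seq_len(taxa_per_family)) {
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        taxon_id = sprintf("T%03d", idx),
        phylum = phylum, class = class_, order = order_, family = family,
        genus = sprintf("Genus_%02d_%02d", f, t),
        sequence = mutate_sequence(ancestor, q_taxon),
        stringsAsFactors = FALSE)
    }
  }
  taxa <- do.call(rbind, rows)
  structure(list(taxa = taxa,
                 params = list(n_families = n_families,
                               taxa_per_family = taxa_per_family,
                               seq_len_range = seq_len_range,
                               between_family_identity = between_family_identity,
                               within_family_identity = within_family_identity)),
            class = "reference_pool")
}

#' Draw a community abundance profile from a reference pool
#'
#' Samples `richness` taxa uniformly without replacement and assigns relative
#' abundances from a log-normal ranked-abundance model with shape `sigma`
#' (sigma = 0 degenerates to the uniform profile).
#'
#' @param pool a [build_reference_pool()] result.
#' @param community_id label for the community (e.g. "C_gut", "KW").
#' @param richness number of taxa with positive weight; must not exceed the
#'   pool size.
#' @param sigma log-normal shape of the abundance distribution.
#' @param seed optional integer seed.
#' @return A `community_profile`: list with `community_id` and `weights`
#'   (named numeric, strictly positive, summing to 1).
#' @export
sample_community_profile <- function(pool, community_id, richness, sigma = 1,
                                     seed = NULL) {
  stopifnot(inherits(pool, "reference_pool"))
  n <- nrow(pool$taxa)
  if (richness < 1L || richness > n)
    gs_stop(sprintf("richness %d outside [1, pool size %d]", richness, n))
  if (sigma < 0) gs_config_error("sigma must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  ids <- sample(pool$taxa$taxon_id, richness)
  w <- rlnorm(richness, meanlog = 0, sdlog = sigma)
  w <- w / sum(w)
  names(w) <- ids
  structure(list(community_id = community_id, weights = w),
            class = "community_profile")
}

# One individual's realized profile from a community master profile. Guts (and
# colonization from a new habitat) are modelled as a capacity bottleneck: an
# individual carries at most `capacity` taxa, drawn abundance-weighted from the
# master. From a rich master two individuals realize largely different subsets
# (high between-individual dispersion); from a poor master they overlap. For
# bulk environmental samples `subsample` retains a fixed high fraction instead.
# Retained weights get a log-normal jitter either way.
# `colonize = TRUE` models first colonization of a new habitat: founder and
# priority effects make which taxa establish (uniform draw) and how abundant
# they get (fresh log-normal weights) largely independent of their abundance
# in the source community.
draw_individual_profile <- function(master, capacity = NULL, subsample = NULL,
                                    jitter_sigma = 0.6, colonize = FALSE) {
  w <- master$weights
  keep_n <- if (!is.null(capacity)) min(as.integer(capacity), length(w))
            else max(1L, round(subsample * length(w)))
  if (keep_n < 1L) gs_config_error("individual profile capacity must be >= 1")
  if (colonize) {
    ids <- if (keep_n >= length(w)) names(w) else sample(names(w), keep_n)
    v <- rlnorm(length(ids), 0, jitter_sigma)
  } else {
    ids <- if (keep_n >= length(w)) names(w) else
      sample(names(w), keep_n, prob = w)
    v <- w[ids] * rlnorm(length(ids), 0, jitter_sigma)
  }
  v <- v / sum(v)
  names(v) <- ids
  structure(list(community_id = master$community_id, weights = v),
            class = "community_profile")
}
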