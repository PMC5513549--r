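# Community comparison: rank aggregation, relative abundance, shared
# membership (Venn regions), Spearman/UPGMA sample clustering, Bray-Curtis
# dissimilarity, NMDS ordination, and the >1% / >2-fold heatmap family filter.

#' Aggregate an OTU table to a taxonomic rank
#'
#' Counts are summed over OTUs sharing the rank label. OTUs unclassified at
#' the rank are pooled into a label of the form `<parent>_unclassified`, where
#' parent is the nearest classified higher rank (or plain "unclassified" when
#' no rank is classified). Per-sample totals are conserved exactly.
#'
#' @param table an [otu_table()] with taxonomy.
#' @param rank one of phylum, class, order, family, genus.
#' @return An [otu_table()] whose rows are rank labels; taxonomy carries the
#'   rank label in the requested rank column.
#' @export
aggregate_to_rank <- function(table, rank) {
  stopifnot(inherits(table, "otu_table"))
  if (!rank %in% LINEAGE_RANKS)
    gs_stop(sprintf("unknown rank '%s'", rank))
  if (is.null(table$taxonomy)) gs_stop("table has no taxonomy")
  tax <- table$taxonomy
  ridx <- match(rank, LINEAGE_RANKS)
  label <- tax[[rank]]
  uncl <- is.na(label) | label == "unclassified"
  if (any(uncl)) {
    parent <- rep("unclassified", sum(uncl))
    if (ridx > 1) {
      higher <- tax[uncl, LINEAGE_RANKS[seq_len(ridx - 1L)], drop = FALSE]
      for (k in rev(seq_len(ridx - 1L))) {
        h <- higher[[k]]
        usable <- parent == "unclassified" & !is.na(h) & h != "unclassified"
        parent[usable] <- paste0(h[usable], "_unclassified")
      }
    }
    label[uncl] <- parent
  }
  counts <- rowsum(table$counts, group = label)
  counts <- counts[order(rownames(counts)), , drop = FALSE]
  tax_out <- data.frame(otu_id = rownames(counts), stringsAsFactors = FALSE)
  for (rk in LINEAGE_RANKS) tax_out[[rk]] <- "unclassified"
  tax_out[[rank]] <- rownames(counts)
  otu_table(counts, taxonomy = tax_out, metadata = table$metadata)
}

#' Relative abundance (proportions per sample)
#'
#' @param x an [otu_table()] or a counts matrix (features x samples).
#' @return matrix of proportions; every column sums to 1.
#' @export
relative_abundance <- function(x) {
  m <- if (inherits(x, "otu_table")) x$counts else x
  totals <- colSums(m)
  zero <- totals == 0
  if (any(zero))
    gs_stop(sprintf("sample(s) with zero total counts: %s",
                    paste(colnames(m)[zero], collapse = ", ")))
  sweep(m, 2L, totals, "/")
}

#' Venn-region counts of shared membership
#'
#' For 2-8 labelled feature sets, counts the disjoint regions of the Venn
#' partition: every non-empty label combination, counting features present in
#' exactly those sets. Region counts sum to the union size.
#'
#' @param sets named list of character vectors (label -> feature ids).
#' @return data.frame with `region` (labels joined by "&") and `count`,
#'   covering all 2^k - 1 combinations.
#' @export
shared_membership <- function(sets) {
  k <- length(sets)
  if (k < 2 || k > 8) gs_stop("need between 2 and 8 labelled sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    gs_stop("sets must be named")
  labels <- names(sets)
  univ <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  memb <- matrix(memb, ncol = k)
  sig <- apply(memb, 1L, function(r) paste(labels[r], collapse = "&"))
  combos <- unlist(lapply(seq_len(k), function(m)
    utils::combn(labels, m, paste, collapse = "&", simplify = FALSE)))
  counts <- table(factor(sig, levels = combos))
  data.frame(region = combos, count = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' Spearman-correlation UPGMA dendrogram of samples
#'
#' Distance between samples is 1 - Spearman's rho (average ranks on ties),
#' clustered by average linkage. Samples are ordered lexicographically before
#' clustering so equal-height merges resolve deterministically.
#'
#' @param props proportion matrix, features x samples (>= 2 samples, each with
#'   at least two distinct values).
#' @return an `hclust` object.
#' @export
correlation_dendrogram <- function(props) {
  if (ncol(props) < 2) gs_stop("need at least 2 samples")
  constant <- apply(props, 2L, function(x) length(unique(x)) < 2L)
  if (any(constant))
    gs_stop(sprintf("constant-valued sample(s): %s",
                    paste(colnames(props)[constant], collapse = ", ")))
  props <- props[, order(colnames(props)), drop = FALSE]
  rho <- cor(props, method = "spearman")
  hclust(as.dist(1 - rho), method = "average")
}

#' Write a dendrogram as Newick with branch heights
#'
#' @param hc an `hclust` object.
#' @param path output path.
#' @export
write_dendrogram <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(x, y) = 1 - 2 sum_i min(x_i, y_i) / (sum x + sum y), via vegan.
#'
#' @param x an [otu_table()] or matrix, features x samples.
#' @return symmetric matrix with zero diagonal, values in [0, 1].
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "otu_table")) x$counts else x
  if (any(colSums(m) == 0)) gs_stop("samples must have positive totals")
  as.matrix(vegan::vegdist(t(m), method = "bray"))
}

mean_offdiag <- function(d) {
  n <- nrow(d)
  if (n < 2) return(NA_real_)
  mean(d[lower.tri(d)])
}

#' Mean within-group Bray-Curtis dispersion
#'
#' @param dist distance matrix with sample ids.
#' @param groups named character vector sample_id -> group.
#' @return data.frame with `group` and `mean_within_bc`.
#' @export
within_group_dispersion <- function(dist, groups) {
  gs <- sort(unique(unname(groups[rownames(dist)])))
  res <- vapply(gs, function(g) {
    ids <- rownames(dist)[groups[rownames(dist)] == g]
    mean_offdiag(dist[ids, ids, drop = FALSE])
  }, numeric(1))
  data.frame(group = gs, mean_within_bc = unname(res), stringsAsFactors = FALSE)
}

# --- NMDS -------------------------------------------------------------------

config_dist_vec <- function(X) {
  d <- dist(X)
  as.vector(d)
}

nmds_stress <- function(dvec_order, X) {
  dc <- config_dist_vec(X)
  dhat <- numeric(length(dc))
  fit <- isoreg(dc[dvec_order])
  dhat[dvec_order] <- fit$yf
  num <- sum((dc - dhat)^2)
  den <- sum(dc^2)
  if (den == 0) return(list(stress = 0, dhat = dhat, dc = dc))
  list(stress = sqrt(num / den), dhat = dhat, dc = dc)
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Alternates pool-adjacent-violators monotone regression of configuration
#' distances on the dissimilarity order with steepest-descent configuration
#' updates under step halving, so the stress of accepted iterations never
#' increases. Only the rank order of the input dissimilarities enters the
#' fit. The default start is the classical metric MDS configuration; a random
#' start is available with a seed.
#'
#' @param d symmetric dissimilarity matrix.
#' @param k embedding dimension (< number of samples).
#' @param init optional starting configuration (n x k matrix), or "random".
#' @param max_iter,tol iteration cap and stress-improvement tolerance.
#' @param seed seed used when `init = "random"`.
#' @return list: `points` (mean-centred n x k configuration), `stress`,
#'   `stress_trace` (accepted iterations), `converged`.
#' @export
nmds <- function(d, k = 2L, init = NULL, max_iter = 500L, tol = 1e-6,
                 seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k >= n) gs_stop("k must be smaller than the number of samples")
  if (max(abs(d - t(d))) > 1e-12) gs_stop("dissimilarity matrix must be symmetric")
  dvec <- as.vector(as.dist(d))
  ord <- order(dvec)
  if (is.null(init)) {
    X <- cmdscale(d, k = k)
    if (ncol(X) < k) X <- cbind(X, matrix(0, n, k - ncol(X)))
  } else if (identical(init, "random")) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    X <- matrix(stats::rnorm(n * k), n, k)
  } else {
    X <- as.matrix(init)
    if (!all(dim(X) == c(n, k))) gs_stop("init must be an n x k matrix")
  }
  scale0 <- mean(dist(X)); if (scale0 == 0) scale0 <- 1

  st <- nmds_stress(ord, X)
  trace <- st$stress
  step <- 0.2 * scale0
  converged <- FALSE
  # pair indices in the order dist() emits: (1,2),(1,3),...,(n-1,n)
  pair_i <- unlist(lapply(seq_len(n - 1L), function(i) rep(i, n - i)))
  pair_j <- unlist(lapply(seq_len(n - 1L), function(i) seq(i + 1L, n)))

  for (it in seq_len(max_iter)) {
    dc <- st$dc
    resid <- dc - st$dhat
    w <- ifelse(dc > 0, resid / dc, 0)
    G <- matrix(0, n, k)
    diffs <- X[pair_i, , drop = FALSE] - X[pair_j, , drop = FALSE]
    gcontrib <- diffs * w
    for (col in seq_len(k)) {
      G[, col] <- unname(tapply(c(gcontrib[, col], -gcontrib[, col]),
                                c(pair_i, pair_j), sum))
    }
    gnorm <- sqrt(sum(G^2))
    if (gnorm < 1e-12) { converged <- TRUE; break }
    accepted <- FALSE
    for (h in seq_len(30L)) {
      Xn <- X - (step / gnorm) * G
      stn <- nmds_stress(ord, Xn)
      if (stn$stress < st$stress - 1e-15) {
        X <- Xn; st <- stn
        trace <- c(trace, st$stress)
        step <- step * 1.5
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; break }
    nt <- length(trace)
    if (nt >= 2 && trace[nt - 1] - trace[nt] < tol) { converged <- TRUE; break }
  }
  X <- sweep(X, 2L, colMeans(X))
  rownames(X) <- rownames(d)
  list(points = X, stress = st$stress, stress_trace = trace,
       converged = converged)
}

#' Select families for the abundance/fold-change heatmap
#'
#' A family is kept when, for at least one native/exchanged group pair, its
#' group-mean relative abundance exceeds 1% in either group of the pair AND
#' its abundance changed more than 2-fold between the pair (either direction;
#' a zero mean against a positive one counts as an infinite fold change).
#' Everything else is pooled as "others".
#'
#' @param group_means matrix of group-mean relative abundances,
#'   families x groups.
#' @param pairs list of length-2 character vectors `c(native, exchanged)`.
#' @param min_abundance,min_fold filter thresholds (defaults 1% and 2-fold).
#' @return list with `selected` (data.frame family, max_abundance, max_fold)
#'   and `others` (character vector of pooled families).
#' @export
heatmap_select <- function(group_means, pairs = list(c("C", "CK"), c("K", "KC")),
                           min_abundance = 0.01, min_fold = 2) {
  for (p in pairs) {
    if (!all(p %in% colnames(group_means)))
      gs_stop(sprintf("missing group pair: %s", paste(p, collapse = "/")))
  }
  fams <- rownames(group_means)
  max_ab <- rep(0, length(fams)); max_fold <- rep(0, length(fams))
  sel <- rep(FALSE, length(fams))
  for (p in pairs) {
    a <- group_means[, p[1]]; b <- group_means[, p[2]]
    ab <- pmax(a, b)
    fold <- ifelse(a == 0 & b == 0, 1,
                   ifelse(pmin(a, b) == 0, Inf, pmax(a / b, b / a)))
    sel <- sel | (ab > min_abundance & fold > min_fold)
    max_ab <- pmax(max_ab, ab); max_fold <- pmax(max_fold, fold)
  }
  list(selected = data.frame(family = fams[sel], max_abundance = max_ab[sel],
                             max_fold = max_fold[sel], stringsAsFactors = FALSE),
       others = fams[!sel])
}
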