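# Alpha diversity: Chao1 (classic and bias-corrected), Shannon (natural log),
# analytic rarefaction, and the Welch test used for group comparison.

check_counts <- function(counts) {
  if (length(counts) == 0 || any(counts < 0) || any(counts != round(counts)))
    gs_stop("counts must be non-negative integers")
  if (sum(counts) == 0) gs_stop("total count must be > 0")
  counts[counts > 0]
}

#' Chao1 richness estimate
#'
#' Bias-corrected form (default): S_obs + F1 (F1 - 1) / (2 (F2 + 1)).
#' Classic form: S_obs + F1^2 / (2 F2) when doubletons exist, falling back to
#' S_obs + F1 (F1 - 1) / 2 when F2 = 0. F1 and F2 are the singleton and
#' doubleton counts. The estimate never falls below observed richness.
#'
#' @param counts non-negative integer abundance vector for one sample.
#' @param bias_corrected use the bias-corrected form (default TRUE).
#' @return the richness estimate (numeric scalar).
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  x <- check_counts(counts)
  s_obs <- length(x)
  f1 <- sum(x == 1L)
  f2 <- sum(x == 2L)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else if (f2 > 0) {
    s_obs + f1^2 / (2 * f2)
  } else {
    s_obs + f1 * (f1 - 1) / 2
  }
}

#' Shannon diversity (natural log)
#'
#' H = -sum p_i ln p_i over taxa with positive counts; delegated to
#' vegan's implementation.
#'
#' @param counts non-negative integer abundance vector.
#' @return H in nats.
#' @export
shannon <- function(counts) {
  x <- check_counts(counts)
  unname(vegan::diversity(x, index = "shannon"))
}

#' Analytic rarefaction curve
#'
#' Expected number of taxa observed in a uniform random subsample of each
#' depth d: E[S(d)] = sum_i (1 - C(N - N_i, d) / C(N, d)), computed via
#' vegan's `rarefy`. Non-decreasing in d, and equal to observed richness at
#' full depth.
#'
#' @param counts non-negative integer abundance vector.
#' @param depths subsample depths, each between 1 and `sum(counts)`.
#' @return data.frame with `depth` and `expected_richness`.
#' @export
rarefaction_curve <- function(counts, depths) {
  x <- check_counts(counts)
  n <- sum(x)
  if (any(depths < 1) || any(depths > n))
    gs_stop(sprintf("depths must lie in [1, %d]", n))
  # vegan::rarefy nags when a sample has no singletons; harmless here
  er <- vapply(depths, function(d)
    unname(c(suppressWarnings(vegan::rarefy(x, sample = d)))), numeric(1))
  data.frame(depth = depths, expected_richness = er)
}

#' Welch two-sample comparison of alpha-diversity values
#'
#' Welch's unequal-variance t-test, two-sided. Degenerate inputs are handled
#' as limits rather than errors: two groups with zero variance get statistic 0
#' and p = 1 when their means agree, and an infinite statistic with p = 0 when
#' they differ.
#'
#' @param a,b numeric vectors of per-sample diversity values (each length >= 2).
#' @return list with `statistic`, `p_value`, `df`, `method`.
#' @export
compare_alpha <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    gs_stop("each group needs at least 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(statistic = if (same) 0 else sign(mean(a) - mean(b)) * Inf,
                p_value = if (same) 1 else 0, df = NA_real_,
                method = "Welch two-sample t-test (degenerate limit)"))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), method = "Welch two-sample t-test")
}

#' Per-sample alpha diversity report
#'
#' @param table an [otu_table()].
#' @param bias_corrected passed to [chao1()].
#' @return data.frame: sample_id, n_reads, s_obs, chao1, shannon.
#' @export
alpha_diversity <- function(table, bias_corrected = TRUE) {
  stopifnot(inherits(table, "otu_table"))
  res <- lapply(colnames(table$counts), function(s) {
    x <- table$counts[, s]
    data.frame(sample_id = s, n_reads = sum(x), s_obs = sum(x > 0),
               chao1 = chao1(x, bias_corrected), shannon = shannon(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
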