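# Independent oracles used across the suite. These deliberately re-derive
# results through different routes than the package implementation: a plain-R
# Needleman-Wunsch with the same tie-break, an exhaustive alignment
# enumerator for tiny sequences, and direct formula evaluations.

ORACLE_BASES <- c("A", "C", "G", "T")

oracle_random_dna <- function(n) {
  paste(sample(ORACLE_BASES, n, replace = TRUE), collapse = "")
}

oracle_mutate <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(ORACLE_BASES, ch[p]), 1)
  paste(ch, collapse = "")
}

# Plain-R global alignment with linear gaps; traceback prefers diagonal, then
# up (gap in b), then left (gap in a), mirroring the documented tie-break.
oracle_nw <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (a > b) { tmp <- a; a <- b; b <- tmp }  # canonical orientation
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0L, n + 1, m + 1)
  S[1, ] <- gap * (0:m)
  S[, 1] <- gap * (0:n)
  for (i in 1:n) for (j in 1:m) {
    S[i + 1, j + 1] <- max(S[i, j] + if (av[i] == bv[j]) match else mismatch,
                           S[i, j + 1] + gap, S[i + 1, j] + gap)
  }
  i <- n; j <- m; matches <- 0L; columns <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (if (av[i] == bv[j]) match else mismatch)) {
      if (av[i] == bv[j]) matches <- matches + 1L
      i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    columns <- columns + 1L
  }
  list(score = S[n + 1, m + 1], identity = matches / columns,
       matches = matches, columns = columns)
}

# Exhaustive enumeration of every global alignment of two tiny sequences;
# returns the optimal score and the identities of all optimal alignments.
oracle_enumerate_alignments <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  out <- list()
  rec <- function(i, j, score, matches, columns) {
    if (i > length(av) && j > length(bv)) {
      out[[length(out) + 1L]] <<- c(score = score, identity = matches / columns)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      rec(i + 1, j + 1,
          score + if (av[i] == bv[j]) match else mismatch,
          matches + (av[i] == bv[j]), columns + 1)
    }
    if (i <= length(av)) rec(i + 1, j, score + gap, matches, columns + 1)
    if (j <= length(bv)) rec(i, j + 1, score + gap, matches, columns + 1)
  }
  rec(1L, 1L, 0, 0L, 0L)
  m <- do.call(rbind, out)
  best <- max(m[, "score"])
  list(best_score = best,
       optimal_identities = sort(unique(m[m[, "score"] == best, "identity"])))
}

# Monte-Carlo rarefaction via sequential conditional hypergeometrics, which
# samples the multivariate hypergeometric exactly (independent of the
# analytic-formula route).
oracle_mc_rarefaction <- function(counts, depth, n_rep = 1e5) {
  counts <- counts[counts > 0]
  S <- length(counts)
  seen <- matrix(FALSE, n_rep, S)
  remaining_total <- sum(counts)
  remaining_draw <- rep(depth, n_rep)
  for (i in seq_len(S)) {
    ki <- stats::rhyper(n_rep, counts[i], remaining_total - counts[i],
                        remaining_draw)
    seen[, i] <- ki > 0
    remaining_draw <- remaining_draw - ki
    remaining_total <- remaining_total - counts[i]
  }
  s_obs <- rowSums(seen)
  list(mean = mean(s_obs), se = stats::sd(s_obs) / sqrt(n_rep))
}

# a compact habitat-exchange scenario that keeps unit tests fast
small_scenario <- function(seed = 42L, ...) {
  scenario_config(n_families = 10L, taxa_per_family = 3L,
                  richness = c(C_gut = 6L, K_gut = 10L, CW = 5L, CS = 6L,
                               KW = 8L, KS = 10L),
                  specific_richness = 2L,
                  gut_capacity = 5L, acquisition_capacity = 3L,
                  env_replicates = 2L, reads_per_sample = 100L,
                  seed = seed, ...)
}

# Crafted 20-read FASTQ exercising every filtering criterion. Returns the
# fixture path, the barcode map, and the expected per-read outcome.
qc_fixture <- function(dir) {
  barcodes <- c(S1 = "ACGTACGTAC", S2 = "TGCATGCAGT")  # Hamming distance 8
  fwd <- "AGAGTTTGATCMTGGCTCAG"   # M matches A or C
  rev <- "GCTGCCTCCCGAGGAGT"
  fwd_a <- sub("M", "A", fwd); fwd_c <- sub("M", "C", fwd)
  body <- function(n) strrep("ACGT", ceiling(n / 4)) |> substr(1, n)
  flip <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  }
  q <- function(seq, mean_q = 38) strrep(rawToChar(as.raw(mean_q + 33)), nchar(seq))

  reads <- list()
  add <- function(id, sample, seq, qual, expect, reason = NA) {
    reads[[length(reads) + 1L]] <<- list(id = id, seq = seq, qual = qual,
                                         sample = sample, expect = expect,
                                         reason = reason)
  }
  mk <- function(bc, primer, core, rv = rev) paste0(bc, primer, core, rv)

  core250 <- body(250)
  # accepted: clean reads, both samples, both M resolutions
  add("r01", "S1", mk(barcodes["S1"], fwd_a, core250), q(mk(barcodes["S1"], fwd_a, core250)), TRUE)
  add("r02", "S2", mk(barcodes["S2"], fwd_c, core250), q(mk(barcodes["S2"], fwd_c, core250)), TRUE)
  # accepted: one barcode error
  add("r03", "S1", mk(flip(barcodes["S1"], 1), fwd_a, core250),
      q(mk(barcodes["S1"], fwd_a, core250)), TRUE)
  # accepted: exactly two forward-primer errors (limit)
  add("r04", "S1", mk(barcodes["S1"], flip(fwd_a, c(1, 3)), core250),
      q(mk(barcodes["S1"], fwd_a, core250)), TRUE)
  # accepted: exactly two reverse-primer errors
  add("r05", "S2", mk(barcodes["S2"], fwd_a, core250, flip(rev, c(2, 4))),
      q(mk(barcodes["S2"], fwd_a, core250)), TRUE)
  # accepted: boundary lengths 200 and 600
  s200 <- mk(barcodes["S1"], fwd_a, body(200))
  add("r06", "S1", s200, q(s200), TRUE)
  s600 <- mk(barcodes["S2"], fwd_c, body(600))
  add("r07", "S2", s600, q(s600), TRUE)
  # accepted: mean quality exactly 30
  s30 <- mk(barcodes["S1"], fwd_a, core250)
  add("r08", "S1", s30, q(s30, 30), TRUE)
  # rejected: two barcode errors
  add("r09", NA, mk(flip(barcodes["S1"], c(1, 2)), fwd_a, core250),
      q(s30), FALSE, "barcode")
  # rejected: three forward-primer errors
  add("r10", NA, mk(barcodes["S1"], flip(fwd_a, c(1, 3, 5)), core250),
      q(s30), FALSE, "primer")
  # rejected: M position violated (G) plus two more errors = three
  add("r11", NA, mk(barcodes["S1"], flip(sub("M", "G", fwd), c(1, 3)), core250),
      q(s30), FALSE, "primer")
  # rejected: three reverse-primer errors
  add("r12", NA, mk(barcodes["S2"], fwd_a, core250, flip(rev, c(1, 2, 3))),
      q(s30), FALSE, "primer")
  # rejected: trimmed length 150 / 601
  s150 <- mk(barcodes["S1"], fwd_a, body(150))
  add("r13", NA, s150, q(s150), FALSE, "length")
  s601 <- mk(barcodes["S2"], fwd_c, body(601))
  add("r14", NA, s601, q(s601), FALSE, "length")
  # rejected: mean quality 29.9 over a 200 nt core (180 @30 + 20 @29)
  core200 <- body(200)
  s299 <- mk(barcodes["S1"], fwd_a, core200)
  q299 <- paste0(q(paste0(barcodes["S1"], fwd_a)),
                 strrep(rawToChar(as.raw(30 + 33)), 180),
                 strrep(rawToChar(as.raw(29 + 33)), 20), q(rev))
  add("r15", NA, s299, q299, FALSE, "quality")
  # accepted: barcode error + two primer errors together
  add("r16", "S2", mk(flip(barcodes["S2"], 5), flip(fwd_c, c(2, 6)), core250),
      q(s30), TRUE)
  # rejected: barcode failure wins over a length failure
  add("r17", NA, mk(flip(barcodes["S1"], c(3, 4)), fwd_a, body(150)),
      q(s150), FALSE, "barcode")
  # rejected: primer failure wins over a quality failure
  add("r18", NA, mk(barcodes["S1"], flip(fwd_a, c(2, 4, 6)), core200),
      q299, FALSE, "primer")
  # accepted: second sample clean again
  add("r19", "S2", mk(barcodes["S2"], fwd_a, core250), q(s30), TRUE)
  # rejected: quality just below threshold (29 flat)
  s29 <- mk(barcodes["S1"], fwd_c, core250)
  add("r20", NA, s29, q(s29, 29), FALSE, "quality")

  df <- data.frame(read_id = vapply(reads, `[[`, "", "id"),
                   sequence = vapply(reads, `[[`, "", "seq"),
                   quality = vapply(reads, `[[`, "", "qual"),
                   stringsAsFactors = FALSE)
  stopifnot(all(nchar(df$quality) == nchar(df$sequence)))
  path <- file.path(dir, "qc_fixture.fastq")
  write_fastq(df, path)
  list(path = path, barcodes = barcodes,
       expect = data.frame(
         read_id = df$read_id,
         accepted = vapply(reads, `[[`, TRUE, "expect"),
         sample = vapply(reads, function(r) as.character(r$sample), ""),
         reason = vapply(reads, function(r) as.character(r$reason), ""),
         stringsAsFactors = FALSE))
}
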