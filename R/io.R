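# Sequence and table IO plus the demultiplex/quality-filter stage. FASTA goes
# through Biostrings; 4-line FASTQ is parsed directly so malformed records can
# be reported by record index and quality/sequence length mismatches caught.

#' Quality-control policy for demultiplexing and filtering
#'
#' Defaults are the filtering criteria of the emulated pipeline: trimmed length
#' within 200-600 nt, mean Phred quality at least 30, at most 1 barcode error
#' and at most 2 primer errors (IUPAC-aware), with 10-nt sample barcodes.
#'
#' @param min_len,max_len allowed trimmed read length range in nt.
#' @param min_mean_quality minimum mean Phred score over the trimmed read.
#' @param max_barcode_mismatch,max_primer_mismatch allowed Hamming errors.
#' @param barcode_length barcode length in nt.
#' @param forward_primer,reverse_primer IUPAC primer strings; the reverse
#'   primer is matched at the 3' end in the given orientation.
#' @return A `qc_policy` list.
#' @export
qc_policy <- function(min_len = 200L, max_len = 600L, min_mean_quality = 30,
                      max_barcode_mismatch = 1L, max_primer_mismatch = 2L,
                      barcode_length = 10L,
                      forward_primer = FORWARD_PRIMER,
                      reverse_primer = REVERSE_PRIMER) {
  if (!(min_len > 0L && min_len <= max_len))
    gs_config_error("need 0 < min_len <= max_len")
  if (max_barcode_mismatch < 0L || max_primer_mismatch < 0L)
    gs_config_error("mismatch limits must be >= 0")
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 min_mean_quality = min_mean_quality,
                 max_barcode_mismatch = as.integer(max_barcode_mismatch),
                 max_primer_mismatch = as.integer(max_primer_mismatch),
                 barcode_length = as.integer(barcode_length),
                 forward_primer = forward_primer,
                 reverse_primer = reverse_primer),
            class = "qc_policy")
}

#' Read sequences from FASTA or FASTQ
#'
#' @param path file path.
#' @param format "fasta" or "fastq"; inferred from the extension by default.
#' @return data.frame with columns `read_id`, `sequence`, `quality`
#'   (Phred+33 string, `NA` for FASTA). Order-preserving.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) "fastq" else "fasta"
  }
  if (!file.exists(path)) gs_stop(sprintf("file not found: %s", path))
  if (format == "fasta") {
    if (file.size(path) == 0)
      return(data.frame(read_id = character(0), sequence = character(0),
                        quality = character(0), stringsAsFactors = FALSE))
    ss <- Biostrings::readDNAStringSet(path)
    return(data.frame(read_id = sub("\\s.*$", "", names(ss)),
                      sequence = as.character(ss), quality = NA_character_,
                      stringsAsFactors = FALSE, row.names = NULL))
  }
  lines <- readLines(path)
  if (length(lines) == 0)
    return(data.frame(read_id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  if (length(lines) %% 4L != 0L)
    gs_stop(sprintf("FASTQ parse error at record %d: truncated record",
                    length(lines) %/% 4L + 1L))
  n <- length(lines) %/% 4L
  hd <- lines[seq(1L, by = 4L, length.out = n)]
  sq <- lines[seq(2L, by = 4L, length.out = n)]
  pl <- lines[seq(3L, by = 4L, length.out = n)]
  ql <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hd, "@"))
  if (length(bad)) gs_stop(sprintf(
    "FASTQ parse error at record %d: header does not start with '@'", bad[1]))
  bad <- which(!startsWith(pl, "+"))
  if (length(bad)) gs_stop(sprintf(
    "FASTQ parse error at record %d: separator line does not start with '+'", bad[1]))
  bad <- which(nchar(sq) != nchar(ql))
  if (length(bad)) gs_stop(sprintf(
    "FASTQ parse error at record %d: quality length differs from sequence length",
    bad[1]))
  data.frame(read_id = sub("\\s.*$", "", substring(hd, 2L)), sequence = sq,
             quality = ql, stringsAsFactors = FALSE)
}

#' Write reads to a 4-line FASTQ file
#'
#' @param reads data.frame with `read_id`, `sequence`, `quality`.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  if (any(is.na(reads$quality)) ||
      any(nchar(reads$quality) != nchar(reads$sequence)))
    gs_stop("every read needs a quality string matching its sequence length")
  writeLines(as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                             "+", reads$quality)), path)
  invisible(path)
}

iupac_allowed <- function() {
  # Biostrings' IUPAC table, e.g. M -> "AC"
  strsplit(Biostrings::IUPAC_CODE_MAP, "")
}

# mismatch counts of fixed-position pattern vs reads (IUPAC in pattern only);
# positions beyond a read's end count as mismatches
pattern_mismatches <- function(seqs, pattern, offset = 0L) {
  allowed <- iupac_allowed()
  pat <- strsplit(pattern, "")[[1]]
  mm <- integer(length(seqs))
  for (i in seq_along(pat)) {
    ch <- substr(seqs, offset + i, offset + i)
    ok_set <- allowed[[pat[i]]]
    if (is.null(ok_set)) ok_set <- pat[i]
    mm <- mm + !(ch %in% ok_set)
  }
  mm
}

mean_phred <- function(qual) {
  vapply(qual, function(q) {
    if (is.na(q) || !nzchar(q)) return(NA_real_)
    mean(as.integer(charToRaw(q))) - 33
  }, numeric(1), USE.NAMES = FALSE)
}

#' Demultiplex and quality-filter reads
#'
#' Applies, in a fixed order per read, the four filtering criteria: barcode
#' assignment (Hamming distance on the leading `barcode_length` bases), primer
#' match (IUPAC-aware, both forward after the barcode and reverse at the 3'
#' end), trimmed length window, and minimum mean Phred quality. Each rejected
#' read is logged with the first failing criterion; accepted reads are trimmed
#' of barcode and primers and assigned to their sample. Reads without quality
#' strings (FASTA input) skip the quality criterion.
#'
#' @param reads data.frame from [read_sequences()].
#' @param barcode_map named character vector, sample_id -> barcode.
#' @param policy a [qc_policy()].
#' @return list with `accepted` (sample_id, read_id, sequence, quality) and
#'   `rejected` (read_id, reason in barcode/primer/length/quality).
#' @export
demultiplex_filter <- function(reads, barcode_map, policy = qc_policy()) {
  bl <- policy$barcode_length
  if (any(nchar(barcode_map) != bl))
    gs_config_error("all barcodes must have length barcode_length")
  if (anyDuplicated(names(barcode_map)))
    gs_config_error("duplicate sample ids in barcode_map")
  bc_chars <- strsplit(barcode_map, "")
  if (length(barcode_map) > 1) {
    for (i in seq_along(barcode_map)[-1]) for (j in seq_len(i - 1)) {
      d <- sum(bc_chars[[i]] != bc_chars[[j]])
      if (d <= 2L * policy$max_barcode_mismatch)
        gs_config_error(sprintf(
          "ambiguous barcodes: %s and %s are within Hamming distance %d",
          names(barcode_map)[i], names(barcode_map)[j], d))
    }
  }
  n <- nrow(reads)
  if (n == 0)
    return(list(accepted = data.frame(sample_id = character(0),
                                      read_id = character(0),
                                      sequence = character(0),
                                      quality = character(0)),
                rejected = data.frame(read_id = character(0),
                                      reason = character(0))))

  # barcode distances, reads x barcodes
  dist <- vapply(seq_along(barcode_map), function(k)
    pattern_mismatches(reads$sequence, barcode_map[[k]], offset = 0L),
    integer(n))
  dist <- matrix(dist, nrow = n)
  best <- max.col(-dist, ties.method = "first")
  best_d <- dist[cbind(seq_len(n), best)]
  sample_id <- names(barcode_map)[best]
  fail_barcode <- best_d > policy$max_barcode_mismatch

  fwd_mm <- pattern_mismatches(reads$sequence, policy$forward_primer, offset = bl)
  rev_len <- nchar(policy$reverse_primer)
  core_start <- bl + nchar(policy$forward_primer) + 1L
  core_end <- nchar(reads$sequence) - rev_len
  rev_mm <- integer(n)
  for (i in seq_len(rev_len)) {
    ch <- substr(reads$sequence, core_end + i, core_end + i)
    pat_i <- substr(policy$reverse_primer, i, i)
    ok_set <- iupac_allowed()[[pat_i]]
    if (is.null(ok_set)) ok_set <- pat_i
    rev_mm <- rev_mm + !(ch %in% ok_set)
  }
  fail_primer <- fwd_mm > policy$max_primer_mismatch |
    rev_mm > policy$max_primer_mismatch

  core_seq <- substr(reads$sequence, core_start, core_end)
  core_len <- nchar(core_seq)
  fail_length <- core_len < policy$min_len | core_len > policy$max_len

  core_qual <- ifelse(is.na(reads$quality), NA_character_,
                      substr(reads$quality, core_start, core_end))
  mq <- mean_phred(core_qual)
  fail_quality <- !is.na(mq) & mq < policy$min_mean_quality

  reason <- rep(NA_character_, n)
  reason[fail_quality] <- "quality"
  reason[fail_length] <- "length"
  reason[fail_primer] <- "primer"
  reason[fail_barcode] <- "barcode"
  keep <- is.na(reason)

  list(accepted = data.frame(sample_id = sample_id[keep],
                             read_id = reads$read_id[keep],
                             sequence = core_seq[keep],
                             quality = core_qual[keep],
                             stringsAsFactors = FALSE),
       rejected = data.frame(read_id = reads$read_id[!keep],
                             reason = reason[!keep],
                             stringsAsFactors = FALSE))
}

# --- OTU table container ----------------------------------------------------

#' Construct an OTU count table
#'
#' @param counts non-negative integer matrix, OTUs x samples, with dimnames.
#' @param taxonomy data.frame with `otu_id` and the five lineage ranks; rows
#'   for every OTU in `counts` (missing ranks may be "unclassified").
#' @param metadata optional data.frame keyed by `sample_id` (group, type,
#'   habitat, replicate).
#' @return An `otu_table` object.
#' @export
otu_table <- function(counts, taxonomy = NULL, metadata = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    gs_stop("counts must have OTU rownames and sample colnames")
  if (anyDuplicated(colnames(counts))) gs_stop("sample ids must be unique")
  if (any(counts < 0) || any(counts != round(counts)))
    gs_stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    missing <- setdiff(rownames(counts), taxonomy$otu_id)
    if (length(missing))
      gs_stop(sprintf("taxonomy missing for OTUs: %s",
                      paste(utils::head(missing, 3), collapse = ", ")))
    taxonomy <- taxonomy[match(rownames(counts), taxonomy$otu_id), , drop = FALSE]
    rownames(taxonomy) <- NULL
  }
  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples, %s taxonomy, %s metadata\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$taxonomy)) "no" else "with",
              if (is.null(x$metadata)) "no" else "with"))
  invisible(x)
}

lineage_string <- function(taxonomy) {
  apply(taxonomy[LINEAGE_RANKS], 1L, paste, collapse = ";")
}

#' Write an OTU table to a tab-separated file
#'
#' Columns: `otu_id`, one column per sample, and (when taxonomy is present) a
#' final `taxonomy` column of semicolon-joined lineages. [read_count_table()]
#' round-trips counts, taxonomy and sample order exactly.
#'
#' @param table an [otu_table()].
#' @param path output path.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  df <- data.frame(otu_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(table$taxonomy)) {
    if (any(grepl(";", unlist(table$taxonomy[LINEAGE_RANKS]))))
      gs_stop("lineage ranks must not contain ';'")
    df$taxonomy <- lineage_string(table$taxonomy)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OTU table written by [write_count_table()]
#'
#' @param path input path.
#' @return An [otu_table()] (without sample metadata).
#' @export
read_count_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (!"otu_id" %in% names(df)) gs_stop("count table must have an otu_id column")
  has_tax <- "taxonomy" %in% names(df)
  sample_cols <- setdiff(names(df), c("otu_id", "taxonomy"))
  counts <- suppressWarnings(
    vapply(df[sample_cols], as.numeric, numeric(nrow(df))))
  counts <- matrix(counts, nrow = nrow(df),
                   dimnames = list(df$otu_id, sample_cols))
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    gs_stop("count table contains negative, non-integer or non-numeric counts")
  taxonomy <- NULL
  if (has_tax) {
    parts <- strsplit(df$taxonomy, ";", fixed = TRUE)
    if (any(lengths(parts) != length(LINEAGE_RANKS)))
      gs_stop("taxonomy column must have 5 semicolon-separated ranks")
    taxonomy <- data.frame(otu_id = df$otu_id,
                           do.call(rbind, parts), stringsAsFactors = FALSE)
    names(taxonomy) <- c("otu_id", LINEAGE_RANKS)
  }
  otu_table(counts, taxonomy)
}
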