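#' N50 of a set of sequence lengths
#'
#' The length such that sequences of that length or longer contain at least
#' half of all assembled bases: sort descending, accumulate, and return the
#' first length at which the cumulative sum reaches `total/2` (ties and the
#' exact-half boundary included, i.e. cumulative `>=` half).
#'
#' @param lengths positive integer sequence lengths, non-empty.
#' @return the N50 in bases; always an element of `lengths`.
#' @examples
#' n50(c(5, 4, 3, 2, 1)) # 4
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) stop("empty length set", call. = FALSE)
  if (any(!is.finite(lengths)) || any(lengths < 1)) {
    stop("lengths must be positive", call. = FALSE)
  }
  s <- sort(unname(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Gap ratio of assembled sequences
#'
#' Fraction of N characters (unknown bases inserted when scaffolding joins
#' contigs across unsequenced gaps) in each sequence.
#'
#' @param sequences character vector or [Biostrings::DNAStringSet] of
#'   sequences over A/C/G/T/N (case-insensitive).
#' @return numeric vector of per-sequence gap ratios in \[0, 1\].
#' @examples
#' gap_ratio("ACGTNNNNNN") # 0.6
#' @export
gap_ratio <- function(sequences) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- as.character(sequences)
  }
  if (length(sequences) == 0 || any(nchar(sequences) == 0)) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  sequences <- toupper(unname(sequences))
  n_gap <- vapply(strsplit(sequences, ""), function(b) sum(b == "N"), 0)
  n_gap / nchar(sequences)
}

#' Fraction of sequences with acceptable gap content
#'
#' Proportion of sequences whose [gap_ratio()] is strictly below `threshold`
#' (default 5%), the usual screen for whether a scaffolded unigene set is
#' clean enough for downstream expression analysis.
#'
#' @param sequences as in [gap_ratio()], non-empty.
#' @param threshold gap-ratio cutoff (default 0.05).
#' @return fraction in \[0, 1\].
#' @export
gap_ok_fraction <- function(sequences, threshold = 0.05) {
  mean(gap_ratio(sequences) < threshold)
}

#' Per-base quality, N and GC percentages of a read set
#'
#' The three headline sequencing QC numbers: `q20_pct`, the percentage of
#' bases whose Phred quality meets the threshold (default `Q >= 20`, the
#' standard Q20 convention; set `strict_gt = TRUE` for a literal `Q > 20`);
#' `n_pct`, the percentage of N base calls; and `gc_pct`, the percentage of
#' G or C bases. N bases are excluded from the GC numerator but included in
#' every denominator.
#'
#' @param sequences character vector of read sequences.
#' @param qualities list of integer Phred scores, one vector per read, with
#'   `length(qualities[[i]]) == nchar(sequences[i])`.
#' @param q_threshold quality threshold (default 20).
#' @param strict_gt if `TRUE`, count only bases with quality strictly above
#'   the threshold.
#' @return named numeric vector `c(q20_pct, n_pct, gc_pct)` (unrounded).
#' @examples
#' fastq_stats("ACGN", list(c(40L, 40L, 10L, 40L))) # 75, 25, 25
#' @export
fastq_stats <- function(sequences, qualities, q_threshold = 20,
                        strict_gt = FALSE) {
  if (length(sequences) == 0) stop("empty read set", call. = FALSE)
  if (length(sequences) != length(qualities)) {
    stop("sequences and qualities differ in length", call. = FALSE)
  }
  seq_len_bp <- nchar(sequences)
  qual_len <- lengths(qualities)
  if (!all(seq_len_bp == qual_len)) {
    stop("per-read sequence and quality lengths differ", call. = FALSE)
  }
  total <- sum(seq_len_bp)
  q <- unlist(qualities, use.names = FALSE)
  n_q_ok <- if (strict_gt) sum(q > q_threshold) else sum(q >= q_threshold)
  bases <- unlist(strsplit(toupper(paste(sequences, collapse = "")), ""),
                  use.names = FALSE)
  c(q20_pct = 100 * n_q_ok / total,
    n_pct = 100 * sum(bases == "N") / total,
    gc_pct = 100 * sum(bases %in% c("G", "C")) / total)
}

#' Bin sequence lengths and report the long-sequence proportion
#'
#' Counts lengths into half-open bins `[e_i, e_{i+1})` and reports the
#' percentage of sequences at or above a cutoff, rounded half-up to two
#' decimals as in printed assembly summaries.
#'
#' @param lengths sequence lengths.
#' @param bin_edges strictly increasing bin edges.
#' @param cutoff optional length cutoff for the `prop_ge_cutoff_pct` summary
#'   (default 500 bp).
#' @return list with `bins` (data.frame `bin`, `count`, `proportion_pct`)
#'   and `prop_ge_cutoff_pct`.
#' @export
length_bins <- function(lengths, bin_edges, cutoff = 500) {
  if (any(diff(bin_edges) <= 0)) {
    stop("bin_edges must be strictly increasing", call. = FALSE)
  }
  counts <- vapply(seq_len(length(bin_edges) - 1), function(i) {
    sum(lengths >= bin_edges[i] & lengths < bin_edges[i + 1])
  }, 0L)
  labels <- sprintf("[%s,%s)", bin_edges[-length(bin_edges)], bin_edges[-1])
  list(
    bins = data.frame(bin = labels, count = counts,
                      proportion_pct =
                        round_half_up(100 * counts / length(lengths), 2),
                      stringsAsFactors = FALSE),
    prop_ge_cutoff_pct =
      round_half_up(100 * sum(lengths >= cutoff) / length(lengths), 2)
  )
}

#' Assembly statistics block for a sequence set
#'
#' The per-assembly summary printed for contigs, scaffolds and unigenes:
#' sequence and base totals, N50, mean length, length-bin counts and the
#' fraction of sequences with gap ratio below the threshold.
#'
#' @param sequences character vector or [Biostrings::DNAStringSet].
#' @param bin_edges length-bin edges (default `c(0, 200, 500, 1000, 2000,
#'   Inf)`).
#' @param gap_threshold gap-ratio cutoff (default 0.05).
#' @return list with fields `n_sequences`, `total_bases`, `n50`,
#'   `mean_length`, `bins`, `prop_ge_500_pct`, `gap_ok_fraction`.
#' @export
assembly_stats <- function(sequences,
                           bin_edges = c(0, 200, 500, 1000, 2000, Inf),
                           gap_threshold = 0.05) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- as.character(sequences)
  }
  lens <- nchar(sequences)
  lb <- length_bins(lens, bin_edges, cutoff = 500)
  list(
    n_sequences = length(sequences),
    total_bases = sum(lens),
    n50 = n50(lens),
    mean_length = mean(lens),
    bins = lb$bins,
    prop_ge_500_pct = lb$prop_ge_cutoff_pct,
    gap_ok_fraction = gap_ok_fraction(sequences, gap_threshold)
  )
}

# FASTA / FASTQ I/O -----------------------------------------------------------

#' Read a FASTA file of assembled sequences
#'
#' @param path FASTA file ('>' headers; wrapped or single-line).
#' @return named character vector of upper-case sequences.
#' @export
read_fasta_sequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Read a FASTQ file into sequences and decoded Phred qualities
#'
#' @param path FASTQ file (4-line records, '@'/'+' framing).
#' @param phred_offset quality encoding offset, 33 (Sanger/modern Illumina)
#'   or 64 (early Illumina).
#' @return list with `sequences` (character) and `qualities` (list of
#'   integer vectors).
#' @export
read_fastq_reads <- function(path, phred_offset = 33) {
  if (!phred_offset %in% c(33, 64)) {
    stop("phred_offset must be 33 or 64", call. = FALSE)
  }
  scoring <- if (phred_offset == 33) "phred" else "illumina"
  x <- tryCatch(
    suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(path,
                                                quality.scoring = scoring)),
    error = function(e) {
      stop(sprintf("failed to decode qualities at Phred offset %d: %s",
                   phred_offset, conditionMessage(e)), call. = FALSE)
    })
  # coercions drop Biostrings metadata columns we never use
  quals <- suppressWarnings(as.list(as(Biostrings::quality(x), "IntegerList")))
  lo <- suppressWarnings(min(unlist(quals, use.names = FALSE)))
  if (is.finite(lo) && lo < 0) {
    stop(sprintf(paste0("negative quality score after decoding at Phred ",
                        "offset %d; the file is probably encoded at a ",
                        "different offset"), phred_offset), call. = FALSE)
  }
  list(sequences = suppressWarnings(as.character(x)), qualities = quals)
}
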