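#' Define a synthetic two-library scenario
#'
#' Parameters of the generator that emulates a two-condition, no-replicate
#' RNA-seq design: two libraries of unequal depth, log-normal baseline
#' abundances, a DE fraction split into effect-size classes, log-normal
#' transcript lengths, and Poisson count sampling.
#'
#' Defaults describe the elicitation-study shape at desk scale: library
#' sizes 29,460 and 29,896 (the two sequenced libraries' read totals scaled
#' down by 10^3), 2,000 genes, 28.9% of genes DE, and DE effects split
#' evenly between strong (|log2 FC| = 2.5) and slight (|log2 FC| = 1.25)
#' classes in both directions.
#'
#' @param n_genes number of genes.
#' @param lib_size_a,lib_size_b library totals (the test's N1, N2).
#' @param baseline_log_mean,baseline_log_sd log-normal abundance parameters.
#' @param de_fraction proportion of genes that are differentially expressed.
#' @param lfc_classes data.frame `class`, `log2fc`, `weight` describing the
#'   DE effect-size mixture; weights must sum to 1.
#' @param length_log_mean,length_log_sd log-normal transcript-length
#'   parameters (defaults give a mean length near 744 bp).
#' @param dispersion gamma-Poisson overdispersion; 0 (default) gives pure
#'   Poisson sampling, matching the exact test's null model. Positive values
#'   are an extension for demonstrating the anti-conservativeness of
#'   no-replicate testing under biological variability.
#' @param seed RNG seed (integer).
#' @return object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_genes = 2000,
                               lib_size_a = 29460,
                               lib_size_b = 29896,
                               baseline_log_mean = 1.2,
                               baseline_log_sd = 1.6,
                               de_fraction = 0.289,
                               lfc_classes = default_lfc_classes(),
                               length_log_mean = 6.5,
                               length_log_sd = 0.6,
                               dispersion = 0,
                               seed = 1L) {
  stopifnot(n_genes >= 1, lib_size_a >= 1, lib_size_b >= 1,
            de_fraction >= 0, de_fraction < 1, dispersion >= 0)
  if (nrow(lfc_classes) == 0 || all(lfc_classes$weight == 0)) {
    stop("degenerate scenario: lfc_classes has no mass", call. = FALSE)
  }
  if (abs(sum(lfc_classes$weight) - 1) > 1e-8) {
    stop("lfc_classes weights must sum to 1", call. = FALSE)
  }
  structure(list(
    n_genes = as.integer(n_genes),
    lib_size_a = lib_size_a, lib_size_b = lib_size_b,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    de_fraction = de_fraction, lfc_classes = lfc_classes,
    length_log_mean = length_log_mean, length_log_sd = length_log_sd,
    dispersion = dispersion, seed = as.integer(seed)
  ), class = "synthetic_scenario")
}

#' Default DE effect-size classes
#'
#' Strong (|log2 FC| = 2.5) and slight (|log2 FC| = 1.25) up- and
#' down-regulation in equal weight, mirroring the split between strongly and
#' slightly induced pathway genes observed in elicited cultures.
#'
#' @return data.frame `class`, `log2fc`, `weight`.
#' @export
default_lfc_classes <- function() {
  data.frame(
    class = c("strong_up", "slight_up", "strong_down", "slight_down"),
    log2fc = c(2.5, 1.25, -2.5, -1.25),
    weight = c(0.25, 0.25, 0.25, 0.25),
    stringsAsFactors = FALSE
  )
}

# sub-seeds for independent generator streams; kept < 2^31
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %%
               2147483647)
}

#' Simulate a two-library count table with known DE structure
#'
#' Per gene: relative abundance `a_g` ~ log-normal; condition-B abundance
#' `a_g * 2^log2fc`; expected count `lambda = lib_size * a_g L_g /
#' sum(a L)` (per condition); counts ~ Poisson(lambda), or gamma-Poisson
#' when `dispersion > 0`. Deterministic for a fixed scenario seed.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with `counts` (data.frame `gene_id`, `length_bp`, `x`, `y`)
#'   and `truth` (data.frame `gene_id`, `length_bp`, `true_log2fc`,
#'   `true_status`, `class`, `lambda_a`, `lambda_b`).
#' @export
simulate_counts <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  s <- scenario
  set.seed(derive_seed(s$seed, 1L))

  gene_id <- sprintf("gene%05d", seq_len(s$n_genes))
  length_bp <- pmax(100L, as.integer(round(
    stats::rlnorm(s$n_genes, s$length_log_mean, s$length_log_sd))))
  abund <- stats::rlnorm(s$n_genes, s$baseline_log_mean, s$baseline_log_sd)

  n_de <- round(s$de_fraction * s$n_genes)
  de_idx <- sample.int(s$n_genes, n_de)
  log2fc <- numeric(s$n_genes)
  class <- rep("null", s$n_genes)
  if (n_de > 0) {
    k <- sample.int(nrow(s$lfc_classes), n_de, replace = TRUE,
                    prob = s$lfc_classes$weight)
    log2fc[de_idx] <- s$lfc_classes$log2fc[k]
    class[de_idx] <- s$lfc_classes$class[k]
  }

  w_a <- abund * length_bp
  w_b <- abund * 2^log2fc * length_bp
  lambda_a <- s$lib_size_a * w_a / sum(w_a)
  lambda_b <- s$lib_size_b * w_b / sum(w_b)

  draw <- function(lambda) {
    if (s$dispersion > 0) {
      mu <- lambda * stats::rgamma(length(lambda),
                                   shape = 1 / s$dispersion,
                                   rate = 1 / s$dispersion)
      stats::rpois(length(lambda), mu)
    } else {
      stats::rpois(length(lambda), lambda)
    }
  }
  x <- draw(lambda_a)
  y <- draw(lambda_b)

  status <- ifelse(log2fc > 0, "up", ifelse(log2fc < 0, "down", "not_de"))
  list(
    counts = data.frame(gene_id = gene_id, length_bp = length_bp,
                        x = x, y = y, stringsAsFactors = FALSE),
    truth = data.frame(gene_id = gene_id, length_bp = length_bp,
                       true_log2fc = log2fc, true_status = status,
                       class = class, lambda_a = lambda_a,
                       lambda_b = lambda_b, stringsAsFactors = FALSE)
  )
}

#' Simulate a FASTA set with controlled gap content
#'
#' Generates assembled-sequence records of log-normal length in which a
#' target fraction of sequences carries benign gap content (N runs totalling
#' less than `gap_threshold` of the length) while the remainder carries
#' heavy gap content above it, emulating scaffolded unigenes of varying
#' quality.
#'
#' @param n number of records.
#' @param length_log_mean,length_log_sd log-normal length parameters.
#' @param gap_ok_target fraction of records whose gap ratio should fall
#'   below `gap_threshold` (default 0.8547).
#' @param gap_threshold the gap-ratio boundary (default 0.05).
#' @param seed RNG seed.
#' @return list with `sequences` (named character vector) and `truth`
#'   (data.frame `seq_id`, `length_bp`, `gap_ratio`, `gap_ok`).
#' @export
simulate_fasta <- function(n, length_log_mean = 6.5, length_log_sd = 0.6,
                           gap_ok_target = 0.8547, gap_threshold = 0.05,
                           seed = 1L) {
  stopifnot(n >= 1, gap_ok_target >= 0, gap_ok_target <= 1)
  set.seed(derive_seed(seed, 2L))
  lens <- pmax(100L, as.integer(round(
    stats::rlnorm(n, length_log_mean, length_log_sd))))
  ok <- stats::runif(n) < gap_ok_target
  gap_frac <- ifelse(ok,
                     stats::runif(n, 0, gap_threshold * 0.98),
                     stats::runif(n, gap_threshold * 1.02,
                                  min(4 * gap_threshold, 1)))
  seqs <- character(n)
  realized <- numeric(n)
  for (i in seq_len(n)) {
    n_gap <- round(gap_frac[i] * lens[i])
    # guard rounding across the threshold
    if (ok[i]) n_gap <- min(n_gap, ceiling(gap_threshold * lens[i]) - 1L)
    else n_gap <- max(n_gap, floor(gap_threshold * lens[i]) + 1L)
    n_gap <- max(0L, min(n_gap, lens[i]))
    bases <- sample(c("A", "C", "G", "T"), lens[i], replace = TRUE)
    if (n_gap > 0) {
      # one contiguous N run at a random interior position, as a scaffold gap
      at <- sample.int(lens[i] - n_gap + 1L, 1L)
      bases[at:(at + n_gap - 1L)] <- "N"
    }
    seqs[i] <- paste(bases, collapse = "")
    realized[i] <- n_gap / lens[i]
  }
  ids <- sprintf("synthetic_unigene%05d", seq_len(n))
  names(seqs) <- ids
  list(sequences = seqs,
       truth = data.frame(seq_id = ids, length_bp = lens,
                          gap_ratio = realized,
                          gap_ok = realized < gap_threshold,
                          stringsAsFactors = FALSE))
}

#' Simulate a FASTQ read set with controlled quality and composition
#'
#' Per-base qualities are drawn so that `P(Q >= 20) = q20_target` (passing
#' bases uniform on Q 20-40, failing bases uniform on Q 2-19); base
#' composition has `P(G or C) = gc_target` and `P(N) = n_rate`
#' unconditionally, with A/T sharing the remaining mass.
#'
#' @param n_reads number of reads.
#' @param read_length bases per read (default 200, one 2012-era assembled
#'   read length).
#' @param q20_target probability a base meets Q20 (default 0.9385).
#' @param gc_target probability a base is G or C (default 0.4569).
#' @param n_rate probability a base is N (default 1e-4).
#' @param seed RNG seed.
#' @return list with `sequences` (named character) and `qualities` (list of
#'   integer vectors).
#' @export
simulate_fastq <- function(n_reads, read_length = 200,
                           q20_target = 0.9385, gc_target = 0.4569,
                           n_rate = 1e-4, seed = 1L) {
  stopifnot(n_reads >= 1, read_length >= 1,
            q20_target >= 0, q20_target <= 1,
            gc_target >= 0, n_rate >= 0, gc_target + n_rate <= 1)
  set.seed(derive_seed(seed, 3L))
  total <- n_reads * read_length
  p_at <- 1 - gc_target - n_rate
  bases <- sample(c("G", "C", "A", "T", "N"), total, replace = TRUE,
                  prob = c(gc_target / 2, gc_target / 2,
                           p_at / 2, p_at / 2, n_rate))
  ok <- stats::runif(total) < q20_target
  quals <- integer(total)
  quals[ok] <- sample(20:40, sum(ok), replace = TRUE)
  quals[!ok] <- sample(2:19, sum(!ok), replace = TRUE)

  base_mat <- matrix(bases, nrow = n_reads, byrow = TRUE)
  seqs <- apply(base_mat, 1, paste, collapse = "")
  names(seqs) <- sprintf("synthetic_read%06d", seq_len(n_reads))
  qual_list <- split(quals, rep(seq_len(n_reads), each = read_length))
  names(qual_list) <- names(seqs)
  list(sequences = seqs, qualities = qual_list)
}

# writers ---------------------------------------------------------------------

#' Write sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output path.
#' @param seed optional seed recorded in a comment line of the header of the
#'   first record's description.
#' @return `path`, invisibly.
#' @export
write_fasta_sequences <- function(sequences, path, seed = NULL) {
  x <- Biostrings::DNAStringSet(sequences)
  if (!is.null(seed)) {
    names(x)[1] <- paste0(names(x)[1], " seed=", seed)
  }
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads list with `sequences` and `qualities` as produced by
#'   [simulate_fastq()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq_reads <- function(reads, path) {
  qual_strings <- unname(vapply(reads$qualities, function(q) {
    rawToChar(as.raw(q + 33L))
  }, ""))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$sequences),
    Biostrings::PhredQuality(qual_strings))
  suppressWarnings(Biostrings::writeQualityScaledXStringSet(x, path))
  invisible(path)
}

#' Write a count table and its truth table as TSV
#'
#' The count TSV has the pipeline's input layout `gene_id  length  count_a
#' count_b` plus a comment header recording the seed and library sizes.
#'
#' @param sim output of [simulate_counts()].
#' @param scenario the scenario that produced it.
#' @param counts_path,truth_path output paths.
#' @return `counts_path`, invisibly.
#' @export
write_count_table <- function(sim, scenario, counts_path, truth_path = NULL) {
  con <- file(counts_path, "w")
  writeLines(sprintf("# seed=%d lib_size_a=%s lib_size_b=%s",
                     scenario$seed, format(scenario$lib_size_a),
                     format(scenario$lib_size_b)), con)
  df <- sim$counts
  names(df) <- c("gene_id", "length", "count_a", "count_b")
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  if (!is.null(truth_path)) {
    utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(counts_path)
}
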