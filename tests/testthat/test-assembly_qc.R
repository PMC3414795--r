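test_that("n50 matches brute-force accumulation", {
  expect_equal(n50(7), 7)
  expect_equal(n50(c(5, 4, 3, 2, 1)), 4) # total 15; 5, 9 >= 7.5 at length 4
  expect_equal(n50(c(2, 2, 2, 2)), 2)
  expect_error(n50(integer(0)), "empty")
  expect_error(n50(c(3, 0)), "positive")
})

test_that("n50 satisfies the half-of-bases property and invariances", {
  set.seed(5)
  for (rep in 1:10) {
    lens <- sample(100:5000, 200, replace = TRUE)
    v <- n50(lens)
    expect_true(v %in% lens)
    expect_gte(sum(lens[lens >= v]), sum(lens) / 2)
    # everything strictly longer than N50 covers less than half
    expect_lt(sum(lens[lens > v]), sum(lens) / 2 + sum(lens[lens == v]))
    expect_equal(n50(sample(lens)), v)
    expect_equal(n50(rep(lens, 3)), v)
  }
})

test_that("gap ratio counts N characters case-insensitively", {
  expect_equal(gap_ratio("ACGT"), 0)
  expect_equal(gap_ratio("ACGTNNNNNN"), 0.6)
  expect_equal(gap_ratio("NNNN"), 1)
  expect_equal(gap_ratio("acgtn"), 0.2)
  expect_error(gap_ratio(character(0)), "non-empty")
  expect_error(gap_ratio(c("ACGT", "")), "non-empty")
})

test_that("gap_ok_fraction uses a strict threshold", {
  expect_equal(gap_ok_fraction(c("ACGT", "ACGT", "ACGT")), 1)
  seqs <- c("NNAANNAANN", "ACGTACGTAA", "ACGTACGTAC", "ACGTACGTAG")
  expect_equal(gap_ok_fraction(seqs, threshold = 0.5), 0.75)
  # gap ratio exactly at the threshold does not count as ok
  expect_equal(gap_ok_fraction("NACGTACGTA", threshold = 0.1), 0)
})

test_that("fastq_stats computes Q20, N and GC percentages per definition", {
  expect_equal(fastq_stats("GGCC", list(rep(40L, 4))),
               c(q20_pct = 100, n_pct = 0, gc_pct = 100))
  # ACGN at Q 40,40,10,40: 3/4 bases meet Q20, 1/4 N, 2/4 G or C
  s <- fastq_stats("ACGN", list(c(40L, 40L, 10L, 40L)))
  expect_equal(s[["q20_pct"]], 75)
  expect_equal(s[["n_pct"]], 25)
  expect_equal(s[["gc_pct"]], 50)
  # q20_pct plus the below-threshold percentage is exactly 100
  set.seed(9)
  q <- lapply(1:20, function(i) sample(0:41, 50, replace = TRUE))
  seqs <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T", "N"), 50, TRUE), collapse = ""), "")
  st <- fastq_stats(seqs, q)
  below <- 100 * sum(unlist(q) < 20) / (20 * 50)
  expect_equal(st[["q20_pct"]] + below, 100)
  # strict mode counts only Q > threshold
  expect_equal(fastq_stats("AC", list(c(20L, 21L)),
                           strict_gt = TRUE)[["q20_pct"]], 50)
  expect_error(fastq_stats("ACG", list(c(40L, 40L))), "lengths differ")
})

test_that("GC content is strand-symmetric for N-free sequences", {
  set.seed(21)
  seqs <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = ""), "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
  q <- lapply(seqs, function(s) rep(30L, nchar(s)))
  expect_equal(fastq_stats(seqs, q)[["gc_pct"]], fastq_stats(rc, q)[["gc_pct"]])
})

test_that("length bins are half-open and proportions round half-up", {
  lb <- length_bins(c(100, 600), c(0, 500, 1000), cutoff = 500)
  expect_equal(lb$bins$count, c(1L, 1L))
  expect_equal(lb$prop_ge_cutoff_pct, 50)
  # published contig tally: 14,309 long contigs of 109,489
  lens <- c(rep(600, 14309), rep(150, 109489 - 14309))
  expect_equal(length_bins(lens, c(0, 500, Inf))$prop_ge_cutoff_pct, 13.07)
  expect_equal(length_bins(c(100, 200), c(0, 50, 75, 300))$bins$count[1], 0L)
  # boundary value falls in the upper bin
  expect_equal(length_bins(500, c(0, 500, 1000))$bins$count, c(0L, 1L))
  expect_error(length_bins(1:5, c(0, 500, 500)), "strictly increasing")
})

test_that("assembly_stats summarises a sequence set coherently", {
  seqs <- c(a = "ACGTACGTAC", b = strrep("ACGT", 50), c = strrep("AN", 30))
  st <- assembly_stats(seqs, bin_edges = c(0, 50, 500), gap_threshold = 0.2)
  expect_equal(st$n_sequences, 3)
  expect_equal(st$total_bases, 10 + 200 + 60)
  expect_equal(st$n50, 200)
  expect_equal(sum(st$bins$count), 3)
  expect_equal(st$gap_ok_fraction, 2 / 3)
})

test_that("FASTA and FASTQ round-trip through files", {
  fa <- simulate_fasta(20, seed = 4)
  tf <- tempfile(fileext = ".fasta")
  write_fasta_sequences(fa$sequences, tf)
  back <- read_fasta_sequences(tf)
  expect_equal(unname(back), unname(fa$sequences))
  expect_equal(gap_ratio(back), fa$truth$gap_ratio, tolerance = 1e-12)

  fq <- simulate_fastq(10, read_length = 30, seed = 4)
  tq <- tempfile(fileext = ".fastq")
  write_fastq_reads(fq, tq)
  r <- read_fastq_reads(tq)
  expect_equal(unname(r$sequences), unname(fq$sequences))
  expect_equal(unname(lapply(r$qualities, as.integer)),
               unname(lapply(fq$qualities, as.integer)))
})

test_that("decoding at the wrong Phred offset is reported, not silently wrong", {
  fq <- simulate_fastq(5, read_length = 12, seed = 2)
  tq <- tempfile(fileext = ".fastq")
  write_fastq_reads(fq, tq) # Phred+33
  expect_error(read_fastq_reads(tq, phred_offset = 64), "offset 64")
  expect_error(read_fastq_reads(tq, phred_offset = 59), "33 or 64")
})
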