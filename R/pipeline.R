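#' Read a two-library count table
#'
#' Parses the TSV layout `gene_id  length  count_a  count_b` (comment lines
#' starting with `#` ignored), with parse errors reported with their line
#' number.
#'
#' @param path TSV path.
#' @return data.frame `gene_id`, `length`, `count_a`, `count_b`.
#' @export
read_count_table <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#")
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0) stop("empty count table", call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("gene_id", "length", "count_a", "count_b")
  if (!all(need %in% header)) {
    stop(sprintf("line %d: header must contain %s", line_no[1],
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (length(lines) == 1) stop("count table has no data rows", call. = FALSE)
  df <- tryCatch(
    utils::read.table(text = lines[-1], sep = "\t", header = FALSE,
                      col.names = header, stringsAsFactors = FALSE),
    error = function(e) {
      stop(sprintf("malformed count table near line %d: %s", line_no[2],
                   conditionMessage(e)), call. = FALSE)
    })
  bad <- which(!is.finite(df$count_a) | !is.finite(df$count_b) |
                 df$count_a < 0 | df$count_b < 0)
  if (length(bad)) {
    stop(sprintf("line %d: counts must be non-negative numbers",
                 line_no[-1][bad[1]]), call. = FALSE)
  }
  df[need]
}

#' Run the full differential-expression pipeline
#'
#' Executes, in order: RPKM quantification of both libraries, the exact
#' two-library test, BH FDR adjustment, and DEG classification against the
#' `FDR <= fdr_cut` and `|log2 ratio| >= lfc_cut` thresholds.
#'
#' Library totals default to the count-table column sums ("uniquely aligned"
#' interpretation); pass `n1`/`n2` to use externally counted totals (e.g.
#' total clean reads) instead.
#'
#' Zero-RPKM handling: the log2 ratio floors each RPKM at the value a single
#' read would attain in the smaller library on that gene's length, so ratios
#' stay finite and reflect sequencing depth; override with `floor_rpkm`.
#'
#' @param counts data.frame as returned by [read_count_table()], or a path
#'   to such a TSV.
#' @param n1,n2 optional library totals; default column sums.
#' @param fdr_cut FDR threshold (default 0.001).
#' @param lfc_cut absolute log2 ratio threshold (default 1).
#' @param floor_rpkm optional fixed RPKM floor for [log2_ratio()].
#' @param out_dir optional directory; when given, writes
#'   `expression_table.tsv`, `deg_table.tsv` and `summary.tsv` there.
#' @return list with `table` (per-gene results: `gene_id`, `length`, `x`,
#'   `y`, `rpkm_a`, `rpkm_b`, `log2_ratio`, `p_value`, `q_value`, `status`)
#'   and `summary` (`n_genes`, `n_up`, `n_down`, `n_total`, `n1`, `n2`,
#'   `fdr_cut`, `lfc_cut`).
#' @export
run_deg_pipeline <- function(counts, n1 = NULL, n2 = NULL,
                             fdr_cut = 0.001, lfc_cut = 1.0,
                             floor_rpkm = NULL, out_dir = NULL) {
  if (is.character(counts)) counts <- read_count_table(counts)
  if (nrow(counts) == 0) stop("empty count table", call. = FALSE)
  if (fdr_cut <= 0 || lfc_cut <= 0) {
    stop("fdr_cut and lfc_cut must be positive", call. = FALSE)
  }
  if (is.null(n1)) n1 <- sum(counts$count_a)
  if (is.null(n2)) n2 <- sum(counts$count_b)

  rpkm_a <- rpkm(counts$count_a, n1, counts$length)
  rpkm_b <- rpkm(counts$count_b, n2, counts$length)
  floor <- if (is.null(floor_rpkm)) {
    rpkm(1, min(n1, n2), counts$length) # one read in the smaller library
  } else {
    rep_len(floor_rpkm, nrow(counts))
  }
  lfc <- log2_ratio(rpkm_b, rpkm_a, floor)

  ac <- run_ac_tests(
    data.frame(gene_id = counts$gene_id, x = counts$count_a,
               y = counts$count_b, stringsAsFactors = FALSE),
    n1, n2)
  status <- classify_deg(ac$q_value, lfc, fdr_cut, lfc_cut)

  table <- data.frame(
    gene_id = counts$gene_id, length = counts$length,
    x = counts$count_a, y = counts$count_b,
    rpkm_a = rpkm_a, rpkm_b = rpkm_b, log2_ratio = lfc,
    p_value = ac$p_value, q_value = ac$q_value, status = status,
    stringsAsFactors = FALSE
  )
  summary <- summary_report(sum(status == "up"), sum(status == "down"),
                            n_genes = nrow(table), n1 = n1, n2 = n2,
                            fdr_cut = fdr_cut, lfc_cut = lfc_cut)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(table, file.path(out_dir, "expression_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(table[table$status != "not_significant", ],
                       file.path(out_dir, "deg_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(field = names(unlist(summary)), value = unlist(summary)),
      file.path(out_dir, "summary.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(table = table, summary = summary)
}

#' Build a DEG summary report
#'
#' Book-keeping block for a differential-expression run; enforces the
#' consistency identity `n_total = n_up + n_down`.
#'
#' @param n_up,n_down DEG counts by direction.
#' @param n_genes genes tested.
#' @param n1,n2 library totals.
#' @param fdr_cut,lfc_cut thresholds used.
#' @return named list including `n_total = n_up + n_down` and
#'   `pct_de` (percentage of tested genes called DE, round-half-up, 2 dp).
#' @export
summary_report <- function(n_up, n_down, n_genes,
                           n1 = NA, n2 = NA,
                           fdr_cut = 0.001, lfc_cut = 1.0) {
  stopifnot(n_up >= 0, n_down >= 0, n_genes >= n_up + n_down)
  list(n_genes = n_genes, n_up = n_up, n_down = n_down,
       n_total = n_up + n_down,
       pct_de = round_half_up(100 * (n_up + n_down) / n_genes, 2),
       n1 = n1, n2 = n2, fdr_cut = fdr_cut, lfc_cut = lfc_cut)
}

#' Percentages from count pairs
#'
#' Annotation-rate style percentages `100 * numerator / denominator`,
#' rounded half-up to `digits` decimals (2 by default, 1 available for
#' one-decimal reporting styles).
#'
#' @param numerator,denominator non-negative integer vectors with
#'   `numerator <= denominator` and `denominator >= 1`.
#' @param digits decimal places (default 2).
#' @return numeric vector of percentages.
#' @examples
#' rate_summary(25812, 46581) # 55.41
#' @export
rate_summary <- function(numerator, denominator, digits = 2) {
  if (any(denominator < 1)) stop("denominator must be >= 1", call. = FALSE)
  if (any(numerator < 0) || any(numerator > denominator)) {
    stop("numerator must lie in [0, denominator]", call. = FALSE)
  }
  round_half_up(100 * numerator / denominator, digits)
}

#' Calibrate type-I error and power of the no-replicate test
#'
#' Repeatedly simulates a scenario, runs the full pipeline at the given
#' thresholds, and reports the empirical false-positive rate on truly-null
#' genes and the sensitivity per effect-size class, with Monte-Carlo
#' standard errors across replicates (SEs are `NA` when `n_reps = 1`).
#'
#' @param scenario a [synthetic_scenario()]; its seed is combined with
#'   `seed` and the replicate index.
#' @param n_reps number of replicate simulations (>= 1).
#' @param seed root seed for the replicate stream.
#' @param fdr_cut,lfc_cut DEG thresholds (defaults 0.001 and 1).
#' @return list with `type1` (data.frame `rate`, `se`, `n_null`) and
#'   `power` (data.frame per class: `class`, `sensitivity`, `se`, `n_genes`)
#'   and `n_reps`.
#' @export
calibrate <- function(scenario, n_reps, seed = 1L,
                      fdr_cut = 0.001, lfc_cut = 1.0) {
  stopifnot(inherits(scenario, "synthetic_scenario"), n_reps >= 1)
  classes <- unique(scenario$lfc_classes$class)
  null_rates <- numeric(n_reps)
  n_null_tot <- 0
  sens <- matrix(NA_real_, n_reps, length(classes),
                 dimnames = list(NULL, classes))
  n_class_tot <- stats::setNames(numeric(length(classes)), classes)

  for (r in seq_len(n_reps)) {
    s <- scenario
    s$seed <- derive_seed(seed, 100L + r) %% 1000000L + scenario$seed
    sim <- simulate_counts(s)
    counts <- data.frame(gene_id = sim$counts$gene_id,
                         length = sim$counts$length_bp,
                         count_a = sim$counts$x, count_b = sim$counts$y,
                         stringsAsFactors = FALSE)
    res <- run_deg_pipeline(counts, n1 = s$lib_size_a, n2 = s$lib_size_b,
                            fdr_cut = fdr_cut, lfc_cut = lfc_cut)
    called <- res$table$status != "not_significant"
    is_null <- sim$truth$true_status == "not_de"
    null_rates[r] <- if (any(is_null)) mean(called[is_null]) else NA_real_
    n_null_tot <- n_null_tot + sum(is_null)
    for (cl in classes) {
      in_cl <- sim$truth$class == cl
      if (any(in_cl)) {
        sens[r, cl] <- mean(called[in_cl])
        n_class_tot[cl] <- n_class_tot[cl] + sum(in_cl)
      }
    }
  }
  mc_se <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
  }
  list(
    type1 = data.frame(rate = mean(null_rates, na.rm = TRUE),
                       se = mc_se(null_rates), n_null = n_null_tot),
    power = data.frame(class = classes,
                       sensitivity = colMeans(sens, na.rm = TRUE),
                       se = apply(sens, 2, mc_se),
                       n_genes = as.numeric(n_class_tot),
                       row.names = NULL, stringsAsFactors = FALSE),
    n_reps = n_reps
  )
}
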