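#' RPKM expression value
#'
#' Reads Per Kilobase of transcript per Million mapped reads,
#' \eqn{\mathrm{RPKM} = 10^9 C / (N L)}, where `C` is the number of reads
#' uniquely aligned to the transcript, `N` the total number of uniquely
#' aligned reads in the library, and `L` the transcript length in bases.
#'
#' @param c read count for the transcript (non-negative, vectorised).
#' @param n total mapped reads in the library (positive).
#' @param l transcript length in bp (positive, vectorised).
#' @return RPKM values; exactly 0 where `c == 0`.
#' @examples
#' rpkm(10, 1e6, 1000) # 10
#' @export
rpkm <- function(c, n, l) {
  if (any(!is.finite(n)) || any(n < 1)) {
    stop("total mapped reads n must be >= 1", call. = FALSE)
  }
  if (any(!is.finite(l)) || any(l < 1)) {
    stop("transcript length l must be >= 1", call. = FALSE)
  }
  if (any(!is.finite(c)) || any(c < 0)) {
    stop("count c must be non-negative", call. = FALSE)
  }
  1e9 * c / (n * l)
}

#' Floored log2 expression ratio
#'
#' `log2(max(rpkm_b, floor) / max(rpkm_a, floor))`. The floor keeps ratios
#' finite when one condition has zero reads; a depth-aware choice is the RPKM
#' a single read would attain in the smaller library on this gene's length
#' (see [run_deg_pipeline()]).
#'
#' Because transcript length cancels within one gene, the RPKM ratio equals
#' the raw count ratio rescaled by the library-size ratio
#' \eqn{(C_b/C_a)(N_a/N_b)}; either formulation gives the same log2 ratio.
#'
#' @param rpkm_b,rpkm_a RPKM of the gene in condition B / A (vectorised).
#' @param floor positive pseudo-expression floor (vectorised).
#' @return log2 ratio (B over A).
#' @export
log2_ratio <- function(rpkm_b, rpkm_a, floor) {
  if (any(!is.finite(floor)) || any(floor <= 0)) {
    stop("floor must be positive", call. = FALSE)
  }
  log2(pmax(rpkm_b, floor) / pmax(rpkm_a, floor))
}

#' Classify a gene as up-, down-regulated or not significant
#'
#' A gene is a DEG when it passes both cuts: `q <= fdr_cut` and
#' `|log2_ratio| >= lfc_cut`; boundary equality passes. Direction follows
#' the sign of the log2 ratio.
#'
#' @param q FDR-adjusted q-value (vectorised).
#' @param log2_ratio log2 expression ratio, condition B over A (vectorised).
#' @param fdr_cut FDR threshold (default 0.001).
#' @param lfc_cut absolute log2 ratio threshold (default 1).
#' @return character vector in `c("up", "down", "not_significant")`.
#' @examples
#' classify_deg(0.0005, 2.47)  # "up"
#' classify_deg(0.001, -1.0)   # "down" (boundary inclusive)
#' @export
classify_deg <- function(q, log2_ratio, fdr_cut = 0.001, lfc_cut = 1.0) {
  if (any(!is.finite(q)) || any(q < 0) || any(q > 1)) {
    stop("q must lie in [0, 1]", call. = FALSE)
  }
  if (fdr_cut <= 0 || lfc_cut <= 0) {
    stop("fdr_cut and lfc_cut must be positive", call. = FALSE)
  }
  status <- rep("not_significant", max(length(q), length(log2_ratio)))
  sig <- q <= fdr_cut & abs(log2_ratio) >= lfc_cut
  status[sig & log2_ratio > 0] <- "up"
  status[sig & log2_ratio < 0] <- "down"
  status
}

#' Comparative-Ct (delta-delta-Ct) relative expression
#'
#' qRT-PCR relative quantification against an internal reference gene:
#' fold change \eqn{2^{-\Delta\Delta C_t}} with
#' \eqn{\Delta\Delta C_t = (C_t^{tgt,trt} - C_t^{ref,trt}) -
#' (C_t^{tgt,ctl} - C_t^{ref,ctl})}. Ct values are replicate-averaged
#' threshold cycles; values outside the typical 5-40 cycle range trigger a
#' warning.
#'
#' @param ct_target_treated,ct_target_control Ct of the target gene in
#'   treated / control samples.
#' @param ct_ref_treated,ct_ref_control Ct of the reference gene (e.g. 18S
#'   rDNA) in treated / control samples.
#' @return positive fold change of the target in treated relative to control.
#' @examples
#' relative_expression_ddct(20, 24, 15, 15) # 16
#' @export
relative_expression_ddct <- function(ct_target_treated, ct_target_control,
                                     ct_ref_treated, ct_ref_control) {
  cts <- c(ct_target_treated, ct_target_control,
           ct_ref_treated, ct_ref_control)
  if (any(!is.finite(cts))) stop("Ct values must be finite", call. = FALSE)
  if (any(cts < 5 | cts > 40)) {
    warning("Ct value outside the typical 5-40 cycle range")
  }
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' Taxol biosynthesis pathway RPKM pairs
#'
#' The twelve taxol (paclitaxel) biosynthesis unigenes profiled in
#' MeJA-elicited versus mock-treated Taxus chinensis cell cultures, with
#' their published RPKM values in the mock (T0) and 16 h MeJA (T16)
#' libraries. Used as the worked example for fold-change classification:
#' nine genes clear the |log2 ratio| >= 1 cut (strongly or slightly
#' up-regulated) and three (TBT, T13aH, T2aH) do not.
#'
#' @return data.frame with columns `gene_id`, `symbol`, `annotation`,
#'   `rpkm_t0`, `rpkm_t16`.
#' @export
taxol_pathway_rpkm <- function() {
  data.frame(
    gene_id = c("Unigene10976_All", "Unigene40124_All", "Unigene7834_All",
                "Unigene40964_All", "Unigene11678_All", "Unigene2856_All",
                "Unigene39159_All", "Unigene18076_All", "Unigene6346_All",
                "Unigene13946_All", "Unigene35728_All", "Unigene46528_All"),
    symbol = c("TS", "DBAT", "TAT", "TBT", "T10bH", "T13aH",
               "BAPT", "DBTNBT", "T2aH", "T5aH", "PAM", "T7bH"),
    annotation = c(
      "taxadiene synthase",
      "10-O-acetyltransferase",
      "5-O-acetyltransferase",
      "2-benzoyltransferase",
      "taxane 10-beta hydroxylase",
      "taxane 13-alpha hydroxylase",
      "phenylpropanoyltransferase",
      "3'-N-debenzoyltaxol N-benzoyltransferase",
      "taxane 2-alpha hydroxylase",
      "taxane 5-alpha hydroxylase",
      "phenylalanine aminomutase",
      "taxane 7-beta hydroxylase"),
    rpkm_t0 = c(1.1866, 2.5128, 216.7005, 1.1164, 1.2889, 7.4494,
                2.1889, 2.6067, 17.2825, 2.3604, 0.3506, 0.4963),
    rpkm_t16 = c(6.592, 6.2081, 1130.784, 1.931, 22.6354, 8.4546,
                 4.5731, 6.7517, 27.2296, 16.2127, 1.1578, 6.7533),
    stringsAsFactors = FALSE
  )
}
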