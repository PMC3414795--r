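# Exact-rational oracle for the two-library test, evaluated with Python's
# stdlib fractions module (inst/oracle/ac_exact.py). Independent of the
# package's log-space implementation.

oracle_script <- function() {
  p <- system.file("oracle", "ac_exact.py", package = "mejaseq")
  stopifnot(nzchar(p))
  p
}

oracle_call <- function(...) {
  out <- system2("python", c(oracle_script(), ...), stdout = TRUE)
  stopifnot(length(out) >= 1)
  out
}

oracle_prob <- function(y, x, n1, n2) {
  as.numeric(oracle_call("prob", y, x, format(n1, scientific = FALSE),
                         format(n2, scientific = FALSE)))
}

oracle_pval <- function(x, y, n1, n2) {
  as.numeric(oracle_call("pval", x, y, format(n1, scientific = FALSE),
                         format(n2, scientific = FALSE)))
}

# data.frame x, y, pval over the full grid 0..xmax by 0..ymax
oracle_pval_grid <- function(xmax, ymax, n1, n2) {
  out <- oracle_call("grid", xmax, ymax, format(n1, scientific = FALSE),
                     format(n2, scientific = FALSE))
  df <- utils::read.table(text = out, sep = "\t",
                          col.names = c("x", "y", "pval"))
  df
}

# builds a count data.frame in the pipeline's input layout from a simulation
sim_as_pipeline_input <- function(sim) {
  data.frame(gene_id = sim$counts$gene_id, length = sim$counts$length_bp,
             count_a = sim$counts$x, count_b = sim$counts$y,
             stringsAsFactors = FALSE)
}

rel_err <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.xmin)
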