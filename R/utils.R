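#' Round half up
#'
#' Rounds to `digits` decimal places with ties going away from zero for
#' positive values (the convention used when reporting percentages in
#' sequencing summary tables), unlike [round()], which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(0.125, 2) # 0.13
#' round(0.125, 2)         # 0.12 (banker's rounding)
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  # tiny guard so exact .5 ties represented fractionally below .5 still round up
  floor(x * scale + 0.5 + 1e-9) / scale
}

# shared validators -----------------------------------------------------------

assert_counts <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) ||
      any(x != floor(x))) {
    stop(sprintf("'%s' must contain non-negative integers", name),
         call. = FALSE)
  }
  invisible(x)
}

assert_lib_sizes <- function(n1, n2) {
  if (!is.numeric(n1) || !is.numeric(n2) || length(n1) != 1L ||
      length(n2) != 1L || !is.finite(n1) || !is.finite(n2) ||
      n1 < 1 || n2 < 1 || n1 != floor(n1) || n2 != floor(n2)) {
    stop("library sizes n1, n2 must be positive integers", call. = FALSE)
  }
  invisible(NULL)
}
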