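#' Round half away from zero
#'
#' Decimal rounding where ties go up (`0.5 -> 1`), matching how the pipeline's
#' human-readable reports round percentages and factors. `base::round()` uses
#' banker's rounding and is kept for internal arithmetic only.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, ties away from zero.
#' @examples
#' round_half_up(1.2142857, 2) # 1.21
#' round_half_up(89.285, 0)    # 89
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# C-locale string ordering (radix), platform independent
order_c <- function(...) order(..., method = "radix")

stop_input <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-character split to a matrix: rows = sequences (equal length)
seq_char_matrix <- function(x) {
  stopifnot(length(unique(nchar(x))) == 1L)
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), byrow = TRUE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
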