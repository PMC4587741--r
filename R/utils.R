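#' @importFrom stats rnorm rpois runif setNames
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total length of the union of numeric intervals
#'
#' Intervals are treated as half-open `[start, end)` so that intervals
#' sharing an endpoint merge without double-counting the shared boundary.
#' Positions may be fractional (map coordinates are floating bp).
#'
#' @param starts,ends numeric vectors of equal length with `starts <= ends`.
#' @return total length covered by the union (numeric scalar).
#' @keywords internal
interval_union_length <- function(starts, ends) {
  stopifnot(length(starts) == length(ends))
  if (length(starts) == 0L) return(0)
  if (any(ends < starts)) stop("interval with end < start")
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  total <- 0
  cur_s <- starts[1L]; cur_e <- ends[1L]
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= cur_e) {
      cur_e <- max(cur_e, ends[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- starts[i]; cur_e <- ends[i]
    }
  }
  total + (cur_e - cur_s)
}

#' Reverse complement of a nucleotide string
#' @param x single character string (A/C/G/T/N and IUPAC codes).
#' @return reverse-complemented character string.
#' @keywords internal
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Format a bp coordinate the way the native map formats print them: one
# decimal place, no scientific notation.
fmt_bp <- function(x) formatC(x, format = "f", digits = 1, big.mark = "")

stop_parse <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}
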