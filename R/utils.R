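# Small shared helpers. Gap characters follow SILVA conventions: both '-' and
# '.' count as gaps in any alignment handled by the package.

GAP_CHARS <- c("-", ".")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_snotrace <- function(fmt, ..., class = "snotrace_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character scalars, which is how sequences travel through the guide search.
#'
#' @param x single DNA string (A/C/G/T/N).
#' @return the reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Split a sequence string into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

is_gap <- function(ch) ch %in% GAP_CHARS

# Deterministic random DNA (uses the current RNG stream).
random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# All valid integers: positions are 0-based half-open internally.
check_interval <- function(start, end, what = "interval") {
  if (any(start >= end)) {
    stop_snotrace("%s must satisfy start < end (0-based half-open)", what)
  }
  invisible(TRUE)
}
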