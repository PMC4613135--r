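# Internal helpers shared across modules.

# The 20 standard amino acids, alphabetical one-letter codes.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA20_REGEX <- "^[ACDEFGHIKLMNPQRSTVWY]+$"

# codon -> amino acid lookup (standard genetic code; stop = "*")
codon_map <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

is_aa20 <- function(x) {
  nzchar(x) & grepl(AA20_REGEX, x)
}

assert_aa20 <- function(x, what = "sequence") {
  bad <- which(!is_aa20(x))
  if (length(bad) > 0) {
    stop(sprintf(
      "%s %d ('%s') contains characters outside the 20-letter amino-acid alphabet",
      what, bad[1], x[bad[1]]
    ), call. = FALSE)
  }
  invisible(x)
}

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Translate a vector of nucleotide strings (lengths must be multiples of 3).
# Returns amino-acid strings with "*" for stops. Non-ACGT codons give "X".
translate_nt <- function(x) {
  map <- codon_map()
  vapply(x, function(s) {
    n <- nchar(s)
    if (n == 0L) return("")
    if (n %% 3L != 0L) {
      stop("nucleotide length not a multiple of 3: ", n, call. = FALSE)
    }
    starts <- seq.int(1L, n, 3L)
    cods <- substring(s, starts, starts + 2L)
    aa <- unname(map[cods])
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Normalise to upper case and strip whitespace.
clean_seq <- function(x) toupper(gsub("[[:space:]]", "", x))

`%||%` <- function(a, b) if (is.null(a)) b else a

new_tbl <- function(...) tibble::tibble(...)

# Draw n samples from a named probability vector.
sample_named <- function(prob, n) {
  if (length(prob) == 1L) return(rep(names(prob), n))
  sample(names(prob), n, replace = TRUE, prob = prob)
}
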