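# Independent brute-force oracles, deliberately written without reusing any
# package internals.

# All 20 standard amino-acid letters.
AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Exhaustive Hamming assignment: compare against every equal-length germline,
# return the name with the fewest mismatches (lexicographic tie-break).
oracle_assign <- function(observed, germ_names, germ_seqs) {
  o <- strsplit(observed, "")[[1]]
  ord <- order(germ_names)
  germ_names <- germ_names[ord]
  germ_seqs <- germ_seqs[ord]
  best_name <- "unassigned"
  best_mm <- Inf
  for (i in seq_along(germ_seqs)) {
    g <- strsplit(germ_seqs[i], "")[[1]]
    if (length(g) != length(o)) next
    mm <- sum(g != o)
    if (mm < best_mm) {
      best_mm <- mm
      best_name <- germ_names[i]
    }
  }
  list(name = best_name, mm = if (is.infinite(best_mm)) NA_integer_ else best_mm)
}

# Sliding-window PTM motif detector: checks every window explicitly.
# Returns TRUE when the flanked sequence carries at least one reportable
# motif (hits entirely inside a flank ignored; Met exempt at H1 position 4
# and at the third-from-last position of H3).
oracle_has_ptm <- function(seq, region, left = "", right = "") {
  full <- paste0(left, seq, right)
  ch <- strsplit(full, "")[[1]]
  n <- length(ch)
  nL <- nchar(left)
  n_seq <- nchar(seq)
  overlaps_cdr <- function(start, span) {
    (start + span - 1) >= (nL + 1) && start <= (nL + n_seq)
  }
  exempt <- integer(0)
  if (region == "H1") exempt <- 4L
  if (region == "H3") exempt <- n_seq - 2L
  for (i in seq_len(n)) {
    if (i + 2 <= n && ch[i] == "N" && ch[i + 1] != "P" &&
        ch[i + 2] %in% c("S", "T") && overlaps_cdr(i, 3)) {
      return(TRUE)
    }
    if (i + 1 <= n && paste0(ch[i], ch[i + 1]) %in% c("DG", "NG", "DP") &&
        overlaps_cdr(i, 2)) {
      return(TRUE)
    }
    if (ch[i] == "C" && overlaps_cdr(i, 1)) return(TRUE)
    if (ch[i] == "M" && overlaps_cdr(i, 1) && !((i - nL) %in% exempt)) {
      return(TRUE)
    }
  }
  FALSE
}

random_aa <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(AA_LETTERS, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Small germline set used across tests.
toy_germlines <- function() {
  germline_set(data.frame(
    region = c("K1", "K1", "K2", "K2", "H1"),
    name = c("gA", "gB", "gC", "gD", "gH"),
    sequence = c("QSVSS", "QDISN", "AASSLQS", "DASNRAT", "SYAMS")
  ))
}
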