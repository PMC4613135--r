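#' Germline CDR sets
#'
#' A germline CDR set holds the named germline-encoded CDR amino-acid
#' sequences against which observed CDRs are compared and from which
#' germline-based repertoires are simulated. It is a tibble with columns
#' `region` (two-character CDR code), `name` (germline name, unique within a
#' region) and `sequence` (upper-case amino acids, 20-letter alphabet only).
#'
#' @param x a data frame with columns `region`, `name`, `sequence`.
#' @return a validated `germline_set` tibble.
#' @examples
#' gs <- germline_set(data.frame(
#'   region = c("H1", "K2"),
#'   name = c("VH3-a", "VK1-a"),
#'   sequence = c("SYAMS", "AASSLQS")
#' ))
#' gs
#' @export
germline_set <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("region", "name", "sequence")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("germline set needs columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(x[need])
  out$region <- assert_region(out$region)
  out$sequence <- clean_seq(out$sequence)
  assert_aa20(out$sequence, "germline sequence")
  dup <- out |>
    dplyr::count(.data$region, .data$name) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate germline name(s) within a region: ",
         paste(dup$region, dup$name, sep = "/", collapse = ", "), call. = FALSE)
  }
  class(out) <- c("germline_set", class(tibble::tibble()))
  out
}

germlines_for <- function(germlines, region) {
  region <- assert_region(region)
  sub <- germlines[germlines$region == region, , drop = FALSE]
  stats::setNames(sub$sequence, sub$name)
}

#' Read and write germline CDR sets
#'
#' TSV files must have a header with columns `region`, `name`, `sequence`.
#' FASTA files encode region and name in the header as `>REGION|NAME`.
#'
#' @param path file path.
#' @param format `"tsv"` or `"fasta"`; default guessed from the extension.
#' @return `read_germline_set()` returns a [germline_set()];
#'   `write_germline_set()` returns `path` invisibly.
#' @export
read_germline_set <- function(path, format = c("auto", "tsv", "fasta")) {
  format <- guess_format(path, match.arg(format))
  if (format == "tsv") {
    df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
    if (nrow(df) == 0) stop("empty germline set file: ", path, call. = FALSE)
    return(germline_set(df))
  }
  fa <- read_fasta(path)
  if (length(fa) == 0) stop("empty germline set file: ", path, call. = FALSE)
  parts <- strsplit(names(fa), "|", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad) > 0) {
    stop("malformed FASTA germline header at record ", bad[1],
         " (expected '>REGION|NAME'): ", names(fa)[bad[1]], call. = FALSE)
  }
  germline_set(tibble::tibble(
    region = vapply(parts, `[[`, "", 1),
    name = vapply(parts, function(p) paste(p[-1], collapse = "|"), ""),
    sequence = unname(fa)
  ))
}

#' @param x object to write.
#' @rdname read_germline_set
#' @export
write_germline_set <- function(x, path, format = c("auto", "tsv", "fasta")) {
  format <- guess_format(path, match.arg(format))
  x <- germline_set(x)
  if (format == "tsv") {
    readr::write_tsv(x, path)
  } else {
    write_fasta(stats::setNames(x$sequence, paste(x$region, x$name, sep = "|")), path)
  }
  invisible(path)
}

#' Natural CDR repertoires
#'
#' A repertoire is the list of observed CDR amino-acid sequences for one
#' region, with redundancy preserved. Stored as a tibble with columns
#' `region` and `sequence`.
#'
#' @param sequences character vector of amino-acid sequences.
#' @param region two-character CDR region code.
#' @return a `cdr_repertoire` tibble.
#' @examples
#' cdr_repertoire(c("SYAMS", "SYAMS", "NYGMS"), "H1")
#' @export
cdr_repertoire <- function(sequences, region) {
  region <- assert_region(region)
  stopifnot(length(region) == 1L)
  sequences <- clean_seq(sequences)
  if (length(sequences) == 0) stop("empty repertoire", call. = FALSE)
  if (any(grepl("*", sequences, fixed = TRUE))) {
    stop("repertoire contains stop symbols ('*')", call. = FALSE)
  }
  assert_aa20(sequences, "repertoire sequence")
  out <- tibble::tibble(region = region, sequence = sequences)
  class(out) <- c("cdr_repertoire", class(tibble::tibble()))
  out
}

#' Read and write CDR repertoires
#'
#' Accepts FASTA or plain one-sequence-per-line text; input order and
#' redundancy are preserved.
#'
#' @inheritParams cdr_repertoire
#' @param path file path.
#' @return `read_repertoire()` returns a [cdr_repertoire()];
#'   `write_repertoire()` returns `path` invisibly (FASTA if the extension
#'   says so, otherwise plain lines).
#' @export
read_repertoire <- function(path, region) {
  if (!file.exists(path)) stop("repertoire file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty repertoire file: ", path, call. = FALSE)
  if (startsWith(lines[1], ">")) {
    seqs <- unname(read_fasta(path))
  } else {
    seqs <- trimws(lines)
  }
  cdr_repertoire(seqs, region)
}

#' @param x a `cdr_repertoire` (or data frame with a `sequence` column).
#' @rdname read_repertoire
#' @export
write_repertoire <- function(x, path) {
  seqs <- x$sequence
  if (grepl("\\.(fa|fasta|faa)$", path, ignore.case = TRUE)) {
    write_fasta(stats::setNames(seqs, sprintf("seq%06d", seq_along(seqs))), path)
  } else {
    writeLines(seqs, path)
  }
  invisible(path)
}

#' Framework scaffolds
#'
#' A scaffold holds the four framework regions (FR1-FR4) of one variable
#' domain as matched nucleotide and protein sequences, plus the anchor window
#' length used by the read annotator (the terminal 5 residues of each FR by
#' default). Protein sequences are derived from the nucleotide sequences by
#' translation, and consistency is enforced.
#'
#' @param chain `"heavy"`, `"kappa"` or `"lambda"`.
#' @param fr_nucleotide character vector of four FR nucleotide sequences
#'   (FR1..FR4), each a multiple of 3 nt with no internal stop codon.
#' @param anchor_len terminal window length for anchor alignment (default 5).
#' @return a `framework_scaffold` object (list with `chain`, `fr_protein`,
#'   `fr_nucleotide`, `anchor_len`).
#' @export
framework_scaffold <- function(chain, fr_nucleotide, anchor_len = 5L) {
  chain <- match.arg(chain, c("heavy", "kappa", "lambda"))
  fr_nucleotide <- clean_seq(fr_nucleotide)
  if (length(fr_nucleotide) != 4L) {
    stop("a scaffold needs exactly four framework regions (FR1..FR4)", call. = FALSE)
  }
  nlen <- nchar(fr_nucleotide)
  if (any(nlen %% 3L != 0L)) {
    stop("FR", which(nlen %% 3L != 0L)[1], " nucleotide length (", nlen[nlen %% 3L != 0L][1],
         ") is not a multiple of 3", call. = FALSE)
  }
  fr_protein <- translate_nt(fr_nucleotide)
  if (any(grepl("*", fr_protein, fixed = TRUE))) {
    stop("FR", which(grepl("\\*", fr_protein))[1], " contains an internal stop codon",
         call. = FALSE)
  }
  assert_aa20(fr_protein, "framework translation")
  if (any(nchar(fr_protein) < anchor_len)) {
    stop("every FR must be at least anchor_len (", anchor_len, ") residues", call. = FALSE)
  }
  structure(
    list(
      chain = chain,
      fr_protein = stats::setNames(fr_protein, paste0("FR", 1:4)),
      fr_nucleotide = stats::setNames(fr_nucleotide, paste0("FR", 1:4)),
      anchor_len = as.integer(anchor_len)
    ),
    class = "framework_scaffold"
  )
}

#' @export
print.framework_scaffold <- function(x, ...) {
  cat("<framework_scaffold> chain:", x$chain,
      "| FR protein lengths:", paste(nchar(x$fr_protein), collapse = "/"),
      "| anchor_len:", x$anchor_len, "\n")
  invisible(x)
}

#' Read and write framework scaffolds
#'
#' The FASTA file holds nucleotide FR records with headers `>CHAIN_FRi`
#' (for example `>heavy_FR1`); one scaffold is built per chain present.
#'
#' @param path FASTA file path.
#' @param anchor_len anchor window length passed to [framework_scaffold()].
#' @return `read_frameworks()` returns a named list of scaffolds (by chain);
#'   `write_frameworks()` returns `path` invisibly.
#' @export
read_frameworks <- function(path, anchor_len = 5L) {
  fa <- read_fasta(path)
  if (length(fa) == 0) stop("empty framework file: ", path, call. = FALSE)
  m <- regmatches(names(fa), regexec("^(heavy|kappa|lambda)_FR([1-4])$", names(fa)))
  bad <- which(lengths(m) == 0 | vapply(m, length, 0L) < 3)
  if (length(bad) > 0) {
    stop("malformed framework header at record ", bad[1],
         " (expected '>CHAIN_FRi'): ", names(fa)[bad[1]], call. = FALSE)
  }
  chain <- vapply(m, `[[`, "", 2)
  fr <- as.integer(vapply(m, `[[`, "", 3))
  out <- lapply(split(seq_along(fa), chain), function(idx) {
    if (length(idx) != 4L || !setequal(fr[idx], 1:4)) {
      stop("chain '", chain[idx[1]], "' must have exactly FR1..FR4 records", call. = FALSE)
    }
    framework_scaffold(chain[idx[1]], unname(fa[idx][order(fr[idx])]), anchor_len)
  })
  out[intersect(c("heavy", "kappa", "lambda"), names(out))]
}

#' @param scaffolds a single scaffold or list of scaffolds.
#' @rdname read_frameworks
#' @export
write_frameworks <- function(scaffolds, path) {
  if (inherits(scaffolds, "framework_scaffold")) scaffolds <- list(scaffolds)
  recs <- unlist(unname(lapply(scaffolds, function(s) {
    stats::setNames(unname(s$fr_nucleotide), paste0(s$chain, "_FR", 1:4))
  })))
  write_fasta(recs, path)
  invisible(path)
}

#' Designed CDR repertoires
#'
#' The output of the designer for one region: the accepted simulated
#' sequences in draw order (redundancy allowed, the "total" count) plus the
#' number of distinct sequences (the "unique" count).
#'
#' @param sequences accepted amino-acid sequences, in order.
#' @param region two-character CDR region code.
#' @return a `designed_repertoire` tibble (columns `region`, `sequence`) with
#'   attributes `unique_count` and `total_count`.
#' @export
designed_repertoire <- function(sequences, region) {
  out <- cdr_repertoire(sequences, region)
  attr(out, "total_count") <- nrow(out)
  attr(out, "unique_count") <- length(unique(out$sequence))
  class(out) <- c("designed_repertoire", class(out))
  out
}

#' @exportS3Method generics::glance
glance.designed_repertoire <- function(x, ...) {
  tibble::tibble(
    region = x$region[1],
    total = attr(x, "total_count"),
    unique = attr(x, "unique_count")
  )
}

# --- plain-text FASTA / FASTQ helpers -------------------------------------

read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(clean_seq(as.character(x)), sub("\\s.*$", "", names(x)))
}

write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Read sequencing reads
#'
#' Accepts FASTA or FASTQ (qualities ignored). Returns a tibble with columns
#' `read_id` and `sequence` (upper-case nucleotides).
#'
#' @param path file path.
#' @return tibble of reads.
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("reads file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) stop("empty reads file: ", path, call. = FALSE)
  if (startsWith(first, "@")) {
    x <- Biostrings::readBStringSet(path, format = "fastq")
    seqs <- stats::setNames(clean_seq(as.character(x)), sub("\\s.*$", "", names(x)))
  } else {
    seqs <- read_fasta(path)
  }
  tibble::tibble(read_id = names(seqs), sequence = unname(seqs))
}

guess_format <- function(path, format) {
  if (format != "auto") return(format)
  if (grepl("\\.(fa|fasta|faa)$", path, ignore.case = TRUE)) "fasta" else "tsv"
}
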