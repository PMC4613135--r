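#' Preferred codon table for reverse translation
#'
#' One codon per residue, chosen among codons common in highly expressed
#' E. coli genes; used for deterministic, round-trip-safe reverse
#' translation of designed CDRs into synthesis oligos.
#'
#' @return named character vector mapping the 20 amino acids to codons.
#' @export
preferred_codons <- function() {
  c(A = "GCG", C = "TGC", D = "GAT", E = "GAA", F = "TTT",
    G = "GGC", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
    M = "ATG", N = "AAC", P = "CCG", Q = "CAG", R = "CGT",
    S = "AGC", T = "ACC", V = "GTG", W = "TGG", Y = "TAT")
}

#' Reverse-translate amino-acid sequences
#'
#' @param seqs amino-acid strings.
#' @param codon_table named codon vector covering every residue used.
#' @return nucleotide strings.
#' @export
reverse_translate <- function(seqs, codon_table = preferred_codons()) {
  vapply(seqs, function(s) {
    ch <- chars(s)
    cod <- codon_table[ch]
    if (anyNA(cod)) {
      stop("residue '", ch[which(is.na(cod))[1]], "' missing from codon table",
           call. = FALSE)
    }
    paste(cod, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Partition a designed repertoire into synthesis pools
#'
#' Array synthesis bounds the number of oligonucleotides per pool; the
#' repertoire is split, in order, into the minimum number of pools of at
#' most `capacity` sequences. Concatenating the pools in pool order
#' reconstitutes the repertoire exactly.
#'
#' @param rep a [designed_repertoire()] or any tibble with `region` and
#'   `sequence` columns (multiple regions may share a pool series).
#' @param capacity maximum sequences per pool (default 3,918).
#' @return the input tibble with a `pool_id` column prepended.
#' @examples
#' rep <- designed_repertoire(rep("ART", 5), "H1")
#' partition_pools(rep, capacity = 2)
#' @export
partition_pools <- function(rep, capacity = 3918L) {
  stopifnot(capacity > 0)
  n <- nrow(rep)
  if (n == 0) stop("empty repertoire", call. = FALSE)
  out <- tibble::as_tibble(rep)
  dplyr::bind_cols(
    tibble::tibble(pool_id = as.integer(ceiling(seq_len(n) / capacity))),
    out
  )
}

#' Emit framework-flanked synthesis oligos for pooled CDRs
#'
#' Each designed CDR is reverse-translated and flanked by the last
#' `flank_nt` nucleotides of its upstream framework region and the first
#' `flank_nt` of its downstream framework region, giving the oligo that
#' array synthesis produces and overlap-extension PCR consumes. The central
#' segment of every oligo translates back to its CDR.
#'
#' @param pools output of [partition_pools()] (columns `pool_id`, `region`,
#'   `sequence`), or a designed repertoire (a single implicit pool).
#' @param scaffolds a [framework_scaffold()] or named list of scaffolds by
#'   chain covering every region present.
#' @param flank_nt framework nucleotides on each side (default 18).
#' @param codon_table named codon vector for reverse translation.
#' @return tibble with columns `pool_id`, `region`, `cdr`, `oligo`.
#' @export
emit_oligo_pool <- function(pools, scaffolds, flank_nt = 18L,
                            codon_table = preferred_codons()) {
  if (inherits(scaffolds, "framework_scaffold")) {
    scaffolds <- stats::setNames(list(scaffolds), scaffolds$chain)
  }
  if (!"pool_id" %in% names(pools)) {
    pools <- partition_pools(pools, capacity = nrow(pools))
  }
  info <- cdr_region_info(pools$region)
  oligos <- character(nrow(pools))
  for (region in unique(pools$region)) {
    idx <- which(pools$region == region)
    chain <- info$chain[idx[1]]
    loop <- info$loop[idx[1]]
    sc <- scaffolds[[chain]]
    if (is.null(sc)) stop("no scaffold for chain '", chain, "'", call. = FALSE)
    up <- sc$fr_nucleotide[[loop]]
    down <- sc$fr_nucleotide[[loop + 1L]]
    if (flank_nt > nchar(up) || flank_nt > nchar(down)) {
      stop("flank_nt (", flank_nt, ") exceeds framework length around ", region,
           call. = FALSE)
    }
    left <- substr(up, nchar(up) - flank_nt + 1L, nchar(up))
    right <- substr(down, 1L, flank_nt)
    oligos[idx] <- paste0(left, reverse_translate(pools$sequence[idx], codon_table), right)
  }
  tibble::tibble(
    pool_id = pools$pool_id,
    region = pools$region,
    cdr = pools$sequence,
    oligo = oligos
  )
}

#' Assemble an scFv amino-acid sequence from CDRs and scaffolds
#'
#' Interleaves framework regions and CDRs as
#' `FR1-CDR1-FR2-CDR2-FR3-CDR3-FR4` for the heavy domain, appends the
#' linker, then the same for the light domain.
#'
#' @param heavy_cdrs,light_cdrs character vectors of three CDR amino-acid
#'   sequences each (CDR1, CDR2, CDR3); none may be empty.
#' @param heavy_scaffold,light_scaffold [framework_scaffold()] objects.
#' @param linker inter-domain peptide linker (default `(G4S)3`).
#' @return the scFv amino-acid string.
#' @export
assemble_scfv <- function(heavy_cdrs, light_cdrs, heavy_scaffold, light_scaffold,
                          linker = "GGGGSGGGGSGGGGS") {
  stopifnot(length(heavy_cdrs) == 3L, length(light_cdrs) == 3L)
  if (any(!nzchar(c(heavy_cdrs, light_cdrs)))) {
    stop("empty CDR in scFv assembly", call. = FALSE)
  }
  paste0(
    domain_protein(heavy_cdrs, heavy_scaffold), linker,
    domain_protein(light_cdrs, light_scaffold)
  )
}

domain_protein <- function(cdrs, scaffold) {
  fr <- scaffold$fr_protein
  paste0(fr[[1]], cdrs[1], fr[[2]], cdrs[2], fr[[3]], cdrs[3], fr[[4]])
}

# Nucleotide segments of one variable domain: named vector
# FR1, CDR1, FR2, CDR2, FR3, CDR3, FR4.
domain_segments_nt <- function(cdrs, scaffold, codon_table = preferred_codons()) {
  fr <- scaffold$fr_nucleotide
  cdr_nt <- reverse_translate(cdrs, codon_table)
  stats::setNames(
    c(fr[[1]], cdr_nt[1], fr[[2]], cdr_nt[2], fr[[3]], cdr_nt[3], fr[[4]]),
    c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")
  )
}

#' Extract CDRs back out of an assembled domain or scFv
#'
#' Splits on exact framework matches; a convenience inverse of
#' [assemble_scfv()] for error-free sequences (the NGS annotator handles
#' imperfect reads).
#'
#' @param protein domain amino-acid string.
#' @param scaffold the domain's [framework_scaffold()].
#' @return character vector of the three CDRs.
#' @export
extract_cdrs <- function(protein, scaffold) {
  fr <- scaffold$fr_protein
  pos1 <- regexpr(fr[[1]], protein, fixed = TRUE)
  if (pos1 < 0) stop("FR1 not found in sequence", call. = FALSE)
  rest <- substr(protein, pos1 + nchar(fr[[1]]), nchar(protein))
  cdrs <- character(3)
  for (i in 2:4) {
    p <- regexpr(fr[[i]], rest, fixed = TRUE)
    if (p < 0) stop("FR", i, " not found in sequence", call. = FALSE)
    cdrs[i - 1L] <- substr(rest, 1L, p - 1L)
    rest <- substr(rest, p + nchar(fr[[i]]), nchar(rest))
  }
  cdrs
}
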