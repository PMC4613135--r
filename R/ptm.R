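#' Post-translational-modification liability policy
#'
#' The motifs removed from designed CDRs: N-glycosylation sequons
#' `N-X-S/T` with `X != P` (`glyc`), deamidation `NG`, isomerization `DG`,
#' non-enzymatic backbone cleavage `DP`, and the oxidation-prone residues
#' Cys and Met. Methionine is exempt at two positions where it is common or
#' predominant in natural antibodies: the fourth residue of the 5-residue
#' CDR-H1 (Kabat H34) and the first residue of the terminal 3-mer of CDR-H3
#' (Kabat H100, i.e. third from the end). `junction_flank` framework
#' residues are appended on each side of a CDR before scanning so that
#' motifs straddling the CDR-framework junction are also caught.
#'
#' @param glyc scan for N-glycosylation sequons (default `TRUE`).
#' @param dipeptide_motifs dipeptides to ban (default `DG`, `NG`, `DP`).
#' @param banned_residues single residues to ban (default `C`, `M`).
#' @param exemptions tibble with columns `region`, `residue`, `position`
#'   (positive = from the CDR start, negative = from its end) at which the
#'   residue is tolerated. Defaults to Met at H1 position 4 and H3 position -3.
#' @param junction_flank framework residues scanned on each side (default 2).
#' @return a `ptm_policy` object.
#' @examples
#' ptm_policy()
#' @export
ptm_policy <- function(glyc = TRUE,
                       dipeptide_motifs = c("DG", "NG", "DP"),
                       banned_residues = c("C", "M"),
                       exemptions = NULL,
                       junction_flank = 2L) {
  if (is.null(exemptions)) {
    exemptions <- tibble::tibble(
      region = c("H1", "H3"),
      residue = c("M", "M"),
      position = c(4L, -3L)
    )
  }
  stopifnot(junction_flank >= 0)
  structure(
    list(
      glyc = isTRUE(glyc),
      dipeptide_motifs = dipeptide_motifs,
      banned_residues = banned_residues,
      exemptions = exemptions,
      junction_flank = as.integer(junction_flank)
    ),
    class = "ptm_policy"
  )
}

#' @export
print.ptm_policy <- function(x, ...) {
  cat("<ptm_policy> glyc:", x$glyc,
      "| dipeptides:", paste(x$dipeptide_motifs, collapse = ","),
      "| residues:", paste(x$banned_residues, collapse = ","),
      "| junction_flank:", x$junction_flank, "\n")
  invisible(x)
}

exempt_positions <- function(policy, region, seq_len, residue = "M") {
  ex <- policy$exemptions
  ex <- ex[ex$region == region & ex$residue == residue, , drop = FALSE]
  if (nrow(ex) == 0) return(integer(0))
  pos <- ifelse(ex$position > 0, ex$position, seq_len + 1L + ex$position)
  pos[pos >= 1L & pos <= seq_len]
}

motif_kinds <- function(policy) {
  kinds <- character(0)
  if (policy$glyc) kinds <- "glyc"
  res_kind <- c(C = "Cys", M = "Met")
  c(kinds, policy$dipeptide_motifs,
    unname(res_kind[policy$banned_residues]))
}

# Positions (1-based) of each motif kind in a single string. Returns a list
# kind -> integer starts; spans: glyc 3, dipeptides 2, residues 1.
motif_starts <- function(x, policy) {
  out <- list()
  if (policy$glyc) {
    out$glyc <- regexpr_starts(x, "N(?=[^P][ST])")
  }
  for (d in policy$dipeptide_motifs) {
    out[[d]] <- regexpr_starts(x, paste0(substr(d, 1, 1), "(?=", substr(d, 2, 2), ")"))
  }
  for (r in policy$banned_residues) {
    kind <- c(C = "Cys", M = "Met")[[r]]
    out[[kind]] <- regexpr_starts(x, r, fixed = TRUE)
  }
  out
}

regexpr_starts <- function(x, pattern, fixed = FALSE) {
  m <- gregexpr(pattern, x, perl = !fixed, fixed = fixed)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

motif_span <- function(kind) {
  if (kind == "glyc") 3L else if (kind %in% c("Cys", "Met")) 1L else 2L
}

#' Scan a CDR for PTM liability motifs
#'
#' The CDR is scanned together with `junction_flank` framework residues on
#' each side (supplied as `left_flank` / `right_flank`), so motifs that
#' straddle a CDR-framework junction are reported. Hits lying entirely
#' inside a flank are not reported; Met hits at the policy's exempt CDR
#' positions are suppressed.
#'
#' @param seq CDR amino-acid string.
#' @param region two-character CDR region code (for exemptions).
#' @param policy a [ptm_policy()].
#' @param left_flank,right_flank framework residues adjoining the CDR
#'   (each of length `policy$junction_flank`, or `""` to scan the bare CDR).
#' @return tibble with columns `motif_kind` (`glyc`, `DG`, `NG`, `DP`,
#'   `Cys`, `Met`), `start` (1-based in the flanked string), `span`, and
#'   `seq_start` (1-based in the CDR itself; can be <= 0 for junction hits).
#' @examples
#' scan_ptm("WISPDGG", "H2", ptm_policy())
#' scan_ptm("SYAMS", "H1", ptm_policy())   # H34 Met exemption: no hits
#' @export
scan_ptm <- function(seq, region, policy = ptm_policy(),
                     left_flank = "", right_flank = "") {
  region <- assert_region(region)
  seq <- clean_seq(seq)
  scanned <- paste0(left_flank, seq, right_flank)
  nL <- nchar(left_flank)
  n_seq <- nchar(seq)
  starts <- motif_starts(scanned, policy)
  ex_met <- exempt_positions(policy, region, n_seq, "M")
  rows <- purrr::imap(starts, function(pos, kind) {
    if (length(pos) == 0) return(NULL)
    span <- motif_span(kind)
    # keep hits overlapping the CDR (not fully inside a flank)
    keep <- (pos + span - 1L) >= (nL + 1L) & pos <= (nL + n_seq)
    pos <- pos[keep]
    if (kind == "Met" && length(ex_met) > 0) {
      pos <- pos[!(pos - nL) %in% ex_met]
    }
    if (length(pos) == 0) return(NULL)
    tibble::tibble(motif_kind = kind, start = pos, span = span,
                   seq_start = pos - nL)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(motif_kind = character(), start = integer(),
                          span = integer(), seq_start = integer())
  }
  dplyr::arrange(out, .data$start, .data$motif_kind)
}

# Vectorised: which motif kinds hit each sequence? Returns a logical matrix
# (sequences x kinds). Used by the designer's rejection filter and by
# ptm_statistics().
ptm_hit_matrix <- function(seqs, region, policy = ptm_policy(),
                           left_flank = "", right_flank = "") {
  scanned <- paste0(left_flank, seqs, right_flank)
  nL <- nchar(left_flank)[1]
  n_seq <- nchar(seqs)
  kinds <- motif_kinds(policy)
  out <- matrix(FALSE, nrow = length(seqs), ncol = length(kinds),
                dimnames = list(NULL, kinds))
  pats <- list(
    glyc = "N(?=[^P][ST])", DG = "D(?=G)", NG = "N(?=G)", DP = "D(?=P)",
    Cys = "C", Met = "M"
  )
  for (kind in kinds) {
    pat <- pats[[kind]]
    span <- motif_span(kind)
    fixed <- kind %in% c("Cys", "Met")
    m <- gregexpr(pat, scanned, perl = !fixed, fixed = fixed)
    hit <- vapply(seq_along(seqs), function(i) {
      pos <- m[[i]]
      if (pos[1] == -1L) return(FALSE)
      pos <- as.integer(pos)
      keep <- (pos + span - 1L) >= (nL + 1L) & pos <= (nL + n_seq[i])
      pos <- pos[keep]
      if (kind == "Met") {
        ex <- exempt_positions(policy, region, n_seq[i], "M")
        if (length(ex) > 0) pos <- pos[!(pos - nL) %in% ex]
      }
      length(pos) > 0
    }, logical(1))
    out[, kind] <- hit
  }
  out
}

ptm_clean <- function(seqs, region, policy = ptm_policy(),
                      left_flank = "", right_flank = "") {
  !apply(ptm_hit_matrix(seqs, region, policy, left_flank, right_flank), 1, any)
}

sanitize_seqs <- function(seqs) {
  while (any(grepl("[DN]G", seqs))) {
    seqs <- gsub("[DN]G", "SG", seqs)
  }
  seqs
}

#' Remove deamidation/isomerization motifs from germline CDRs
#'
#' Germline CDRs (notably heavy-chain CDR2) often contain `DG` and `NG`
#' dipeptides. Before simulation these are substituted with `SG`,
#' left-to-right and repeatedly until none remain; other motif kinds are
#' left untouched at this stage (the rejection filter handles them during
#' simulation).
#'
#' @param germlines a [germline_set()].
#' @param policy a [ptm_policy()] (present for interface symmetry; the
#'   substitution always targets `DG`/`NG`).
#' @return a sanitised [germline_set()].
#' @examples
#' gs <- germline_set(data.frame(region = "H2", name = "g1", sequence = "INSDGSST"))
#' sanitize_germline(gs)$sequence  # "INSSGSST"
#' @export
sanitize_germline <- function(germlines, policy = ptm_policy()) {
  germlines$sequence <- sanitize_seqs(germlines$sequence)
  germline_set(germlines)
}
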