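#' Annotate merged NGS reads by framework-anchor alignment
#'
#' Each read is translated in all three reading frames and the terminal
#' 5-residue windows of the reference framework regions (the "anchors":
#' end of FR1, start and end of FR2 and FR3, start of FR4) are searched in
#' left-to-right order, allowing up to `max_anchor_mismatch` amino-acid
#' mismatches per window so that reads with synthesis or PCR point errors
#' are still annotated. Because indels shift the reading frame mid-read,
#' each anchor may be found in a different frame. The sequence between the
#' end-anchor of FR \emph{k} and the start-anchor of FR \emph{k+1} is the
#' CDR: it is \emph{in frame} when its nucleotide span is a multiple of 3
#' and contains no stop codon, has the \emph{designed length} when its
#' translation's length occurs in the designed repertoire, and is a
#' \emph{designed sequence} when the translation is itself a designed
#' sequence. Reads in which fewer than two anchors are found for every
#' scaffold get `chain = "unknown"` and all flags `FALSE`.
#'
#' @param reads tibble with `read_id` and `sequence` columns (see
#'   [read_reads()]), or a character vector of nucleotide strings.
#' @param scaffolds a [framework_scaffold()] or list of scaffolds; each read
#'   is assigned to the scaffold matching the most anchors.
#' @param designs optional named list (by region code) of designed
#'   repertoires or character vectors; enables the designed-length /
#'   designed-sequence flags and coverage statistics.
#' @param max_anchor_mismatch mismatches tolerated per 5-residue anchor
#'   window (default 1).
#' @return a `read_annotations` tibble, one row per read x CDR loop, with
#'   columns `read_id`, `chain`, `frame` (0/1/2 of the first anchor, `NA`
#'   when unannotatable), `n_anchors`, `region`, `cdr_seq` (`NA` unless in
#'   frame), `cdr_nt_len`, `in_frame`, `designed_length`,
#'   `designed_sequence`, `has_stop`, `fr_mutations`, `fr_residues` (the
#'   last three are read-level and repeated across the read's rows).
#' @export
annotate_reads <- function(reads, scaffolds, designs = NULL,
                           max_anchor_mismatch = 1L) {
  if (is.character(reads)) {
    reads <- tibble::tibble(
      read_id = if (is.null(names(reads))) sprintf("read%06d", seq_along(reads)) else names(reads),
      sequence = unname(reads)
    )
  }
  if (inherits(scaffolds, "framework_scaffold")) scaffolds <- list(scaffolds)
  names(scaffolds) <- vapply(scaffolds, `[[`, "", "chain")

  design_sets <- prepare_design_sets(designs)
  sc_pre <- lapply(scaffolds, precompute_scaffold)

  n <- nrow(reads)
  aa_frames <- translate_frames(reads$sequence)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    aa_int <- lapply(1:3, function(f) utf8ToInt(aa_frames[[f]][i]))
    best <- NULL
    for (sc_name in names(sc_pre)) {
      res <- anchor_search(aa_int, sc_pre[[sc_name]], max_anchor_mismatch)
      if (is.null(best) || res$n_found > best$n_found ||
          (res$n_found == best$n_found && res$total_mm < best$total_mm)) {
        res$chain <- sc_name
        best <- res
      }
      if (best$n_found == 6L && best$total_mm == 0L) break
    }
    rows[[i]] <- annotate_one(reads$read_id[i], reads$sequence[i], aa_frames, i,
                              best, sc_pre[[best$chain]], design_sets)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("read_annotations", class(tibble::tibble()))
  out
}

prepare_design_sets <- function(designs) {
  if (is.null(designs)) return(NULL)
  lapply(designs, function(d) {
    seqs <- if (is.data.frame(d)) d$sequence else as.character(d)
    list(seqs = unique(seqs), lens = unique(nchar(seqs)))
  })
}

translate_frames <- function(seqs) {
  lapply(0:2, function(f) {
    n <- nchar(seqs)
    keep_len <- pmax(3L * ((n - f) %/% 3L), 0L)
    sub <- substr(seqs, f + 1L, f + keep_len)
    aa <- character(length(seqs))
    nz <- which(nchar(sub) > 0)
    if (length(nz) > 0) {
      aa[nz] <- as.character(Biostrings::translate(
        Biostrings::DNAStringSet(sub[nz]), if.fuzzy.codon = "X"
      ))
    }
    aa
  })
}

precompute_scaffold <- function(scaffold) {
  al <- scaffold$anchor_len
  fr <- scaffold$fr_protein
  anchor_str <- c(
    substr(fr[[1]], nchar(fr[[1]]) - al + 1L, nchar(fr[[1]])),
    substr(fr[[2]], 1L, al), substr(fr[[2]], nchar(fr[[2]]) - al + 1L, nchar(fr[[2]])),
    substr(fr[[3]], 1L, al), substr(fr[[3]], nchar(fr[[3]]) - al + 1L, nchar(fr[[3]])),
    substr(fr[[4]], 1L, al)
  )
  list(
    scaffold = scaffold,
    anchor_len = al,
    anchors = lapply(anchor_str, utf8ToInt),
    anchor_str = anchor_str,
    fr2_len = nchar(fr[[2]]),
    fr3_len = nchar(fr[[3]]),
    chain = scaffold$chain
  )
}

# positions (aa, 1-based) where anchor matches subject with <= mm mismatches,
# together with the mismatch count at each position
match_positions <- function(subject_int, anchor_int, mm) {
  L <- length(subject_int)
  al <- length(anchor_int)
  npos <- L - al + 1L
  if (npos < 1L) return(list(pos = integer(0), mm = integer(0)))
  m <- integer(npos)
  for (k in seq_len(al)) {
    m <- m + (subject_int[k:(k + npos - 1L)] != anchor_int[k])
  }
  keep <- which(m <= mm)
  list(pos = keep, mm = m[keep])
}

# Greedy in-order anchor placement across the three frame translations.
# Returns nt start (1-based), frame (0-2), aa position and mismatch count
# per anchor; total_mm breaks ties between near-identical scaffolds
# (kappa and lambda frameworks differ at few residues).
anchor_search <- function(aa_int, pre, mm) {
  n_anchor <- 6L
  al <- pre$anchor_len
  cand <- vector("list", n_anchor)
  for (a in seq_len(n_anchor)) {
    per_frame <- lapply(1:3, function(f) match_positions(aa_int[[f]], pre$anchors[[a]], mm))
    cand[[a]] <- per_frame
  }
  nt_start <- rep(NA_integer_, n_anchor)
  frame <- rep(NA_integer_, n_anchor)
  aa_pos <- rep(NA_integer_, n_anchor)
  anchor_mm <- rep(NA_integer_, n_anchor)
  cur <- 0L
  for (a in seq_len(n_anchor)) {
    # prefer the leftmost exact match; fall back to the leftmost match
    # within the mismatch tolerance (a mutated true anchor)
    best_nt <- NA_integer_
    for (pass_mm in c(0L, mm)) {
      for (f in 1:3) {
        pos <- cand[[a]][[f]]$pos
        pmm <- cand[[a]][[f]]$mm
        keep <- pmm <= pass_mm
        pos <- pos[keep]
        pmm <- pmm[keep]
        if (length(pos) == 0) next
        nt <- (f - 1L) + 3L * (pos - 1L) + 1L
        ok <- nt > cur
        if (any(ok)) {
          sel <- which(ok)[which.min(nt[ok])]
          if (is.na(best_nt) || nt[sel] < best_nt) {
            best_nt <- nt[sel]
            frame[a] <- f - 1L
            aa_pos[a] <- pos[sel]
            anchor_mm[a] <- pmm[sel]
          }
        }
      }
      if (!is.na(best_nt)) break
    }
    if (!is.na(best_nt)) {
      nt_start[a] <- best_nt
      cur <- best_nt + 3L * al - 1L
    }
  }
  list(
    nt_start = nt_start, frame = frame, aa_pos = aa_pos, anchor_mm = anchor_mm,
    n_found = sum(!is.na(nt_start)),
    total_mm = sum(anchor_mm, na.rm = TRUE)
  )
}

annotate_one <- function(read_id, seq_nt, aa_frames, i, best, pre, design_sets) {
  sc <- pre$scaffold
  al <- pre$anchor_len
  regions <- chain_regions(sc$chain)
  base <- tibble::tibble(
    read_id = read_id,
    chain = if (best$n_found >= 2L) sc$chain else "unknown",
    frame = NA_integer_,
    n_anchors = best$n_found,
    region = regions,
    cdr_seq = NA_character_,
    cdr_nt_len = NA_integer_,
    in_frame = FALSE,
    designed_length = FALSE,
    designed_sequence = FALSE,
    has_stop = FALSE,
    fr_mutations = NA_integer_,
    fr_residues = NA_integer_
  )
  if (best$n_found < 2L) return(base)

  found_frames <- best$frame[!is.na(best$frame)]
  base$frame <- as.integer(names(sort(table(found_frames), decreasing = TRUE))[1])

  has_stop <- FALSE
  fr_mut <- 0L
  fr_res <- 0L

  # framework comparison: FR1 end / FR4 start anchor windows, full FR2 / FR3
  cmp_window <- function(a) {
    if (is.na(best$aa_pos[a])) return(NULL)
    f <- best$frame[a] + 1L
    w <- substr(aa_frames[[f]][i], best$aa_pos[a], best$aa_pos[a] + al - 1L)
    list(obs = w, ref = pre$anchor_str[a])
  }
  count_mm <- function(obs, ref) sum(chars(obs) != chars(ref))

  fr_full <- list(c(2L, 3L, pre$fr2_len, 2L), c(4L, 5L, pre$fr3_len, 3L))
  full_done <- c(FR2 = FALSE, FR3 = FALSE)
  for (spec in fr_full) {
    a1 <- spec[1]; a2 <- spec[2]; frlen <- spec[3]; fridx <- spec[4]
    if (!is.na(best$aa_pos[a1]) && !is.na(best$aa_pos[a2]) &&
        identical(best$frame[a1], best$frame[a2]) &&
        (best$aa_pos[a2] + al - best$aa_pos[a1]) == frlen) {
      f <- best$frame[a1] + 1L
      obs <- substr(aa_frames[[f]][i], best$aa_pos[a1], best$aa_pos[a2] + al - 1L)
      ref <- sc$fr_protein[[fridx]]
      fr_mut <- fr_mut + count_mm(obs, ref)
      fr_res <- fr_res + frlen
      if (grepl("*", obs, fixed = TRUE)) has_stop <- TRUE
      full_done[fridx - 1L] <- TRUE
    }
  }
  for (a in c(1L, 6L)) {
    w <- cmp_window(a)
    if (!is.null(w)) {
      fr_mut <- fr_mut + count_mm(w$obs, w$ref)
      fr_res <- fr_res + al
      if (grepl("*", w$obs, fixed = TRUE)) has_stop <- TRUE
    }
  }
  # anchors of FR2/FR3 counted individually when the full FR was not comparable
  for (spec in fr_full) {
    fridx <- spec[4]
    if (!full_done[fridx - 1L]) {
      for (a in spec[1:2]) {
        w <- cmp_window(a)
        if (!is.null(w)) {
          fr_mut <- fr_mut + count_mm(w$obs, w$ref)
          fr_res <- fr_res + al
          if (grepl("*", w$obs, fixed = TRUE)) has_stop <- TRUE
        }
      }
    }
  }

  for (k in 1:3) {
    a_prev <- 2L * k - 1L
    a_next <- 2L * k
    if (is.na(best$nt_start[a_prev]) || is.na(best$nt_start[a_next])) next
    cdr_start <- best$nt_start[a_prev] + 3L * al
    cdr_end <- best$nt_start[a_next] - 1L
    len <- cdr_end - cdr_start + 1L
    if (len < 0L) next
    base$cdr_nt_len[k] <- len
    if (len > 0L && len %% 3L == 0L) {
      aa <- translate_nt(substr(seq_nt, cdr_start, cdr_end))
      if (grepl("*", aa, fixed = TRUE) || grepl("X", aa, fixed = TRUE)) {
        has_stop <- has_stop || grepl("*", aa, fixed = TRUE)
      } else {
        base$in_frame[k] <- TRUE
        base$cdr_seq[k] <- aa
        ds <- design_sets[[regions[k]]]
        if (!is.null(ds)) {
          base$designed_length[k] <- nchar(aa) %in% ds$lens
          base$designed_sequence[k] <- aa %in% ds$seqs
        } else if (is.null(design_sets)) {
          base$designed_length[k] <- NA
          base$designed_sequence[k] <- NA
        }
      }
    }
  }
  base$has_stop <- has_stop
  base$fr_mutations <- fr_mut
  base$fr_residues <- fr_res
  base
}

#' Summarise library QC from read annotations
#'
#' Computes, per region over the reads in which that region was resolvable
#' (both flanking anchors found): the processed count and the in-frame,
#' designed-length and designed-sequence percentages; design coverage (the
#' percentage of designed unique sequences observed at least once) when
#' `designs` is given; and per chain: the functional-domain percentage
#' (all three CDRs in frame, no stop codon) plus the redundancy spectrum of
#' functional domain sequences.
#'
#' @param annotations a `read_annotations` tibble from [annotate_reads()].
#' @param designs optional named list of designed repertoires (as in
#'   [annotate_reads()]) for coverage.
#' @return a `qc_report`: list with tibbles `region_stats`, `chain_stats`,
#'   `redundancy`, and `n_reads`.
#' @export
summarize_library <- function(annotations, designs = NULL) {
  if (nrow(annotations) == 0) stop("empty annotation collection", call. = FALSE)
  design_sets <- prepare_design_sets(designs)

  resolved <- annotations |> dplyr::filter(!is.na(.data$cdr_nt_len))
  region_stats <- resolved |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      processed = dplyr::n(),
      in_frame_pct = 100 * mean(.data$in_frame),
      designed_length_pct = 100 * mean(.data$designed_length),
      designed_sequence_pct = 100 * mean(.data$designed_sequence),
      .groups = "drop"
    )
  if (!is.null(design_sets)) {
    cov <- purrr::imap_dfr(design_sets, function(ds, region) {
      obs <- resolved$cdr_seq[resolved$region == region & resolved$designed_sequence %in% TRUE]
      tibble::tibble(
        region = region,
        design_unique = length(ds$seqs),
        design_coverage_pct = 100 * length(intersect(unique(obs), ds$seqs)) / length(ds$seqs)
      )
    })
    region_stats <- dplyr::full_join(region_stats, cov, by = "region") |>
      dplyr::arrange(.data$region)
  }

  per_read <- annotations |>
    dplyr::group_by(.data$read_id, .data$chain) |>
    dplyr::summarise(
      complete = all(!is.na(.data$cdr_nt_len)),
      functional = all(!is.na(.data$cdr_nt_len)) && all(.data$in_frame) && !any(.data$has_stop),
      domain_key = paste(.data$cdr_seq, collapse = "|"),
      .groups = "drop"
    )
  chain_stats <- per_read |>
    dplyr::filter(.data$chain != "unknown") |>
    dplyr::group_by(.data$chain) |>
    dplyr::summarise(
      reads = dplyr::n(),
      complete = sum(.data$complete),
      functional_domain_pct = ifelse(sum(.data$complete) > 0,
                                     100 * sum(.data$functional) / sum(.data$complete),
                                     NA_real_),
      .groups = "drop"
    )
  in_frame_prod <- region_stats |>
    dplyr::left_join(cdr_region_info(region_stats$region), by = "region") |>
    dplyr::group_by(.data$chain) |>
    dplyr::summarise(
      product_in_frame_pct = ifelse(dplyr::n() == 3L,
                                    100 * prod(.data$in_frame_pct / 100),
                                    NA_real_),
      .groups = "drop"
    )
  chain_stats <- dplyr::left_join(chain_stats, in_frame_prod, by = "chain")

  redundancy <- per_read |>
    dplyr::filter(.data$functional, .data$chain != "unknown") |>
    dplyr::count(.data$chain, .data$domain_key, name = "times_seen") |>
    dplyr::count(.data$chain, .data$times_seen, name = "n_sequences")

  structure(
    list(
      region_stats = region_stats,
      chain_stats = chain_stats,
      redundancy = redundancy,
      n_reads = length(unique(annotations$read_id))
    ),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>", x$n_reads, "reads\n")
  print(x$region_stats)
  invisible(x)
}

#' @rdname tidy.shm_profile
#' @exportS3Method generics::tidy
tidy.qc_report <- function(x, ...) x$region_stats

#' @rdname tidy.shm_profile
#' @exportS3Method generics::glance
glance.qc_report <- function(x, ...) {
  tibble::tibble(
    n_reads = x$n_reads,
    n_regions = nrow(x$region_stats),
    mean_in_frame_pct = mean(x$region_stats$in_frame_pct, na.rm = TRUE)
  )
}

#' Mutation load relative to the closest germline
#'
#' For every CDR sequence the closest equal-length germline is assigned
#' (see [assign_germlines()]) and the number of amino-acid differences
#' counted; averages are reported per region and length class, plus a
#' per-residue rate. Heavy CDR3 has no germline ancestor and is skipped.
#'
#' @param x a tibble with `region` and `sequence` columns (a designed
#'   repertoire, a natural repertoire, or [cdrs_from_annotations()] output).
#' @param germlines a [germline_set()].
#' @return tibble with columns `region`, `length`, `n`, `mean_mutations`,
#'   `mutations_per_residue` (unassignable sequences are excluded).
#' @export
mutation_statistics <- function(x, germlines) {
  x <- x[x$region != "H3", , drop = FALSE]
  purrr::map_dfr(unique(x$region), function(region) {
    seqs <- x$sequence[x$region == region]
    asg <- assign_germlines(seqs, germlines, region)
    asg <- asg[asg$germline_name != "unassigned", ]
    if (nrow(asg) == 0) return(NULL)
    asg |>
      dplyr::mutate(length = nchar(.data$observed)) |>
      dplyr::group_by(.data$length) |>
      dplyr::summarise(
        n = dplyr::n(),
        mean_mutations = mean(.data$mismatch_count),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        region = region,
        mutations_per_residue = .data$mean_mutations / .data$length
      ) |>
      dplyr::select("region", "length", "n", "mean_mutations", "mutations_per_residue")
  })
}

#' Framework mutation rate from annotations
#'
#' Total framework amino-acid mismatches over total compared framework
#' residues, per chain.
#'
#' @param annotations a `read_annotations` tibble.
#' @return tibble with `chain`, `fr_mutations`, `fr_residues`,
#'   `mutations_per_residue`.
#' @export
fr_mutation_rate <- function(annotations) {
  annotations |>
    dplyr::distinct(.data$read_id, .keep_all = TRUE) |>
    dplyr::filter(.data$chain != "unknown", !is.na(.data$fr_residues), .data$fr_residues > 0) |>
    dplyr::group_by(.data$chain) |>
    dplyr::summarise(
      fr_mutations = sum(.data$fr_mutations),
      fr_residues = sum(.data$fr_residues),
      mutations_per_residue = sum(.data$fr_mutations) / sum(.data$fr_residues),
      .groups = "drop"
    )
}

#' Extract resolved CDR sequences from annotations
#'
#' @param annotations a `read_annotations` tibble.
#' @param in_frame_only keep only in-frame CDRs (default `TRUE`).
#' @return tibble with `region` and `sequence` columns.
#' @export
cdrs_from_annotations <- function(annotations, in_frame_only = TRUE) {
  out <- annotations |>
    dplyr::filter(!is.na(.data$cdr_seq)) |>
    dplyr::select(region = "region", sequence = "cdr_seq")
  out
}

#' PTM motif burden of a sequence collection
#'
#' Per region and motif kind, the percentage of sequences containing at
#' least one reportable hit; the `Total` row is the percentage with at
#' least one hit of any kind (at most the sum of the motif rows, since
#' motifs co-occur). Sequences are scanned without junction flanks; the
#' policy's Met exemptions apply.
#'
#' @param x tibble with `region` and `sequence` columns.
#' @param policy a [ptm_policy()].
#' @return tibble with columns `region`, `motif`, `pct`.
#' @export
ptm_statistics <- function(x, policy = ptm_policy()) {
  purrr::map_dfr(unique(x$region), function(region) {
    seqs <- x$sequence[x$region == region]
    hits <- ptm_hit_matrix(seqs, region, policy)
    tibble::tibble(
      region = region,
      motif = c(colnames(hits), "Total"),
      pct = 100 * unname(c(colMeans(hits), mean(apply(hits, 1, any))))
    )
  })
}

#' Compare an observed library with its design
#'
#' Restricted to designed sequences observed in the data, pairs each
#' designed sequence's design frequency with its observed frequency and
#' reports the squared Pearson correlation per region (undefined when fewer
#' than three designed sequences were observed); also reports designed vs
#' observed length distributions and the per-region redundancy spectrum of
#' observed sequences.
#'
#' @param annotations a `read_annotations` tibble.
#' @param designs named list (by region) of designed repertoires.
#' @return a `design_comparison`: list with tibbles `r2`, `freq_pairs`,
#'   `length_dist` and `redundancy`.
#' @export
compare_design <- function(annotations, designs) {
  resolved <- annotations |> dplyr::filter(!is.na(.data$cdr_seq))
  if (nrow(resolved) == 0) stop("no resolved CDRs to compare", call. = FALSE)

  pieces <- purrr::imap(designs, function(d, region) {
    des <- if (is.data.frame(d)) d$sequence else as.character(d)
    des_freq <- table(des) / length(des)
    obs <- resolved$cdr_seq[resolved$region == region]
    obs_des <- obs[obs %in% names(des_freq)]
    shared <- unique(obs_des)
    pairs <- tibble::tibble(
      region = region,
      sequence = shared,
      designed_freq = as.numeric(des_freq[shared]),
      observed_freq = as.numeric(table(obs_des)[shared]) / length(obs_des)
    )
    r2 <- tibble::tibble(
      region = region,
      n_shared = length(shared),
      r_squared = if (length(shared) >= 3 &&
                      stats::sd(pairs$designed_freq) > 0 &&
                      stats::sd(pairs$observed_freq) > 0) {
        stats::cor(pairs$designed_freq, pairs$observed_freq)^2
      } else {
        NA_real_
      }
    )
    ld <- dplyr::bind_rows(
      tibble::tibble(region = region, set = "designed", length = nchar(des)),
      tibble::tibble(region = region, set = "observed", length = nchar(obs))
    ) |>
      dplyr::count(.data$region, .data$set, .data$length) |>
      dplyr::group_by(.data$region, .data$set) |>
      dplyr::mutate(freq = .data$n / sum(.data$n)) |>
      dplyr::ungroup()
    red <- tibble::tibble(sequence = obs) |>
      dplyr::count(.data$sequence, name = "times_seen") |>
      dplyr::count(.data$times_seen, name = "n_sequences") |>
      dplyr::mutate(region = region, .before = 1)
    list(pairs = pairs, r2 = r2, ld = ld, red = red)
  })

  structure(
    list(
      r2 = purrr::map_dfr(pieces, "r2"),
      freq_pairs = purrr::map_dfr(pieces, "pairs"),
      length_dist = purrr::map_dfr(pieces, "ld"),
      redundancy = purrr::map_dfr(pieces, "red")
    ),
    class = "design_comparison"
  )
}

#' @export
print.design_comparison <- function(x, ...) {
  cat("<design_comparison>\n")
  print(x$r2)
  invisible(x)
}

#' @rdname tidy.shm_profile
#' @exportS3Method generics::tidy
tidy.design_comparison <- function(x, ...) x$r2
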