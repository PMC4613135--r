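#' Assign the germline ancestor of an observed CDR
#'
#' Each observed CDR is compared with the germline CDR sequences of the same
#' region and the same length, and the germline with the fewest amino-acid
#' mismatches (minimal Hamming distance) is assigned as its ancestor. Ties
#' are broken lexicographically by germline name so the assignment is
#' deterministic. When no germline of matching length exists the sequence is
#' `"unassigned"`.
#'
#' @param observed amino-acid string(s); `assign_germline()` takes one,
#'   `assign_germlines()` a vector.
#' @param germlines a [germline_set()].
#' @param region two-character CDR region code.
#' @return a tibble with one row per observed sequence and columns
#'   `observed`, `germline_name`, `mismatch_count` and `mismatch_positions`
#'   (list column of tibbles with `position` (1-based) and `observed_residue`).
#'   For unassigned sequences `germline_name` is `"unassigned"` and the
#'   mismatch fields are `NA`/empty.
#' @examples
#' gs <- germline_set(data.frame(region = "K1", name = c("a", "b"),
#'                               sequence = c("QSVSS", "QDISN")))
#' assign_germline("QSVTS", gs, "K1")
#' @export
assign_germline <- function(observed, germlines, region) {
  stopifnot(length(observed) == 1L)
  assign_germlines(observed, germlines, region)
}

#' @rdname assign_germline
#' @export
assign_germlines <- function(observed, germlines, region) {
  region <- assert_region(region)
  observed <- clean_seq(observed)
  if (any(!nzchar(observed))) stop("empty observed sequence", call. = FALSE)
  assert_aa20(observed, "observed sequence")
  glset <- germlines_for(germlines, region)
  if (length(glset) == 0) {
    stop("no germline sequences for region ", region, call. = FALSE)
  }
  glset <- glset[order(names(glset))]  # lexicographic tie-break
  gl_len <- nchar(glset)

  out_name <- rep("unassigned", length(observed))
  out_mm <- rep(NA_integer_, length(observed))
  out_pos <- vector("list", length(observed))

  obs_len <- nchar(observed)
  for (L in unique(obs_len)) {
    idx <- which(obs_len == L)
    cand <- glset[gl_len == L]
    if (length(cand) == 0) {
      out_pos[idx] <- list(tibble::tibble(position = integer(), observed_residue = character()))
      next
    }
    obs_mat <- matrix(unlist(strsplit(observed[idx], "", fixed = TRUE)),
                      nrow = length(idx), byrow = TRUE)
    for (i in seq_along(idx)) {
      best_mm <- Inf
      best_g <- NA_integer_
      for (g in seq_along(cand)) {
        mm <- sum(obs_mat[i, ] != chars(cand[[g]]))
        if (mm < best_mm) {
          best_mm <- mm
          best_g <- g
        }
      }
      pos <- which(obs_mat[i, ] != chars(cand[[best_g]]))
      j <- idx[i]
      out_name[j] <- names(cand)[best_g]
      out_mm[j] <- as.integer(best_mm)
      out_pos[[j]] <- tibble::tibble(position = pos, observed_residue = obs_mat[i, pos])
    }
  }
  tibble::tibble(
    observed = observed,
    germline_name = out_name,
    mismatch_count = out_mm,
    mismatch_positions = out_pos
  )
}

#' Estimate a somatic-hypermutation profile for one CDR region
#'
#' For every assignable sequence in the repertoire (a germline of matching
#' length exists) the germline ancestor is assigned with
#' [assign_germlines()]. The profile then records, over the assignable
#' sequences: the utilisation frequency of each germline ancestor (`usage`),
#' the per-position frequency of substitution to each of the 19 non-germline
#' residues conditioned on the ancestor (`spectrum`), and the CDR length
#' distribution (`length_dist`). Sequences with no length-matched germline
#' are excluded and counted in `n_unassigned`.
#'
#' @param rep a [cdr_repertoire()].
#' @param germlines a [germline_set()] covering the repertoire's region.
#' @param pooled if `TRUE`, substitution spectra are pooled across germlines
#'   of equal length (each germline then shares its length class's pooled
#'   spectrum); default `FALSE` conditions per germline.
#' @return an `shm_profile` object: list with `region`, `usage` (named
#'   frequencies), `germline_seqs`, `spectrum` (per germline, a 20 x L matrix
#'   of substitution frequencies, zero on the germline residue), `length_dist`,
#'   `n_assigned`, `n_unassigned`.
#' @export
build_shm_profile <- function(rep, germlines, pooled = FALSE) {
  region <- rep$region[1]
  asg <- assign_germlines(rep$sequence, germlines, region)
  keep <- asg$germline_name != "unassigned"
  n_un <- sum(!keep)
  if (!any(keep)) stop("no sequence could be assigned to a germline", call. = FALSE)
  asg <- asg[keep, ]
  glset <- germlines_for(germlines, region)

  counts <- table(asg$germline_name)
  usage <- as.numeric(counts) / nrow(asg)
  names(usage) <- names(counts)

  spectrum <- lapply(names(usage), function(g) {
    gl <- glset[[g]]
    L <- nchar(gl)
    m <- matrix(0, nrow = 20L, ncol = L, dimnames = list(AA20, NULL))
    sub <- asg[asg$germline_name == g, ]
    mp <- dplyr::bind_rows(sub$mismatch_positions)
    if (nrow(mp) > 0) {
      tab <- table(factor(mp$observed_residue, levels = AA20), factor(mp$position, levels = seq_len(L)))
      m <- m + unclass(tab) / nrow(sub)
    }
    m
  })
  names(spectrum) <- names(usage)

  if (pooled) {
    glen <- nchar(glset[names(usage)])
    for (L in unique(glen)) {
      gset <- names(usage)[glen == L]
      w <- usage[gset]
      pooled_m <- Reduce(`+`, Map(function(g, wi) spectrum[[g]] * wi, gset, w)) / sum(w)
      for (g in gset) {
        m <- pooled_m
        m[cbind(match(chars(glset[[g]]), AA20), seq_len(L))] <- 0
        spectrum[[g]] <- m
      }
    }
  }

  len_tab <- table(nchar(asg$observed))
  length_dist <- as.numeric(len_tab) / nrow(asg)
  names(length_dist) <- names(len_tab)

  structure(
    list(
      region = region,
      usage = usage,
      germline_seqs = glset[names(usage)],
      spectrum = spectrum,
      length_dist = length_dist,
      n_assigned = nrow(asg),
      n_unassigned = n_un
    ),
    class = "shm_profile"
  )
}

#' @export
print.shm_profile <- function(x, ...) {
  cat("<shm_profile>", x$region, "|", length(x$usage), "germlines |",
      x$n_assigned, "assigned,", x$n_unassigned, "unassigned\n")
  invisible(x)
}

#' Expected mutations per simulated sequence under a profile
#'
#' The usage-weighted sum over positions of the total substitution rate;
#' the mean mutation count a large germline-based simulation will show.
#'
#' @param profile an `shm_profile`.
#' @return a single number.
#' @export
expected_mutations <- function(profile) {
  sum(vapply(names(profile$usage), function(g) {
    profile$usage[[g]] * sum(colSums(profile$spectrum[[g]]))
  }, numeric(1)))
}

#' Estimate a positional profile for CDR-H3
#'
#' CDR-H3 has no practical germline ancestor, so it is profiled positionally:
#' per length, the frequency of each of the 20 amino acids at each of the
#' first `length - terminal_len` positions; the last `terminal_len` residues
#' (the J-segment-derived tail, Kabat 100-102 for the default of 3) are
#' profiled as whole units pooled across lengths. The length distribution is
#' restricted to `length_range` and renormalised.
#'
#' @param rep a [cdr_repertoire()] for region `H3`.
#' @param length_range integer length 2, inclusive bounds (default 9-20).
#' @param terminal_len tail unit length (default 3; 0 disables the tail model).
#' @return an `h3_profile` object: list with `length_dist`, `positional`
#'   (per length, a 20 x (length - terminal_len) column-stochastic matrix),
#'   `terminal_units` (named unit frequencies), `terminal_len`, `n`.
#' @export
build_h3_profile <- function(rep, length_range = c(9L, 20L), terminal_len = 3L) {
  seqs <- rep$sequence
  len <- nchar(seqs)
  keep <- len >= length_range[1] & len <= length_range[2] & len > terminal_len
  if (!any(keep)) {
    stop("no sequence within length range [", length_range[1], ", ",
         length_range[2], "]", call. = FALSE)
  }
  seqs <- seqs[keep]
  len <- len[keep]

  len_tab <- table(len)
  length_dist <- as.numeric(len_tab) / length(seqs)
  names(length_dist) <- names(len_tab)

  positional <- lapply(as.integer(names(len_tab)), function(L) {
    s <- seqs[len == L]
    ncol <- L - terminal_len
    m <- matrix(unlist(strsplit(substr(s, 1L, ncol), "", fixed = TRUE)),
                nrow = length(s), byrow = TRUE)
    freq <- apply(m, 2, function(col) table(factor(col, levels = AA20)) / length(col))
    matrix(as.numeric(freq), nrow = 20L, dimnames = list(AA20, NULL))
  })
  names(positional) <- names(len_tab)

  if (terminal_len > 0) {
    tails <- substr(seqs, len - terminal_len + 1L, len)
    unit_tab <- table(tails)
    terminal_units <- as.numeric(unit_tab) / length(tails)
    names(terminal_units) <- names(unit_tab)
  } else {
    terminal_units <- stats::setNames(numeric(0), character(0))
  }

  structure(
    list(
      length_dist = length_dist,
      positional = positional,
      terminal_units = terminal_units,
      terminal_len = as.integer(terminal_len),
      n = length(seqs)
    ),
    class = "h3_profile"
  )
}

#' @export
print.h3_profile <- function(x, ...) {
  cat("<h3_profile> lengths", paste(range(as.integer(names(x$length_dist))), collapse = "-"),
      "|", length(x$terminal_units), "terminal units | n =", x$n, "\n")
  invisible(x)
}

#' Default light-chain CDR3 tail split rule
#'
#' The last two residues of short CDR-L3s (length <= 9) and the last three of
#' longer ones are treated as the J-segment-derived tail.
#'
#' @param lengths integer vector of CDR lengths.
#' @return named integer vector mapping length to tail length.
#' @export
l3_split_rule <- function(lengths) {
  stats::setNames(ifelse(lengths <= 9L, 2L, 3L), lengths)
}

#' Estimate a tail profile for light-chain CDR3
#'
#' Light-chain CDR3s are modelled as a germline-based head followed by a
#' short tail derived from the J segment. This profiles the tail: per CDR
#' length, the per-position amino-acid frequencies of the last `tail_len`
#' residues, where `tail_len` comes from `split_rule`.
#'
#' @param rep a [cdr_repertoire()] for region `K3` or `L3`.
#' @param split_rule named integer vector (names are CDR lengths) or a
#'   function of lengths; defaults to [l3_split_rule()]. Lengths absent from
#'   a vector rule are excluded with a warning.
#' @return an `l3_tail_profile`: list with `region`, `tail_len` (named by
#'   length), `tail_positional` (per length, 20 x tail_len column-stochastic
#'   matrix), `n`.
#' @export
build_l3_tail_profile <- function(rep, split_rule = l3_split_rule) {
  region <- rep$region[1]
  if (!region %in% c("K3", "L3")) {
    stop("tail profiles are defined for light-chain CDR3 (K3/L3), got ", region,
         call. = FALSE)
  }
  len <- nchar(rep$sequence)
  ulen <- sort(unique(len))
  if (is.function(split_rule)) {
    rule <- split_rule(ulen)
    names(rule) <- ulen
  } else {
    rule <- split_rule
    missing_len <- setdiff(as.character(ulen), names(rule))
    if (length(missing_len) > 0) {
      warning("CDR length(s) ", paste(missing_len, collapse = ", "),
              " absent from split_rule; excluded from the tail profile",
              call. = FALSE)
    }
  }
  keep <- as.character(len) %in% names(rule)
  if (!any(keep)) stop("no sequence covered by split_rule", call. = FALSE)
  seqs <- rep$sequence[keep]
  len <- len[keep]

  tail_positional <- lapply(sort(unique(len)), function(L) {
    tl <- rule[[as.character(L)]]
    s <- substr(seqs[len == L], L - tl + 1L, L)
    m <- matrix(unlist(strsplit(s, "", fixed = TRUE)), ncol = tl, byrow = TRUE)
    freq <- apply(m, 2, function(col) table(factor(col, levels = AA20)) / length(col))
    matrix(as.numeric(freq), nrow = 20L, dimnames = list(AA20, NULL))
  })
  names(tail_positional) <- sort(unique(len))

  structure(
    list(
      region = region,
      tail_len = vapply(names(tail_positional), function(L) as.integer(rule[[L]]), integer(1)),
      tail_positional = tail_positional,
      n = length(seqs)
    ),
    class = "l3_tail_profile"
  )
}

#' @export
print.l3_tail_profile <- function(x, ...) {
  cat("<l3_tail_profile>", x$region, "| lengths:",
      paste(names(x$tail_positional), collapse = ", "), "| n =", x$n, "\n")
  invisible(x)
}

# --- broom-style methods ---------------------------------------------------

#' Tidy somatic-hypermutation and positional profiles
#'
#' `tidy()` returns the profile's frequencies in long form; `glance()` a
#' one-row summary.
#'
#' @param x a profile object.
#' @param ... unused.
#' @return a tibble.
#' @exportS3Method generics::tidy
tidy.shm_profile <- function(x, ...) {
  purrr::map_dfr(names(x$spectrum), function(g) {
    m <- x$spectrum[[g]]
    tibble::tibble(
      region = x$region,
      germline = g,
      position = rep(seq_len(ncol(m)), each = 20L),
      residue = rep(AA20, ncol(m)),
      frequency = as.numeric(m)
    )
  }) |>
    dplyr::filter(.data$frequency > 0 | FALSE)
}

#' @rdname tidy.shm_profile
#' @exportS3Method generics::glance
glance.shm_profile <- function(x, ...) {
  tibble::tibble(
    region = x$region,
    n_germlines = length(x$usage),
    n_assigned = x$n_assigned,
    n_unassigned = x$n_unassigned,
    expected_mutations = expected_mutations(x)
  )
}

#' @rdname tidy.shm_profile
#' @exportS3Method generics::tidy
tidy.h3_profile <- function(x, ...) {
  purrr::map_dfr(names(x$positional), function(L) {
    m <- x$positional[[L]]
    tibble::tibble(
      length = as.integer(L),
      position = rep(seq_len(ncol(m)), each = 20L),
      residue = rep(AA20, ncol(m)),
      frequency = as.numeric(m)
    )
  })
}

#' @rdname tidy.shm_profile
#' @exportS3Method generics::glance
glance.h3_profile <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_lengths = length(x$length_dist),
    n_terminal_units = length(x$terminal_units),
    terminal_len = x$terminal_len
  )
}

#' @rdname tidy.shm_profile
#' @exportS3Method generics::tidy
tidy.l3_tail_profile <- function(x, ...) {
  purrr::map_dfr(names(x$tail_positional), function(L) {
    m <- x$tail_positional[[L]]
    tibble::tibble(
      region = x$region,
      length = as.integer(L),
      tail_position = rep(seq_len(ncol(m)), each = 20L),
      residue = rep(AA20, ncol(m)),
      frequency = as.numeric(m)
    )
  })
}
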