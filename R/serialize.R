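#' Serialize profiles to versioned JSON
#'
#' Profiles (somatic-hypermutation, CDR-H3 positional, light-CDR3 tail)
#' round-trip through a small versioned JSON document so they can be
#' inspected, archived and fed to the command-line interface.
#'
#' @param profile an `shm_profile`, `h3_profile` or `l3_tail_profile`.
#' @param path output file path.
#' @return `write_profile_json()` returns `path` invisibly;
#'   `read_profile_json()` the reconstructed profile object.
#' @export
write_profile_json <- function(profile, path) {
  type <- class(profile)[1]
  stopifnot(type %in% c("shm_profile", "h3_profile", "l3_tail_profile"))
  enc_mat <- function(m) list(residues = rownames(m), values = as.numeric(m), ncol = ncol(m))
  data <- unclass(profile)
  # named atomic vectors serialize as JSON objects (names kept) via lists
  for (fld in c("usage", "germline_seqs", "length_dist", "terminal_units", "tail_len")) {
    if (!is.null(data[[fld]])) data[[fld]] <- as.list(data[[fld]])
  }
  if (type == "shm_profile") data$spectrum <- lapply(data$spectrum, enc_mat)
  if (type == "h3_profile") data$positional <- lapply(data$positional, enc_mat)
  if (type == "l3_tail_profile") data$tail_positional <- lapply(data$tail_positional, enc_mat)
  doc <- list(format = "cdrforge-profile", version = 1L, type = type, data = data)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile_json
#' @export
read_profile_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "cdrforge-profile")) {
    stop("not a cdrforge profile document: ", path, call. = FALSE)
  }
  dec_mat <- function(e) {
    matrix(as.numeric(e$values), nrow = length(e$residues),
           dimnames = list(e$residues, NULL))
  }
  dec_named_num <- function(x) {
    out <- as.numeric(unlist(x))
    names(out) <- names(unlist(x))
    out
  }
  data <- doc$data
  type <- doc$type
  if (type == "shm_profile") {
    data$usage <- dec_named_num(data$usage)
    data$germline_seqs <- unlist(data$germline_seqs)
    data$spectrum <- lapply(data$spectrum, dec_mat)
    data$length_dist <- dec_named_num(data$length_dist)
  } else if (type == "h3_profile") {
    data$length_dist <- dec_named_num(data$length_dist)
    data$positional <- lapply(data$positional, dec_mat)
    data$terminal_units <- dec_named_num(data$terminal_units)
  } else {
    data$tail_len <- vapply(data$tail_len, as.integer, integer(1))
    data$tail_positional <- lapply(data$tail_positional, dec_mat)
  }
  structure(data, class = type)
}
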