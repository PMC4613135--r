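#' Run the full design-and-QC pipeline on synthetic inputs
#'
#' Wires every stage together: fixture germlines and scaffolds, synthetic
#' natural repertoires with known parameters, profile estimation, PTM-
#' filtered repertoire design for all nine regions, synthesis-pool
#' partitioning and oligo emission, error-bearing read simulation, read
#' annotation and the full QC report with estimators. When `out_dir` is
#' given, all artifacts are written there (designed repertoires and oligo
#' pools, profile JSON, QC tables, and a run manifest recording the seed
#' and parameters so the run is replayable).
#'
#' @param seed integer seed driving every stochastic stage.
#' @param targets named per-region design totals (default [design_config()]
#'   targets; pass smaller values for quick runs).
#' @param rep_sizes named natural-repertoire sizes per chain.
#' @param depth number of simulated clones (two domain reads each).
#' @param read_errors list overriding [read_sim_spec()] error rates.
#' @param out_dir optional output directory.
#' @return (invisibly) a list with `germlines`, `scaffolds`, `profiles`,
#'   `designs`, `pools`, `reads`, `annotations`, `report`, `mutations`,
#'   `ptm`, `comparison`, `functional`, `ptm_free`.
#' @export
run_pipeline <- function(seed = 1L,
                         targets = NULL,
                         rep_sizes = c(heavy = 8846L, kappa = 3110L, lambda = 2440L),
                         depth = 1000L,
                         read_errors = list(),
                         out_dir = NULL) {
  cfg <- design_config(targets = targets)
  germlines <- demo_germline_set()
  scaffolds <- demo_scaffolds()

  message("Generating natural repertoires and profiles ...")
  naturals <- list()
  profiles <- list()
  for (region in cdr_regions()) {
    chain <- cdr_region_info(region)$chain
    spec <- demo_repertoire_spec(region, n = rep_sizes[[chain]],
                                 seed = seed + match(region, cdr_regions()))
    nat <- generate_natural_repertoire(spec, germlines)
    naturals[[region]] <- nat
    profiles[[region]] <- if (region == "H3") {
      list(h3 = build_h3_profile(nat, cfg$h3_length_range))
    } else if (substr(region, 2, 2) == "3") {
      list(shm = build_shm_profile(nat, germlines),
           l3_tail = build_l3_tail_profile(nat))
    } else {
      list(shm = build_shm_profile(nat, germlines))
    }
  }

  message("Designing PTM-filtered repertoires ...")
  designs <- list()
  for (region in cdr_regions()) {
    chain <- cdr_region_info(region)$chain
    designs[[region]] <- design_repertoire(
      profiles[[region]], region, scaffold = scaffolds[[chain]],
      n_target = cfg$targets[[region]], policy = cfg$ptm,
      seed = seed + 100L + match(region, cdr_regions())
    )
  }

  message("Partitioning synthesis pools ...")
  pools_h3 <- partition_pools(designs$H3, cfg$pool_capacity)
  others <- dplyr::bind_rows(designs[setdiff(cdr_regions(), "H3")])
  pools_other <- partition_pools(others, cfg$pool_capacity)
  pools_other$pool_id <- pools_other$pool_id + max(pools_h3$pool_id)
  pools <- dplyr::bind_rows(pools_h3, pools_other)
  oligos <- emit_oligo_pool(pools, scaffolds)

  message("Simulating and annotating reads ...")
  err <- utils::modifyList(
    list(substitution_rate = 0.002, deletion_rate = 0.002,
         insertion_rate = 0.001, stop_inject_rate = 0.01, proofread = FALSE),
    read_errors
  )
  rspec <- read_sim_spec(
    designs, scaffolds, depth = depth,
    substitution_rate = err$substitution_rate, deletion_rate = err$deletion_rate,
    insertion_rate = err$insertion_rate, stop_inject_rate = err$stop_inject_rate,
    proofread = err$proofread, seed = seed + 200L
  )
  reads <- generate_library_reads(rspec)
  annotations <- annotate_reads(reads, scaffolds, designs)

  report <- summarize_library(annotations, designs)
  mutations <- mutation_statistics(
    dplyr::bind_rows(lapply(designs, tibble::as_tibble)), germlines
  )
  ptm <- ptm_statistics(cdrs_from_annotations(annotations), cfg$ptm)
  comparison <- compare_design(annotations, designs)
  functional <- estimate_functional_fractions(report)
  ptm_free <- estimate_ptm_free_fraction(ptm)

  result <- list(
    germlines = germlines, scaffolds = scaffolds, profiles = profiles,
    designs = designs, pools = pools, oligos = oligos, reads = reads,
    annotations = annotations, report = report, mutations = mutations,
    ptm = ptm, comparison = comparison, functional = functional,
    ptm_free = ptm_free
  )
  if (!is.null(out_dir)) {
    write_pipeline_outputs(result, out_dir, seed, cfg, rspec)
  }
  invisible(result)
}

write_pipeline_outputs <- function(result, out_dir, seed, cfg, rspec) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (region in names(result$designs)) {
    write_repertoire(result$designs[[region]],
                     file.path(out_dir, paste0("design_", region, ".fasta")))
  }
  readr::write_tsv(result$oligos, file.path(out_dir, "oligo_pools.tsv"))
  for (region in names(result$profiles)) {
    p <- result$profiles[[region]]
    nm <- names(p)[1]
    write_profile_json(p[[nm]], file.path(out_dir, paste0("profile_", region, ".json")))
  }
  readr::write_tsv(result$report$region_stats, file.path(out_dir, "qc_regions.tsv"))
  readr::write_tsv(result$report$chain_stats, file.path(out_dir, "qc_chains.tsv"))
  readr::write_tsv(result$mutations, file.path(out_dir, "qc_mutations.tsv"))
  readr::write_tsv(result$ptm, file.path(out_dir, "qc_ptm.tsv"))
  readr::write_tsv(result$comparison$r2, file.path(out_dir, "qc_fidelity_r2.tsv"))
  readr::write_tsv(result$functional, file.path(out_dir, "qc_functional.tsv"))
  readr::write_tsv(result$ptm_free, file.path(out_dir, "qc_ptm_free.tsv"))
  manifest <- list(
    tool = "cdrforge",
    version = as.character(utils::packageVersion("cdrforge")),
    r_version = as.character(getRversion()),
    seed = seed,
    targets = as.list(cfg$targets),
    pool_capacity = cfg$pool_capacity,
    depth = rspec$depth,
    error_rates = list(
      substitution = rspec$substitution_rate, deletion = rspec$deletion_rate,
      insertion = rspec$insertion_rate, stop_inject = rspec$stop_inject_rate,
      proofread = rspec$proofread
    ),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Command-line entry point
#'
#' A thin dispatcher behind the `inst/cli/cdrforge.R` script. Subcommands:
#' `pipeline` (full synthetic run into an output directory), `profile`
#' (estimate a profile from repertoire + germline files), `design`
#' (simulate a PTM-filtered repertoire from a profile JSON), `simulate`
#' (generate synthetic reads from design FASTAs) and `qc` (annotate reads
#' and write the QC report).
#'
#' @param args character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly (0 on success).
#' @export
cdrforge_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    cat("usage: cdrforge.R <pipeline|profile|design|simulate|qc> [options]\n")
    return(invisible(0L))
  }
  sub <- args[1]
  rest <- args[-1]
  opt <- parse_kv(rest)
  status <- tryCatch({
    switch(
      sub,
      pipeline = {
        run_pipeline(
          seed = as.integer(opt$seed %||% 1),
          depth = as.integer(opt$depth %||% 1000),
          out_dir = opt$out %||% "cdrforge_out"
        )
        0L
      },
      profile = {
        rep <- read_repertoire(opt$repertoire, opt$region)
        if (opt$region == "H3") {
          prof <- build_h3_profile(rep)
        } else {
          gs <- read_germline_set(opt$germlines)
          prof <- build_shm_profile(rep, gs)
        }
        write_profile_json(prof, opt$out)
        0L
      },
      design = {
        prof <- read_profile_json(opt$profile)
        profiles <- if (inherits(prof, "h3_profile")) list(h3 = prof) else list(shm = prof)
        if (!is.null(opt$tail_profile)) {
          profiles$l3_tail <- read_profile_json(opt$tail_profile)
        }
        sc <- if (!is.null(opt$frameworks)) {
          read_frameworks(opt$frameworks)[[cdr_region_info(opt$region)$chain]]
        }
        rep <- design_repertoire(profiles, opt$region, scaffold = sc,
                                 n_target = as.integer(opt$n %||% NA) %|na|% NULL,
                                 seed = as.integer(opt$seed %||% 1))
        write_repertoire(rep, opt$out)
        0L
      },
      simulate = {
        designs <- read_design_dir(opt$designs)
        scaffolds <- read_frameworks(opt$frameworks)
        spec <- read_sim_spec(designs, scaffolds,
                              depth = as.integer(opt$depth %||% 1000),
                              seed = as.integer(opt$seed %||% 1))
        reads <- generate_library_reads(spec)
        write_fasta(stats::setNames(reads$sequence, reads$read_id), opt$out)
        0L
      },
      qc = {
        reads <- read_reads(opt$reads)
        scaffolds <- read_frameworks(opt$frameworks)
        designs <- if (!is.null(opt$designs)) read_design_dir(opt$designs)
        ann <- annotate_reads(reads, scaffolds, designs)
        report <- summarize_library(ann, designs)
        dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
        readr::write_tsv(report$region_stats, file.path(opt$out, "qc_regions.tsv"))
        readr::write_tsv(report$chain_stats, file.path(opt$out, "qc_chains.tsv"))
        jsonlite::write_json(
          list(region_stats = report$region_stats, chain_stats = report$chain_stats,
               n_reads = report$n_reads),
          file.path(opt$out, "qc_report.json"), auto_unbox = TRUE, digits = NA
        )
        0L
      },
      {
        message("unknown subcommand: ", sub)
        2L
      }
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%|na|%` <- function(a, b) if (length(a) == 1 && is.na(a)) b else a

parse_kv <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i + 1L <= length(args) && !startsWith(args[i + 1L], "--")) {
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      out[[key]] <- TRUE
      i <- i + 1L
    }
  }
  out
}

read_design_dir <- function(dir) {
  files <- list.files(dir, pattern = "^design_[HKL][123]\\.fasta$", full.names = TRUE)
  if (length(files) == 0) stop("no design_<region>.fasta files in ", dir, call. = FALSE)
  regions <- sub("^design_([HKL][123])\\.fasta$", "\\1", basename(files))
  out <- lapply(files, function(f) unname(read_fasta(f)))
  stats::setNames(out, regions)
}
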