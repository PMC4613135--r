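test_that("pool partitioning matches the synthesis capacity arithmetic", {
  rep <- designed_repertoire(random_aa(200, 5), "H1")
  # 7,836 sequences at capacity 3,918 fill exactly two pools
  big <- designed_repertoire(rep(rep$sequence, length.out = 7836), "H1")
  pools <- partition_pools(big, 3918L)
  expect_equal(max(pools$pool_id), 2L)
  expect_true(all(table(pools$pool_id) <= 3918))

  # 11,000 sequences need three pools
  other <- designed_repertoire(rep(rep$sequence, length.out = 11000), "H1")
  expect_equal(max(partition_pools(other, 3918L)$pool_id), 3L)

  one <- partition_pools(designed_repertoire("ART", "H1"), 3918L)
  expect_equal(max(one$pool_id), 1L)

  # concatenation in pool order reconstitutes the repertoire exactly
  expect_identical(pools$sequence, big$sequence)
  expect_error(partition_pools(big[0, ], 10), "empty")
})

test_that("oligo emission flanks reverse-translated CDRs with framework ends", {
  sc <- demo_scaffolds()$heavy
  pool <- partition_pools(designed_repertoire(c("ART", "GYSSA"), "H1"), 10L)
  oligos <- emit_oligo_pool(pool, sc, flank_nt = 18L)
  expect_equal(nchar(oligos$oligo[1]), 18L + 9L + 18L)  # 45 nt for a 3-mer CDR
  # central segment translates back to the CDR
  central <- substr(oligos$oligo, 19L, nchar(oligos$oligo) - 18L)
  expect_equal(cdrforge:::translate_nt(central), oligos$cdr)
  # flanks really come from the frameworks
  fr1 <- sc$fr_nucleotide[["FR1"]]
  expect_equal(substr(oligos$oligo[1], 1, 18),
               substr(fr1, nchar(fr1) - 17L, nchar(fr1)))

  expect_error(emit_oligo_pool(pool, sc, flank_nt = 50L), "flank_nt")
  expect_error(
    emit_oligo_pool(pool, sc, codon_table = preferred_codons()[-1]),
    "missing from codon table"
  )
})

test_that("scFv assembly is additive in its parts and invertible on clean sequences", {
  mk <- function(chain, lens) {
    framework_scaffold(chain, vapply(lens, function(k) {
      paste(rep(c("GCT", "TAC", "GGT"), length.out = k), collapse = "")
    }, character(1)))
  }
  heavy <- mk("heavy", c(25, 14, 32, 11))
  light <- mk("kappa", c(10, 17, 36, 10))
  withr::with_seed(31, {
    h_cdrs <- c(random_aa(1, 5), random_aa(1, 17), random_aa(1, 12))
    l_cdrs <- c(random_aa(1, 16), random_aa(1, 7), random_aa(1, 9))
  })
  scfv <- assemble_scfv(h_cdrs, l_cdrs, heavy, light, linker = strrep("G", 15))
  expect_equal(nchar(scfv), (25 + 14 + 32 + 11 + 5 + 17 + 12) + 15 +
                 (10 + 17 + 36 + 10 + 16 + 7 + 9))
  expect_equal(nchar(scfv), 236L)

  # extracting between framework matches recovers the CDRs
  heavy_part <- substr(scfv, 1, 82 + 34)
  expect_equal(extract_cdrs(heavy_part, heavy), h_cdrs)

  expect_error(assemble_scfv(c("A", "B", ""), l_cdrs, heavy, light), "empty CDR")
})
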