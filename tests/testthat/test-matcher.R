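test_that("sequence index returns exactly the records holding a sequence", {
  cat_ <- fixture_catalog()
  idx <- build_sequence_index(cat_)
  row <- idx[idx$sequence == MONOCOT_MIR168, ]
  expect_equal(row$matched_ids,
               "osa-miR168a,sbi-miR168,zma-miR168a,zma-miR168b")
  expect_true(row$has_plant)
  expect_false(row$has_animal)
  expect_false(strrep("A", 21) %in% idx$sequence)
  expect_error(build_sequence_index(cat_[0, ]), "empty catalog")
})

test_that("genome k-mer filter detects >=20-nt matches on either strand only", {
  g <- make_toy_genome(2000, seed = 11)
  gidx <- build_genome_index(g$sequence)
  # verbatim substring
  sub21 <- substr(g$sequence, 101, 121)
  expect_true(has_genome_match(sub21, gidx))
  # reverse complement of a genome substring
  rc <- oracle_genome_match(sub21, g$sequence) # sanity for the oracle itself
  expect_true(rc)
  rc21 <- paste(rev(strsplit(chartr("ACGT", "TGCA", sub21), "")[[1]]),
                collapse = "")
  expect_true(has_genome_match(rc21, gidx))
  # reads shorter than k never match
  expect_false(has_genome_match(substr(g$sequence, 101, 119), gidx))
})

test_that("a 19-nt shared block is below the genome-filter threshold", {
  g <- make_toy_genome(1000, seed = 7)
  gidx <- build_genome_index(g$sequence)
  withr::with_seed(8, {
    # 19 genome-derived nt flanked by a random tail: max shared block 19
    repeat {
      block19 <- substr(g$sequence, 501, 519)
      tail2 <- paste(sample(c("A", "C", "G", "T"), 2, replace = TRUE),
                     collapse = "")
      read <- paste0(block19, tail2)
      if (!oracle_genome_match(read, g$sequence)) break
    }
    expect_false(has_genome_match(read, gidx))
  })
})

test_that("strict classification implements whole-read perfect identity", {
  cat_ <- fixture_catalog()
  idx <- build_sequence_index(cat_)
  # DNA form of the monocot miR168 variant
  asn <- classify_read("TCGCTTGGTGCAGATCGGGAC", idx)
  expect_equal(asn$category, "plant_mirna")
  expect_equal(asn$family, "miR168")
  expect_equal(asn$clades, "monocot")

  # same read with the 21-mer planted in the host genome -> host-derived
  g <- make_toy_genome(5000, planted_kmers = MONOCOT_MIR168, seed = 2)
  gidx <- build_genome_index(g$sequence)
  expect_equal(classify_read("TCGCTTGGTGCAGATCGGGAC", idx, gidx)$category,
               "host_genome_derived")

  # one substitution away from every catalog sequence -> unassigned
  near <- paste0(substr(MONOCOT_MIR168, 1, 20), "G")
  expect_equal(classify_read(near, idx)$category, "unassigned")
  # animal sequences classify as animal and are never genome-screened
  bmo <- dplyr::filter(cat_, mirna_id == "bmo-miR-279")$sequence
  g2 <- make_toy_genome(5000, planted_kmers = bmo, seed = 3)
  expect_equal(classify_read(bmo, idx, build_genome_index(g2$sequence))$category,
               "animal_mirna")
  expect_error(classify_read("", idx), "empty read")
})

test_that("reads matching both kingdoms are surfaced as ambiguous", {
  fa <- write_fasta(c("osa-miRX", "anm-miRY"),
                    rep("ACGUACGUACGUACGUACGUA", 2))
  cat_ <- read_mirna_catalog(fa, tiny_species_meta())
  asn <- classify_read("ACGTACGTACGTACGTACGTA", build_sequence_index(cat_))
  expect_equal(asn$category, "ambiguous_kingdom")
  prof <- profile_library(asn, "lib")
  expect_equal(prof$plant_reads, 0)
  expect_equal(prof$animal_reads, 0)
  expect_equal(prof$ambiguous_reads, 1)
})

test_that("contains mode accepts mature sequences with flanking bases", {
  idx <- build_sequence_index(fixture_catalog())
  untrimmed <- paste0("AG", MONOCOT_MIR168, "CT")
  expect_equal(classify_read(untrimmed, idx)$category, "unassigned")
  got <- classify_read(untrimmed, idx, match_mode = "contains")
  expect_equal(got$category, "plant_mirna")
  expect_equal(got$family, "miR168")
})

test_that("library classification preserves order, counts and multiplicity", {
  idx <- build_sequence_index(fixture_catalog())
  reads <- tibble::tibble(
    read_id = c("a", "b", "c"),
    sequence = c(MONOCOT_MIR168, strrep("A", 21), DICOT_MIR168),
    count = c(5L, 2L, 7L)
  )
  asn <- classify_library(reads, idx)
  expect_equal(asn$read_id, reads$read_id)
  expect_equal(sum(asn$count), sum(reads$count))
  expect_equal(asn$count[1], 5L) # collapsed multiplicity passes through
  expect_equal(nrow(classify_library(reads[0, ], idx)), 0)
})

test_that("classification agrees with the per-read oracle and is order-invariant", {
  withr::with_seed(101, {
    toy <- make_toy_catalog(5, 5, seed = 55)
    idx <- build_sequence_index(toy)
    g <- make_toy_genome(3000, planted_kmers = toy$sequence[1:4], seed = 56)
    gidx <- build_genome_index(g$sequence)
    reads <- random_reads(200, len_range = 21)
    # seed in some catalog sequences so all categories are exercised
    reads$sequence[1:40] <- sample(chartr("U", "T", toy$sequence), 40,
                                   replace = TRUE)
    asn <- classify_library(reads, idx, gidx)
    expected <- vapply(reads$sequence, oracle_classify, character(1),
                       catalog = toy, genome = g$sequence, USE.NAMES = FALSE)
    expect_equal(asn$category, expected)
    expect_gt(length(unique(asn$category)), 2)

    # permuting reads or catalog rows changes nothing
    perm <- sample(nrow(reads))
    asn_perm <- classify_library(reads[perm, ], idx, gidx)
    expect_equal(asn_perm$category, asn$category[perm])
    idx2 <- build_sequence_index(toy[sample(nrow(toy)), ])
    expect_equal(classify_library(reads, idx2, gidx)$category, asn$category)
  })
})

test_that("growing the host genome only ever demotes plant calls", {
  withr::with_seed(77, {
    toy <- make_toy_catalog(3, 8, seed = 77)
    idx <- build_sequence_index(toy)
    plant_seqs <- dplyr::filter(toy, kingdom == "plant")$sequence
    reads <- tibble::tibble(read_id = paste0("r", seq_along(plant_seqs)),
                            sequence = plant_seqs, count = 1L)
    g_small <- make_toy_genome(500, planted_kmers = plant_seqs[1], seed = 1)
    g_big <- build_genome_index(c(g_small$sequence,
                                  paste(plant_seqs[1:5], collapse = "")))
    cat_small <- classify_library(reads, idx, build_genome_index(g_small$sequence))
    cat_big <- classify_library(reads, idx, g_big)
    demoted <- cat_small$category == "plant_mirna" &
      cat_big$category == "host_genome_derived"
    promoted <- cat_small$category == "host_genome_derived" &
      cat_big$category == "plant_mirna"
    expect_true(any(demoted))
    expect_false(any(promoted))
  })
})

test_that("reads round-trip through the collapsed FASTA and FASTQ dialects", {
  reads <- tibble::tibble(read_id = c("r1", "r2"),
                          sequence = c("ACGTACGTACGTACGTACGTA", "TTTTACGT"),
                          count = c(12L, 1L))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_srna_reads(reads, fa)
  expect_equal(as.data.frame(read_srna_reads(fa)), as.data.frame(reads))
  fq <- withr::local_tempfile(fileext = ".fq")
  write_srna_reads(reads, fq, format = "fastq")
  expect_equal(as.data.frame(read_srna_reads(fq)), as.data.frame(reads))
})
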