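make_asn <- function(seqs, counts, category = "plant_mirna") {
  tibble::tibble(
    read_id = sprintf("r%d", seq_along(seqs)), sequence = seqs,
    count = as.integer(counts), category = category,
    family = "miR168", clades = NA_character_, matched_ids = NA_character_
  )
}

test_that("clade breakdown attributes miR168 variants and pools unresolved", {
  cat_ <- fixture_catalog()
  all_mono <- make_asn(MONOCOT_MIR168, 120)
  bd <- clade_breakdown(all_mono, cat_, family = "miR168")
  expect_equal(bd$clade, "monocot")
  expect_equal(bd$percent, 100)

  mix <- make_asn(c(MONOCOT_MIR168, DICOT_MIR168), c(96, 4))
  bd <- clade_breakdown(mix, cat_)
  expect_equal(bd$percent[bd$clade == "monocot"], 96)
  expect_equal(bd$percent[bd$clade == "dicot"], 4)
  expect_equal(sum(bd$percent), 100)

  expect_equal(nrow(clade_breakdown(make_asn(MONOCOT_MIR168, 5,
                                             category = "animal_mirna"),
                                    cat_)), 0)
  # a sequence absent from the catalog's plant side is unresolved, not dropped
  odd <- make_asn(c(MONOCOT_MIR168, strrep("G", 21)), c(3, 1))
  bd <- clade_breakdown(odd, cat_)
  expect_equal(sum(bd$percent), 100)
  expect_equal(bd$reads[bd$clade == "unresolved"], 1)
})

test_that("profile similarity is rank-based, symmetric and centered under the null", {
  a <- c(miR1 = 100, miR2 = 50, miR3 = 10, miR4 = 1)
  expect_equal(profile_similarity(a, a), 1)
  expect_equal(profile_similarity(a, a^2 * 3), 1) # monotone-transform invariant
  b <- c(miR4 = 80, miR3 = 60, miR2 = 40, miR1 = 5)
  expect_equal(profile_similarity(a, b), profile_similarity(b, a))
  expect_equal(profile_similarity(a, rev(b)), profile_similarity(a, b))
  expect_error(profile_similarity(c(x = 1), c(y = 2)), "at least 3")

  withr::with_seed(99, {
    sims <- replicate(1000, {
      fams <- paste0("f", 1:50)
      profile_similarity(setNames(runif(50), fams), setNames(runif(50), fams))
    })
    expect_lt(abs(mean(sims)), 0.05)
  })
})

test_that("marker tracing counts exact occurrences and identifies sources", {
  marker <- "ACGGUUUAGGCCUAAGCGAUACGG"
  libs <- list(
    lettuce = tibble::tibble(sequence = c(marker, "AAAA"),
                             count = c(500L, 99500L)),
    insect1 = tibble::tibble(sequence = c(marker, "CCCC"),
                             count = c(3L, 99997L)),
    other_run = tibble::tibble(sequence = "GGGG", count = 1000L)
  )
  manifest <- tibble::tibble(library_id = names(libs),
                             role = c("plant_source", "animal_sample",
                                      "animal_sample"))
  tr <- trace_marker(marker, libs, manifest)
  expect_equal(tr$source_libraries, "lettuce")
  per <- tr$per_library
  expect_equal(per$reads[per$library_id == "insect1"], 3)
  expect_equal(per$reads[per$library_id == "other_run"], 0)

  # marker present only in its source: recipients all zero, still traceable
  clean <- libs
  clean$insect1$count[1] <- 0L
  expect_equal(sum(trace_marker(marker, clean, manifest)$per_library$reads[-1]), 0)
  # absent everywhere -> unusable
  expect_error(trace_marker(strrep("U", 24), libs, manifest), "not a usable marker")
})

test_that("bleed-rate estimation inverts the marker arithmetic", {
  marker <- "ACGGUUUAGGCCUAAGCGAUACGG"
  # source: 1e6 reads, 1% marker; recipient: 1e5 reads, pool 1e6
  libs <- list(
    src = tibble::tibble(sequence = c(marker, "A"), count = c(10000L, 990000L)),
    rec = tibble::tibble(sequence = c(marker, "C"), count = c(1L, 99999L))
  )
  manifest <- tibble::tibble(library_id = c("src", "rec"),
                             role = c("plant_source", "animal_sample"))
  tr <- trace_marker(marker, libs, manifest)
  est <- estimate_bleed_rate(tr)
  # 1 = 1e5 * bleed * 10000/1e6  =>  bleed = 1e-3
  expect_equal(as.numeric(est), 1e-3)

  zero <- libs
  zero$rec$count[1] <- 0L
  expect_equal(as.numeric(estimate_bleed_rate(trace_marker(marker, zero, manifest))), 0)
})

test_that("simulated bleed is recovered and matched across recipients", {
  toy <- make_toy_catalog(8, 12, seed = 3)
  idx <- build_sequence_index(toy)
  bleed <- 0.01
  cfg <- example_run_config(toy, seed = 4, bleed_rate = bleed,
                            spike_fraction = 0)
  sim <- simulate_run(cfg)
  man <- sim$manifest
  markers <- find_marker_sequences(sim$reads, man, toy)
  expect_equal(markers$source_library, "lettuce1")
  tr <- trace_marker(markers$sequence[1], sim$reads, man)
  est <- estimate_bleed_rate(tr)
  # binomial SE of the pooled estimate via expected marker bleed counts
  lam <- sum(attr(est, "per_recipient")$total_reads) * bleed *
    sum(tr$per_library$reads[tr$per_library$is_source]) / 1e6
  expect_lt(abs(as.numeric(est) - bleed), 3 * bleed / sqrt(lam))

  # two same-sized recipients agree within sampling error
  per <- attr(est, "per_recipient")
  insects <- per[grepl("insect", per$library_id), ]
  expect_lt(diff(range(insects$bleed_estimate)), 6 * bleed / sqrt(lam / 6))
})

test_that("library verdicts weigh similarity margin and clade identity", {
  cat_ <- fixture_catalog()
  diet <- c(miR168 = 100, miR535 = 40, miR156 = 10, miR159 = 5)
  pool <- c(miR159 = 300, miR396 = 200, miR1507 = 90, miR168 = 20)

  # monocot-fed animal whose plant reads are all dicot variants
  dicot_bd <- clade_breakdown(make_asn(DICOT_MIR168, 100), cat_)
  v <- diagnose_library(c(miR168 = 100, miR535 = 2, miR156 = 1), diet, pool,
                        dicot_bd, diet_clades = "monocot")
  expect_equal(v$verdict, "contamination_suspected")

  # profile tracks the pooled run, not the diet
  libp <- c(miR159 = 150, miR396 = 90, miR1507 = 50, miR168 = 4)
  mono_bd <- clade_breakdown(make_asn(MONOCOT_MIR168, 10), cat_)
  v <- diagnose_library(libp, diet, pool, mono_bd, diet_clades = "monocot")
  expect_equal(v$verdict, "contamination_suspected")

  # concordant case: profile equals diet, clades match
  v <- diagnose_library(diet, diet, pool, mono_bd, diet_clades = "monocot")
  expect_equal(v$verdict, "diet_consistent")

  # missing diet profile falls back to clade evidence, flagged
  v <- diagnose_library(libp, NULL, pool, dicot_bd, diet_clades = "monocot")
  expect_equal(v$verdict, "contamination_suspected")
  expect_match(v$note, "clade evidence only")

  # no plant reads at all is inconclusive
  v <- diagnose_library(setNames(numeric(), character()), diet, pool,
                        clade_breakdown(make_asn("X", 1,
                                                 category = "unassigned"),
                                        cat_),
                        diet_clades = "monocot")
  expect_equal(v$verdict, "inconclusive")
})

test_that("end-to-end: bleed marks animal libraries contaminated; verdicts are monotone", {
  toy <- make_toy_catalog(8, 12, seed = 3)
  idx <- build_sequence_index(toy)
  run_verdicts <- function(bleed, seed) {
    cfg <- example_run_config(toy, seed = seed, bleed_rate = bleed,
                              spike_fraction = 0)
    sim <- simulate_run(cfg)
    asn <- lapply(sim$reads, classify_library, index = idx)
    man <- sim$manifest
    man$diet <- attr(cfg, "declared_diets")[man$library_id]
    tidy(diagnose_run(asn, man, toy))$verdict
  }
  v_hi <- run_verdicts(0.001, 6)
  expect_true(all(v_hi == "contamination_suspected"))
  # same seed stream, more bleed: no verdict flips back to diet_consistent
  v_higher <- run_verdicts(0.01, 6)
  expect_false(any(v_hi == "contamination_suspected" &
                     v_higher == "diet_consistent"))
})

test_that("single-library runs come back inconclusive with a note", {
  toy <- make_toy_catalog(4, 8, seed = 9)
  asn <- classify_library(
    tibble::tibble(read_id = "r1", sequence = toy$sequence[1], count = 3L),
    build_sequence_index(toy)
  )
  man <- tibble::tibble(run_id = "solo", library_id = "only",
                        organism = "anm", role = "animal_sample",
                        diet = "zma")
  d <- diagnose_run(list(only = asn), man, toy, trace_markers = FALSE)
  expect_equal(tidy(d)$verdict, "inconclusive")
  expect_match(tidy(d)$note, "no co-multiplexed")
})
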