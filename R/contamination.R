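#' Monocot/dicot breakdown of a library's plant miRNA reads
#'
#' Attributes each plant-classified sequence variant to a clade by exact
#' catalog lookup ([sequence_clades()]) and reports read percentages per
#' clade. Variants carried by both clades, or by none (possible under
#' `contains` matching), are pooled under `unresolved` rather than split
#' fractionally. This is the miR168-style origin test: the monocot and dicot
#' 21-nt variants differ at two positions, so a library whose miR168 reads
#' are 100% the monocot variant cannot be explained by a dicot diet.
#'
#' @param assignments An `xmir_assignments` tibble.
#' @param catalog The `xmir_catalog` the reads were classified against.
#' @param family Optional family key; when given, only that family's plant
#'   reads are broken down (e.g. `"miR168"`), otherwise all plant reads.
#' @return A tibble `clade`, `reads`, `percent` (percent over all
#'   clade-assigned reads including `unresolved`; sums to 100 when any rows
#'   exist). Zero qualifying reads give a zero-row tibble.
#' @export
clade_breakdown <- function(assignments, catalog, family = NULL) {
  plant <- filter(assignments, .data$category == "plant_mirna")
  if (!is.null(family)) plant <- filter(plant, .data$family == !!family)
  empty <- tibble(clade = character(), reads = numeric(), percent = numeric())
  if (nrow(plant) == 0) return(empty)
  per_seq <- plant |>
    group_by(.data$sequence) |>
    summarise(reads = sum(.data$count), .groups = "drop")
  per_seq$clade <- map_chr(per_seq$sequence, function(s) {
    cl <- sequence_clades(s, catalog)
    if (length(cl) == 1) cl else "unresolved"
  })
  out <- per_seq |>
    group_by(.data$clade) |>
    summarise(reads = sum(.data$reads), .groups = "drop") |>
    mutate(percent = 100 * .data$reads / sum(.data$reads)) |>
    arrange(desc(.data$reads))
  out
}

#' Rank similarity between two plant miRNA family profiles
#'
#' Spearman rank correlation over the union of family keys (families absent
#' from one profile count as 0 there), computed on log1p-transformed counts.
#' Monotone-invariant and robust to library-size differences, so profiles of
#' very different depth compare on equal footing.
#'
#' @param family_counts_a,family_counts_b Named numeric vectors
#'   (family -> count) or two-column data frames (`family`, `reads`).
#' @return A score in \[-1, 1\].
#' @export
profile_similarity <- function(family_counts_a, family_counts_b) {
  as_vec <- function(x) {
    if (is.data.frame(x)) setNames(x$reads, x$family) else x
  }
  a <- as_vec(family_counts_a)
  b <- as_vec(family_counts_b)
  keys <- union(names(a), names(b))
  if (length(keys) < 3) {
    abort("profile similarity needs at least 3 families in the union")
  }
  av <- ifelse(is.na(a[keys]), 0, a[keys])
  bv <- ifelse(is.na(b[keys]), 0, b[keys])
  # a constant profile (e.g. no plant reads at all) has no rank information
  if (length(unique(av)) < 2 || length(unique(bv)) < 2) return(NA_real_)
  cor(log1p(av), log1p(bv), method = "spearman")
}

#' Trace a library-specific marker sequence across a run
#'
#' Counts exact occurrences of a marker sequence in every library of a run.
#' A marker is "library-specific" in the sense of the contamination
#' diagnostic: abundant in one (plant) source library and absent from the
#' references of every other organism in the run, so any reads of it in the
#' other libraries must have bled across during multiplexed sequencing or
#' library preparation.
#'
#' @param marker_sequence The marker sequence (DNA or RNA alphabet).
#' @param libraries_reads Named list (library_id -> tibble with `sequence`
#'   and `count`); `xmir_assignments` tibbles work directly.
#' @param manifest Run manifest tibble with at least `library_id` and `role`.
#' @param source_threshold Relative-abundance cutoff above which a library
#'   counts as a source of the marker (default 1e-4).
#' @return An `xmir_marker_trace`: list with `marker_sequence`,
#'   `per_library` (tibble `library_id`, `reads`, `total_reads`,
#'   `rel_abundance`, `is_source`) and `source_libraries`.
#' @export
trace_marker <- function(marker_sequence, libraries_reads, manifest = NULL,
                         source_threshold = 1e-4) {
  m <- normalize_rna(marker_sequence)
  per <- imap(libraries_reads, function(lib, id) {
    s <- normalize_rna(lib$sequence)
    n_marker <- sum(lib$count[s == m])
    tibble(library_id = id, reads = n_marker, total_reads = sum(lib$count))
  }) |> list_rbind()
  if (sum(per$reads) == 0) {
    abort("marker sequence not observed in any library; not a usable marker")
  }
  per <- mutate(per,
    rel_abundance = .data$reads / .data$total_reads,
    is_source = .data$rel_abundance > source_threshold
  )
  if (!is.null(manifest) && "role" %in% names(manifest)) {
    roles <- setNames(manifest$role, manifest$library_id)
    per$is_source <- per$is_source &
      roles[per$library_id] %in% "plant_source"
  }
  structure(list(
    marker_sequence = m,
    per_library = per,
    source_libraries = per$library_id[per$is_source]
  ), class = "xmir_marker_trace")
}

#' @export
print.xmir_marker_trace <- function(x, ...) {
  cat(sprintf("<xmir_marker_trace> %s\n  sources: %s\n", x$marker_sequence,
              paste(x$source_libraries, collapse = ", ")))
  print(x$per_library)
  invisible(x)
}

#' Find candidate library-specific marker sequences
#'
#' Scans a run for sequences whose relative abundance in exactly one
#' plant-source library exceeds `min_abundance` and which are absent from the
#' miRNA catalog (so they cannot be legitimate dietary miRNAs shared between
#' libraries).
#'
#' @param libraries_reads Named list of read/assignment tibbles.
#' @param manifest Run manifest with `library_id`, `role`.
#' @param catalog Optional `xmir_catalog`; catalog sequences are excluded.
#' @param min_abundance Source abundance cutoff (default 1e-4).
#' @return Tibble `sequence`, `source_library`, `source_reads`.
#' @export
find_marker_sequences <- function(libraries_reads, manifest, catalog = NULL,
                                  min_abundance = 1e-4) {
  sources <- manifest$library_id[manifest$role == "plant_source"]
  cand <- imap(libraries_reads[intersect(names(libraries_reads), sources)],
    function(reads, id) {
      tot <- sum(reads$count)
      reads |>
        mutate(sequence = normalize_rna(.data$sequence)) |>
        group_by(.data$sequence) |>
        summarise(reads = sum(.data$count), .groups = "drop") |>
        filter(.data$reads / tot > min_abundance) |>
        mutate(source_library = id)
    }) |> list_rbind()
  if (nrow(cand) == 0) return(tibble(sequence = character(),
                                     source_library = character(),
                                     source_reads = numeric()))
  if (!is.null(catalog)) {
    cand <- filter(cand, !.data$sequence %in% catalog$sequence)
  }
  cand |>
    group_by(.data$sequence) |>
    filter(n() == 1) |>
    ungroup() |>
    select("sequence", "source_library", source_reads = "reads")
}

#' Estimate the inter-library bleed rate from a marker trace
#'
#' Under the uniform bleed model — every recipient read slot draws a
#' contaminating read from the pooled co-multiplexed foreign libraries with
#' probability equal to the bleed rate — the expected marker count in a
#' recipient is `n_recipient * bleed * (marker reads in sources / foreign
#' pool size)`. Inverting gives a per-recipient estimate; the returned value
#' is their mean, with the per-recipient table attached as an attribute.
#'
#' @param marker_trace An `xmir_marker_trace` whose `per_library` table
#'   covers one multiplex group (sources and recipients together).
#' @param library_totals Optional named vector of per-library total reads;
#'   defaults to the totals recorded in the trace.
#' @return The estimated bleed fraction (>= 0), attribute `per_recipient`.
#' @export
estimate_bleed_rate <- function(marker_trace, library_totals = NULL) {
  per <- marker_trace$per_library
  if (!is.null(library_totals)) {
    per$total_reads <- unname(library_totals[per$library_id])
  }
  src <- filter(per, .data$is_source)
  rec <- filter(per, !.data$is_source)
  if (nrow(src) == 0) abort("marker trace has no source library")
  if (nrow(rec) == 0) abort("marker trace has no recipient library")
  marker_in_sources <- sum(src$reads)
  if (marker_in_sources == 0) abort("marker has zero abundance in sources")
  total_all <- sum(per$total_reads)
  rec <- mutate(rec,
    foreign_pool = total_all - .data$total_reads,
    bleed_estimate = .data$reads * .data$foreign_pool /
      (.data$total_reads * marker_in_sources)
  )
  structure(mean(rec$bleed_estimate), per_recipient = rec)
}

#' Verdict for one library: dietary uptake or run contamination?
#'
#' Combines two lines of evidence. (1) Profile similarity: if the library's
#' plant-family profile tracks the pooled profile of every plant library in
#' its multiplexed run much better than it tracks its own declared diet
#' (margin `decision_margin`), the plant reads look like run bleed, not food.
#' (2) Clade identity: if a clade absent from the declared diet accounts for
#' at least `clade_threshold` percent of clade-assignable reads (e.g. >=50%
#' monocot-variant miR168 in a dicot-fed animal), the diet cannot be the
#' source. Either triggers `contamination_suspected`; a dominant
#' diet-similarity with diet-consistent clades gives `diet_consistent`;
#' anything else is `inconclusive`.
#'
#' @param library_profile Plant family counts for the library (named vector
#'   or `family`/`reads` data frame).
#' @param diet_profile Same, for the declared diet source; `NULL` when the
#'   diet was not sequenced (verdict then rests on clade evidence, flagged).
#' @param pooled_run_profile Same, pooled over all plant libraries of the
#'   run; `NULL` when the library was not co-multiplexed with plant material.
#' @param clade_breakdown Tibble from [clade_breakdown()] for this library.
#' @param diet_clades Character vector of clades consistent with the declared
#'   diet (e.g. `"monocot"` for a corn diet).
#' @param decision_margin Similarity excess of pooled-run over diet required
#'   to call contamination (default 0.2).
#' @param clade_threshold Off-diet clade percentage required to call
#'   contamination on clade evidence alone (default 50).
#' @return One-row tibble: `similarity_to_diet`, `similarity_to_pooled_run`,
#'   `off_diet_clade_pct`, `verdict`, `note`.
#' @export
diagnose_library <- function(library_profile, diet_profile,
                             pooled_run_profile, clade_breakdown,
                             diet_clades = character(),
                             decision_margin = 0.2, clade_threshold = 50) {
  sim_safe <- function(a, b) {
    if (is.null(a) || is.null(b)) return(NA_real_)
    tryCatch(profile_similarity(a, b), error = function(e) NA_real_)
  }
  sim_diet <- sim_safe(library_profile, diet_profile)
  sim_pool <- sim_safe(library_profile, pooled_run_profile)

  off_diet_pct <- 0
  if (nrow(clade_breakdown) > 0) {
    off <- !clade_breakdown$clade %in% c(diet_clades, "unresolved")
    off_diet_pct <- sum(clade_breakdown$percent[off])
  }

  notes <- character()
  if (is.null(diet_profile)) notes <- c(notes, "no diet profile; clade evidence only")
  if (is.null(pooled_run_profile)) notes <- c(notes, "no co-multiplexed libraries")

  n_plant <- if (is.data.frame(library_profile)) {
    sum(library_profile$reads)
  } else sum(library_profile)

  verdict <- if (is.null(n_plant) || n_plant == 0) {
    notes <- c(notes, "no plant miRNA reads")
    "inconclusive"
  } else if (off_diet_pct >= clade_threshold) {
    "contamination_suspected"
  } else if (!is.na(sim_pool) && !is.na(sim_diet) &&
             sim_pool - sim_diet >= decision_margin) {
    "contamination_suspected"
  } else if (!is.na(sim_diet) &&
             (is.na(sim_pool) || sim_diet >= sim_pool) &&
             sim_diet > 0 && off_diet_pct < clade_threshold) {
    "diet_consistent"
  } else if (is.null(diet_profile) && !is.null(pooled_run_profile) &&
             nrow(clade_breakdown) > 0 && length(diet_clades) > 0 &&
             off_diet_pct < clade_threshold) {
    # clade-only concordance, usable only when a run context existed
    "diet_consistent"
  } else {
    "inconclusive"
  }

  tibble(
    similarity_to_diet = sim_diet,
    similarity_to_pooled_run = sim_pool,
    off_diet_clade_pct = off_diet_pct,
    verdict = verdict,
    note = if (length(notes) > 0) paste(notes, collapse = "; ") else NA_character_
  )
}

plant_family_vector <- function(assignments) {
  plant <- filter(assignments, .data$category == "plant_mirna",
                  !is.na(.data$family))
  if (nrow(plant) == 0) return(setNames(numeric(), character()))
  agg <- plant |>
    group_by(.data$family) |>
    summarise(reads = sum(.data$count), .groups = "drop")
  setNames(agg$reads, agg$family)
}

#' Contamination diagnostics for a whole multiplexed run
#'
#' Runs [diagnose_library()] for every animal library of a run: the diet
#' profile is taken from the plant-source library/libraries whose organism
#' matches the declared diet, the pooled-run profile sums all plant-source
#' libraries, clades consistent with the diet come from the catalog's species
#' metadata, and (optionally) library-specific markers are traced and used to
#' estimate the bleed rate.
#'
#' @param assignments_by_library Named list of `xmir_assignments`, one per
#'   library in the run (plant sources included).
#' @param manifest Tibble with `run_id`, `library_id`, `organism`, `role`
#'   (`plant_source`/`animal_sample`), `diet` (organism name of the diet
#'   source, or NA).
#' @param catalog The `xmir_catalog` used for classification.
#' @param trace_markers Trace auto-detected library-specific markers and
#'   estimate bleed (default TRUE).
#' @param decision_margin,clade_threshold,marker_min_abundance Thresholds,
#'   see [diagnose_library()] and [find_marker_sequences()].
#' @return An `xmir_contamination` object: `per_library` verdict tibble,
#'   `marker_traces`, `bleed_rate` estimate (NA when no marker usable).
#'   [tidy()] returns the per-library table.
#' @export
diagnose_run <- function(assignments_by_library, manifest, catalog,
                         trace_markers = TRUE, decision_margin = 0.2,
                         clade_threshold = 50, marker_min_abundance = 1e-4) {
  manifest <- as_tibble(manifest)
  stopifnot(!anyDuplicated(manifest$library_id))
  meta <- species_meta(catalog)

  plant_libs <- manifest$library_id[manifest$role == "plant_source"]
  plant_vecs <- map(assignments_by_library[intersect(names(assignments_by_library), plant_libs)],
                    plant_family_vector)
  pooled <- NULL
  if (length(plant_vecs) > 0) {
    keys <- unique(unlist(map(plant_vecs, names)))
    if (length(keys) > 0) {
      pooled <- setNames(rep(0, length(keys)), keys)
      for (v in plant_vecs) pooled[names(v)] <- pooled[names(v)] + v
    }
  }

  # diets are named by the species code of the source plant
  diet_clades_of <- function(diet) {
    if (length(diet) == 0 || is.na(diet)) return(character())
    setdiff(unique(meta$clade[meta$species_code == diet]), "not_applicable")
  }

  animal <- filter(manifest, .data$role == "animal_sample")
  rows <- map(seq_len(nrow(animal)), function(i) {
    lib <- animal$library_id[i]
    a <- assignments_by_library[[lib]]
    if (is.null(a)) abort(sprintf("no assignments supplied for library %s", lib))
    lib_vec <- plant_family_vector(a)
    diet <- animal$diet[i]
    diet_src <- manifest$library_id[manifest$role == "plant_source" &
                                      manifest$organism %in% diet]
    diet_vec <- NULL
    if (length(diet_src) > 0) {
      vs <- plant_vecs[intersect(names(plant_vecs), diet_src)]
      if (length(vs) > 0) {
        keys <- unique(unlist(map(vs, names)))
        diet_vec <- setNames(rep(0, length(keys)), keys)
        for (v in vs) diet_vec[names(v)] <- diet_vec[names(v)] + v
      }
    }
    bd <- clade_breakdown(a, catalog)
    res <- diagnose_library(lib_vec, diet_vec, pooled, bd,
                            diet_clades = diet_clades_of(diet),
                            decision_margin = decision_margin,
                            clade_threshold = clade_threshold)
    bd_pct <- function(cl) {
      p <- bd$percent[bd$clade == cl]
      if (length(p) == 0) 0 else p
    }
    tibble(
      run_id = animal$run_id[i], library_id = lib,
      organism = animal$organism[i], diet = diet,
      plant_reads = sum(lib_vec),
      pct_monocot = bd_pct("monocot"), pct_dicot = bd_pct("dicot"),
      pct_unresolved = bd_pct("unresolved")
    ) |> dplyr::bind_cols(res)
  })
  per_library <- list_rbind(rows)

  traces <- list()
  bleed <- NA_real_
  if (trace_markers && length(plant_libs) > 0) {
    markers <- find_marker_sequences(assignments_by_library, manifest,
                                     catalog, marker_min_abundance)
    if (nrow(markers) > 0) {
      best <- markers |> arrange(desc(.data$source_reads)) |> head(5)
      traces <- map(best$sequence, function(s) {
        trace_marker(s, assignments_by_library, manifest,
                     source_threshold = marker_min_abundance)
      })
      ests <- map_dbl(traces, function(tr) {
        tryCatch(as.numeric(estimate_bleed_rate(tr)),
                 error = function(e) NA_real_)
      })
      if (any(!is.na(ests))) bleed <- mean(ests, na.rm = TRUE)
    }
  }

  structure(list(
    run_id = unique(manifest$run_id)[1],
    per_library = per_library,
    marker_traces = traces,
    bleed_rate = bleed,
    thresholds = list(decision_margin = decision_margin,
                      clade_threshold = clade_threshold,
                      marker_min_abundance = marker_min_abundance)
  ), class = "xmir_contamination")
}

#' @export
print.xmir_contamination <- function(x, ...) {
  cat(sprintf("<xmir_contamination> run %s, %d librar%s, bleed estimate %s\n",
              x$run_id, nrow(x$per_library),
              if (nrow(x$per_library) == 1) "y" else "ies",
              format(x$bleed_rate, digits = 3)))
  print(select(x$per_library, "library_id", "diet", "plant_reads",
               "pct_monocot", "pct_dicot", "similarity_to_diet",
               "similarity_to_pooled_run", "verdict"))
  invisible(x)
}

#' @export
tidy.xmir_contamination <- function(x, ...) {
  x$per_library
}

#' @export
glance.xmir_contamination <- function(x, ...) {
  tibble(
    run_id = x$run_id,
    n_libraries = nrow(x$per_library),
    n_contamination_suspected =
      sum(x$per_library$verdict == "contamination_suspected"),
    n_diet_consistent = sum(x$per_library$verdict == "diet_consistent"),
    n_inconclusive = sum(x$per_library$verdict == "inconclusive"),
    bleed_rate = x$bleed_rate
  )
}

#' @export
autoplot.xmir_contamination <- function(object, ...) {
  dat <- tidyr::pivot_longer(
    object$per_library,
    c("similarity_to_diet", "similarity_to_pooled_run"),
    names_to = "comparison", values_to = "similarity"
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$library_id,
                                    y = .data$similarity,
                                    fill = .data$comparison)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~.data$verdict, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Spearman similarity") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
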