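#' Assemble (or load) a pipeline configuration
#'
#' The end-to-end pipeline is driven by a flat configuration: where the
#' catalog, species metadata, per-organism genomes, run manifest and read
#' files live, plus the analysis thresholds. Configurations can be built in
#' R or loaded from a YAML file with the same field names.
#'
#' @param catalog Path to the mature-miRNA FASTA.
#' @param species_meta Path to the species metadata TSV.
#' @param manifest Path to the run manifest TSV (`run_id`, `library_id`,
#'   `organism`, `role`, `diet`, ...).
#' @param reads Named character vector or list: library_id -> reads file
#'   (FASTA/FASTQ).
#' @param genomes Named list: organism -> genome FASTA (or raw sequence).
#'   Libraries whose organism has no genome are classified with the genome
#'   screen skipped and flagged.
#' @param match_mode `"strict"` or `"contains"`.
#' @param threshold_pct Significance threshold on `pct_plant_of_animal`.
#' @param decision_margin,clade_threshold,marker_min_abundance Diagnostic
#'   thresholds (see [diagnose_library()]).
#' @param out_dir Report directory.
#' @param seed Seed recorded in the run log (the analysis itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(catalog, species_meta, manifest, reads,
                            genomes = list(), match_mode = "strict",
                            threshold_pct = 0.050, decision_margin = 0.2,
                            clade_threshold = 50,
                            marker_min_abundance = 1e-4,
                            out_dir = "xenomir_out", seed = 1L) {
  stopifnot(threshold_pct >= 0, decision_margin >= 0, decision_margin <= 2,
            clade_threshold >= 0, clade_threshold <= 100)
  for (p in c(catalog, species_meta, manifest, unlist(reads))) {
    if (!file.exists(p)) abort(sprintf("configured path does not exist: %s", p))
  }
  structure(list(
    catalog = catalog, species_meta = species_meta, manifest = manifest,
    reads = as.list(reads), genomes = genomes, match_mode = match_mode,
    threshold_pct = threshold_pct, decision_margin = decision_margin,
    clade_threshold = clade_threshold,
    marker_min_abundance = marker_min_abundance,
    out_dir = out_dir, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with the `pipeline_config()` fields.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full detection and diagnostics pipeline
#'
#' Stages, in fixed order: parse catalog -> classify each library (strict
#' full-length identity) -> genome-screen plant hits (>=20-nt exclusion,
#' skipped with a flag when no genome is configured for the organism) ->
#' per-library family profiles -> significance flagging -> clade breakdown
#' -> contamination diagnostics. All interchange files are flat TSV; a
#' machine-readable run log carries the package version, seed, thresholds,
#' config hash and per-stage read-count conservation checks (any violation
#' aborts).
#'
#' @param config A `pipeline_config` (or path to its YAML).
#' @return Invisibly, a list with `profiles`, `significant`, `diagnostics`,
#'   `assignments`, `log`. Reports are written under `config$out_dir`:
#'   `assignments/<library>.tsv`, `profiles.tsv`, `significant.tsv`,
#'   `clade_breakdown.tsv`, `contamination.tsv`, `marker_traces.json`,
#'   `run_log.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(config$out_dir, "assignments"), showWarnings = FALSE)
  provenance <- list(
    package = "xenomir",
    version = as.character(utils::packageVersion("xenomir")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    thresholds = config[c("threshold_pct", "decision_margin",
                          "clade_threshold", "marker_min_abundance")],
    match_mode = config$match_mode
  )

  catalog <- read_mirna_catalog(config$catalog, config$species_meta)
  index <- build_sequence_index(catalog)
  manifest <- readr::read_tsv(config$manifest,
                              col_types = readr::cols(.default = "c"),
                              progress = FALSE)
  required <- c("run_id", "library_id", "organism", "role", "diet")
  missing <- setdiff(required, names(manifest))
  if (length(missing) > 0) {
    abort(paste("manifest is missing column(s):", paste(missing, collapse = ", ")))
  }
  manifest$diet[manifest$diet %in% c("", "NA")] <- NA_character_

  genome_indices <- map(config$genomes, build_genome_index)
  conservation <- list()
  assignments <- list()
  genome_screen_skipped <- character()

  for (lib in names(config$reads)) {
    reads <- read_srna_reads(config$reads[[lib]])
    org <- manifest$organism[manifest$library_id == lib][1]
    gidx <- genome_indices[[org]]
    if (is.null(gidx)) genome_screen_skipped <- c(genome_screen_skipped, lib)
    asn <- classify_library(reads, index, gidx,
                            match_mode = config$match_mode)
    if (sum(asn$count) != sum(reads$count)) {
      abort(sprintf("read-count conservation violated in classify for %s", lib))
    }
    conservation[[lib]] <- list(reads_in = sum(reads$count),
                                reads_assigned = sum(asn$count),
                                conserved = TRUE)
    write_assignments_tsv(asn, file.path(config$out_dir, "assignments",
                                         paste0(lib, ".tsv")))
    assignments[[lib]] <- asn
  }

  profiles <- profile_libraries(assignments) |>
    mutate(genome_screen_skipped = .data$library_id %in% genome_screen_skipped)
  readr::write_tsv(profiles, file.path(config$out_dir, "profiles.tsv"),
                   na = "", progress = FALSE)

  significant <- flag_significant(profiles, config$threshold_pct)
  readr::write_tsv(significant, file.path(config$out_dir, "significant.tsv"),
                   na = "", progress = FALSE)

  breakdowns <- imap(assignments, function(a, id) {
    bd <- clade_breakdown(a, catalog)
    if (nrow(bd) > 0) mutate(bd, library_id = id) else NULL
  }) |> purrr::compact() |> list_rbind()
  if (is.null(breakdowns) || nrow(breakdowns) == 0) {
    breakdowns <- tibble(clade = character(), reads = numeric(),
                         percent = numeric(), library_id = character())
  }
  readr::write_tsv(breakdowns,
                   file.path(config$out_dir, "clade_breakdown.tsv"),
                   progress = FALSE)

  diagnostics <- diagnose_run(
    assignments, manifest, catalog,
    decision_margin = config$decision_margin,
    clade_threshold = config$clade_threshold,
    marker_min_abundance = config$marker_min_abundance
  )
  readr::write_tsv(tidy(diagnostics),
                   file.path(config$out_dir, "contamination.tsv"),
                   na = "", progress = FALSE)
  jsonlite::write_json(
    map(diagnostics$marker_traces, function(tr) {
      list(marker_sequence = tr$marker_sequence,
           source_libraries = tr$source_libraries,
           per_library = tr$per_library)
    }),
    file.path(config$out_dir, "marker_traces.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )

  log <- c(provenance, list(
    libraries = names(config$reads),
    genome_screen_skipped = genome_screen_skipped,
    bleed_rate_estimate = diagnostics$bleed_rate,
    conservation = conservation
  ))
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(profiles = profiles, significant = significant,
                 diagnostics = diagnostics, assignments = assignments,
                 log = log))
}
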