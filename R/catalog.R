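#' Normalize a miRNA identifier to its family key
#'
#' Collapses miRBase-style identifiers to the family designation used for
#' per-family counting: the species prefix (text before the first dash, when it
#' looks like a species code) is dropped, a single trailing lowercase variant
#' letter after a digit is removed (`miR168a` -> `miR168`), and a trailing
#' `-1`/`-2` locus suffix is removed. Arm suffixes `-3p`/`-5p` are retained, so
#' `dme-miR-8-5p` normalizes to `miR-8-5p`, distinct from `miR-8-3p`.
#' Applying the function to an already-normalized family key returns it
#' unchanged. Plant-style (`miR168`) and animal-style (`miR-279`) spellings are
#' kept verbatim; no cross-style unification is attempted.
#'
#' @param mirna_id Character vector of miRNA identifiers or family keys.
#' @return Character vector of family keys.
#' @export
#' @examples
#' mirna_family(c("zma-miR168a", "ath-miR168b", "dme-miR-8-5p", "miR168"))
mirna_family <- function(mirna_id) {
  name <- sub("^[a-z0-9]{2,4}-(?=(miR|mir|let|lin|bantam|iab))", "",
              mirna_id, perl = TRUE)
  arm <- stringr::str_extract(name, "-[35]p$")
  core <- ifelse(is.na(arm), name, stringr::str_remove(name, "-[35]p$"))
  # locus suffix: only -1/-2, and never when the numeric part itself is 1/2
  stripped <- stringr::str_remove(core, "(?<=[0-9a-z])-[12]$")
  core <- ifelse(grepl("[0-9]", stripped), stripped, core)
  core <- stringr::str_remove(core, "(?<=[0-9])[a-z]$")
  ifelse(is.na(arm), core, paste0(core, arm))
}

species_of <- function(mirna_id) {
  no_dash <- !grepl("-", mirna_id, fixed = TRUE)
  if (any(no_dash)) {
    abort(sprintf("malformed miRNA id (no '-' separator): %s",
                  paste(head(mirna_id[no_dash], 3), collapse = ", ")))
  }
  sub("-.*$", "", mirna_id)
}

#' Read a species metadata table
#'
#' @param path Tab-separated file with header columns `species_code`,
#'   `kingdom` (`plant`/`animal`) and `clade` (`monocot`/`dicot`/
#'   `not_applicable`).
#' @return A tibble with those three columns.
#' @export
read_species_meta <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  required <- c("species_code", "kingdom", "clade")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    abort(paste("species metadata is missing column(s):",
                paste(missing, collapse = ", ")))
  }
  validate_species_meta(meta[required])
}

validate_species_meta <- function(meta) {
  meta <- as_tibble(meta)
  bad_k <- setdiff(unique(meta$kingdom), c("plant", "animal"))
  bad_c <- setdiff(unique(meta$clade), c("monocot", "dicot", "not_applicable"))
  if (length(bad_k) > 0) abort(paste("unknown kingdom:", paste(bad_k, collapse = ", ")))
  if (length(bad_c) > 0) abort(paste("unknown clade:", paste(bad_c, collapse = ", ")))
  meta
}

new_catalog <- function(records, species_meta) {
  out <- as_tibble(records)
  attr(out, "species_meta") <- as_tibble(species_meta)
  class(out) <- c("xmir_catalog", class(tibble()))
  out
}

#' Species metadata attached to a catalog
#'
#' @param catalog An `xmir_catalog`.
#' @return The species metadata tibble (`species_code`, `kingdom`, `clade`).
#' @export
species_meta <- function(catalog) {
  attr(catalog, "species_meta")
}

#' Parse a mature-miRNA FASTA into an annotated catalog
#'
#' Reads a miRBase-dialect mature FASTA (header `>id description`, DNA or RNA
#' alphabet) and annotates every record with its species code, normalized
#' family key, kingdom and clade. Sequences are upper-cased with T converted
#' to U. Records duplicated as identical (id, sequence) pairs are collapsed
#' to one.
#'
#' @param fasta Path to the mature FASTA file.
#' @param species_meta A species metadata tibble (see [read_species_meta()]),
#'   or a path to one. Every species code occurring in the FASTA must be
#'   covered; an unknown code is an error.
#' @return An `xmir_catalog`: a tibble with columns `mirna_id`,
#'   `species_code`, `family`, `kingdom`, `clade`, `sequence`, carrying the
#'   species metadata as an attribute.
#' @export
#' @examples
#' fa <- system.file("extdata", "mature_synthetic.fa", package = "xenomir")
#' meta <- system.file("extdata", "species_meta.tsv", package = "xenomir")
#' cat <- read_mirna_catalog(fa, meta)
#' dplyr::count(cat, kingdom, clade)
read_mirna_catalog <- function(fasta, species_meta) {
  if (is.character(species_meta) && length(species_meta) == 1 &&
      file.exists(species_meta)) {
    species_meta <- read_species_meta(species_meta)
  }
  species_meta <- validate_species_meta(species_meta)

  seqs <- Biostrings::readBStringSet(fasta)
  if (length(seqs) == 0) {
    return(new_catalog(
      tibble(mirna_id = character(), species_code = character(),
             family = character(), kingdom = character(),
             clade = character(), sequence = character()),
      species_meta
    ))
  }
  ids <- stringr::str_split_i(names(seqs), "\\s+", 1)
  sequence <- unname(normalize_rna(as.character(seqs)))
  assert_rna_alphabet(sequence, "mature sequence")

  records <- tibble(
    mirna_id = ids,
    species_code = species_of(ids),
    family = mirna_family(ids),
    sequence = sequence
  )
  records <- distinct(records, .data$mirna_id, .data$sequence, .keep_all = TRUE)

  unknown <- setdiff(unique(records$species_code), species_meta$species_code)
  if (length(unknown) > 0) {
    abort(sprintf("species code(s) not in species metadata: %s",
                  paste(unknown, collapse = ", ")))
  }
  records <- left_join(records, species_meta, by = "species_code")
  new_catalog(
    select(records, "mirna_id", "species_code", "family", "kingdom",
           "clade", "sequence"),
    species_meta
  )
}

#' Write a catalog back to FASTA or to a summary TSV
#'
#' `write_catalog_fasta()` emits `>mirna_id` headers with the RNA-alphabet
#' mature sequence; re-parsing the file with the same species metadata
#' round-trips the record set. `write_catalog_tsv()` emits one row per record.
#'
#' @param catalog An `xmir_catalog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog_fasta <- function(catalog, path) {
  lines <- as.vector(rbind(paste0(">", catalog$mirna_id), catalog$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_catalog_fasta
#' @export
write_catalog_tsv <- function(catalog, path) {
  readr::write_tsv(as_tibble(catalog), path, progress = FALSE)
  invisible(path)
}

#' Clades carrying a given mature sequence
#'
#' Looks up which plant clades (monocot, dicot) contain a catalog record whose
#' mature sequence is exactly the query. This is the origin-attribution
#' primitive behind monocot/dicot assignment of miR168-style variants: the two
#' canonical 21-nt miR168 sequences differ at two positions and partition
#' cleanly between the clades.
#'
#' @param sequence A single RNA/DNA-alphabet sequence.
#' @param catalog An `xmir_catalog`.
#' @return Character vector of clades (possibly empty) among plant records
#'   holding the sequence.
#' @export
sequence_clades <- function(sequence, catalog) {
  s <- normalize_rna(sequence)
  hits <- filter(catalog, .data$kingdom == "plant", .data$sequence == s)
  sort(unique(hits$clade))
}

#' Hamming distance between equal-length sequences
#'
#' @param seq_a,seq_b Sequences of equal length (same alphabet).
#' @return Integer count of differing positions.
#' @export
#' @examples
#' hamming_distance("UCGCUUGGUGCAGGUCGGGAA", "UCGCUUGGUGCAGAUCGGGAC") # 2
hamming_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) {
    abort("hamming distance undefined for sequences of unequal length")
  }
  sum(utf8ToInt(seq_a) != utf8ToInt(seq_b))
}

#' Sequences shared identically across kingdoms
#'
#' Scans the catalog for mature sequences carried by at least one plant AND
#' one animal record. A non-empty result means exact-match read classification
#' cannot distinguish the kingdoms for those sequences (reads matching them
#' are categorized `ambiguous_kingdom` downstream).
#'
#' @param catalog An `xmir_catalog`.
#' @return A tibble with columns `sequence`, `plant_ids`, `animal_ids`
#'   (comma-collapsed id lists); zero rows when the kingdoms' sequence sets
#'   are disjoint.
#' @export
cross_kingdom_identical <- function(catalog) {
  by_seq <- catalog |>
    group_by(.data$sequence) |>
    summarise(
      plant_ids = collapse_set(.data$mirna_id[.data$kingdom == "plant"]),
      animal_ids = collapse_set(.data$mirna_id[.data$kingdom == "animal"]),
      .groups = "drop"
    ) |>
    filter(!is.na(.data$plant_ids), !is.na(.data$animal_ids))
  arrange(by_seq, .data$sequence)
}
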