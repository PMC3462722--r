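#' Build an exact-match lookup over catalog mature sequences
#'
#' Precomputes, per distinct mature sequence, which records carry it and the
#' derived annotation a read assignment needs (kingdoms present, plant/animal
#' family keys, plant clades). Lookup is by hashed match, independent of
#' catalog order.
#'
#' @param catalog An `xmir_catalog` with at least one record.
#' @return A `xmir_seq_index`: a tibble keyed by `sequence` with columns
#'   `has_plant`, `has_animal`, `plant_families`, `animal_families`,
#'   `clades`, `matched_ids`.
#' @export
build_sequence_index <- function(catalog) {
  if (nrow(catalog) == 0) abort("cannot index an empty catalog")
  idx <- catalog |>
    group_by(.data$sequence) |>
    summarise(
      has_plant = any(.data$kingdom == "plant"),
      has_animal = any(.data$kingdom == "animal"),
      plant_families = collapse_set(.data$family[.data$kingdom == "plant"]),
      animal_families = collapse_set(.data$family[.data$kingdom == "animal"]),
      clades = collapse_set(.data$clade[.data$kingdom == "plant"]),
      matched_ids = collapse_set(.data$mirna_id),
      .groups = "drop"
    )
  class(idx) <- c("xmir_seq_index", class(idx))
  idx
}

#' Build a k-mer index over a host genome
#'
#' Stores the set of all length-`k` substrings of the genome, both strands, in
#' the DNA alphabet. A read "matches the genome" when any of its length-`k`
#' windows is in this set, i.e. when read and genome share a contiguous exact
#' match of at least `k` nt on either strand. The default `k = 20` implements
#' the host-genome exclusion rule: putative plant-miRNA reads with a >=20-nt
#' perfect genome match are attributed to the host genome, not the diet.
#'
#' @param genome Character vector of genome sequences (multi-record genomes
#'   are allowed), or a path to a genome FASTA.
#' @param k Minimum exact-match length (default 20).
#' @return An `xmir_genome_index` (list with `k` and the k-mer set).
#' @export
build_genome_index <- function(genome, k = 20L) {
  is_seq <- length(genome) >= 1 && all(!grepl("[^ACGTUNacgtun]", genome))
  if (!is_seq && length(genome) == 1 && file.exists(genome)) {
    genome <- as.character(Biostrings::readBStringSet(genome))
  }
  genome <- normalize_dna(genome)
  kmers_of <- function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, 1:(n - k + 1), k:n)
  }
  both <- c(genome, revcomp_dna(genome))
  kmers <- unique(unlist(lapply(both, kmers_of), use.names = FALSE))
  structure(list(k = as.integer(k), kmers = kmers),
            class = "xmir_genome_index")
}

#' Does a read share a >=k-nt exact match with the host genome?
#'
#' @param sequence Character vector of read sequences (DNA or RNA alphabet).
#' @param genome_index An `xmir_genome_index` from [build_genome_index()].
#' @return Logical vector; reads shorter than `k` are `FALSE`. Both genome
#'   strands were indexed, so a reverse-complement match also returns `TRUE`.
#' @export
has_genome_match <- function(sequence, genome_index) {
  k <- genome_index$k
  s <- normalize_dna(sequence)
  vapply(s, function(x) {
    n <- nchar(x)
    if (n < k) return(FALSE)
    any(substring(x, 1:(n - k + 1), k:n) %in% genome_index$kmers)
  }, logical(1), USE.NAMES = FALSE)
}

assignment_categories <- c("animal_mirna", "plant_mirna",
                           "host_genome_derived", "ambiguous_kingdom",
                           "unassigned")

#' Classify a library of reads against the catalog
#'
#' Each read is compared against the catalog by strict full-length identity
#' (after T->U normalization): a read is a miRNA match iff its sequence equals
#' a mature sequence exactly — same length, zero mismatches. Reads matching
#' only animal records are `animal_mirna`; reads matching only plant records
#' are screened against the host genome index and become `host_genome_derived`
#' on a >=20-nt hit, otherwise `plant_mirna`; reads matching records in both
#' kingdoms are `ambiguous_kingdom` (excluded from both kingdom totals
#' downstream); everything else is `unassigned`. Animal-matching reads are
#' never genome-screened.
#'
#' With `match_mode = "contains"`, a read with no strict match is additionally
#' accepted when it contains a full mature sequence with flanking bases
#' (untrimmed-read tolerance); strict equality remains the default contract.
#'
#' @param reads Tibble with `read_id`, `sequence`, `count` (see
#'   [read_srna_reads()]); `count` defaults to 1 when absent.
#' @param index An `xmir_seq_index`, or an `xmir_catalog` (indexed on the fly).
#' @param genome_index Optional `xmir_genome_index` for the host organism.
#'   When `NULL` the genome screen is skipped and plant matches are reported
#'   unfiltered.
#' @param match_mode `"strict"` (default) or `"contains"`.
#' @return An `xmir_assignments` tibble: `read_id`, `sequence`, `count`,
#'   `category`, `family`, `clades`, `matched_ids`. One row per input read,
#'   order preserved, total multiplicity conserved.
#' @export
classify_library <- function(reads, index, genome_index = NULL,
                             match_mode = c("strict", "contains")) {
  match_mode <- match.arg(match_mode)
  if (inherits(index, "xmir_catalog")) index <- build_sequence_index(index)
  reads <- as_tibble(reads)
  if (!"count" %in% names(reads)) reads$count <- 1L
  if (nrow(reads) == 0) {
    return(structure(
      tibble(read_id = character(), sequence = character(),
             count = integer(), category = character(),
             family = character(), clades = character(),
             matched_ids = character()),
      class = c("xmir_assignments", class(tibble()))
    ))
  }
  empty <- !nzchar(reads$sequence) | is.na(reads$sequence)
  if (any(empty)) {
    abort(sprintf("empty read sequence for read id(s): %s",
                  paste(head(reads$read_id[empty], 3), collapse = ", ")))
  }

  norm <- normalize_rna(reads$sequence)
  hit <- match(norm, index$sequence)

  if (match_mode == "contains") {
    unmatched <- which(is.na(hit))
    if (length(unmatched) > 0) {
      for (j in seq_len(nrow(index))) {
        if (length(unmatched) == 0) break
        found <- stringr::str_detect(norm[unmatched],
                                     stringr::fixed(index$sequence[j]))
        if (any(found)) {
          hit[unmatched[found]] <- j
          unmatched <- unmatched[!found]
        }
      }
    }
  }

  has_plant <- !is.na(hit) & index$has_plant[hit]
  has_animal <- !is.na(hit) & index$has_animal[hit]

  category <- rep("unassigned", nrow(reads))
  category[has_animal & !has_plant] <- "animal_mirna"
  category[has_plant & has_animal] <- "ambiguous_kingdom"
  plant_only <- has_plant & !has_animal
  if (any(plant_only) && !is.null(genome_index)) {
    genomic <- has_genome_match(norm[plant_only], genome_index)
    category[plant_only] <- ifelse(genomic, "host_genome_derived",
                                   "plant_mirna")
  } else {
    category[plant_only] <- "plant_mirna"
  }

  family <- rep(NA_character_, nrow(reads))
  family[has_plant & !has_animal] <- index$plant_families[hit[has_plant & !has_animal]]
  family[has_animal & !has_plant] <- index$animal_families[hit[has_animal & !has_plant]]

  out <- tibble(
    read_id = reads$read_id,
    sequence = norm,
    count = as.integer(reads$count),
    category = category,
    family = family,
    clades = ifelse(has_plant, index$clades[hit], NA_character_),
    matched_ids = ifelse(is.na(hit), NA_character_, index$matched_ids[hit])
  )
  class(out) <- c("xmir_assignments", class(tibble()))
  out
}

#' Classify a single read
#'
#' Convenience wrapper over [classify_library()] for one read.
#'
#' @param sequence The read sequence.
#' @param index,genome_index,match_mode As in [classify_library()].
#' @param read_id,count Read identity and multiplicity.
#' @return A one-row `xmir_assignments` tibble.
#' @export
classify_read <- function(sequence, index, genome_index = NULL,
                          read_id = "read1", count = 1L,
                          match_mode = "strict") {
  classify_library(
    tibble(read_id = read_id, sequence = sequence, count = count),
    index, genome_index, match_mode = match_mode
  )
}

#' Write / read the per-read assignment interchange TSV
#'
#' @param assignments An `xmir_assignments` tibble.
#' @param path File path.
#' @return `path` (write) or the assignments tibble (read).
#' @export
write_assignments_tsv <- function(assignments, path) {
  readr::write_tsv(as_tibble(assignments), path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_assignments_tsv
#' @export
read_assignments_tsv <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    read_id = "c", sequence = "c", count = "i", category = "c",
    family = "c", clades = "c", matched_ids = "c"
  ), na = "", progress = FALSE)
  bad <- setdiff(out$category, c(assignment_categories, NA))
  if (length(bad) > 0) {
    abort(paste("invalid category value(s) in assignment file:",
                paste(bad, collapse = ", ")))
  }
  class(out) <- c("xmir_assignments", class(out))
  out
}
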