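#' Read small-RNA reads from FASTA or FASTQ
#'
#' Accepts adapter-trimmed reads either as FASTQ (qualities ignored) or as
#' FASTA, optionally in the collapsed-read dialect where a `_xN` suffix on the
#' header carries the read multiplicity (`>read1_x512`). Formats are detected
#' from the first character of the file unless `format` is given.
#'
#' @param path Path to the reads file.
#' @param format `"auto"` (default), `"fasta"` or `"fastq"`.
#' @return A tibble with columns `read_id`, `sequence`, `count`. For the
#'   `_xN` dialect the suffix is stripped from `read_id` and becomes `count`;
#'   otherwise every record has `count = 1`.
#' @export
read_srna_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (startsWith(first, "@")) "fastq" else "fasta"
  }
  seqs <- Biostrings::readBStringSet(path, format = format)
  ids <- stringr::str_split_i(names(seqs), "\\s+", 1)
  counts <- suppressWarnings(
    as.integer(stringr::str_match(ids, "_x(\\d+)$")[, 2])
  )
  tibble(
    read_id = ifelse(is.na(counts), ids, stringr::str_remove(ids, "_x\\d+$")),
    sequence = unname(toupper(as.character(seqs))),
    count = ifelse(is.na(counts), 1L, counts)
  )
}

#' Write reads as collapsed FASTA
#'
#' Emits the `_xN` collapsed-count FASTA dialect (or FASTQ with constant
#' quality `I`), the inverse of [read_srna_reads()].
#'
#' @param reads A tibble with `read_id`, `sequence`, `count`.
#' @param path Output path.
#' @param format `"fasta"` (default) or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_srna_reads <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  id <- paste0(reads$read_id, "_x", reads$count)
  if (format == "fasta") {
    lines <- as.vector(rbind(paste0(">", id), reads$sequence))
  } else {
    qual <- strrep("I", nchar(reads$sequence))
    lines <- as.vector(rbind(paste0("@", id), reads$sequence, "+", qual))
  }
  writeLines(lines, path)
  invisible(path)
}
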