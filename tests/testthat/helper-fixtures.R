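# Shared fixtures and independent oracles, built in code.

MONOCOT_MIR168 <- "UCGCUUGGUGCAGAUCGGGAC"
DICOT_MIR168 <- "UCGCUUGGUGCAGGUCGGGAA"

fixture_catalog <- function() {
  read_mirna_catalog(
    system.file("extdata", "mature_synthetic.fa", package = "xenomir"),
    system.file("extdata", "species_meta.tsv", package = "xenomir")
  )
}

tiny_species_meta <- function() {
  tibble::tibble(
    species_code = c("osa", "zma", "ath", "gma", "anm", "xxx"),
    kingdom = c("plant", "plant", "plant", "plant", "animal", "plant"),
    clade = c("monocot", "monocot", "dicot", "dicot", "not_applicable",
              "monocot")
  )
}

write_fasta <- function(ids, seqs, path = withr::local_tempfile(fileext = ".fa",
                                                                .local_envir = parent.frame())) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

random_reads <- function(n, len_range = 18:24) {
  len <- sample(len_range, n, replace = TRUE)
  seqs <- vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
  tibble::tibble(read_id = sprintf("r%04d", seq_len(n)), sequence = seqs,
                 count = sample(1:5, n, replace = TRUE))
}

# --- independent oracles -------------------------------------------------

# genome match by brute-force scan of every shared substring, both strands
oracle_genome_match <- function(read, genome, k = 20) {
  read <- chartr("Uu", "TT", toupper(read))
  genome <- chartr("Uu", "TT", toupper(genome))
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", genome), "")[[1]]),
              collapse = "")
  n <- nchar(read)
  if (n < k) return(FALSE)
  wins <- substring(read, 1:(n - k + 1), k:n)
  any(vapply(wins, function(w) {
    grepl(w, genome, fixed = TRUE) || grepl(w, rc, fixed = TRUE)
  }, logical(1)))
}

# classification by comparing the read against every catalog record in turn
oracle_classify <- function(read_seq, catalog, genome = NULL, k = 20) {
  s <- chartr("Tt", "UU", toupper(read_seq))
  hits <- catalog[catalog$sequence == s, ]
  if (nrow(hits) == 0) return("unassigned")
  kingdoms <- unique(hits$kingdom)
  if (length(kingdoms) == 2) return("ambiguous_kingdom")
  if (kingdoms == "animal") return("animal_mirna")
  if (!is.null(genome) && oracle_genome_match(s, genome, k)) {
    return("host_genome_derived")
  }
  "plant_mirna"
}

# all-pairs cross-kingdom identity
oracle_cross_kingdom <- function(catalog) {
  plant <- catalog[catalog$kingdom == "plant", ]
  animal <- catalog[catalog$kingdom == "animal", ]
  shared <- character()
  for (i in seq_len(nrow(plant))) {
    for (j in seq_len(nrow(animal))) {
      if (plant$sequence[i] == animal$sequence[j]) {
        shared <- c(shared, plant$sequence[i])
      }
    }
  }
  sort(unique(shared))
}

# competition rank by sort-and-insert
oracle_rank <- function(x, counts) {
  which(sort(c(x, counts), decreasing = TRUE) == x)[1]
}
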