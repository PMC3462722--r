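# Synthetic multiplexed sRNA runs with known ground truth.
#
# The simulator emulates the study design this package diagnoses: animal
# libraries carrying an endogenous miRNA background, dietary plant-miRNA
# spike-ins at fractions of order 0.05-0.5% of animal miRNA reads,
# host-genome-derived reads, length-18-30 noise reads, and — within a
# multiplexed group — inter-library bleed at a configurable rate, plus
# co-multiplexed plant libraries (the bleed donors).

random_seq <- function(n, len, alphabet = c("A", "C", "G", "U")) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Specify one simulated library
#'
#' @param library_id Unique library identifier.
#' @param organism Species code of the sampled organism (must be covered by
#'   the catalog's species metadata).
#' @param role `"animal_sample"` or `"plant_source"` (a co-multiplexed plant
#'   library, e.g. a diet or lettuce library).
#' @param n_reads Library depth (read slots before bleed arrivals).
#' @param family_profile Named numeric weights over miRNA families: the
#'   library's own expression profile (animal families for animal samples,
#'   plant families for plant sources). Not all zero.
#' @param dietary_spike For animal samples: `list(species = , fraction = )`,
#'   the diet plant's species code and the spike as a fraction of the
#'   library's animal-miRNA reads (Table-1-scale values are 0.0005-0.005).
#'   `NULL` for no dietary uptake.
#' @param genome_read_fraction Fraction of reads drawn as random substrings
#'   of the organism's toy genome.
#' @param unassigned_fraction Fraction of random noise reads (18-30 nt).
#' @param marker Optional `list(sequence = , weight = )`: a library-specific
#'   non-miRNA sequence emitted at the given fraction of reads (the
#'   "lettuce-specific sequence" device for marker tracing).
#' @return A `library_spec` list.
#' @export
library_spec <- function(library_id, organism, role = c("animal_sample", "plant_source"),
                         n_reads = 1e5, family_profile,
                         dietary_spike = NULL,
                         genome_read_fraction = 0, unassigned_fraction = 0,
                         marker = NULL) {
  role <- match.arg(role)
  stopifnot(n_reads >= 1, all(family_profile >= 0), any(family_profile > 0))
  fr <- c(genome_read_fraction, unassigned_fraction,
          dietary_spike$fraction %||% 0, marker$weight %||% 0)
  if (any(fr < 0) || sum(fr) > 1) {
    abort("library fractions must be in [0,1] and jointly at most 1")
  }
  structure(list(
    library_id = library_id, organism = organism, role = role,
    n_reads = as.integer(n_reads), family_profile = family_profile,
    dietary_spike = dietary_spike,
    genome_read_fraction = genome_read_fraction,
    unassigned_fraction = unassigned_fraction,
    marker = marker
  ), class = "library_spec")
}

#' Assemble a simulation configuration
#'
#' @param libraries List of [library_spec()]s (unique ids).
#' @param catalog An `xmir_catalog` covering every species the specs use.
#' @param seed Integer seed; together with the config it fully determines
#'   the simulated run (two invocations are identical).
#' @param bleed_rate Per-read-slot probability, within the multiplex group,
#'   of receiving an extra read drawn from the pooled co-multiplexed foreign
#'   libraries (donors weighted by size). In \[0, 0.05\].
#' @param toy_genomes Named list (organism -> genome sequence) for
#'   `genome_read_fraction` draws.
#' @param run_id Run label written into the manifest.
#' @param comultiplexed Were the libraries pooled in one run? Bleed only
#'   applies when TRUE.
#' @return A `simulation_config`.
#' @export
simulation_config <- function(libraries, catalog, seed = 1L,
                              bleed_rate = 0, toy_genomes = list(),
                              run_id = "run1", comultiplexed = TRUE) {
  ids <- map_chr(libraries, "library_id")
  stopifnot(!anyDuplicated(ids), bleed_rate >= 0, bleed_rate <= 0.05)
  meta <- species_meta(catalog)
  for (spec in libraries) {
    if (!spec$organism %in% meta$species_code) {
      abort(sprintf("library %s: organism '%s' absent from catalog species metadata",
                    spec$library_id, spec$organism))
    }
    diet <- spec$dietary_spike$species
    if (!is.null(diet) && !diet %in% meta$species_code) {
      abort(sprintf("library %s: diet species '%s' absent from catalog species metadata",
                    spec$library_id, diet))
    }
    if (spec$genome_read_fraction > 0 && is.null(toy_genomes[[spec$organism]])) {
      abort(sprintf("library %s requests genome reads but no toy genome for '%s'",
                    spec$library_id, spec$organism))
    }
  }
  structure(list(
    libraries = libraries, catalog = catalog, seed = as.integer(seed),
    bleed_rate = bleed_rate, toy_genomes = toy_genomes,
    run_id = run_id, comultiplexed = comultiplexed
  ), class = "simulation_config")
}

# One mature sequence per (family, record-set) cell: deterministic choice of
# the lexicographically-smallest id keeps draws reproducible across catalog
# orderings.
family_sequences <- function(catalog, kingdom, clade = NULL) {
  recs <- filter(catalog, .data$kingdom == !!kingdom)
  if (!is.null(clade)) recs <- filter(recs, .data$clade == !!clade)
  recs |>
    arrange(.data$mirna_id) |>
    group_by(.data$family) |>
    summarise(sequence = .data$sequence[1], .groups = "drop")
}

draw_family_reads <- function(n, profile, fam_seqs) {
  fam_seqs <- filter(fam_seqs, .data$family %in% names(profile))
  if (nrow(fam_seqs) == 0 || n == 0) {
    return(tibble(sequence = character(), count = integer()))
  }
  w <- profile[fam_seqs$family]
  if (sum(w) == 0) return(tibble(sequence = character(), count = integer()))
  counts <- as.integer(rmultinom(1, n, w))
  tibble(sequence = fam_seqs$sequence, count = counts) |>
    filter(.data$count > 0)
}

simulate_one_library <- function(spec, catalog, toy_genomes) {
  meta <- species_meta(catalog)
  clade_of <- function(code) meta$clade[meta$species_code == code][1]

  g <- spec$genome_read_fraction
  u <- spec$unassigned_fraction
  m <- spec$marker$weight %||% 0
  s <- spec$dietary_spike$fraction %||% 0

  own_frac <- 1 - g - u - m
  if (spec$role == "animal_sample") {
    a <- own_frac / (1 + s)     # endogenous animal miRNA share
    p <- a * s                  # dietary plant share (fraction s OF a)
    comp <- c(animal = a, diet = p, genome = g, noise = u, marker = m)
  } else {
    comp <- c(plant = own_frac, genome = g, noise = u, marker = m)
  }
  n_comp <- as.integer(rmultinom(1, spec$n_reads, comp))
  names(n_comp) <- names(comp)

  parts <- list()
  if (spec$role == "animal_sample") {
    parts$`own-animal` <- draw_family_reads(
      n_comp[["animal"]], spec$family_profile,
      family_sequences(catalog, "animal")
    )
    if (n_comp[["diet"]] > 0) {
      diet_clade <- clade_of(spec$dietary_spike$species)
      spike_profile <- spec$dietary_spike$profile
      fam_seqs <- family_sequences(catalog, "plant", diet_clade)
      if (is.null(spike_profile)) {
        spike_profile <- setNames(rep(1, nrow(fam_seqs)), fam_seqs$family)
      }
      parts$`own-diet` <- draw_family_reads(n_comp[["diet"]], spike_profile,
                                            fam_seqs)
    }
  } else {
    own_clade <- clade_of(spec$organism)
    parts$`own-plant` <- draw_family_reads(
      n_comp[["plant"]], spec$family_profile,
      family_sequences(catalog, "plant", own_clade)
    )
  }
  if (n_comp[["genome"]] > 0) {
    gseq <- normalize_dna(toy_genomes[[spec$organism]])
    len <- sample(20:24, n_comp[["genome"]], replace = TRUE)
    start <- map_int(len, function(l) sample.int(nchar(gseq) - l + 1L, 1L))
    sub <- normalize_rna(substring(gseq, start, start + len - 1L))
    parts$genome <- tibble(sequence = sub, count = 1L)
  }
  if (n_comp[["noise"]] > 0) {
    len <- sample(18:30, n_comp[["noise"]], replace = TRUE)
    noise <- random_seq(n_comp[["noise"]], 30)
    noise <- substring(noise, 1, len)
    # guarantee exact-zero plant calls in null configurations
    clash <- noise %in% catalog$sequence
    while (any(clash)) {
      noise[clash] <- substring(random_seq(sum(clash), 30), 1, len[clash])
      clash <- noise %in% catalog$sequence
    }
    parts$noise <- tibble(sequence = noise, count = 1L)
  }
  if (n_comp[["marker"]] > 0) {
    parts$marker <- tibble(sequence = normalize_rna(spec$marker$sequence),
                           count = n_comp[["marker"]])
  }
  imap(parts, function(p, origin) mutate(p, origin = origin)) |>
    list_rbind() |>
    group_by(.data$sequence, .data$origin) |>
    summarise(count = sum(.data$count), .groups = "drop")
}

#' Simulate a multiplexed small-RNA run with ground truth
#'
#' Draws every library's reads multinomially from its configured composition,
#' then applies inter-library bleed within the multiplex group: each
#' recipient read slot receives, with probability `bleed_rate * (donor size /
#' foreign pool size)` per donor, an extra read drawn from that donor's own
#' composition. The per-slot bleed probabilities over all donors sum to
#' `bleed_rate`, so the configured rate is directly the expected bled
#' fraction and is what [estimate_bleed_rate()] recovers. Reads are returned
#' collapsed (one row per distinct sequence with a count) in the DNA
#' alphabet, as a sequencer would emit them.
#'
#' @param config A [simulation_config()].
#' @return A `xmir_simulation`: list with `reads` (named list of
#'   `read_id`/`sequence`/`count` tibbles), `truth` (tibble `library_id`,
#'   `sequence`, `origin`, `count`; origins are `own-animal`, `own-diet`,
#'   `own-plant`, `genome`, `noise`, `marker`, `bleed-from:<library>`),
#'   `manifest` (consumable by [diagnose_run()]) and the `config`.
#' @export
simulate_run <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  specs <- config$libraries
  ids <- map_chr(specs, "library_id")

  own <- map(specs, simulate_one_library, catalog = config$catalog,
             toy_genomes = config$toy_genomes)
  names(own) <- ids
  sizes <- setNames(map_int(specs, "n_reads"), ids)

  truth <- imap(own, function(tbl, id) mutate(tbl, library_id = id)) |>
    list_rbind()

  if (config$bleed_rate > 0 && config$comultiplexed && length(specs) > 1) {
    bled <- map(ids, function(rid) {
      foreign <- setdiff(ids, rid)
      pool <- sum(sizes[foreign])
      rows <- map(foreign, function(did) {
        nb <- rbinom(1, sizes[[rid]], config$bleed_rate * sizes[[did]] / pool)
        if (nb == 0) return(NULL)
        donor <- own[[did]]
        picks <- as.integer(rmultinom(1, nb, donor$count))
        tibble(sequence = donor$sequence, count = picks,
               origin = paste0("bleed-from:", did), library_id = rid) |>
          filter(.data$count > 0)
      })
      list_rbind(purrr::compact(rows))
    })
    truth <- bind_rows(truth, list_rbind(purrr::compact(bled)))
  }

  reads <- map(ids, function(id) {
    lib <- truth |>
      filter(.data$library_id == id) |>
      group_by(.data$sequence) |>
      summarise(count = sum(.data$count), .groups = "drop") |>
      arrange(.data$sequence)
    tibble(
      read_id = sprintf("%s_seq%05d", id, seq_len(nrow(lib))),
      sequence = normalize_dna(lib$sequence),
      count = as.integer(lib$count)
    )
  })
  names(reads) <- ids

  manifest <- tibble(
    run_id = config$run_id,
    library_id = ids,
    organism = map_chr(specs, "organism"),
    role = map_chr(specs, "role"),
    diet = map_chr(specs, function(s) s$dietary_spike$species %||% NA_character_),
    n_reads = unname(sizes),
    comultiplexed = config$comultiplexed
  )

  structure(list(reads = reads, truth = truth, manifest = manifest,
                 config = config), class = "xmir_simulation")
}

#' Write a simulated run to disk
#'
#' One collapsed FASTA (or FASTQ) per library plus `truth.tsv` and
#' `manifest.tsv`.
#'
#' @param sim An `xmir_simulation`.
#' @param dir Output directory (created if needed).
#' @param format Read file format, `"fasta"` or `"fastq"`.
#' @return `dir`, invisibly.
#' @export
write_run <- function(sim, dir, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "fasta") ".fa" else ".fq"
  for (id in names(sim$reads)) {
    write_srna_reads(sim$reads[[id]], file.path(dir, paste0(id, ext)), format)
  }
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  readr::write_tsv(sim$manifest, file.path(dir, "manifest.tsv"),
                   progress = FALSE)
  invisible(dir)
}

#' Build a toy catalog with the canonical miR168 clade variants
#'
#' Generates unique random 21-nt mature sequences for the requested numbers
#' of animal and plant families. Every generated plant family gets a monocot
#' variant and a dicot variant (distinct sequences), mirroring how real
#' families carry clade-distinguishable sequence variants. The catalog always
#' additionally contains the two canonical miR168 variants — the monocot
#' sequence `UCGCUUGGUGCAGAUCGGGAC` (osa/zma) and the dicot sequence
#' `UCGCUUGGUGCAGGUCGGGAA` (ath/gma), which differ at two positions — so
#' worked examples of clade attribution run against any toy catalog.
#'
#' @param n_animal_families,n_plant_families Family counts, each >= 1.
#' @param seed Integer seed.
#' @return An `xmir_catalog` with species metadata for osa/zma (monocot),
#'   ath/gma/lsa (dicot) and anm (animal).
#' @export
make_toy_catalog <- function(n_animal_families, n_plant_families, seed = 1L) {
  if (n_animal_families < 1 || n_plant_families < 1) {
    abort("need at least one animal and one plant family")
  }
  set.seed(seed)
  mir168_mono <- "UCGCUUGGUGCAGAUCGGGAC"
  mir168_dico <- "UCGCUUGGUGCAGGUCGGGAA"

  n_needed <- n_animal_families + 2 * n_plant_families
  seqs <- unique(random_seq(n_needed * 2, 21))
  seqs <- setdiff(seqs, c(mir168_mono, mir168_dico))
  while (length(seqs) < n_needed) {
    seqs <- setdiff(unique(c(seqs, random_seq(n_needed, 21))),
                    c(mir168_mono, mir168_dico))
  }
  seqs <- seqs[seq_len(n_needed)]

  plant_fams <- sprintf("miR95%02d", seq_len(n_plant_families))
  animal_fams <- sprintf("miR-98%02d", seq_len(n_animal_families))
  mono_sp <- rep_len(c("osa", "zma"), n_plant_families)
  dico_sp <- rep_len(c("ath", "gma"), n_plant_families)

  records <- bind_rows(
    tibble(mirna_id = c("osa-miR168a", "zma-miR168a"),
           sequence = mir168_mono),
    tibble(mirna_id = c("ath-miR168a", "gma-miR168"),
           sequence = mir168_dico),
    tibble(mirna_id = paste0(mono_sp, "-", plant_fams),
           sequence = seqs[seq_len(n_plant_families)]),
    tibble(mirna_id = paste0(dico_sp, "-", plant_fams),
           sequence = seqs[n_plant_families + seq_len(n_plant_families)]),
    tibble(mirna_id = paste0("anm-", animal_fams),
           sequence = seqs[2 * n_plant_families + seq_len(n_animal_families)])
  )
  meta <- tibble(
    species_code = c("osa", "zma", "ath", "gma", "lsa", "anm"),
    kingdom = c("plant", "plant", "plant", "plant", "plant", "animal"),
    clade = c("monocot", "monocot", "dicot", "dicot", "dicot",
              "not_applicable")
  )
  records <- records |>
    mutate(
      species_code = species_of(.data$mirna_id),
      family = mirna_family(.data$mirna_id)
    ) |>
    left_join(meta, by = "species_code") |>
    select("mirna_id", "species_code", "family", "kingdom", "clade",
           "sequence")
  new_catalog(records, meta)
}

#' Build a toy genome with planted k-mers
#'
#' Random ACGT sequence of the given length with each requested k-mer
#' written in verbatim at a recorded (non-overlapping where possible)
#' position, for exercising the >=20-nt host-genome filter with known truth.
#'
#' @param length Genome length (>= 100).
#' @param planted_kmers Character vector of sequences to embed (DNA or RNA
#'   alphabet; stored as DNA). Each must fit within the genome.
#' @param seed Integer seed.
#' @return A list: `sequence` (the genome string) and `planted` (tibble
#'   `kmer`, `start`, `end`).
#' @export
make_toy_genome <- function(length, planted_kmers = character(), seed = 1L) {
  stopifnot(length >= 100)
  planted_kmers <- normalize_dna(planted_kmers)
  if (any(nchar(planted_kmers) > length)) {
    abort("planted k-mer longer than the genome")
  }
  set.seed(seed)
  genome <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                  collapse = "")
  planted <- tibble(kmer = character(), start = integer(), end = integer())
  used <- integer()
  for (km in planted_kmers) {
    l <- nchar(km)
    for (try in 1:100) {
      start <- sample.int(length - l + 1L, 1L)
      span <- start:(start + l - 1L)
      if (!any(span %in% used) || try == 100) break
    }
    used <- c(used, span)
    substr(genome, start, start + l - 1L) <- km
    planted <- bind_rows(planted,
                         tibble(kmer = km, start = start,
                                end = start + l - 1L))
  }
  list(sequence = genome, planted = planted)
}

# Rank-skewed (zipf-like) expression weights: real miRNA profiles are
# dominated by a few families, with a long shallow tail. `ranks` is a
# permutation: the family with rank 1 carries the largest weight.
zipf_weights <- function(families, ranks, s = 1.3) {
  setNames(1 / ranks^s, families)
}

#' Canonical study-condition run configuration
#'
#' The reference multiplexed-run design the package's validation is built
#' around, emulating a run where insect libraries were pooled with their
#' plant diet libraries and a large set of unrelated (lettuce-style) plant
#' libraries: one dominant dicot plant library carrying a library-specific
#' marker sequence, a monocot (corn-style, `zma`) and a dicot (soybean-style,
#' `gma`) diet library, and four animal libraries — two declared corn-fed,
#' two soybean-fed. Each plant species expresses the shared plant families
#' under a species-specific rank-skewed profile, so diet and pooled-run
#' profiles are distinguishable; dietary spikes reproduce the diet library's
#' profile, restricted to the diet's clade variants. Animal libraries carry a
#' 1% host-genome read fraction and 2% unassignable noise.
#'
#' @param catalog A toy catalog from [make_toy_catalog()] (needs `zma`,
#'   `gma`, `lsa`, `anm` species and at least 8 plant and 5 animal families).
#' @param seed Seed for [simulation_config()].
#' @param bleed_rate Within-run bleed rate (0 for a spike-only design).
#' @param spike_fraction Dietary spike as a fraction of animal miRNA reads
#'   (0 for a bleed-only design); 0.002 sits in the observed 0.05-0.5%
#'   plant/animal range.
#' @param n_reads Depth of each animal library; the lettuce-style library is
#'   5x deeper, diet libraries equally deep.
#' @param toy_genome Optional genome string for the animal organism
#'   (generated at 10 kb when NULL).
#' @return A [simulation_config()].
#' @export
example_run_config <- function(catalog, seed = 1L, bleed_rate = 0.001,
                               spike_fraction = 0.002, n_reads = 1e5,
                               toy_genome = NULL) {
  plant_fams <- sort(unique(catalog$family[catalog$kingdom == "plant"]))
  animal_fams <- sort(unique(catalog$family[catalog$kingdom == "animal"]))
  np <- length(plant_fams)
  if (np < 8 || length(animal_fams) < 5) {
    abort("catalog too small for the canonical run design")
  }
  # fixed, species-specific family rank orders (chosen once; mutually
  # rank-uncorrelated linear-congruence permutations)
  perm_of <- function(mult, off) {
    (((seq_len(np) - 1) * mult + off) %% np) + 1
  }
  lettuce_prof <- zipf_weights(plant_fams, perm_of(3, 4))
  corn_prof    <- zipf_weights(plant_fams, perm_of(5, 9))
  soy_prof     <- zipf_weights(plant_fams, perm_of(7, 2))
  host_prof    <- zipf_weights(animal_fams, seq_along(animal_fams))

  marker <- list(sequence = "ACGGUUUAGGCCUAAGCGAUACGG", weight = 0.01)
  if (is.null(toy_genome)) {
    toy_genome <- make_toy_genome(10000, seed = seed + 1000L)$sequence
  }
  spike <- function(species, profile) {
    if (spike_fraction == 0) return(NULL)
    list(species = species, fraction = spike_fraction, profile = profile)
  }
  libs <- list(
    library_spec("lettuce1", "lsa", "plant_source", n_reads * 5,
                 lettuce_prof, marker = marker, unassigned_fraction = 0.02),
    library_spec("corn_diet", "zma", "plant_source", n_reads,
                 corn_prof, unassigned_fraction = 0.02),
    library_spec("soy_diet", "gma", "plant_source", n_reads,
                 soy_prof, unassigned_fraction = 0.02),
    library_spec("insect_corn1", "anm", "animal_sample", n_reads, host_prof,
                 dietary_spike = spike("zma", corn_prof),
                 genome_read_fraction = 0.01, unassigned_fraction = 0.02),
    library_spec("insect_corn2", "anm", "animal_sample", n_reads, host_prof,
                 dietary_spike = spike("zma", corn_prof),
                 genome_read_fraction = 0.01, unassigned_fraction = 0.02),
    library_spec("insect_soy1", "anm", "animal_sample", n_reads, host_prof,
                 dietary_spike = spike("gma", soy_prof),
                 genome_read_fraction = 0.01, unassigned_fraction = 0.02),
    library_spec("insect_soy2", "anm", "animal_sample", n_reads, host_prof,
                 dietary_spike = spike("gma", soy_prof),
                 genome_read_fraction = 0.01, unassigned_fraction = 0.02)
  )
  if (spike_fraction == 0) {
    # declared diets are kept in the manifest even without uptake
    for (i in 4:7) {
      libs[[i]]$dietary_spike <- NULL
    }
  }
  cfg <- simulation_config(libs, catalog, seed = seed,
                           bleed_rate = bleed_rate,
                           toy_genomes = list(anm = toy_genome))
  # diet declarations for the manifest (independent of uptake)
  attr(cfg, "declared_diets") <- c(
    insect_corn1 = "zma", insect_corn2 = "zma",
    insect_soy1 = "gma", insect_soy2 = "gma"
  )
  cfg
}
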