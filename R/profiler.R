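#' Plant reads as a percentage of animal miRNA reads
#'
#' The headline per-library statistic: plant-matching miRNA reads expressed
#' as a percentage of the *animal-only* miRNA reads, i.e.
#' `100 * plant / (total - plant)` where `total` counts animal + plant miRNA
#' reads together. Rounded half-up to 3 decimals, the precision at which
#' per-library summary tables are printed.
#'
#' @param plant_count Plant miRNA read count.
#' @param total_mirna_reads Animal + plant miRNA read count.
#' @return Percentage, 3 decimals.
#' @export
#' @examples
#' percent_of_animal(5342, 1175650) # 0.456
percent_of_animal <- function(plant_count, total_mirna_reads) {
  if (any(total_mirna_reads <= plant_count)) {
    abort("no animal miRNA reads: total must exceed plant count")
  }
  round_half_up(100 * plant_count / (total_mirna_reads - plant_count), 3)
}

#' Share of one family among a library's plant miRNA reads
#'
#' `100 * family_count / plant_total`, rounded half-up to 1 decimal. Half-up
#' rounding matters at the top edge: 2015 of 2016 reads prints as 100.0.
#'
#' @param family_count Reads in the family.
#' @param plant_total All plant miRNA reads in the library.
#' @return Percentage, 1 decimal.
#' @export
#' @examples
#' family_share(2856, 5342) # 53.5
family_share <- function(family_count, plant_total) {
  if (any(plant_total == 0)) {
    abort("family share undefined: library has no plant miRNA reads")
  }
  round_half_up(100 * family_count / plant_total, 1)
}

#' Competition rank of a count among animal miRNA families
#'
#' Rank 1 is the most abundant animal family; ties share the smaller rank
#' (an equal animal family does not push the query down).
#'
#' @param family_count Query read count (e.g. the top plant family's reads).
#' @param animal_family_counts Named or unnamed numeric vector of per-family
#'   animal miRNA read counts; must be non-empty.
#' @return Integer rank.
#' @export
rank_in_animal_families <- function(family_count, animal_family_counts) {
  if (length(animal_family_counts) == 0) {
    abort("animal family counts are empty; rank undefined")
  }
  1L + sum(animal_family_counts > family_count)
}

#' Summarize a classified library into a family-level profile
#'
#' Aggregates per-read assignments into per-family read counts and derives
#' the per-library summary statistics: total miRNA reads (animal + plant),
#' plant reads and their percentage of animal reads, the most abundant plant
#' family with its share of plant reads, its percentage of animal reads, and
#' its competition rank among animal miRNA families.
#' `host_genome_derived` and `ambiguous_kingdom` multiplicities are excluded
#' from both kingdom totals and reported as side counts. Ties for the top
#' plant family resolve to the lexicographically smallest key and are flagged.
#'
#' @param assignments An `xmir_assignments` tibble from [classify_library()].
#' @param library_id Library identifier carried into the profile.
#' @return An `xmir_profile` object. Use [glance()] for the one-row summary
#'   tibble, [tidy()] for the long per-family count table, and [autoplot()]
#'   for a family-share bar chart.
#' @export
profile_library <- function(assignments, library_id = "library") {
  fam_counts <- function(cat) {
    assignments |>
      filter(.data$category == cat) |>
      group_by(family = .data$family) |>
      summarise(reads = sum(.data$count), .groups = "drop") |>
      arrange(desc(.data$reads), .data$family)
  }
  plant <- fam_counts("plant_mirna")
  animal <- fam_counts("animal_mirna")
  side <- function(cat) sum(assignments$count[assignments$category == cat])

  plant_reads <- sum(plant$reads)
  animal_reads <- sum(animal$reads)
  total <- plant_reads + animal_reads

  if (plant_reads > 0) {
    top_n <- max(plant$reads)
    tied <- plant$family[plant$reads == top_n]
    top_family <- min(tied)
    pct_plant <- if (animal_reads > 0) {
      percent_of_animal(plant_reads, total)
    } else NA_real_
    top <- list(
      family = top_family,
      reads = top_n,
      pct_of_plant = family_share(top_n, plant_reads),
      pct_of_animal = if (animal_reads > 0) {
        percent_of_animal(top_n, top_n + animal_reads)
      } else NA_real_,
      rank = if (nrow(animal) > 0) {
        rank_in_animal_families(top_n, animal$reads)
      } else NA_integer_,
      tie = length(tied) > 1,
      rank_tie = nrow(animal) > 0 && any(animal$reads == top_n)
    )
  } else {
    pct_plant <- if (animal_reads > 0) 0 else NA_real_
    top <- list(family = NA_character_, reads = NA_integer_,
                pct_of_plant = NA_real_, pct_of_animal = NA_real_,
                rank = NA_integer_, tie = FALSE, rank_tie = FALSE)
  }

  structure(list(
    library_id = library_id,
    total_mirna_reads = total,
    plant_reads = plant_reads,
    animal_reads = animal_reads,
    plant_family_counts = plant,
    animal_family_counts = animal,
    pct_plant_of_animal = pct_plant,
    top_plant_family = top$family,
    top_family_reads = top$reads,
    top_family_pct_of_plant = top$pct_of_plant,
    top_family_pct_of_animal = top$pct_of_animal,
    top_family_rank_in_animal = top$rank,
    top_family_tie = top$tie,
    rank_tie = top$rank_tie,
    host_genome_reads = side("host_genome_derived"),
    ambiguous_reads = side("ambiguous_kingdom"),
    unassigned_reads = side("unassigned")
  ), class = "xmir_profile")
}

#' @export
print.xmir_profile <- function(x, ...) {
  cat(sprintf("<xmir_profile> %s\n", x$library_id))
  cat(sprintf("  miRNA reads (animal + plant): %d  plant: %d (%s%% of animal)\n",
              x$total_mirna_reads, x$plant_reads,
              format(x$pct_plant_of_animal)))
  if (!is.na(x$top_plant_family)) {
    cat(sprintf("  top plant family: %s (%d reads, %s%% of plant, animal rank %s)\n",
                x$top_plant_family, x$top_family_reads,
                format(x$top_family_pct_of_plant),
                format(x$top_family_rank_in_animal)))
  }
  invisible(x)
}

#' @export
glance.xmir_profile <- function(x, ...) {
  tibble(
    library_id = x$library_id,
    total_mirna_reads = x$total_mirna_reads,
    plant_reads = x$plant_reads,
    animal_reads = x$animal_reads,
    pct_plant_of_animal = x$pct_plant_of_animal,
    top_plant_family = x$top_plant_family,
    top_family_reads = x$top_family_reads,
    top_family_pct_of_plant = x$top_family_pct_of_plant,
    top_family_pct_of_animal = x$top_family_pct_of_animal,
    top_family_rank_in_animal = x$top_family_rank_in_animal,
    top_family_tie = x$top_family_tie,
    rank_tie = x$rank_tie,
    host_genome_reads = x$host_genome_reads,
    ambiguous_reads = x$ambiguous_reads,
    unassigned_reads = x$unassigned_reads
  )
}

#' @export
tidy.xmir_profile <- function(x, ...) {
  bind_rows(
    mutate(x$plant_family_counts, kingdom = "plant"),
    mutate(x$animal_family_counts, kingdom = "animal")
  ) |>
    mutate(library_id = x$library_id) |>
    select("library_id", "kingdom", "family", "reads")
}

#' @export
autoplot.xmir_profile <- function(object, kingdom = "plant", top_n = 15, ...) {
  dat <- tidy(object) |>
    filter(.data$kingdom == !!kingdom) |>
    head(top_n)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$family, .data$reads), y = .data$reads
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "reads",
      title = sprintf("%s: %s miRNA families", object$library_id, kingdom)
    )
}

#' Profile several libraries at once
#'
#' @param assignments_by_library Named list of `xmir_assignments`.
#' @return A tibble with one [glance()] row per library.
#' @export
profile_libraries <- function(assignments_by_library) {
  imap(assignments_by_library,
       function(a, id) glance(profile_library(a, id))) |>
    list_rbind()
}

#' Keep libraries whose plant fraction clears the significance threshold
#'
#' @param profiles A tibble of profile summaries (from [profile_libraries()]
#'   or row-bound [glance()] outputs), or a list of `xmir_profile` objects.
#' @param threshold_pct Inclusive lower bound on `pct_plant_of_animal`
#'   (default 0.050, i.e. plant reads at least 0.050% of animal miRNA reads).
#' @return The qualifying rows, sorted by decreasing `pct_plant_of_animal`.
#' @export
flag_significant <- function(profiles, threshold_pct = 0.050) {
  if (is.list(profiles) && !is.data.frame(profiles)) {
    profiles <- list_rbind(map(profiles, glance))
  }
  profiles |>
    filter(!is.na(.data$pct_plant_of_animal),
           .data$pct_plant_of_animal >= threshold_pct) |>
    arrange(desc(.data$pct_plant_of_animal))
}

#' Published per-library survey counts (regression fixture)
#'
#' Read counts and printed percentage columns for 19 public animal sRNA
#' libraries in which plant miRNA reads reached at least 0.050% of animal
#' miRNA reads, as reported in the survey this package's statistics
#' reproduce. Feeding the count columns through [percent_of_animal()] and
#' [family_share()] must reproduce the printed percentage columns digit for
#' digit.
#'
#' @return A tibble with columns `run_id`, `organism`, `source`,
#'   `total_mirna_reads`, `plant_reads`, `pct_plant_of_animal`,
#'   `top_family`, `top_family_reads`, `top_pct_of_plant`,
#'   `top_pct_of_animal`, `rank_in_animal`.
#' @export
survey_counts_fixture <- function() {
  readr::read_tsv(
    system.file("extdata", "survey_counts.tsv", package = "xenomir"),
    col_types = "ccciidciddi", progress = FALSE
  )
}
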