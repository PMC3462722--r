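# xenomir

Detection and contamination diagnostics for plant microRNAs (xeno-miRNAs)
in animal small-RNA sequencing libraries.

## The problem

Plant miRNAs — most notoriously miR168 — keep turning up in deep-sequenced
animal small-RNA libraries, at fractions of roughly 0.05–0.5% of the animal
miRNA reads. Two explanations compete: genuine dietary uptake (plant miRNAs
surviving the gut and circulating systemically) and sequencing artefact
(cross-contamination between libraries that were barcoded and pooled in the
same multiplexed run, or contamination during library preparation). The
distinction matters for anyone interpreting cross-kingdom small-RNA signals:
the two explanations make different predictions about *which* plant miRNAs
appear, *which sequence variant* of each family appears, and *how the
family-abundance profile compares* to the animal's actual diet versus the
other libraries in the run.

`xenomir` implements the computational side of that analysis as a tested,
reusable pipeline for bioinformaticians working with small-RNA data:

1. **Exact-match read classification.** A read is called a miRNA match only
   on perfect full-length identity with a mature sequence from a
   kingdom-annotated catalog (miRBase-dialect FASTA): same length, zero
   mismatches. Reads matching plant records are then screened against the
   host genome — any read sharing a ≥ 20-nt perfect match (either strand)
   with the host genome is reclassified as host-derived, not dietary.
2. **Per-library abundance statistics.** For each library with plant miRNA
   reads *P* out of *T* total miRNA reads (animal + plant):
   `% of animal miRNAs = 100 · P / (T − P)`, per-family shares
   `100 · n_fam / P`, the most abundant plant family, and its competition
   rank among the animal miRNA families. Libraries are flagged significant
   at ≥ 0.050% plant/animal.
3. **Clade attribution.** The monocot and dicot variants of miR168 (21 nt,
   Hamming distance 2) partition cleanly between flowering-plant clades, so
   each plant-matching sequence variant is assigned monocot / dicot /
   unresolved — a monocot-variant signal in a dicot-fed animal cannot come
   from the diet.
4. **Run-level contamination diagnostics.** Spearman rank correlation (on
   log1p family counts) of each animal library's plant-miRNA profile against
   (a) its declared diet library and (b) the pooled plant libraries of its
   multiplexed run; tracing of library-specific marker sequences across the
   run; and a moment-based estimate of the inter-library bleed rate from
   marker counts. Each library gets a verdict: `diet_consistent`,
   `contamination_suspected`, or `inconclusive`.
5. **A ground-truth simulator** of multiplexed runs (animal backgrounds,
   dietary spike-ins, host-genome reads, noise, configurable bleed) so every
   stage is validated against known truth without any downloads.

## Worked example

Classify the monocot miR168 sequence (as a DNA-alphabet read) against the
shipped catalog fixture:

```r
library(xenomir)
cat_ <- read_mirna_catalog(
  system.file("extdata", "mature_synthetic.fa", package = "xenomir"),
  system.file("extdata", "species_meta.tsv", package = "xenomir")
)
classify_read("TCGCTTGGTGCAGATCGGGAC", build_sequence_index(cat_))
#>   read_id              sequence count    category family  clades
#> 1   read1 UCGCUUGGUGCAGAUCGGGAC     1 plant_mirna miR168 monocot
#>                                      matched_ids
#> 1 osa-miR168a,sbi-miR168,zma-miR168a,zma-miR168b
```

The read is a perfect full-length match to the monocot miR168 variant
carried by rice, corn and sorghum — so if this animal was fed on a dicot,
that is already evidence against a dietary origin.

End to end on a simulated multiplexed run with bleed 10⁻³ and **no** dietary
uptake (10⁵ reads per animal library):

```r
toy <- make_toy_catalog(8, 12, seed = 3)
cfg <- example_run_config(toy, seed = 1, bleed_rate = 1e-3, spike_fraction = 0)
sim <- simulate_run(cfg)
asn <- lapply(sim$reads, classify_library, index = build_sequence_index(toy))
man <- sim$manifest
man$diet <- attr(cfg, "declared_diets")[man$library_id]
diagnose_run(asn, man, toy)
#> <xmir_contamination> run run1, 4 libraries, bleed estimate 0.000669
#>   library_id   diet  plant_reads pct_monocot pct_dicot similarity_to_diet ... verdict
#> 1 insect_corn1 zma            72        6.94      93.1            -0.215      contamination_suspected
#> 2 insect_corn2 zma            74       12.2       87.8             0.246      contamination_suspected
#> 3 insect_soy1  gma            68       11.8       88.2            -0.0504     contamination_suspected
#> 4 insect_soy2  gma            50       12         88               0.0112     contamination_suspected
```

Every animal library shows 50–80 plant miRNA reads it never ate:
corn-(monocot-)fed insects carry ~90% *dicot*-variant sequences, each
library's plant profile tracks the pooled run far better than its own diet,
and the marker trace recovers a bleed rate near the configured 10⁻³ — all
four verdicts are `contamination_suspected`, correctly. Re-running with
`bleed_rate = 0, spike_fraction = 0.002` flips all verdicts to
`diet_consistent` with the clades matching each diet.

`autoplot()` methods produce family-profile bar charts and
similarity/verdict panels; `tidy()`/`glance()` return the tables above.

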