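# crisprtrip

Multiplexed profiling of CRISPR-Cas9-induced mutations in barcoded reporter
amplicons.

## The problem

When Cas9 cuts thousands of identical target sequences integrated at random
genomic positions (barcoded "integrated reporters", IRs, of a
thousands-of-reporters-in-parallel design), deep sequencing of the amplified
target regions lets one ask what determines repair outcome: the guide RNA,
the locus, the repair template, the promoter driving the reporter, or the
chromatin context. The package implements the full analysis for such
experiments, for computational biologists working with amplicon deep
sequencing of Cas9-edited reporters:

* **Read calling** — amplicon reads carrying a 16-nt unique molecular
  identifier (UID) and the reporter barcode are parsed, aligned to the
  wild-type region by semi-global alignment with affine gaps
  (match +2, mismatch −2, gap open −5, gap extension −0.5, initial
  score 30; a gap of length *L* costs `open + (L−1)·extend` and reference
  end-gaps are free) and classified as wild-type, deletion, insertion or
  complex, with knock-in detection against an ssODN template. Reads sharing
  a UID are collapsed to molecules by majority vote.
* **Profiles** — per-IR outcome frequencies (coverage ≥ 30 in every assay),
  deletion/insertion size spectra, deletion-boundary frequencies at the
  canonical 3|4 and alternative 4|5 break sites (ambiguous placements
  weighted `m/k`), 1-bp inserted-base distributions, and barcode-count
  expression normalisation (log2 cDNA/gDNA with pseudocounts).
* **Effects** — ordinary least squares between assays; η² variance
  decomposition of mutation frequency over locus, guide, ssODN, promoter
  and locus×guide by type-II ANOVA (promoter nested in locus is detected
  and reported); Wilcoxon tests with Hodges–Lehmann shift estimates;
  knock-in / error-insertion ratios binned by mutation frequency with
  bootstrap confidence intervals.
* **Genomic context** — mean feature-track scores in a 2-kb window around
  each integration, Pearson correlations with Benjamini–Hochberg
  adjustment.
* **Insertion cleavage models** — the core inference. A 1-bp insertion next
  to an identical base is ambiguous (TA→T**T**A and T**T**A are the same
  read); runs of a base induce windows of equivalent junctions. Ambiguous
  counts are redistributed under three Cas9 cleavage models: **blunt**
  (template-independent insertions at 3|4 upstream of the PAM; windows
  split proportionally to unambiguous counts), **staggered** (1-nt 5′
  overhang with termini 3|4 on the target strand and 4|5 on the non-target
  strand; fill-in duplicates ntDNA nucleotide 4; template-unlikely sites
  get the mean of other-base counts, likely sites the remainder), and
  **combined**.
* **DNA end structures** — enumeration of all double-strand-break end
  conformations in a 30-bp window, their expected hairpin-capture
  bisulfite reads (a k-nt 5′ overhang appears as a k-base apex
  duplication), degeneracy grouping, and matching of observed hairpin
  reads with substitution masking.
* **Synthetic data** — a fully seed-controlled generator for reporter
  libraries, outcome-mixture amplicon reads (template-dependent vs
  -independent insertions, microhomology deletion spikes, ssODN
  knock-ins), correlated feature tracks, and bisulfite-noised hairpin
  reads, with truth tables for every molecule.

## Worked example

Simulate a 36-IR clonal reporter line, call mutations, and ask whether the
1-bp insertion pattern favours the staggered cleavage model:

```r
library(crisprtrip)
library(dplyr)

cfg <- simulation_config(seed = 42, n_irs = 36, coverage_mean = 80)
lib <- generate_reporter_library(cfg)
g   <- trip_guides()$sgRNA3            # ntDNA nucleotide 4 = T
sim <- simulate_cas9_reads(lib, g, cfg)

parsed <- parse_amplicons(sim$reads, lib)
attr(parsed, "parse_stats")
#>   aberrant_barcode    ok total parse_rate
#> 1               58  3087  3145      0.982

calls    <- collapse_uids(call_reads(parsed, lib, g))
profiles <- compute_profiles(calls %>% mutate(assay = "sgRNA3"))
profiles
#> # A tibble: 36 × 10
#>   barcode  assay  coverage wild_type deletion insertion complex ...
#> 1 ACAGGGT… sgRNA3      125    0.176     0.704    0.088   0.032
#> 2 AGCCGCC… sgRNA3       61    0.0164    0.803    0.115   0.0656
```

98.2% of reads parse (the rest carry sequencing errors inside the barcode);
per-IR mutation frequencies vary strongly with locus, as the per-IR Beta
propensities dictate. The insertion counts then go through the
ambiguity-window machinery:

```r
tab <- insertion_count_table(calls)
tab
#> <insertion_count_table> junctions 0|1..8|9: 2 unambiguous,
#>   241 ambiguous in 8 windows
redistribute_counts(tab, "combined") %>%
  filter(junction %in% 3:4) %>% arrange(desc(count))
#>   junction base  unambiguous redistributed  count
#> 1        4 T               0        238.   238.
#> 2        3 C               0          2      2
```

Nearly every 1-bp insertion is a T that the combined model places at
junction 4|5 — the template-dependent duplication of ntDNA nucleotide 4
expected when this guide (staggered-end fraction 0.97) cleaves with a 1-nt
5′ overhang. The redistributed base-4 share, 0.984, sits at the closed-form
mixture expectation `f + (1−f)/4 ≈ 0.978`.

`run_pipeline(pipeline_config(...))` chains all stages (with caching and a
checksummed run manifest), `make_fixtures()` writes the bundled demo
datasets, and `plot_outcome_profiles()`, `plot_insertion_counts()`,
`autoplot()` on the effect fit, and `plot_end_structures()` draw the
standard displays. `tidy()`/`glance()` give broom-style summaries of the
effect decomposition.

## Acceptance script

`scripts/acceptance.R` re-runs the whole machinery from scratch against the
installed package: it simulates a multi-promoter pool (three assays,
including an ssODN editing arm), executes parsing → calling → UID collapse
→ profiles → η² decomposition → insertion-count redistribution, and runs
the hairpin-capture end-structure round trip, then writes its
machine-readable result table:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Progress and summary statistics are printed to stderr.
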