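---
title: "Models and methods behind crisprtrip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crisprtrip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprtrip)
library(dplyr)
```

This vignette is the package's own account of its science: the coordinate
conventions, the alignment and calling rules, the cleavage models, the
statistical machinery, and — importantly — what the synthetic-data
generator does and does not establish.

## Coordinates

Everything is anchored to the PAM on the non-target DNA strand (ntDNA, the
strand carrying protospacer + PAM read 5′→3′). Position *k* is the *k*-th
nucleotide upstream of the PAM (position 1 abuts it); junction *j*|*j*+1 is
the phosphodiester bond between positions *j* and *j*+1. The canonical
blunt Cas9 cut is at 3|4; the staggered alternative leaves a 1-nt 5′
overhang with termini 3|4 on the target strand and 4|5 on the ntDNA, whose
polymerase fill-in duplicates ntDNA nucleotide 4. `guide_target()` fixes
this frame; `guide_base4()` reads off the template base.

## Alignment and mutation calling

Reads are aligned to the wild-type amplicon region with a semi-global
affine-gap aligner (match +2, mismatch −2, gap open −5, gap extension −0.5,
plus a constant initial score of 30 that never changes the optimum and is
kept only so scores are comparable with the original scheme).
Design choices that the scores alone do not pin down:

* *Semi-global* means end gaps in the query row — unaligned reference
  flanks — are free, because reads span a fixed PCR amplicon and flank
  overhangs reflect layout, not biology. The read itself must align fully.
* *Affine accounting*: the first gap column costs the opening penalty and
  each further column the extension penalty, i.e. a gap of length *L*
  costs 5 + (*L*−1)·0.5. Some conventions charge open+extend on the first
  column; this one is stated explicitly because the two differ by 0.5 per
  gap.
* *Tie-breaking*: the dynamic program prefers diagonal moves over gaps and
  deletions over insertions, and every indel is then normalised to its
  3′-most equivalent placement — the convention deterministic variant
  callers exhibit when an insertion repeats its neighbour. Downstream
  analyses never rely on this placement: each indel carries its full
  equivalence window.
* `N` matches nothing and scores as a mismatch.

Classification: zero indels is wild-type (substitution-only reads stay
wild-type — the outcome taxonomy has no substitution class and isolated
substitutions are dominated by PCR/sequencing error), one deletion or one
insertion gives that class, two or more separate indel events give
"complex". An insertion identical to the 21-nt ssODN insert flags the read
as a knock-in. Each indel's placement window is computed literally: every
alternative placement is checked to reconstruct the same mutated string.
One consequence worth knowing: with these weights, a 1-bp deletion whose
downstream context re-aligns with a single mismatch is occasionally
absorbed as a substitution (penalty 4 < gap penalty 5), so perfect
truth-table recovery is not attainable by any caller using this scoring —
the package's round-trip contract is ≥ 99.9%, not 100%.

A deletion's equivalence window can be larger than intuition suggests: in
a CGGCGG repeat, deleting *any* three consecutive bases gives the same
product, so the window has four placements, of which two abut junction 3|4
(weight 2/4) and one abuts 4|5 (weight 1/4). Boundary statistics always
use these literal windows.

UID collapse takes the majority outcome per (barcode, UID); ties break
toward wild-type (then deletion > insertion > complex, for determinism) —
conservative, because a disagreeing pair of reads most often reflects an
error on the mutated reading.

## Ambiguity windows and redistribution

For each base, maximal runs of that base induce windows of equivalent
insertion junctions (a run of *k* identical bases gives *k*+1 junctions).
Windows are constructed by run extension and verified in the test suite
against brute-force enumeration plus sequence-identity grouping.

Ambiguous counts are redistributed per window:

* **blunt** — proportionally to the total unambiguous counts (all four
  bases) at each junction of the window; all-zero weights split uniformly.
  The proportions are taken over all four bases because the ambiguous base
  has, by definition, no unambiguous counts inside its own window.
* **staggered** — junctions whose PAM-side (downstream) neighbour equals
  the inserted base are *likely*; every unlikely junction receives the
  mean of the unambiguous counts of the **other three** bases at that
  junction, and the remainder goes to likely junctions proportionally.
  A negative remainder is clamped at zero and reported — this occurs when
  other-base activity at unlikely sites exceeds the window total, and the
  clamp count is the honest diagnostic. The other-base mean is biased low
  when some other bases are themselves ambiguous at that junction (their
  counts sit in their own windows); this is inherent to the rule as
  stated.
* **combined** — junction 4|5 is governed by the staggered rule and all
  other junctions by the proportional rule. In a window containing a
  template-likely 4|5, the other junctions receive their
  template-independent estimate (the other-base mean) and 4|5 attracts the
  remainder; this is the reading that reproduces the expected combined
  signature — near-uniform bases at 3|4, a base-4 spike at 4|5. The
  package deliberately does **not** estimate the blunt:staggered mixture
  fraction from data: re-cleavage of accurately repaired molecules skews
  mutated-vs-wild-type ratios over time, so only the presence of both
  signatures is claimed (`model_concordance()` describes fit, not
  fractions).

Counts are conserved exactly within each window, absent clamping. Because
of that conservation, the *total* base-4 share of a redistributed table
under the combined model has a closed form under the generator's mixture:
`f + (1−f)/4` for staggered fraction `f` (staggered events always insert
base 4; blunt events do so a quarter of the time). The acceptance suite
checks this at the table level; the share assigned specifically to
junction 4|5 is `f` minus the unlikely-site mean, which is the rule's
behaviour, not an error.

## Effect decomposition

Mutation frequency is modelled as a linear function of locus, guide,
ssODN, promoter and locus×guide. Effect sizes are η² = SS(term)/SS(total)
with type-II (marginality-respecting) sums of squares computed by explicit
refits, so they are independent of term entry order by construction. In
the reporter design each locus carries exactly one promoter, making
promoter perfectly aliased with locus; the package detects the nesting,
fits promoter on the between-locus contrast first, attributes the
remaining between-locus variation to locus, and labels the output
(`promoter_aliased`). This is one defensible resolution of an aliasing the
design cannot break; promoter varying *within* locus is rejected as rank
deficiency. Shift effect sizes are Hodges–Lehmann estimates with 0.95
confidence intervals attached to two-tailed Wilcoxon tests — the estimator
is a package choice, made because it is the location estimate canonically
paired with rank tests. Knock-in/error-insertion ratios drop IRs with zero
error insertions (no clamping; the count is reported), use 10-point bins
by default, and percentile bootstrap intervals (2000 seeded resamples).

## Hairpin-capture end structures

A DSB end with ntDNA terminus *a* and tDNA terminus *b* (PAM-relative
junctions) is read, after hairpin ligation of the PAM-proximal fragment
and bisulfite conversion, as

```
revcomp(S[P−b ..]) + loop + S[P−a ..]
```

where `S` is the ntDNA top strand and `P` the PAM start index. Relative to
the blunt reference (a = b = 3), a 1-nt 5′ overhang (3|4t, 4|5nt) shows a
one-base apex duplication of ntDNA base 4; a recessed strand shows an apex
loss; equal-length conformations (a+b constant) differ from the reference
only at substituted positions. Expected reads are built in fully
C→T-converted space — the form the sequencer sees — and conformations with
literally identical expected reads merge into degeneracy groups.
Observed reads are aligned with the package's own semi-global aligner
(the original re-analysis used an external local-alignment search; only
spans and indel operations are consumed, so the substitution changes
nothing material and is noted here), filtered (alignment ≥ 50 columns,
≤ 5 gap columns, spanning 50 bp around the target), and matched by exact
signature within a 30-bp window around the apex. With substitution masking
on (the default), conformations whose signatures coincide once
substitutions are ignored are merged into one reporting row — this is the
"could not be discerned" phenomenon, and it is why masked and as-is
tallies differ: with masking off, reads carrying bisulfite-failure
substitutions inside the window simply fail to match and inflate "other".
The bisulfite noise model converts every C of the single-stranded hairpin
molecule, with a per-C failure probability (default 5%) that leaves an
original C in place; failures therefore appear only at C positions of the
converted strand, read as T→C substitutions against the converted
reference. The loop sequence is configurable and excluded from the
signature window; the maximal overhang defaults to 14 nt, half the window.

## The synthetic world

The generator encodes the conditions the analyses assume, chosen once:

* Per-IR mutation propensity ~ Beta(2, 2): locus effects dominate variance
  and span the unit interval broadly; the field reports locus-driven
  variance but no distributional form, so a symmetric, wide Beta is the
  neutral choice.
* Guide efficiency multipliers (1, 1.04, 1.3) reproduce the reported
  1.30/1.26-fold efficiency gaps between the strongest and weaker guides.
* Staggered-end fractions per guide (0.52, 0.65, 0.97) are back-computed
  from the reported dominant 1-bp insertion shares via
  `share = f + (1−f)/4`.
* Outcome mixture per mutated molecule: deletion 0.78, insertion 0.12,
  complex 0.10; knock-in probability 0.06 given an ssODN — together these
  land near the reported per-IR averages (error insertions ≈ 3–4%,
  knock-ins ≈ 1.7% at ~30% mutation frequency).
* Deletion sizes: truncated geometric on 1..30 bp with p = 0.14, so about
  three quarters of deletions are < 10 bp, matching the reported tail
  constraint; an optional microhomology spike deletes a configured triplet
  just upstream of the PAM. Deletions always span or abut the 3|4 cut.
* Complex outcomes are one deletion plus one separate insertion placed
  downstream of the PAM — the mechanistic definition of "complex" is not
  settled, and separating the two events keeps the caller's event count
  meaningful.
* Coverage ~ NegBin(mean 100, size 10); sequencing error i.i.d.
  substitutions at 0.1% per base (indel errors off by default — they would
  confound the calls under test and can be enabled explicitly).
* One root seed; per-IR child streams derived arithmetically, so adding an
  IR never changes another IR's reads.

What a green test establishes: the pipeline recovers, at stated
tolerances, the parameters of *this* world — mixture fractions, variance
shares, correlations, end-structure mixtures. What it does not establish:
robustness to real-world read artefacts (adapter chimeras, PCR jackpots
beyond UID duplication, indel sequencing errors, translocations), the
correctness of any specific biological fraction in real data, or
genome-mapping steps (out of scope entirely). The bundled guides are
synthetic stand-ins sharing the documented properties of the study guides
(GC content, template base, a CGG repeat), not the laboratory sequences.

## Numerical details and degenerate inputs

* Scores are half-integer exact in double precision; score comparisons in
  the dynamic program are exact.
* Zero-coverage IRs are dropped; empty call sets return empty profiles
  with a warning; empty knock-in bins are missing, not zero.
* Expression normalisation uses log2 with pseudocount 1 on both
  numerator and denominator — the ratio alone is the defined quantity,
  the log form is chosen for symmetry in downstream Pearson analyses.
* All-zero proportional weights in redistribution fall back to a uniform
  split (an unstated degenerate case); windows whose only in-range
  junction is template-unlikely fall back to the proportional rule.
* Barcode matching is exact by default; with a tolerance, ties at the best
  Hamming distance are rejected as ambiguous rather than guessed.
* The pipeline cache keys stage results by a hash of stage name and
  inputs; a rerun with an unchanged configuration reuses every stage.

## Known limitations

Calling is not quality-aware and does not detect chimeras or
translocations; the parse-rejection taxonomy is a superset of any
particular wet-lab filter set; the promoter/locus aliasing resolution is
one of several defensible conventions and is labelled in the output; the
end-structure analysis reproduces the re-analysis logic on synthetic
hairpin data — reproducing the published percentages requires the archived
sequencing runs, which are deliberately not bundled.
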