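---
title: "Partitioning proteomes and decomposing the kingdom disorder gap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning proteomes and decomposing the kingdom disorder gap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkerscape)
```

## The question and the procedure

Predicted intrinsic disorder is much more prevalent in eukaryotic than in
prokaryotic proteins. Because sequence-based predictors see nothing but
amino-acid composition and order, any such gap must be carried by the
sequences themselves. `linkerscape` localizes the gap structurally and then
decomposes it compositionally:

1. **Dataset hygiene.** Genomes with GC outside 20–60% are removed, as are
   four genera with non-standard codon usage (Mycoplasma, Spiroplasma,
   Ureaplasma, Mesoplasma). Extreme-GC genomes would otherwise confound
   amino-acid frequencies through codon structure alone; after the cut,
   kingdom GC distributions are comparable and within-family comparisons
   need no further GC correction.
2. **Partition.** Domain families present in at least 10 eukaryotic and 10
   prokaryotic genomes, with no kingdom holding more than 99.9% of
   instances, are *shared*. Proteins carrying at least one shared domain
   are segmented exactly into shared-domain, specific-domain and linker
   intervals; every residue is labelled once, so per-type lengths sum to
   the protein length. Linkers are typed N-terminal, central or C-terminal.
3. **Disorder.** Per-residue scores from an external predictor are
   binarized at 0.4 (strictly greater; a score of exactly 0.4 is ordered).
   Both pooled residue-weighted fractions and per-protein means with
   standard errors are reported: the two differ when long proteins are
   atypical, and published summaries use both kinds without comment.
   TOP-IDP mean propensities complement the track-based measure with a
   predictor-free one.
4. **Composition.** Frequency profiles over the 20 standard amino acids per
   kingdom × region class; kingdom deltas against the eukaryote baseline
   (an amino acid more abundant in eukaryotes shifts *downwards*);
   Pearson-correlation similarity of profiles with average-linkage
   clustering on `1 - r`; per-family shifts restricted to families with at
   least 100 members in both bacteria and eukaryotes; optional
   secondary-structure stratification of instance residues by alignment
   column.
5. **Decomposition.** The propensity gap between two profiles splits
   exactly into `c_aa = s_aa * delta_f_aa`; by linearity the terms sum to
   the difference of TOP-IDP means, machine-exactly. The leave-out variant
   removes a residue set (by default Ser, Pro, Ile), renormalizes both
   17-component profiles and recomputes the gap.
6. **Nulls and tests.** Expected frequencies from codon usage alone are a
   one-parameter (GC) closed form; the kingdom effect on per-genome
   frequencies is tested with an F-test for the kingdom factor added to a
   GC-only linear model.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_gc`, `max_gc` | 0.20, 0.60 | inclusive GC retention window (fractions) |
| `min_genomes` | 10 | genome-presence threshold per side (eukaryote; bacteria+archaea jointly) |
| `max_share` | 0.999 | maximum single-kingdom share of a family's instances |
| `disorder_threshold` | 0.4 | score binarization, strict `>` |
| `min_family_members` | 100 | per-family instance floor (bacteria and eukaryotes) for family shifts |
| `builtin_window` | 21 residues | smoothing window of the fallback predictor |

All of them are `pipeline_config()` keys; the defaults are the published
operating points of this analysis style and are not tuned per dataset.

## Decisions where the procedure was genuinely open

* **"Members" in the 99.9% rule** is read as domain *instances*, while the
  10-genome presence rule counts *genomes*: presence language naturally
  refers to genomes, while a share of "all the members" of a family reads
  as instances. Both counters are computed and kept in the output so the
  other reading can be audited.
* **Prokaryote presence** requires 10 prokaryotic genomes *jointly*
  (bacteria plus archaea), not 10 of each — "ten prokaryotes" is the
  minimal reading. Families found only in the two prokaryotic kingdoms are
  non-shared, and proteins carrying only such families land in the
  kingdom-specific group even though their domains span two kingdoms; the
  trichotomy is closed that way deliberately.
* **GC bounds are inclusive** (a genome at exactly 0.60 survives) because
  the exclusion targets genomes with *more* than 60% or *less* than 20%.
* **Threshold strictness**: "higher than 0.4" is a strict inequality; ties
  at the threshold count as ordered.
* **Overlapping domain hits** are resolved greedily by descending score,
  ties broken by length, then start, then accession; an overlapping hit is
  dropped whole. Real annotation pipelines rarely emit overlaps, but the
  segmentation contract (exact partition) requires a deterministic rule.
* **Stop codons** in the codon null are excluded and the 61 sense codons
  renormalized — otherwise amino-acid frequencies from "random
  nucleotides" are undefined. Renormalization happens after exclusion. A
  note on symmetry: per-codon probabilities are exactly symmetric under
  swapping GC for 1−GC together with the A↔G, T↔C relabelling, but the
  renormalized amino-acid frequencies are *not*, because the three stop
  codons are not an invariant set under that relabelling.
* **The kingdom ANOVA** is covariate-adjusted: `freq ~ gc + kingdom`, with
  the kingdom F from the extra sum of squares over the GC-only model. A
  two-factor layout with binned GC is available (`gc_bins`), but a
  continuous covariate is the minimal faithful model when no binning is
  specified. No multiple-testing correction is applied by default;
  `p.adjust` on the returned column is a one-liner for users who want it.
* **Per-family shifts** are computed over instance residues (pooling all
  residues of a family's instances per kingdom), not per-genome means.
* **Secondary-structure ties** (e.g. one helix and one sheet observation)
  break to coil; columns with no structural observation are *unassigned*
  and treated as the disordered class.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` describes kingdom-labelled genomes (default 100 per
kingdom, GC ~ Normal(0.44, 0.08) clamped away from 0 and 1), ~100 proteins
per genome split 60/25/15 into shared / kingdom-specific / no-domain
groups, a 30-family shared inventory plus 10 specific families per
kingdom, domain lengths uniform on 80–200 residues, and kingdom-dependent
Poisson linker lengths (terminal means 103 vs 44 residues, central 64.4 vs
27.5) chosen so that expected linker totals are ~258 residues in
eukaryotes vs ~110 in prokaryotes, with a 40/20/40 expected
N-terminal/central/C-terminal split. Region residues are drawn i.i.d. from
the reference kingdom-by-region compositions (`reference_compositions()`,
with eukaryotic linkers at 8.9% Ser, 5.9% Pro, 4.9% Ile against 6.5%,
4.0%, 6.9% in bacterial linkers), and per-residue disorder scores from
Beta distributions with concentration 4 whose mean is calibrated by
root-finding (tolerance 1e-12) so that the mass above 0.4 equals the
planted disorder level exactly — 38% for eukaryotic linkers vs 14%/16% in
bacteria/archaea, 8–17% for domains, 42%/13%/15% for no-domain proteins.
The first domain of every shared protein cycles the shared-family
inventory, so each shared family reaches every genome whenever a genome's
shared proteins outnumber the inventory — that is what guarantees the
10-genome presence rule for designated-shared families; later domain slots
draw from the kingdom-specific inventory with probability 0.2, producing
the mixed architectures that populate the specific-domain region class.

Because residues are i.i.d. within a region, every statistic the pipeline
computes (compositions, threshold fractions, interval bookkeeping) has an
exactly known sampling distribution — recovery tests compare estimates to
planted values within three binomial standard errors. The generator does
**not** emulate positional correlation along sequences, domain sequence
conservation within families, phylogenetic correlation between genomes, or
any GC dependence of amino-acid composition; passing recovery tests
therefore demonstrates that the pipeline measures what was planted, not
that real proteomes behave like the plant. The planted compositions also
make the per-family shifts essentially homogeneous across families —
cleaner than the ~70–85% family agreement seen in real data.

## Numerical and degenerate-input choices

Frequency profiles exclude X/B/Z/U/O from numerator and denominator, so
they always sum to 1; those residues still count toward protein length and
interval bookkeeping. Empty interval sets, zero countable residues,
all-excluded profiles and single-observation standard errors are errors,
not NAs, except where a summary row legitimately reports an empty class
(`n = 0` with blank statistics). Zero pooled variance in the t-test gives
`t = 0, P = 1` for equal means and an explicit infinite `t` with `P = 0`
otherwise. The built-in window predictor normalizes by the scale's own
extremes (poly-Pro scores 1, poly-Trp 0), truncates windows at termini,
skips non-standard residues within a window, and scores a window with no
standard residue at 0.5. The codon model accepts the closed GC limits 0
and 1, where the enumeration degenerates gracefully (at GC = 1 only the
eight G/C-only sense codons survive, giving Ala = Gly = Pro = Arg = 0.25).

## Problem sizes

The test suite exercises most operations on bundles of 12–15 genomes per
kingdom with 30–40 proteins each (seconds per test), and the acceptance
checks run the full default spec — 300 genomes, ~100 proteins each, about
11 million residues — once, in roughly two minutes. Statistical
calibration of the kingdom test uses 2,000 null replicates of 60 genomes.
These sizes give binomial standard errors small enough that planted-value
recovery is a sharp check while keeping a complete run on a laptop scale.

## Known limitations

* The built-in predictor is a composition smoother; it reproduces
  *composition-driven* disorder signal only and is no substitute for an
  energy-based predictor on real sequences.
* Secondary-structure stratification assumes ungapped instances (hit
  position i = alignment column i), which the generator satisfies; real
  gapped Pfam alignments would need an explicit state mapping that is out
  of scope here.
* The pipeline ingests disorder tracks; it does not reimplement IUPred or
  its short/long variants.
* Family classification treats each genome's annotation as complete;
  missing annotations shift proteins toward the no-domain group rather
  than producing errors.
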