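# linkerscape

Eukaryotic proteins are predicted to be far more intrinsically disordered
than prokaryotic ones. `linkerscape` is an R pipeline for dissecting *why*:
it partitions proteins into domain and linker regions from Pfam-style
annotations, quantifies disorder and amino-acid composition per region and
kingdom, and decomposes the disorder gap into per-amino-acid contributions
— showing how shifts in just three residues (more serine and proline, less
isoleucine, in eukaryotic linkers) account for the difference, while a
GC-parameterized codon-usage null model controls for nucleotide composition.

The package is aimed at comparative proteomics: users with proteome FASTA
files, per-protein domain annotations (TSV), genome metadata (kingdom,
phylum, GC) and per-residue disorder-score tracks from an external
predictor such as IUPred. A fully parameterized synthetic-proteome
generator with planted, recoverable structure makes every stage testable
without any downloads.

## The quantities at the core

* **Region partition.** A domain family is *shared* when it occurs in at
  least 10 eukaryotic and 10 prokaryotic genomes and no kingdom holds more
  than 99.9% of its instances. Proteins containing a shared domain are
  segmented exactly into `shared_domain`, `specific_domain` and `linker`
  regions (N-terminal / central / C-terminal), so region lengths sum to the
  protein length.
* **Disorder.** A residue is disordered when its predictor score exceeds
  0.4 (strictly). Per region class the pipeline reports the pooled
  residue-weighted disorder fraction, per-protein means and standard
  errors, and mean TOP-IDP propensities `sum(f_aa * s_aa)`.
* **Decomposition.** For two compositions (eukaryote baseline vs a
  prokaryote) the disorder-propensity gap splits exactly into
  `c_aa = s_aa * (f_other,aa − f_euk,aa)`, with `sum(c_aa)` equal to the
  TOP-IDP mean difference. A leave-out variant renormalizes the profiles
  without Ser/Pro/Ile and asks whether any gap remains.
* **Codon null.** With base probabilities `P(G) = P(C) = gc/2`, stop codons
  excluded and the 61 sense codons renormalized, the expected amino-acid
  frequency at a given genomic GC is a closed-form product — the reference
  line against which observed per-genome frequencies are plotted, and the
  covariate behind the GC-adjusted kingdom ANOVA.

## Worked example

```r
library(linkerscape)

spec <- synthetic_spec(
  n_genomes = c(eukaryote = 30, bacterium = 30, archaeon = 30),
  proteins_per_genome = 50)
bundle <- generate_proteomes(spec, seed = 11)
res <- run_pipeline(bundle)
print(res)
#> Kingdom disorder/composition pipeline run
#>   genomes: 88 retained of 90
#>   proteins: 4400 (kingdom_specific_protein=1135, no_domain_protein=613, shared_protein=2652)
#>   domain families: 60 (30 shared)
#>   regions: 12288 (424892 linker residues)
#>   predictor: external score tracks
```

Two genomes drew extreme GC and were filtered out; the rest partition into
the three protein groups. The disorder summary shows the planted kingdom
contrast — eukaryotic linkers approaching 38% disordered residues versus
~14–16% in prokaryotes, with domains far more ordered:

```r
summary(res)
#> Pooled disorder fraction by kingdom and region type:
#>           linker shared_domain
#> eukaryote 0.3796        0.1184
#> bacterium 0.1390        0.0799
#> archaeon  0.1591        0.0908
#>
#> Top |propensity x delta-frequency| contributions (eukaryote baseline):
#>  vs bacterium : P, I, S, K, Y
#>  vs archaeon : P, I, S, E, K
```

The decomposition table makes the three-residue story quantitative: the
largest absolute contributions to the eukaryote-bacteria linker propensity
gap come from proline, isoleucine and serine (negative `delta` = more
abundant in eukaryotes):

```r
co <- res$contributions$bacterium
head(co[order(-abs(co$contribution)), ], 5)
#>    aa  scale   delta contribution
#> 13  P  0.987 -0.0192     -0.01897
#> 8   I -0.486  0.0189     -0.00917
#> 16  S  0.341 -0.0239     -0.00814
#> 9   K  0.586  0.0139      0.00813
#> 20  Y -0.510  0.0079     -0.00403
```

`plot(res, "similarity")` draws the clustered Pearson heat map of the nine
kingdom-by-region profiles (the eukaryotic-linker profile is the outlier),
`plot(res, "contributions")` the decomposition bars, and
`plot(res, "gc", aa = "S")` per-genome serine frequency against GC with the
codon-null curve. `write_summary_tables(res, "out/")` emits the
protein-level and region-level TSV summaries.

Real data enter through `read_fasta()`, `read_genome_tsv()`,
`read_domain_tsv()` and `read_disorder_tracks()`; a small synthetic toy
set in `inst/extdata/` shows the expected formats. When no predictor
output is available, `pipeline_config(use_builtin = TRUE)` scores residues
with a TOP-IDP window smoother (clearly flagged in the run manifest — it
is not an energy-based predictor).

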