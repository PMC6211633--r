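---
title: "Methods: chimeric-gene genotyping, breakpoint mapping and sweep scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chimeric-gene genotyping, breakpoint mapping and sweep scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimerapop)
options(chimerapop.log_level = "warn")
```

## The problem

Pyrethroid resistance in the cotton bollworm *Helicoverpa armigera* can be
conferred by the chimeric cytochrome P450 gene *CYP337B3*, a fusion of two
tandem paralogs produced by unequal crossing-over: the 5' part of the coding
sequence comes from a *CYP337B2*-like parent and the 3' part — including the
single intron — from a *CYP337B1*-like parent.  Studying such a locus in a
field survey raises a chain of connected questions that this package answers
as one tested pipeline:

1. **Who carries the chimera?**  A diagnostic PCR with one primer in each
   parental gene amplifies only across the chimeric junction.  We model this
   assay in silico (`find_primer_sites()`, `predict_amplicon()`,
   `classify_genotype()`).
2. **Where did each allele recombine?**  Aligned against its parents, a
   chimera switches from matching the B2-like parent to matching the B1-like
   parent; informative sites bound the crossover (`informative_sites()`,
   `map_crossover()`, `type_alleles()`).
3. **How are genotypes and alleles distributed geographically?**
   (`species_filter()`, `genotype_frequency_table()`,
   `allele_frequency_table()`.)
4. **Has the locus swept?**  A from-scratch sliding-window scan of
   nucleotide diversity and Tajima's D over a diploid genotype matrix
   (`sweep_scan()`, `sweep_report()`).
5. **Did the chimera arise once or repeatedly?**  A distance-based
   (neighbor-joining) monophyly assessment of chimeric-allele introns with
   column bootstrap (`monophyly_bootstrap()`), plus an arithmetic
   feasibility check of whether observed allelic divergence could have
   accumulated within the pyrethroid era (`rate_feasibility()`).

Everything runs on synthetic data with planted truths, so each stage is
testable end-to-end without access to unpublished field data.

## The in-silico PCR model

Primer annealing is exact string matching by default, with an optional
mismatch budget that never applies to the three 3'-terminal primer bases
(polymerase extension requires a matched 3' end).  A product is called when
a forward-strand hit of the forward primer lies 5' of a reverse-strand hit
of the reverse primer within a length cutoff (default 5000 bp, the
practical limit of a standard PCR); of multiple pairings the shortest
product is returned, as the dominant band.

Diploids are screened per haplotype.  The real assay sees both haplotypes
pooled in one tube; screening them separately keeps the classifier exact
while the evidence table still reports the band pattern the pooled reaction
would produce.  The genotype classes are `B3/B3` (both haplotypes carry the
chimera), `B3/par` (one chimeric chromosome, one chromosome carrying both
parental genes in tandem), `par/par`, and `unknown` for absent or
contradictory evidence.  The reciprocal primer pair — which would detect the
complementary 5'-B1 / 3'-B2 fusion — is always run and expected absent.

## Breakpoint intervals, not points

Between two informative sites the crossover position is unidentifiable, so
`map_crossover()` reports the interval from the last B2-matching to the
first B1-matching informative column.  Columns where the chimera matches
neither parent (post-formation mutations) are ignored for switch counting
but logged; chimeras whose state sequence switches more than once are
flagged as gene-conversion or multiple-crossover candidates rather than
forced into a single interval, and degenerate all-B1 or all-B2 chimeras are
marked as carrying no positional information.  The planted-truth harness
(`recover_planted_breakpoints()`) accordingly computes its containment rate
over clean single-switch calls only.

Allele variants are equivalence classes under exact full-sequence identity.
Variant names `v1, v2, ...` follow lexicographic order of the
representative sequences — a deterministic rule; mapping onto any published
allele labels (which encode publication history, not sequence order) is a
user-supplied lookup.

## The sweep scan

Windows of 2500 bp advancing by 1250 bp tile the reference segment; the
final partial window is retained with its true span as the denominator and
flagged rather than silently truncated.  Per window, with `n = 2N`
haplotypes and derived count `j` at a site:

* per-site heterozygosity `2 j (n − j) / (n (n − 1))`;
* `pi` = the sum of per-site heterozygosities divided by the window span in
  bp (the windowed-pi convention of standard VCF tools — filtered or
  inaccessible sites therefore bias `pi` downward, which is logged);
* Tajima's `D = (theta_pi − S / a1) / sqrt(e1 S + e2 S (S − 1))` with the
  usual constants `a1, a2, b1, b2, c1, c2, e1, e2`, where `theta_pi` is the
  un-normalised sum of site mean pairwise differences and `S` the number of
  segregating sites in the window.

Undefined `D` (no segregating sites, or vanishing variance term) propagates
as `NA`, never 0.  Sites with any missing genotype are excluded before
windowing so `n` is constant, as the constants require; the count of
excluded sites is attached to the result.  `sweep_report()` returns means
both over all windows and excluding the partial window, since published
conventions differ on this point.

## The synthetic world

The generator's defaults are a stated world, chosen once:

* **Paralog geometry** — 2000 bp aligned parents, intron at 1200–1700 in
  the B1-like parent, eight named chimeric alleles with crossovers at
  150–410 bp (several hundred bp of 5' coding sequence from B2, intron and
  remainder from B1).  The diagnostic screening product is 355 bp and spans
  every default crossover.
* **Diversity** — the two parental ancestors differ at 5% of sites
  (informative sites); alleles within a pool differ from their ancestor at
  `theta_site = 0.01` per site under an independent-site substitution model
  (no coding indels; optional intron insertion blocks emulate intron size
  variation).  Primer footprints are forced to be parent-diagnostic and are
  protected from allelic substitution, emulating primers designed against
  conserved paralog-specific sites; this is what makes noise-free
  classification exact, and real assays would not enjoy that guarantee.
* **Populations** — the `paper-global` preset draws genotype classes from
  the worldwide 88/9/3 percent homozygous/heterozygous/parental split over
  999 individuals, with an eight-allele mixture weighted like the published
  regional counts.  A parental haplotype carries B1 and B2 in tandem
  separated by a 5 kb spacer, which is what makes the reciprocal-pair
  product exceed the PCR cutoff — the same geometric reason the real
  reciprocal screen is negative.
* **Sweep footprint** — a phenomenological model, not a coalescent:
  candidate sites at density 0.2/bp on a 150 kb segment (matching the scale
  of a BAC-wide scan with ~30 k usable genotypes over 12 diploids) are
  thinned with probability `s·exp(−|x − center|/L)` and, within `L` of the
  center, draw their derived-allele count from a singleton-inflated `1/k`
  spectrum (`k = 1` mass boosted by `1 + 4s`).  Defaults `s = 0.9`,
  `L = 2500` bp.  This plants exactly the two signals a hard sweep leaves —
  a diversity trough and a rare-variant excess — without claiming
  coalescent realism; linkage disequilibrium, recombination within the
  segment, and demography are deliberately absent.  A green localization
  test therefore establishes that the scan finds the footprint the model
  plants, not that the model reproduces nature.
* **Origin alignments** — parental intron haplotypes at ~10% pairwise
  divergence; each chimera-formation event copies one donor, accumulates 3%
  stem divergence (the shared history that makes a true clade detectable),
  and individual chimeric introns add 1% each.  One donor plants
  monophyly; two donors from distant parts of the parental pool plant
  paraphyly.  The 200-column, ~10%-divergence design matches the scale at
  which a bootstrap of 200 replicates separates the two hypotheses cleanly.

All generators are byte-reproducible under a fixed master seed; stages use
fixed offsets (`seed`, `seed + 1`, `seed + 2`) so adding a stage never
perturbs another stage's stream.

## Tree inference surrogate

Model-based phylogenetics (ML or Bayesian, with model selection and
Bayes-factor tests of topology constraints) is out of scope; the question
reproduced is *is the chimeric clade monophyletic*, answered with
p-distances (pairwise deletion), Saitou–Nei neighbor joining (negative
branch lengths clamped to 0; Q-criterion ties broken by the
lexicographically smallest label pair for determinism), an exact
edge-bipartition monophyly test, and a column bootstrap.  Replicates in
which some pair has no comparable column are discarded and logged rather
than imputed.

## Rate feasibility

`rate_feasibility(d_obs, T_years, baseline)` treats the conventional
1.5–2.5% per million years figure as a *pairwise-divergence accumulation
rate* (the common usage of that figure; the alternative per-lineage reading
would halve the folds and is documented here precisely because the choice
is not neutral).  The required rate is `d_obs / T_years`; folds are
required/baseline.  Whether `d_obs` should be the maximum or the total
pairwise divergence among alleles is the user's modelling decision — both
are computable from an alignment with `p_distance()` — so the function
exposes `d_obs` as an input rather than guessing.

## Numerical and design choices

* Coordinates are 0-based half-open internally; 1-based inclusive in every
  file and report (VCF convention).  `find_primer_sites()` is the one
  deliberate exception: its positions are 0-based template offsets, as its
  documentation states.
* The VCF dialect is minimal v4.2, single-contig, GT-only; non-biallelic
  sites, non-SNPs and FILTER failures are dropped into an explicit
  drop-log, so `dropped + retained = input` is checkable.  Phase is
  discarded (`|` read as `/`).  The published analysis removed "LowQual"
  genotypes before windowing without stating how that interacted with
  window site counts; the drop-log makes our equivalent explicit.
* `theta_site = 0` is accepted (degenerate no-diversity pools are useful in
  tests) even though ordinary use keeps it in `(0, 0.5)`.
* Tie-breaks everywhere are deterministic: leftmost window for scan
  argmins, lexicographic label pairs in NJ, lexicographic sequence order
  for variant naming.

## Known limitations

The sweep generator is phenomenological (above); the PCR model has no
thermodynamics, so primer specificity in the simulation is structural
(protected, forced-divergent footprints) rather than kinetic; FASTA headers
carry only id/gene/region, so feature annotation travels in side tables;
and the monophyly surrogate inherits the usual caveats of distance methods
under rate heterogeneity, which the planted designs deliberately avoid.
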