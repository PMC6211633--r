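# chimerapop

Population-genetic analysis of chimeric genes born by unequal
crossing-over between tandem paralogs — motivated by the
insecticide-resistance cytochrome P450 gene *CYP337B3* of the cotton
bollworm *Helicoverpa armigera*, a fusion whose 5' coding sequence derives
from *CYP337B2* and whose 3' coding sequence and intron derive from
*CYP337B1*.

The package is for population geneticists and molecular entomologists who
need to take such a locus from raw field-survey material to inference:

* **in-silico PCR genotyping** — model the diagnostic assay (one primer per
  parental gene, amplifying only across the chimeric junction) on diploid
  haplotype templates: `find_primer_sites()`, `predict_amplicon()`,
  `classify_genotype()`, `screen_population()`;
* **crossover breakpoint mapping** — bound each allele's recombination
  point by informative sites against the aligned parents, flag
  gene-conversion candidates, and cluster alleles into exact-sequence
  variants: `informative_sites()`, `map_crossover()`, `type_alleles()`;
* **frequency tables** — genotype-class and allele frequencies per region,
  with carriage (at least one chimeric allele) percentages:
  `species_filter()`, `genotype_frequency_table()`,
  `allele_frequency_table()`;
* **selective-sweep scan** — sliding-window nucleotide diversity and
  Tajima's D implemented from the statistics' definitions over a minimal
  single-contig VCF: `read_vcf_biallelic()`, `sweep_scan()`,
  `sweep_report()`.  Per window of span `w` with `n` haplotypes and derived
  count `j` per site,
  `pi = sum_sites 2 j (n−j) / (n (n−1)) / w` and
  `D = (theta_pi − S/a1) / sqrt(e1 S + e2 S (S−1))`
  with Tajima's usual constants;
* **origins** — p-distance + neighbor-joining monophyly assessment of
  chimeric-allele introns with column bootstrap, and a divergence-rate
  feasibility check of whether allelic diversity could have arisen within
  the insecticide era: `nj_tree()`, `is_monophyletic()`,
  `monophyly_bootstrap()`, `rate_feasibility()`;
* **synthetic data** — a fully seeded generator that plants every truth the
  pipeline recovers (parental allele pools, single-crossover chimeras,
  regional diploid populations, sweep footprints, single- vs multi-donor
  intron alignments): `simulation_config()`, `simulate_locus()`,
  `simulate_variant_matrix()`, `simulate_origin_alignment()`.

## Worked example

```r
library(chimerapop)
options(chimerapop.log_level = "warn")

# a global survey: 300 diploids, 88/9/3% genotype split, 8 chimeric alleles
cfg <- preset_paper_global(seed = 1, n = 300)
sim <- simulate_locus(cfg)
refs <- screening_products(sim$chimera_pool, sim$primers)
tab <- screen_population(sim$population$templates, sim$primers,
                         allele_refs = refs)
tab$region <- "Global"
genotype_frequency_table(tab, "global")
#>    group   n n_B3B3 n_B3par n_parpar n_unknown pct_B3B3 pct_B3par pct_parpar carriage_pct
#> 1 global 300    265      24       11         0     88.3         8       3.67         96.3
```

265 of 300 simulated individuals are homozygous for the chimera, 24
heterozygous, 11 carry only the parental genes — 96.3% carriage, matching
the configured 88/9/3 world up to sampling noise, and every call agrees
with the generator's planted truth.

```r
# sweep scan over a 150 kb segment with a sweep planted at 75 kb
vm <- simulate_variant_matrix(cfg)
ws <- sweep_scan(vm, window_bp = 2500, step_bp = 1250)
sweep_report(ws)$min_pi_window
#> min pi = 0.00981 in window [73751, 76250]   (planted center: 75000)
#> segment-wide mean pi = 0.0514, mean D = -0.043, D in min-pi window = -1.541
```

The diversity trough localises the planted sweep center to within one
window, and Tajima's D in that window (−1.54) sits far below the
segment-wide mean (−0.04): the rare-variant excess of a hard sweep.

```r
# did the chimera arise once?  bootstrap monophyly of intron alignments
oa <- simulate_origin_alignment(n_donors = 1, seed = 1)   # single origin
monophyly_bootstrap(oa$alignment, oa$b3_labels, 200, seed = 1)
#> 0.985
ob <- simulate_origin_alignment(n_donors = 2, seed = 1)   # two donors
monophyly_bootstrap(ob$alignment, ob$b3_labels, 200, seed = 1)
#> 0

# could the observed allelic divergence postdate pyrethroid use?
rate_feasibility(0.001, 50)
#> <rate_feasibility> d=0.001 over 50 yr -> 2e-05 /site/yr;
#>                    800-1333 x the 1.5-2.5%/Myr baseline
```

A pairwise divergence of only 0.1% would already require a rate 800–1333×
the fast mitochondrial baseline to accumulate in 50 years — the arithmetic
behind preferring selection on standing variation over recent *de novo*
origin.

## Command line

```sh
exec/chimerapop simulate --preset paper-global --seed 1 --n 300 --out-dir out/
exec/chimerapop detect --templates out/templates.fasta --primers out/primers.tsv \
    --out out/genotypes.tsv
exec/chimerapop sweep --vcf out/variants.vcf --out-prefix out/sweep
exec/chimerapop origins --alignment introns.fasta --b3-labels b3.txt \
    --replicates 1000 --seed 1 --rate-d 0.001 --rate-T 50 --out-prefix out/orig
```

Every flag can also be given through `--config file` (flat `key = value`
lines); explicit flags win.

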