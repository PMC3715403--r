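# vardb

`vardb` is an R toolkit for exploring genetic variation from cohort and
family sequencing studies. It loads a VCF (with its sample genotypes), an
optional PED pedigree, snpEff/VEP transcript-consequence annotations, and
any number of user-supplied interval annotation tracks (BED / GFF3 /
sites-only VCF) into **one SQLite file**, then lets you interrogate it
with SQL extended by a per-sample genotype filter language and with
built-in family-genetics screens. It is aimed at medical and population
geneticists who want reproducible, shareable variant analyses without
ad-hoc pipeline scripts.

## What it stores and computes

* One `variants` row per biallelic record (multi-allelic sites are split,
  genotypes recoded per ALT). Genotype information for all samples —
  genotype string, type code, phase, depth — is packed into four
  compressed arrays stored as BLOB columns, so the table size is
  independent of cohort width.
* Per-site statistics with every row: genotype-type counts, call rate,
  alternate allele frequency `aaf = (n_het + 2 n_homalt) / (2 n_called)`,
  a 1-df Hardy-Weinberg chi-square p-value, the inbreeding coefficient
  `F = 1 − Ho/(2p̂q̂)`, and per-site nucleotide diversity
  `π = 2j(m−j)/(m(m−1))`.
* A `variant_impacts` table with standardized consequences (one shared
  Sequence Ontology vocabulary, fixed HIGH/MED/LOW severity map, `is_lof`
  flag, one primary impact per variant).
* `samples` (pedigree) and `resources` (path + MD5 of every input) tables.

Queries use plain SQL plus a `COLUMN.SAMPLE` notation, e.g.

```
select chrom, start, gts.proband from variants where is_lof = 1
  --gt-filter "gt_types.mom == HET and gt_types.dad == HET and gt_types.proband == HOM_ALT"
```

Family screens: `find_de_novo()`, `find_autosomal_recessive()`,
`find_autosomal_dominant()`, `find_comp_hets()` (phase- and
parental-origin-aware). Gene-set and protein-interaction tools:
`sample_pathways()`, `sample_interactions()`. A synthetic-fixture
generator (`simulate_cohort()`, `simulate_families()`, `make_tracks()`)
emits VCF/PED/track files with ground-truth labels for testing.

## Worked example

```r
library(vardb)

# a two-trio study with planted inheritance events and known truth
fx <- simulate_families(n_variants = 1000, seed = 42)
vardb_load("study.db", fx$vcf, ped = fx$ped)

s <- open_session("study.db")
s
#> <vardb session> study.db
#>   1000 variants, 6 samples, schema v1

# MED-severity variants fitting a recessive model in the affected child
run_query(s,
  'select variant_id, chrom, start, ref, alt, gene, aaf, gts.kid1
     from variants where impact_severity = "MED"',
  gt_filter = "gt_types.kid1 == HOM_ALT and gt_types.mom1 == HET and gt_types.dad1 == HET")
#>   variant_id chrom start ref alt    gene       aaf gts.kid1
#> 1         24  chr1  1229   A   T EV00024 0.3333333      T/T
#> 2         49  chr1  1479   C   T EV00049 0.3333333      T/T
#> 3        128  chr1  2269   A   G EV00128 0.3333333      G/G
#> 4        303  chr1  4019   T   A EV00303 0.3333333      A/A
#> 5        634  chr1  7329   T   C EV00634 0.3333333      C/C

# the built-in de novo screen (depth-gated)
dn <- find_de_novo(s, min_depth = 10)
head(dn[, c("variant_id", "family_id", "gene", "gt_child", "gt_father", "gt_mother")], 3)
#>   variant_id family_id    gene gt_child gt_father gt_mother
#> 1         74      fam1 EV00074      A/G       A/A       A/A
#> 2        146      fam1 EV00146      G/C       G/G       G/G
#> 3        153      fam1 EV00153      C/T       C/C       C/C
close_session(s)
```

Each query row is a variant passing both the SQL conditions and the
genotype filter; `gts.kid1` is the child's actual base-level genotype
decoded from the packed arrays, and `aaf` = 1/3 reflects four alternate
alleles among the twelve in the six-sample cohort. The de novo rows show
the supporting genotypes (child heterozygous, both parents homozygous
reference), one row per variant and trio.

A command-line wrapper with the same surface is installed at
`inst/cli/vardb` (`vardb load`, `vardb query -q ... --gt-filter ...`,
`vardb de_novo`, `vardb comp_hets`, `vardb pathways`, `vardb fixtures`,
...).

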