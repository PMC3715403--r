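---
title: "vardb: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vardb: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vardb)
```

# The problem

Cohort and family sequencing studies produce VCF files with millions of
variant rows and tens to thousands of per-sample genotype columns, while the
evidence needed to interpret a variant — population frequency, predicted
transcript consequence, overlap with regulatory or repeat annotation, its
segregation within a family — lives in many other files and formats.
`vardb` loads everything into one SQLite file so that a researcher can ask
integrative questions in SQL ("novel, rare loss-of-function variants where
the proband is heterozygous and both parents are not") without writing
pipeline code.

The package follows the architecture of variant-warehouse tools in this
field: one `variants` row per (biallelic) variant with its statistics and
annotation columns, a `variant_impacts` table with one row per transcript
consequence, a `samples` table carrying the pedigree, and a `resources`
table recording the provenance (path + MD5) of every input so a database is
self-describing.

# Genotype storage model

A naive layout — one row per (variant, sample) genotype — multiplies row
count by cohort size and collapses query performance. `vardb` instead
serializes the four per-sample arrays of each variant (genotype string,
genotype type code, phase flag, read depth) into a fixed little-endian
binary layout, compresses each with zlib, and stores them as four BLOB
columns of the variant row. Because most variants are rare, most genotype
arrays are near-constant and compress heavily. The blob carries a codec
tag, the element count and an Adler-style checksum of the uncompressed
payload, so future codecs can coexist and corrupted blobs are detected
rather than silently mis-decoded. Packing is deterministic: identical
arrays give byte-identical blobs, which the load-determinism contract
below relies on.

Genotype type codes are a fixed public contract: `HOM_REF = 0`, `HET = 1`,
`UNKNOWN = 2`, `HOM_ALT = 3`. `UNKNOWN` means *uncalled*; missing depth is
stored as `-1`, never `0`, so a depth filter can distinguish "no data"
from "zero reads".

**Multi-allelic sites** are split at load into one record per ALT allele.
Genotypes are recoded relative to that allele; a genotype carrying a
*different* ALT becomes uncalled for the split record. This keeps every
downstream definition (heterozygote, allele frequency, inheritance
patterns) unambiguous on a one-row-per-variant table. The cost is that a
`1/2` genotype is invisible to both split records, which slightly
undercounts carriers at truly multi-allelic sites.

# Per-site statistics

For each (split) record the loader stores the genotype-type counts, call
rate, and the alternate allele frequency among called alleles
$\mathrm{aaf} = (n_{het} + 2 n_{homalt}) / (2 n_{called})$, plus three
population-genetics summaries:

* **Hardy-Weinberg test**: Pearson chi-square with 1 degree of freedom, no
  continuity correction, of observed genotype counts against
  $n(\hat p^2, 2\hat p\hat q, \hat q^2)$ with $\hat p$ estimated from the
  same counts. The stored `hwe` column is the upper-tail p-value. An exact
  test was deliberately not implemented: the chi-square is the minimal
  standard choice and is cheap at any cohort size; at monomorphic sites
  observed equals expected so `chi2 = 0`, `p = 1`.
* **Inbreeding coefficient**: $F = 1 - H_o / (2\hat p\hat q)$; undefined
  (NULL) at monomorphic sites.
* **Nucleotide diversity**: the unbiased per-site heterozygosity
  $\pi = 2 j (m - j) / (m (m-1))$ with $j$ alternate alleles among $m$
  called alleles.

Undefined statistics are stored as SQL NULL, never as sentinel numbers.
These formulas are this package's documented contract; the tests pin them
to hand-computed values (counts (50, 30, 20) give
$\chi^2 = 11.605$, $F = 0.3407$, $\pi = 0.4573$) and to calibration under
simulated Hardy-Weinberg cohorts.

# The genotype-filter language

SQLite cannot see inside the packed arrays, so per-sample conditions use a
small expression language applied *after* the SQL runs, by decompressing
each candidate row:

```
expr  := or ; or := and ("or" and)* ; and := unary ("and" unary)*
unary := "not" unary | "(" expr ")" | cmp
cmp   := COLUMN "." SAMPLE OP literal
```

with `COLUMN` one of `gts`, `gt_types`, `gt_phases`, `gt_depths` and the
type names `HOM_REF/HET/HOM_ALT/UNKNOWN` as case-insensitive keywords (the
spaced `=  =` spelling seen in the field's literature is accepted). The
same `COLUMN.SAMPLE` notation in a select list expands to per-sample
values. This post-SQL design is also the honest performance model:
genotype-filtered queries pay for decompression of every row the SQL
returns.

**Missing data.** Comparing an uncalled genotype with `==` is false, and
`!=` is true only for called values, unless the literal itself is
`UNKNOWN`/`"./."`. Missing depth (`-1`) follows plain numeric semantics by
default, because "depth below 10" legitimately includes "no reads"; the
`strict_missing` option makes any comparison on missing data false for
analyses that must not count absent evidence. These rules are enforced
identically in the evaluator and re-stated independently in the test
suite's naive interpreter.

# Loading and determinism

`variant_id` is assigned sequentially in post-split file order *before*
any chunking, chunks are fixed record counts (default 10,000), and chunk
results are merged back in id order. Parallel workers (`cores > 1`,
forked processes) therefore cannot permute ids or content: the canonical
dump of a database is byte-identical for any core count, chunk size or
transaction batch size, and the suite verifies this. Cluster schedulers
are out of scope; the contract is process-level parallelism on one
machine.

# Annotation tracks

Tracks are BED (0-based half-open), GFF3 (1-based inclusive, attribute
extraction) or sites-only VCF files. All intervals are normalized to
0-based half-open and indexed per chromosome with IRanges; a variant's
annotation region is its `[start, end)` span, so SNPs have width 1 and
deletions span the deleted bases. Chromosome names are matched with and
without the `chr` prefix. Strand is ignored — variants are unstranded.
Extract mode joins the unique, lexicographically sorted values of
overlapping records (or takes the numeric maximum), so results are
independent of track file line order. Sites-VCF tracks match by position
overlap by default — the common dbSNP-membership semantics — with an
option requiring REF+ALT identity. Structural variants with imprecise
breakpoints are annotated over their literal `[start, end)` span.

# Family screens

All screens exclude X/Y chromosomes and skip any variant with an uncalled
genotype among the family members tested — missing genotypes are never
guessed.

* **De novo**: both parents HOM_REF, child HET. The reversion
  configuration (parents HOM_ALT, child HET) is excluded by default as a
  likely artifact, behind `include_reversions`. `min_depth > 0` requires
  all three depths to reach the threshold; `min_depth = 0` applies no
  depth condition (a literal `depth >= 0` rule would silently reject any
  VCF without DP fields, where depth is recorded as missing).
* **Autosomal recessive**: affected child HOM_ALT, unaffected parents HET.
* **Autosomal dominant**: every affected member HET, every unaffected
  member HOM_REF (relaxable with `allow_unaffected_carriers` for reduced
  penetrance), and every affected member with genotyped parents must have
  an affected parent — without this transmission rule every de novo
  candidate would double-report as dominant.
* **Compound heterozygotes**: per sample and gene, pairs of variants where
  the sample is HET at both, restricted by default to primary-impact
  severity MED or higher. Phased genotypes are the strongest evidence
  (require opposite haplotypes); otherwise parental origin is used (each
  site exactly one carrier parent, different parents); with neither, the
  pair is reported as `unphased` — putative, not confirmed. Pairs whose
  origin is ambiguous with parents available are dropped rather than
  demoted to putative.

The rules above are this package's documented contract — the underlying
genotype configurations are standard but their edge cases (reversions,
penetrance, origin ambiguity) are rarely written down precisely, so they
are fixed here and pinned by tests.

# Consequence standardization

snpEff (`ANN`, legacy `EFF`) and VEP (`CSQ`) annotations are normalized to
one Sequence Ontology vocabulary; legacy EFF effect names go through a
shipped synonym table. Severity is assigned from the term itself via a
fixed three-level map (HIGH = stop/frameshift/essential-splice/ablation
classes, MED = missense-class, LOW = everything else), never copied from
the annotator's own impact field, so mixed-tool projects are comparable.
`is_lof` marks the classic loss-of-function classes and implies HIGH.
Exactly one impact per variant is flagged primary: highest severity, ties
broken by lexicographically smallest transcript id, then input order.
When a VCF carries both snpEff and VEP annotations the loader refuses to
guess and asks for `impact_source` — reconciling two annotators'
transcript models is not a job to do silently.

# The synthetic-fixture generator

The generator defines the study conditions every guarantee is tested
under, so its defaults are fixed and documented:

* cohort sites draw allele frequencies from Beta(0.5, 5) — a
  rare-variant-heavy site-frequency spectrum — with i.i.d. Hardy-Weinberg
  genotypes, uniform missingness, and Poisson(30) depths;
* family fixtures emit two trios (one with an affected child and
  unaffected parents, one with an affected father and child), transmit
  background variants by Mendelian sampling from Hardy-Weinberg founders,
  and *rejection-sample* backgrounds so no unplanted site matches a
  screened pattern; planted events are constructed to satisfy exactly one
  pattern each, and cis compound-het decoys are emitted phased in both
  the child and the transmitting mother so they are rejected as cis for
  every sample, not just the child;
* truth tables are computed by straightforward standalone code in the
  generator, deliberately separate from the modules they are compared
  against.

What the generator does not emulate: linkage disequilibrium,
recombination, sequencing error models, population structure, or
relatedness beyond the declared pedigrees. Passing tests therefore
demonstrate correctness of the bookkeeping and the screens' logic on
clean, well-formed data — not robustness to caller artifacts or cryptic
relatedness in real cohorts.

# Problem sizes used in the checks

The verification suite exercises: 50 randomized SQL + genotype-filter
queries on a 5,000-variant x 20-sample cohort against a brute-force scan;
five seeds of 1,000-variant family fixtures with planted events (7 de
novo, 5 recessive, 5 dominant, 4 trans compound-het pairs plus 4 cis
decoys); 2,000 simulated Hardy-Weinberg sites of 500 diploids for
calibration (expecting the p < 0.05 fraction in [0.03, 0.07] and mean F
in [-0.02, 0.02]) and planted F of 0.1/0.25 recovered within 0.03;
10,000 randomized codec round trips; three core counts on a
2,000-variant load; 1,000 x 1,000 random interval/variant pairs against
the all-pairs oracle; and a 200-sample x 1,000-variant database compared
against its uncompressed tab-serialized genotype content. These sizes
were chosen as the smallest at which the statistical checks have
negligible error probability.

# Known limitations

* Structural variants are stored and typed but BND algebra is not
  interpreted; spans are literal.
* The recessive screen requires called HET parents — it will not screen
  cohorts without parental genotypes (use the query DSL directly there).
* Gene matching in the pathway/interaction tools is by uppercased symbol;
  alias resolution belongs to the catalog curation step upstream.
* One consequence source per load; the genotype filter runs post-SQL and
  scans every SQL-returned row.
* Appending samples to an existing database is not supported; reload from
  the merged VCF instead.
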