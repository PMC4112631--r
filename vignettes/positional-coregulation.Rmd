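---
title: "Positional co-regulation of adjacent genes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positional co-regulation of adjacent genes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adjacoreg)
```

## The scientific question

Mutants of the plant topoisomerase VI (TopoVI) complex misregulate large,
ontologically unrelated gene sets. One mechanistic signature distinguishes
chromatin-level action from pathway-level action: if the complex remodels
chromatin locally, deregulated genes should cluster at *immediately
adjacent* chromosomal positions more often than chance allows, and the
clustering should be indifferent to gene orientation. `adjacoreg`
implements that test and the companion analyses of a TopoVI subunit B
mutant study: cross-study concordance of deregulated gene lists, Mendelian
segregation tests, starch phenotype summaries, and the molecular
consequence of the causal splice-donor mutation.

## Adjacency model

The positional substrate is a **gene catalogue**: all annotated genes of a
genome, sorted within each chromosome by (start, end, gene id). Two genes
are *immediately adjacent* when they occupy consecutive ranks — no
annotated gene of any kind between them. This is the strictest reading of
adjacency; it is deterministic and makes the detected structures easy to
audit.

Given a deregulated gene set with signs (selected at |log2FC| ≥ 0.8,
i.e. 1.74-fold, and p ≤ 0.05 by default):

* a **co-regulated set** is a *maximal* run of ≥ 2 consecutive-rank genes,
  all deregulated in the same direction. A maximal run counts once whatever
  its length, so three consecutive up-regulated genes are one set of three,
  not two pairs;
* a **discordant pair** is any consecutive-rank pair of deregulated genes
  with opposite signs. A gene may terminate a concordant run *and* sit in a
  discordant pair (signs +, +, − give one set and one pair); counting
  otherwise under-reports discordance;
* adjacent pairs whose members share a `family_id` are **duplicate cases**:
  co-regulation there is attributed to duplicated regulatory elements, so
  the duplicate *edge* is cut and counted. Only the edge is discounted — a
  duplicate gene can still genuinely co-regulate with its other neighbour.
  An isolated duplicate pair therefore disappears; a longer run is
  shortened. The family map is a user input: the package does not infer
  paralogy.

Per-set descriptive statistics are the opposite-strand fraction over
within-set neighbouring pairs (high values argue against transcriptional
read-through) and the genomic span, defined inclusively as
max end − min start + 1; an exclusive variant (subtracting the two
boundary bases) is available by flag since "distance between distal ends"
admits both readings.

## Three null models

**Control-gene chi-square.** The null cohort is built from the genes with
the smallest |log2FC|, taken alternately from the positive and negative
pools so the sign counts differ by at most one ("symmetrically distributed
about zero"; the set's mean log2FC is additionally checked against a
±0.05 tolerance, configurable). Ties on |log2FC| break by gene id, making
the set reproducible. The test is a df = 1 Pearson chi-square, no
continuity correction, on cohort (deregulated vs control) × membership in
a same-sign adjacent *significant* run. Membership requires statistical
significance for both cohorts: co-regulation means concordant *change*,
not a concordant sign of near-zero noise. Control genes, having minimal
fold changes and mostly large p-values, almost never qualify — that
asymmetry is where the test's power comes from, and it is the construction
consistent with the source study's reported control counts. Because the
contingency construction is genuinely not unique, the permutation null
below is provided as the model-free alternative.

**Binomial sign null.** With `p` the fraction of up-regulated genes among
all deregulated genes and `q = 1 − p`, a chance adjacency of two
deregulated genes is concordant with probability `p² + q²` and discordant
with `2pq`. Observed discordant pairs calibrate the chance rate:
`expected concordant = n_discordant × (p² + q²) / 2pq`. The enrichment
ratio divides observed concordant sets by this expectation, and an exact
binomial tail probability is attached. From the study's printed counts
(27 + 24 sets, 14 discordant pairs, 559 up / 514 down genes) this gives
14.05 expected and a ratio of 3.63 — "more than three times" chance.
With zero discordant pairs the expectation is undefined and the ratio is
reported as `Inf`, never silently as a number.

**Permutation null.** Deregulation labels are reassigned uniformly over
catalogue positions (preserving the up and down counts), the concordant
run count recomputed, and the empirical p-value reported as
`(1 + #(null ≥ observed)) / (n_perm + 1)`. A single integer seed drives
the permutation stream through `withr::with_seed`, so results are
bit-reproducible and the caller's RNG state is untouched.

## Cross-study concordance

A reference list records which genes an external study reported as changed
and in which direction. **Overall concordance** counts reference genes
significantly changed in the query in *either* direction (default filter:
p ≤ 0.05, any nonzero fold); **strict concordance** requires the direction
to match. Reference genes absent from the query platform stay in the
denominator — that convention reproduces the published percentages
(34/113 = 30%) — with `drop_unmeasured = TRUE` as the alternative. Display
percentages are rounded to integers as in the source tables; unrounded
values are always retained alongside. Strict can never exceed overall,
which the test suite checks as an invariant.

## Genetics statistics

Segregation tests are Pearson goodness-of-fit chi-squares against a
Mendelian ratio (1 mutant : 3 wild type for non-complementation). No Yates
correction is applied: the printed p-values (0.32, 0.77) are only
reproduced without it. Group summaries report mean and SEM (sample SD over
√n). Fold effects are ratios rounded half away from zero, the convention
implied by the printed starch table; note the printed mutant-leaf SEM
(2.25) was evidently computed from unrounded raw data, since the printed
triple yields 2.2553. End-of-night fold columns in that table similarly do
not equal ratios of the printed means and are therefore not reproduced.
Both pooled-variance and paired t-tests are exposed because the source
figure legend conflates the two; the choice is an explicit flag.

## Splice-donor mutation consequences

A `splice_gene_model` holds ordered exon and intron sequences, the CDS
offset, and the annotated protein length. The donor consensus check is the
invariant GT dinucleotide at intron positions 1–2 — no position-weight
matrix, because the claim under test concerns nucleotide 1 only. Intron
retention concatenates the intron in place; translation (standard nuclear
code, UGA/UAA/UAG stops, via Biostrings with a hand-coded codon-table
oracle in the tests) proceeds from the CDS start to the first stop.

One subtlety matters: the donor mutation itself sits at intron nucleotide
1, so the retained mutant intron differs from the wild-type intron in its
first codon. `predict_truncation()` therefore accepts the variant and
applies it before translating — the synthetic fixture's novel peptide
IIIYSYQV begins with Ile precisely because G→A turns GTT (Val) into ATT
(Ile). The fixture mirrors the study gene's geometry exactly (2212 nt
mature mRNA, 670-residue protein, 100 nt 5′ UTR, 300 nt intron 7 located
immediately after the codon of Met198, in frame), so retention yields a
2512 nt transcript, 8 novel residues, a stop whose first base is intron
nucleotide 25, and 472 lost C-terminal residues. Seeds vary only filler
sequence, never this arithmetic. The real gene's sequences are not
bundled; the fixture is synthetic and labelled as such. The hypothesised
cryptic donor 21 nucleotides into the intron is modelled by
`alternative_donor_splice()`, off by default, which reports the 7
in-frame extra residues.

## Synthetic data generator

The generator produces what the analyses consume, with the statistical
structure they assume:

* **Genome**: 5 chromosomes × 1000 genes by default; log-normal gene
  lengths (mean ≈ 2.2 kb) and intergenic gaps (mean ≈ 2 kb), Bernoulli(0.5)
  strands — compact plant-genome-like spacing. Genes never overlap.
* **Expression**: null genes get Gaussian log2FC noise (sd 0.3) and
  uniform p-values. About 4% of genes are scattered *singleton*
  deregulated genes — mirroring a deregulated cohort of ~1073 in 25673
  genes that is dominated by positional singletons — and these may land
  next to each other, so chance concordant and discordant adjacencies
  arise naturally. Ten injected blocks of 2 consecutive genes at ±2 log2
  units (sign per block) carry the true positional signal; 5 adjacent
  duplicate pairs share a family id and correlated folds. Injected
  p-values follow a scaled Beta(1, 20) (scale 10⁻³) so thresholding
  behaves smoothly. Injected features are placed with a one-gene buffer so
  blocks remain unambiguous truth units.
* **Segregation** draws are binomial; **splice fixtures** are described
  above.

A single integer seed makes every product bit-reproducible; derived seeds
stay within 32-bit range.

What the generator does *not* emulate: microarray intensities, dye effects
or normalization (the study used an established two-colour pipeline for
that), correlated expression neighbourhoods beyond the injected blocks,
chromosome-scale density gradients, and real paralogy structure. Passing
tests therefore demonstrate that the statistics behave correctly under the
stated generative assumptions — calibrated nulls, recovered injections —
not that any particular biological dataset will show enrichment.

## Numerical choices and problem sizes

* Ordering ties in the catalogue break by (start, end, gene id);
  overlapping genes are permitted.
* BED input (0-based half-open) converts to 1-based inclusive on ingest;
  GFF3 ingests feature type `gene` only. Format parsing is delegated to
  `rtracklayer`; the package's own TSV reader reports malformed rows by
  line number.
* The p-value threshold boundary is inclusive (p ≤ 0.05), matching the
  reading of "P < 0.05" that keeps boundary cases; both thresholds are
  parameters.
* Empty inputs yield typed empty results; undefined statistics (strand
  fraction of no sets, chi-square on a zero margin, expectation with zero
  discordant pairs) surface as `NA`/`Inf`/errors, never as silent zeros.
* Calibration checks run 200 replicate null genomes (2 × 500 genes,
  99 permutations each) with deregulation called at relaxed thresholds
  (|log2FC| ≥ 0.3, p ≤ 0.5): a null label set large enough to give the
  discrete set-count statistic a well-spread distribution, keeping the
  empirical p informative. Recovery checks use the default 5000-gene
  genome over 20 seeds. These sizes make the whole suite run in well under
  a minute while leaving the binomial acceptance bands tight.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 101)
catalogue <- simulate_genome(cfg)
sim <- simulate_expression(catalogue, cfg)
report <- run_adjacency_analysis(catalogue, sim$de_table,
                                 family_map = sim$family_map)
report
perm <- permutation_null(catalogue, sim$de_table, n_perm = 999, seed = 101)
perm$empirical_p
```

The `analysis/` directory runs this workflow end to end as numbered
scripts, and `reproduce_study_statistics()` prints the consolidated
pass/fail table of every published desk-scale value the package
recomputes.

## Limitations

The adjacency statistics are positional only: no claim about chromatin
mechanism follows from them, and no Hi-C or epigenomic integration is
attempted. The chi-square's contingency construction is a modelling choice
(documented above) — readers wanting a construction-free answer should
quote the permutation p. External studies' gene lists are inputs, not
re-derived; the genome-scale published counts (27/24/14 sets and pairs,
56% opposite strands, 8 kbp mean span) depend on the study's own DE table
and annotation release and are reproduced here in structure, not in
number.
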