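---
title: "Mapping pathogenic mutation hotspots onto a reference kinase domain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping pathogenic mutation hotspots onto a reference kinase domain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Protein kinases share a conserved catalytic domain of roughly 250-300
residues. Because the domain is structurally conserved across hundreds of
human kinases, clinically observed missense variants from many different
genes can be projected onto a *single* reference kinase structure: a
structure-based multiple sequence alignment (MSA) gives each variant an
alignment column, and the column gives a residue of the reference
structure. Positions of the reference that accumulate many mutations across
the kinome — mutation *hotspots* — point at residues whose perturbation is
recurrently pathogenic, and splitting the mutations by disease class
(cancer-related versus not) asks whether a position is preferentially hit
in one disease context.

`kinasehotspots` implements this projection pipeline end to end:

1. **Parse and filter** a ClinVar-style variant table: keep records asserted
   `Pathogenic` or `Likely pathogenic` whose protein change is a single
   amino-acid substitution.
2. **Map** each variant through the MSA onto the reference structure,
   excluding variants that align to columns where the reference is gapped.
3. **Classify** each record's medical conditions as cancer or non-cancer.
4. **Count** mutations per reference position per class and call the top
   5 percent most-mutated positions per class as hotspots.
5. **Test** each position for over- or under-representation of cancer
   mutations with a 2x2 chi-square test.
6. **Annotate** the reference PDB with per-position counts in the B-factor
   column for visualisation, and run a parallel branch for common benign
   variants (population allele frequency >= 1 percent) as a per-residue
   mutability baseline.

## Coordinate model

All coordinates are 1-based, matching HGVS protein numbering and PDB
residue numbering. Each MSA row carries an `offset`, the full-protein
residue number of its first aligned residue, so a variant at protein
position $p$ sits at the $(p - \mathrm{offset} + 1)$-th non-gap character of
its row. Reference residue numbers come from the structure file's author
numbering, not from any external coordinate system — hotspots are reported
in the numbering a structure viewer will display. Mapping is conservative
by construction: every input record ends as exactly one of `mapped`,
`excluded_reference_gap`, `excluded_out_of_domain`,
`excluded_ref_mismatch`, or `unmatched_gene`, and each non-mapped record is
written to a machine-readable exclusion log.

By default (`verify_ref_aa = TRUE`) the amino acid stated in the variant's
substitution must equal the MSA residue at the mapped cell; disagreements
(typically isoform or numbering mismatches in real exports) are excluded
and logged rather than raising an error, since they are expected at low
rates in real data. Genes contributing several alignment rows
(multi-domain kinases) are mapped against every row; a residue number that
is in-domain in more than one row is ambiguous and raises an error rather
than guessing.

## Statistics

Let $c_i$ and $n_i$ be the cancer and non-cancer mutation counts at
reference position $i$, and $C = \sum_i c_i$, $N = \sum_i n_i$ the class
totals. The per-position quantities are

$$f^{obs}_{c,i} = c_i / C, \qquad
  f^{obs}_{n,i} = n_i / N, \qquad
  f^{exp}_i = (c_i + n_i) / (C + N),$$

and the representation ratio $r_i = f^{obs}_{c,i} / f^{exp}_i$; $r_i > 1$
means cancer mutations are over-represented at $i$ (and necessarily
non-cancer mutations under-represented — the two ratios always sit on
opposite sides of 1). Significance is assessed with a Pearson chi-square
test (1 df) on the 2x2 table

$$\begin{pmatrix} c_i & C - c_i \\ n_i & N - n_i \end{pmatrix},$$

i.e. the cancer:non-cancer composition at the position against the
composition everywhere else. A position is labeled `over_cancer` when
$p < \alpha$ and $r_i > 1$, `over_noncancer` when $p < \alpha$ and
$r_i < 1$. Raw p-values are used at $\alpha = 0.05$ by default, with no
multiple-testing correction; `bh = TRUE` switches the labelling to
Benjamini-Hochberg adjusted p-values as a clearly optional extension.

Numerical conventions: an empty class ($C = 0$) yields `NA` frequencies,
never a division error; positions with $c_i + n_i = 0$ are `undefined` and
skipped; a degenerate table (all mutations of both classes at the single
position) has identical row profiles and is reported as $\chi^2 = 0$,
$p = 1$; positions with any expected cell below 5 are flagged
(`small_expected`) but not removed. The Yates continuity correction is ON
by default, matching the default of `chisq.test()` on 2x2 tables in R;
`yates = FALSE` reproduces the uncorrected convention.

## Hotspot calling and tie handling

A class's hotspots are the top `quantile` (default 0.05) positions by
count. The quantile base is a genuinely open design choice:

* `base = "mutated"` (default): the candidate set is positions with at
  least one mutation of the class, so the number of hotspots tracks the
  amount of mutation data rather than the domain length;
* `base = "structure"`: the quantile is taken over every reference
  position, which is the natural reading when most positions are mutated.

On densely mutated data the two nearly coincide; on sparse data they
diverge strongly (with $m$ mutated positions, `"mutated"` calls
$\lceil 0.05\,m \rceil$ hotspots, which for $m < 20$ is a single
position). In every case $k = \lceil q \cdot m \rceil$ positions are taken
by descending count and **every position tied with the k-th count is
included**: selection is deterministic (count descending, then residue
number ascending) and never drops a tied position arbitrarily.

The counting unit is the input record: each record adds 1 to each class it
belongs to at its position. A record whose conditions span both classes
(one mutation can be relevant to several diseases) counts once in *each*
class. `collapse_aa = TRUE` optionally collapses duplicate records of the
same gene and amino-acid change before counting. Benign counts are tracked
per position but never participate in hotspot selection.

## Condition classification

Assigning each condition string to cancer/non-cancer is, in practice, a
curation step that cannot be reproduced exactly from published methods.
The package replaces it with a reproducible surrogate: a keyword lexicon
(`carcinoma`, `melanoma`, `leukemia`, `neoplasm`, `tumor`, `sarcoma`,
`blastoma`, ... as lowercase substrings) marks a condition as cancer, an
exact-string override table takes precedence over keywords (and supplies
the `ignore` class for entries like "not provided"), and everything else
defaults to non-cancer. Every run emits an audit table listing each
distinct condition, its assigned class, and whether an override, a keyword
or the default decided it — so the automated split is fully reviewable and
correctable via a two-column override TSV. `Likely benign` records are
excluded from the benign branch by default (only asserted-`Benign` records
carry the intended meaning of "benign clinical relevance"); the
allele-frequency threshold is inclusive, keeping AF exactly 0.01 at the
default 1 percent cutoff.

## The synthetic-data generator

Because the real inputs (a curated kinome MSA, a ClinVar export, a gnomAD
export, a reference PDB) are snapshots of external databases, the package
ships a generator that emulates all four with a known planted structure,
so every pipeline stage can be validated against ground truth:

* the MSA has a gap-free reference row plus `insert_columns` columns where
  the reference is gapped (exercising reference-gap exclusion),
  non-reference rows gapped at rate `gap_fraction` (default 0.15), and
  per-row residue offsets sampled in [1, 500] to force nontrivial
  coordinate arithmetic;
* planted hotspots draw Poisson-distributed mutation counts at a chosen
  reference position, landing on rows that carry a residue in that column;
* background mutations are uniform over each row's residues at
  `background_rate` per protein per class — the simplest generative model
  consistent with count-based hotspot calling, and an assumption, not an
  inference about real mutation background;
* benign records get log-uniform allele frequencies straddling the 1
  percent threshold, with one record pinned to exactly 0.01;
* a `truth.tsv` sidecar records every variant's true reference position
  and class. No analysis stage reads it.

Identical configurations (including the seed) produce byte-identical
files. The generator deliberately does *not* emulate realistic kinase
sequence composition, phylogenetic correlation between rows, per-gene
mutability differences, or nucleotide-level effects — passing tests show
the pipeline's bookkeeping and statistics are correct under the stated
generative model, not that real kinome data satisfies that model.

## Validation scales

The test suite validates mapping against a brute-force enumeration oracle
on 500 random alignments (up to 20 rows x 50 columns), the chi-square
statistic against a direct $\sum (O-E)^2/E$ computation on 10,000 random
2x2 tables (tolerance 1e-9), B-factor round-trips over 1,000 random count
maps (counts 0-999, exact recovery), conservation and frequency identities
(to 1e-12) on simulated datasets, planted-hotspot recovery on replicated
studies of 100 proteins x 250 reference residues, and type-I error control
on 200 null replicates (observed significant fraction well under the 0.07
bound). These sizes were chosen to exercise the asymptotic behaviour of
each component while keeping the default test run fast.

One honest caveat from that validation: with a very sparse background
(~0.02 background mutations per protein per class) and three strongly
planted hotspots, the planted positions are always the top three by count,
but the `"mutated"` quantile base yields a single-position hotspot set
($m \approx 6$, $k = 1$), and the chi-square labelling cannot reach
significance because nearly all cancer mutations sit on the planted
positions themselves (each holds about a third of $C$ against an expected
share of about 0.3, and the non-cancer total is ~6). Detecting
*over-representation* requires enough off-hotspot mutation mass to
contrast against; the acceptance checks therefore use a denser background
(0.6 per protein per class) for the end-to-end recovery demonstration.

## Limitations

* The keyword lexicon reproduces common oncology vocabulary but is not a
  clinical ontology; borderline conditions (e.g. predisposition syndromes
  without a cancer keyword) need overrides.
* No isoform or transcript resolution: the variant's residue numbering
  must refer to the same protein sequence as the MSA row (the
  `verify_ref_aa` check catches most violations).
* The PDB dialect is strict: single model, one chain per analysis, no
  altlocs or insertion codes; counts above 999 cannot be encoded in the
  B-factor field and are an error rather than being clipped.
* No per-gene background mutability model and no multiple-testing
  correction by default: the per-position test matches the simple
  observed/expected framework it implements, not a calibrated burden test.
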