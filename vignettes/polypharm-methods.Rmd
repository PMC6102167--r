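---
title: "Methods: harmonizing and scoring drug-target evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonizing and scoring drug-target evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polypharm)
```

## The problem

Evidence that a small molecule modulates a protein target is scattered
across databases that disagree about everything except the underlying
chemistry: potency assays report IC50, XC50, EC50, AC50, C50, Ki, Kd or
"potency" in nM, uM or M; curated resources report a bare drug-gene link
with no number at all; and the same molecule appears under different
names and different SMILES spellings in each source. `polypharm` merges
such sources into one association table keyed by (molecule, target) and
scores every pair, so that questions like "what else does this compound
hit, and how selectively?" have a single queryable answer.

## Harmonization model

**Structure identity.** Two rows describe the same molecule exactly when
their structures standardize to the same canonical SMILES. The
standardizer parses the molecule, perceives aromaticity (so Kekulé and
aromatic spellings meet), renumbers atoms canonically, and preserves
stereochemistry, so enantiomers remain distinct molecules. Salt
counterions are *not* stripped: a hydrochloride and its free base are
distinct registered entities, and merging them would silently pool
assay values measured on different species. Identifiers (`MOL00001`,
...) are assigned by sorting canonical SMILES in the C locale and
numbering, which makes the registry a pure function of the record
multiset — reordering the input rows cannot change any identifier.

Records that carry no structure are still useful for name-based lookup:
if their alias matches an already-registered molecule they are merged
into it, otherwise they become alias-only entries that target queries
can reach but similarity search cannot. Records whose SMILES fails to
parse are skipped and reported; we deliberately do not guess.

**Potency scale.** Every uncensored quantitative measurement is mapped
to pChEMBL = −log10(molar value). The scale is "semi-comparable": an
IC50 and a Kd of 100 nM both land at 7, which is a rough equivalence,
not an assertion that the assays measure the same thing. The per-pair
`mean_pchembl` is the arithmetic mean of the *per-record* pChEMBL values
pooled across value types, not a mean of per-type means: a pair with
four IC50s and one Kd is dominated by the IC50 evidence, which is what
an evidence-weighted summary should do. Per-type means in nM are kept
alongside (`mean_by_type`) for users who need the unpooled view.

**Censored values.** Rows with a relation other than `=` (e.g.
"> 10000 nM") are kept as evidence — they count toward
`n_quantitative` and therefore toward confidence — but are excluded
from `mean_pchembl`, since treating a censoring bound as a measurement
would bias the mean toward the assay's dynamic-range limits.

## Scores

**Known selectivity index.** For drug *d* and target *t*,

$$\mathrm{KSI}_{dt} = \frac{\overline{\mathrm{pChEMBL}}_{dt}}
{\sum_{t' \in T_d} \overline{\mathrm{pChEMBL}}_{dt'}}$$

where the sum runs over all targets of *d* that have a defined mean
pChEMBL. A known-single-target drug has KSI = 1; a promiscuous kinase
inhibitor with eight comparably potent targets has KSIs near 1/8. By
construction the defined KSIs of one molecule sum to 1, which the test
suite asserts to 1e−9. Pairs with only qualitative evidence get no KSI:
there is no potency to apportion.

Note the KSI denominator grows with database coverage, so KSI is a
statement about *known* pharmacology, not about true selectivity — a
compound assayed against one kinase has KSI 1 however promiscuous it
really is.

**Confidence.** The confidence of a pair is the z-score of its total
evidence count,

$$c_{ab} = \frac{(n_{ab} + l_{ab}) - \mu_{all}}{\sigma_{all}},$$

with \(n_{ab}\) quantitative and \(l_{ab}\) qualitative records and
\(\mu_{all}, \sigma_{all}\) the mean and standard deviation of the
count over *all* pairs in the database. We use the population standard
deviation: with it the scores have mean 0 and SD 1 exactly, which is
the property a z-score is meant to have, and the choice is otherwise
arbitrary. Confidence measures accumulation of evidence, not effect
size; a well-studied weak binder outranks a poorly-studied potent one.

## Fingerprints and similarity

Similarity queries use Tanimoto similarity over bit-set fingerprints,
\(|A\cap B| / |A\cup B|\). Three methods are provided:

* `extended` (default): path-based fingerprint with ring features,
  1024 bits. The default for all similarity operations, overridable
  everywhere.
* `circular`: radius-3 circular environment fingerprint (FCFP6-analog)
  folded to 1024 bits. Circular environments as computed here are
  achiral, so we additionally hash each stereo token of the canonical
  SMILES (tetrahedral `@`/`@@`, double-bond `/`, `\`), keyed by its
  occurrence index, into the same 1024-bit space. This keeps
  enantiomer pairs distinguishable at the cost of a handful of bits
  that do not describe 2D substructure; since stereocentre counts are
  small relative to 1024 bits, the perturbation to similarities between
  achiral molecules is nil (they gain no bits).
* `maccs`: the 166 MACCS structural keys.

Folding is by bit position modulo 1024. Bit lengths are recorded on
every fingerprint object. Ties in similarity rankings break by internal
id so output order is reproducible. The default CLI threshold is 0.8 —
tight enough to mean "close analog" for extended fingerprints —
and sweeping it downward is the intended way to widen the chemical
space of a query, exactly as one lowers a cutoff from 1.0 to 0.65 to
move from "this molecule" to "this chemical family".

A query molecule is standardized before fingerprinting, so a query
identical to a database molecule always returns it at similarity 1.0,
and queries need not be in the database at all.

## Enrichment

Target-list enrichment against a GMT collection is a one-sided
hypergeometric upper-tail test (equivalently Fisher's exact test for
over-representation): with a background of \(N\) genes, a set of
size \(K\), a target list of size \(n\) and overlap \(k\), the p-value
is \(P(X \ge k)\) for \(X \sim \mathrm{Hypergeom}(N, K, n)\). The
default background is the collection universe (the union of all sets);
an explicit background restricts everything to it. Benjamini–Hochberg
q-values are computed across the sets of one collection, and raw
p-values are reported alongside. Only over-representation is tested —
depletion of a target list is not biologically interpretable here.

The p-value of a discrete test is super-uniform under the null, with a
CDF that touches the uniform at every achievable value. The test suite
exploits this: on a null with a wide overlap distribution (universe
20,000, one set of 6,000, lists of 1,000; 1,000 draws) the
Kolmogorov–Smirnov statistic shrinks to the largest atom mass and a
uniform fit is not rejected at α = 0.01, while a validity check
confirms the p-values are never anti-conservative.

## Response correlation

Given a query structure and a screening dataset (AUC matrix of drugs ×
cell lines plus a structure table), the analysis (1) picks the
screening drug most similar to the query (Tanimoto argmax, ties by
label; the query itself need not be screened), (2) computes the
Spearman correlation of every other drug's AUC profile against the
reference over pairwise-complete cell lines, and (3) annotates each
drug with its similarity to the *original query*, not the reference —
the output is the point set of a similarity-versus-correlation plot in
which structural analogs with correlated response land in the
high/high corner.

Choices made where the procedure was open: pairwise-complete
observations (no cell-line filtering), a minimum overlap of 3 complete
pairs below which the correlation is reported as undefined (two points
always correlate perfectly), average ranks for ties with a two-sided
t-approximation p-value, and exclusion of the reference's self-row
(self-correlation is uninformative). Spearman correlation is invariant
under strictly monotone transforms of either profile, which the suite
verifies.

## Synthetic fixtures and what they show

The fixture generator emulates the *schemas* the pipeline consumes: a
ChEMBL-style potency table (alias, SMILES, gene, value type, value,
unit, relation), a curated-association table, GMT collections, and a
screening export (AUC matrix + structures). Structures are drawn from
an embedded list of vetted SMILES extended with n-alkanols; potencies
are log-uniform on a configurable nM range (default 1 nM – 10 µM, the
span of a typical potency assay); a configurable fraction of molecules
appears under a second alias in the qualitative source, so structural
consolidation is always exercised; response fixtures embed a drug with
the query's exact structure (the expected reference) and a close
analog whose profile is the reference's plus Gaussian noise. Every
output is a deterministic function of the spec and seed, and a sidecar
JSON records both.

Ground truth is computed by a second, deliberately naive pass — plain
loops over the generated rows with its own unit arithmetic and its own
rank-correlation code — sharing nothing with the pipeline beyond the
canonicalization call that defines molecule identity. The tests demand
*exact* equality between pipeline and ground truth, which is achievable
because both sides perform the identical sequence of floating-point
operations on values read from the same files.

What passing these tests does **not** show: the fixtures do not mimic
real assay heterogeneity (inter-lab IC50 variance, activity-cliff
structure-response relationships, correlated measurement error), so
agreement with ground truth validates the bookkeeping and the formulas,
not the biological reasonableness of any score on real exports. Test
problem sizes (5–12 molecules, up to 60 quantitative rows, 1,000-draw
null simulations) were chosen as the smallest sets that exercise every
code path including collisions and duplicates.

## Numerical and degenerate-input choices

* pChEMBL conversion refuses non-positive potencies (domain error).
* If every pair has the same evidence count, σ is 0 and all
  confidences are set to 0 with a warning rather than NaN.
* A molecule whose mean pChEMBLs sum to ≤ 0 (possible only for
  potencies above 1 M) gets NA KSIs.
* Empty-vs-empty fingerprint comparisons return 0 with a warning.
* Unknown genes in a multi-target query contribute an empty set with a
  warning instead of failing, so one typo does not kill an
  intersection query; an empty gene *list* is a usage error.
* Reported tables round pChEMBL/KSI/confidence to 3 decimals; full
  precision is kept internally and in the lossless database dump.

## Known limitations

* Alias-based merging of structureless records trusts name equality;
  without an external identifier-resolution service, homonyms merge
  and synonyms split. Structure-bearing records are immune.
* KSI and confidence are relative to database coverage (see above);
  neither is comparable across databases built from different sources.
* The pooled pChEMBL mean does not deduplicate repeated measurements
  of the same underlying assay; a heavily re-measured assay weighs
  more.
* Enrichment p-values depend on the background choice; the collection
  universe is a defensible default, not the only one.
* Similarity search scans all fingerprints linearly; at
  hundreds of thousands of molecules an indexed scheme
  (e.g. locality-sensitive hashing) would be needed.
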