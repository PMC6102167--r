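# polypharm

Drug–target evidence is fragmented: potency databases report numeric
IC50/XC50/EC50/AC50/C50/Ki/Kd values in assorted units, curated
resources report bare drug–gene links with no number, and the same
molecule hides behind different names and SMILES spellings in each
source. `polypharm` harmonizes such sources into one scored
drug–target association database and provides the query engine a
pharmacologist needs on top of it: structure-similarity search,
multi-target ("which single molecule hits all of these?") queries,
bipartite network export, target-list enrichment, and correlation of
chemical similarity with drug response in cell-line screens. It is
aimed at preclinical and chemical-biology researchers triaging
off-target liabilities and repurposing hypotheses.

## The model

Structures are standardized to canonical SMILES (stereochemistry
preserved, salts kept) and identical structures are consolidated under
one internal identifier. Every uncensored quantitative measurement is
placed on the pChEMBL scale,

    pChEMBL = -log10(potency in molar),   e.g. 100 nM -> 7,

and each molecule–target pair *(d, t)* is scored with:

* **mean pChEMBL** — arithmetic mean of the per-record pChEMBL values
  pooled across value types;
* **known selectivity index** —
  `KSI_dt = mean_pChEMBL_dt / Σ_{t' ∈ T_d} mean_pChEMBL_dt'`,
  so a known-single-target drug scores 1 and the defined KSIs of a
  molecule always sum to 1;
* **confidence** — the z-score of the pair's total evidence count
  `n_dt + l_dt` (quantitative + qualitative records) over all pairs,
  `c_dt = ((n_dt + l_dt) - μ_all) / σ_all` with the population SD.

Similarity queries use Tanimoto similarity over path-based
("extended", default), circular (FCFP6-analog, chirality-aware) or
MACCS fingerprints. Enrichment is a one-sided hypergeometric test
against GMT gene sets with Benjamini–Hochberg adjustment. The
screening analysis picks the screening drug most similar to a query,
Spearman-correlates its AUC profile with every other drug over
pairwise-complete cell lines, and pairs each correlation with that
drug's similarity to the original query.

## Worked example

```r
library(polypharm)

recs <- rbind(read_quantitative_table("potencies.tsv", "assay_db"),
              read_qualitative_table("curated.tsv", "curated_db"))
db <- build_drug_target_db(recs)
db
#> <drug_target_db: 2 molecules, 6 targets, 6 associations>

id <- resolve_alias(db, "inhib-1")   # "MOL00001"
targets_of(db, id)
#>   gene mean_pchembl n_quant n_qual   ksi confidence
#> 1 SIK2         8.05       1      0 0.347      -0.45
#> 2 PAK1         7.81       2      0 0.337       2.24
#> 3  LCK         7.30       1      0 0.315      -0.45
#> 4 PAK3           NA       0      1    NA      -0.45

similarity_search(db, "CC(C)Cc1ccc(cc1)C(C)C(=O)N", threshold = 0.5)
#>   internal_id similarity           canonical_smiles
#> 1    MOL00001  0.6744186 CC(Cc1ccc(cc1)C(C(=O)O)C)C
```

Reading the output: `inhib-1` hits four targets. Its most potent
association is SIK2 (mean pChEMBL 8.05 ≈ 9 nM), its KSIs are spread
near 1/3 — the compound is *not* selective among its measured targets —
and the PAK1 row carries the most accumulated evidence (confidence
2.24, from 2 records vs 1 elsewhere). PAK3 is supported only by a
curated qualitative link, so it has no potency mean and no KSI. The
amide analog of the registered acid finds it at Tanimoto 0.67; raising
the threshold to 0.8 would exclude it.

A thin command-line front end over the same functions lives at
`inst/cli/polypharm.R` (`build-db`, `query-drug`, `query-targets`,
`network`, `enrich`, `response-corr`, `fixtures`).

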