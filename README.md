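# mesoStrat

Multi-omics stratification and network driver prioritization for
peritoneal mesothelioma (PeM) cohorts.

PeM tumors divide into a deletion subtype — carrying heterozygous or
homozygous copy-number loss of the 3p21 locus around *BAP1* — and
copy-number-intact tumors, and the two differ sharply in immune
microenvironment. `mesoStrat` implements the analysis chain behind that
stratification for anyone integrating exome, transcriptome and
proteome-level data from small tumor cohorts:

* **Alteration calls** — somatic variants filtered by read support
  (> 10 reads), allele fraction (> 10%) and non-silent consequence;
  copy-number segments classified against log2-ratio thresholds
  (±0.2 single-copy, +0.6 amplification, −1.0 homozygous loss, 3-probe
  minimum); everything collapsed into a binary gene × patient alteration
  matrix with per-entry provenance.
* **Expression outliers** — the generalized extreme studentized deviate
  (GESD) test per gene, giving a binary gene × patient outlier matrix.
* **Network influence** — pairwise influence `I(u,v) = 1/(1 + H(u,v))`
  from expected first-passage (hitting) times `H` of the
  weight-proportional random walk on a protein-interaction network,
  computed by one sparse linear solve per target.
* **Driver prioritization** — the minimum set of altered genes whose
  influence covers patients' outliers under the coverage parameters
  α = 0.9 (fraction of achievable influence per outlier), β = 0.6
  (fraction of a patient's outliers), γ = 0.8 (fraction of patients);
  solved exactly by branch-and-bound or at scale by a deterministic
  greedy heuristic, with an independent feasibility verifier.
* **Immune phenotyping** — subtype assignment keyed on the index gene's
  CNA state; rank-sum differential expression with top-500 selection and
  hypergeometric set enrichment; inverse-normal-transform immune/stromal
  scores; simplex-constrained least-squares deconvolution of immune-cell
  fractions with permutation p values; a checkpoint-receptor panel
  (PDCD1, CD274, CTLA4, LAG3, ICOS, ...) with −log10 rank-test p values.
* **Synthetic cohorts** — a seeded generator that plants drivers on
  high-confidence network modules, propagates expression outliers to
  their partners, defines a deletion subtype with an inflamed program,
  and mixes known immune-cell fractions, emitting ground-truth files for
  end-to-end validation.

## Worked example

Simulate a 30-sample cohort with 3 planted drivers, run the driver chain
and assign subtypes:

```r
library(mesoStrat)

cfg <- simulationConfig(seed = 42)
sim <- generateCohort(cfg)
sim$truth
#> SyntheticTruth: 3 planted drivers; 12 del / 18 intact samples; 5 cell types

kept <- filterVariants(sim$variants)       # 43 of 174 survive the filters
geneCna <- callGeneCna(sim$segments, sim$geneMap,
                       samples = colnames(sim$expression))
alt <- buildAlterationMatrix(kept, geneCna, genes = sim$geneMap$gene,
                             samples = colnames(sim$expression))
alt
#> AlterationMatrix: 500 genes x 30 samples; 72 altered entries

out <- buildOutlierMatrix(sim$expression)
out
#> OutlierMatrix: 500 genes x 30 samples; 144 flagged entries (r = 8)

altGenes <- geneIds(alt)[rowSums(as.matrix(alt)) > 0]
outGenes <- geneIds(out)[rowSums(as.matrix(out)) > 0]
infl <- influenceMatrix(sim$network, sources = altGenes,
                        targets = outGenes)
inst <- buildCoverInstance(alt, out, infl)
#> 4 patient(s) without usable alteration/outlier data dropped

sol <- prioritizeDrivers(inst, coverParams(solver = "greedy"))
sol
#> DriverSolution [feasible]: 3 gene(s): G0105, G0093, G0006
#> 23 of 26 patients satisfied
sim$truth@drivers
#> [1] "G0006" "G0105" "G0093"
```

The three selected genes are exactly the planted drivers. Subtype labels
recomputed from copy number alone reproduce the planted 12/18 split, and
the two halves of the inflamed marker panel give strongly correlated
per-sample scores (r = 0.93), the signature of shared infiltration:

```r
rule <- subtypeRule(locusGenes = sim$truth@indexGene,
                    indexGene = sim$truth@indexGene)
table(assignSubtypes(geneCna, rule))
#>    G0006-del G0006-intact
#>           12           18

sc <- immuneStromalScores(sim$expression, sim$inflamedPanel[1:10],
                          sim$inflamedPanel[11:20])
sc$correlation
#> [1] 0.933
```

`runPipeline(inputDir, outDir)` runs the whole chain on a directory of
input files (as written by `writeCohortFiles()`) and writes TSV tables
plus a JSON run summary; two runs with the same seed are byte-identical.

A packaged cohort table (`inst/extdata/pem_cohort.tsv`, 19 tumor samples
from 18 patients: 8 BAP1-del, 15 with transcriptomes, 16 with proteomes)
and a synthetic two-set 141-gene immune/stromal marker GMT are included
as fixtures; `readCohortTable()` / `readGeneSets()` parse them.

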