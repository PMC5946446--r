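# cocnet

Gene regulatory crosstalk between an oocyte and its surrounding cumulus
cells, from per-compartment transcriptomes of single cumulus-oocyte
complexes (COCs).

During folliculogenesis the oocyte and its cumulus layers communicate
continuously — through ligand-receptor signaling, gap junctions and
transported RNAs — and that communication leaves a transcriptional
footprint: genes expressed in the oocyte co-vary, across complexes,
with genes expressed in the surrounding somatic cells. `cocnet`
implements the statistical machinery to detect and organize that
footprint when each COC contributes one oocyte sample, one inner
cumulus (innerCC) sample and one outer cumulus (outerCC) sample:

* **Cross-compartment robust correlation.** For genes *k* (oocyte) and
  *l* (cumulus) with log2(FPKM+1) profiles over COCs *j* = 1..J, the
  biweight midcorrelation bicor(x<sub>kj</sub>, y<sub>lj</sub>)
  down-weights observations beyond 9 MAD from the median with Tukey
  biweights, so one aberrant complex cannot fabricate a correlation.
* **Permutation empirical FDR.** Significance comes from breaking the
  COC linkage: the COC index of the oocyte samples is permuted B times
  and, for a threshold *t*,

      eFDR(t) = sum_b [ #(pairs with |bicor^0b| >= t) + 1 ] / (K*B + 1)

  over all K gene pairs, capped at 1. Pairs with |bicor| > 0.85 are
  reported when the eFDR at that threshold clears the gate.
* **Co-expression modules.** Within a compartment: signed adjacency
  ((1+bicor)/2)^beta, topological overlap (TOM), average-linkage
  clustering of 1−TOM with tree cuts. Across compartments: the
  significant-pair bicor matrix is clustered on both dimensions and
  summarized by per-block mean correlations.
* **Ligand-receptor road map.** Protein-protein interaction sources are
  merged through homology into one gene-level edge set; receptors are
  genes annotated "receptor activity" / "receptor complex"; each pair
  is classified autocrine, paracrine (with direction) or
  autocrine-or-paracrine from per-compartment expression presence
  (FPKM > 0.5 in ≥ 8 samples). Network topology is summarized by a
  log-log degree-frequency fit (scale-free R², bootstrap p) and hub
  edge coverage.
* **Variable genes.** For genes detected in every sample,
  CV = sqrt(exp(x²) − 1) with x the SD of log2(FPKM+1); top-percentile
  selection by the nearest-rank rule.
* **Length-aware enrichment.** GO over-representation with a monotone
  probability-weighting function of gene length and the Wallenius
  noncentral hypergeometric upper tail (exact two-weight-class
  recursion), with BH and BY FDR columns.

A synthetic-data module generates COC datasets with planted
cross-compartment pairs, planted modules, preferential-attachment PPI
graphs and length-biased gene sets, so every stage can be validated
against known truth.

## Worked example

```r
library(cocnet)

# 16 COCs, 5 planted oocyte-outerCC pairs at rho = 0.98
pp <- data.frame(gene_a = sprintf("g%04d", 1:5),  compartment_a = "oocyte",
                 gene_b = sprintf("g%04d", 6:10), compartment_b = "outerCC",
                 rho = 0.98)
sim <- simulateCocDataset(cocSimConfig(nGenes = 100, plantedPairs = pp,
                                       muRange = c(4, 6), seed = 7))
sim$experiment
#> COCExperiment: 100 genes x 48 samples (fpkm scale)
#>   compartments: innerCC=16, oocyte=16, outerCC=16
#>   COCs: 16

lp  <- linkCompartments(sim$experiment, "oocyte", "outerCC")
obs <- crossCompartmentBicor(lp)
nul <- permutedNullBicor(lp, B = 1000, seed = 1)
ef  <- efdrAtThresholds(obs, nul)
ef[abs(ef$threshold - 0.85) < 1e-9, ]
#>   threshold observed_count permuted_exceed_total      efdr
#> 8      0.85              5                    86 0.0003595
sel <- selectSignificantPairs(obs, ef, bicorMin = 0.85, efdrMax = 0.001)
sel
#>   gene_a gene_b     bicor passes
#> 1  g0001  g0006 0.9843701   TRUE
#> 2  g0002  g0007 0.9640973   TRUE
#> 3  g0003  g0008 0.9928256   TRUE
#> 4  g0004  g0009 0.9895577   TRUE
#> 5  g0005  g0010 0.9716742   TRUE
```

All five planted pairs (and nothing else) clear |bicor| > 0.85 at an
empirical FDR of 3.6 × 10⁻⁴: across the 1000 permutations, only 86 of
the K × B = 3,021,000 null pair-permutation values reached 0.85, and
the +1-per-permutation terms of the estimator contribute the rest.

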