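# ceRNAseeker

Competing endogenous RNA (ceRNA) network inference for paired
tumor/normal transcriptome designs, with co-expression module detection
and prognostic evaluation — the analysis chain used in lncRNA sponge
studies of early-stage lung adenocarcinoma, packaged as tested, reusable
R functions.

## Who this is for

Cancer transcriptomics analysts who have (i) raw count matrices for
mRNAs, miRNAs and lncRNAs from paired tumor/normal tissue, (ii)
externally predicted miRNA-target tables carrying prediction scores and
binding free energies, and (iii) clinical follow-up, and who want to go
from counts to a lncRNA–miRNA–mRNA ceRNA network, trait-associated
co-expression modules, hub genes, and survival calls with explicit,
auditable thresholds. Because real studies of this kind rest on
restricted-access patient data, the package ships a synthetic multi-omics
generator with planted ground truth so every stage can be validated
end to end.

## The statistics at the core

- **Differential expression.** Counts are CPM-standardized; per feature,
  a negative-binomial log-linear model with median-of-ratios size-factor
  offsets is fit by IRLS and the condition effect tested with a Wald
  statistic. The gate is `|log2FC| >= 1` and `P <= 0.05` (raw p, both
  thresholds inclusive; BH-adjusted p available).
- **Targeting filter.** Predicted interactions are kept when
  `total score >= 150` and `total energy <= -20 kcal/mol`, then
  restricted to differentially expressed features.
- **Shared-miRNA test.** For each lncRNA–mRNA pair, the overlap *k*
  between the *K* miRNAs targeting the lncRNA and the *n* targeting the
  mRNA, within a universe of *N* miRNAs, is scored by the hypergeometric
  upper tail `P(X >= k)`. A pair becomes a ceRNA triplet (one per shared
  miRNA) when additionally the Pearson correlation of the two
  log2(CPM+1) tumor profiles satisfies `r > 0.5` with `P < 0.05`.
- **Co-expression modules.** Unsigned weighted network
  `a_ij = |cor|^beta` with the soft power chosen by the scale-free fit
  index (target R² = 0.85), topological overlap
  `TOM_ij = (l_ij + a_ij)/(min(k_i,k_j) + 1 - a_ij)`, average-linkage
  clustering of `1 - TOM` with minimum module size 30 and eigengene
  merge height 0.25; hub genes pass `|MM| > 0.8` and `|GS| > 0.4`.
- **Survival.** Median split of expression (ties go high), Kaplan–Meier
  product-limit curves with Greenwood errors, two-group log-rank test,
  and univariate Cox regression (Breslow ties, Newton–Raphson with
  step-halving) reporting `HR = exp(beta)` with a 95% CI.
- **qPCR.** Relative quantification by `2^-ddCt` with a paired Wilcoxon
  signed-rank test.

## Worked example

```r
library(ceRNAseeker)
cfg <- simulation_config(n_pairs = 20, seed = 1)   # 20 tumor/normal pairs
res <- run_pipeline(cfg, "demo_run")
```

On this configuration (10 planted sponge pairs among ~800 candidate
lncRNA–mRNA pairs) the run prints to `demo_run/` and returns:

```
accepted pairs: 9 of 832 scored        # 9/10 planted pairs recovered, 0 false
triplets: 33                           # one row per shared miRNA
    lncrna      mrna k K n  N      hyper_p pearson_r        cor_p
1 lnc_0089 mRNA_0196 4 6 4 55 4.398118e-05 0.8881661 1.720510e-07
2 lnc_0022 mRNA_0173 4 6 6 55 6.186685e-04 0.8452415 2.718582e-06
3 lnc_0129 mRNA_0053 4 6 6 55 6.186685e-04 0.6231137 3.335596e-03
```

Each accepted pair shares `k` of its `K` (lncRNA) and `n` (mRNA)
targeting miRNAs out of a universe of `N = 55` DE miRNAs, with the
hypergeometric and correlation evidence shown. The survival stage
evaluates the planted prognostic lncRNA (`lnc_0129`, planted log-HR
0.5 per SD):

```
HR 1.91 (95% CI 0.99-3.70), Wald p 0.053, log-rank p 0.009
```

(reference group: low expression; at n = 20 subjects the interval is
wide — the planted HR per SD is exp(0.5) = 1.65). The qPCR stage
quantifies a planted ddCt of +1.5 (down-regulation in tumor):

```
qPCR mean fold 0.346, Wilcoxon p 8.8e-06     # 2^-1.5 = 0.354 expected
```

`demo_run/manifest.json` lists every output file with its MD5 checksum;
rerunning with the same config reproduces the checksums exactly.

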