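# dnbr — dynamic network biomarker analysis of stage-ordered expression data

Most expression biomarkers are *static*: they separate case from control at
one point in time. They say nothing about **when** a progressing system —
for example a tumor moving through TNM stages I–IV — approaches a critical
transition after which its state changes qualitatively. Dynamic network
biomarker (DNB) theory predicts that just before such a tipping point a
small dominant group of genes starts to behave distinctively:

1. the deviation of its members from the reference baseline rises,
2. correlations **within** the group rise sharply,
3. correlations between the group and the rest of the system fall,
4. the rest of the system stays quiet.

`dnbr` turns that theory into a tested pipeline for stage-ordered
case/reference expression matrices. For a gene module *M* with case
samples of stage *s* and a pool of reference samples it computes

- `SD_in(M, s)` — mean of |x_gd − x̄_g| over module genes *g* and case
  samples *d*, where x̄_g is the gene's mean in the reference samples;
- `PCC_in(M, s)` — mean |Pearson correlation| over all gene pairs inside
  *M*, on the stage's case samples;
- `PCC_out(M, s)` — mean |Pearson correlation| between *M* and all other
  genes;

and condenses them into the **composite index**

```
CI(M, s) = SD_in · PCC_in / PCC_out
```

The module maximizing CI is the DNB; the stage where its CI trajectory
begins its sharp rise (the maximal forward difference CI(s+1) − CI(s)) is
reported as the **critical transition stage**, the pre-transition state.

Around this core the package provides the supporting stages of a
stage-wise biomarker workflow:

- `call_degs()` — per-stage Welch-*t* differential expression with
  Benjamini–Hochberg FDR and the two-threshold call rule (FDR < 0.05,
  |log2FC| > 2);
- `soft_threshold_scan()`, `pick_power()`, `adjacency()`, `tom()`,
  `cluster_modules()`, `module_eigengene()`, `module_trait_cor()` — a lite
  weighted co-expression analysis (unsigned |r|^β network, scale-free fit
  index, topological overlap, static-cut modules, eigengene–trait
  correlation);
- `compute_centralities()`, `top_k_intersection()` — twelve
  cytoHubba-style hub centralities (degree, clustering coefficient,
  closeness, eccentricity, radiality, stress, betweenness, MNC, DMNC, MCC,
  bottleneck, EPC) with a deterministic top-*k* consensus;
- `suppressor_overlap()` — per-stage intersection of DNB genes,
  down-regulated genes and a tumor-suppressor list;
- `dnb_spec()` / `simulate_dnb_data()` — a synthetic generator that plants
  the four DNB conditions, differentially expressed genes and a
  stage-correlated module with known ground truth;
- `run_all()` / `report()` — a deterministic orchestrator writing every
  artifact plus a hash manifest.

## Worked example

Simulate a four-stage study (500 genes, 20 case samples per stage, 20
reference samples) with a 20-gene module planted to cross its tipping
point at stage III, and fit the DNB model:

```r
library(dnbr)

sim <- simulate_dnb_data(dnb_spec(seed = 1))
fit <- dnb(sim$expr, sim$design)
fit
#> Dynamic network biomarker fit
#>   module: 19 genes (selected at stage IV)
#>   CI trajectory: I=1.092, II=1.175, III=1.637, IV=7.688
#>   critical transition stage: III
#>   peak stage: IV
fit$scores
#>   stage n_cases sd_in pcc_in pcc_out   ci
#>       I      20 0.905  0.225   0.187 1.09
#>      II      20 0.920  0.234   0.183 1.17
#>     III      20 0.994  0.305   0.185 1.64
#>      IV      20 1.758  0.817   0.187 7.69
```

Reading the table: through stages I–III the module's deviation and
internal correlation drift upward while its correlation to the background
(`pcc_out` ≈ 0.19, the independence baseline at n = 20) stays flat; after
stage III the composite index jumps from 1.64 to 7.69. The largest forward
difference starts at stage III, so stage III is called the critical
(pre-transition) stage, with the score peak at stage IV. All 19 selected
genes belong to the planted 20-gene module, and `fit$critical_stage`
equals the planted tipping stage. `plot(fit)` draws the trajectory;
`coef(fit)` returns it as a named vector.

The whole pipeline — simulation, per-stage differential expression, DNB
fit, co-expression modules with stage correlation, hub consensus and
tumor-suppressor overlap — runs with

```r
res <- run_all(pipeline_config(seed = 1), "run1")
report("run1")
```

and is byte-reproducible: rerunning the same configuration yields an
identical `manifest.json`.

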