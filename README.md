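# TriScaleNet

Three-scale graph analysis and classification of brain functional networks.

Resting-state fMRI studies of mild cognitive impairment (MCI) commonly
represent each brain as a weighted functional network — nodes are atlas
regions (ROIs), edges are the absolute Pearson correlation between regional
BOLD time series — and ask how its topology differs from normal controls
(NC) at three scales:

- **Scale I, global**: weighted clustering coefficient *C*, characteristic
  path length *L*, global efficiency *GE*, and small-worldness
  *SW* = (*C*/⟨*C*<sub>rand</sub>⟩)/(*L*/⟨*L*<sub>rand</sub>⟩) against
  degree-preserving rewired null networks.
- **Scale II, nodal**: betweenness centrality *bc*<sub>i</sub>, normalised as
  *BC*<sub>i</sub> = *bc*<sub>i</sub>/⟨*bc*⟩, with hubs defined by
  *BC*<sub>i</sub> > 2.5.
- **Scale III, modular**: Newman modularity *Q*, Louvain community
  detection, and a permutation test of *Q* against randomised networks.

Because most graph metrics depend on edge density, every network is
thresholded to a prescribed **sparsity** (fraction of the *N*(*N*−1)/2
possible edges retained, keeping the strongest ones), and analyses sweep
sparsities from 5% to 50% in 1% steps. Group comparisons use
gender-adjusted logistic regression and partial correlations with four
cognitive scores (ADAS13, CDRSB, MMSE, FAQ); a two-layer random forest
(layer 1 ranks the 4 + 4 + 116 = 124 features by out-of-bag permutation
importance, layer 2 classifies on the top *N* under a 10-fold-outer /
5-fold-inner nested cross-validation) discriminates the groups.

The package implements this pipeline end to end, together with a
**synthetic cohort generator** — multivariate Gaussian ROI time series with
planted correlation modules, planted hub regions, group-dependent topology
and clinically oriented score models — so that every stage is testable with
known ground truth, without access to clinical data.

## Worked example

```r
library(TriScaleNet)
spec <- cohortSpec()          # 30 + 30 subjects, 116 ROIs, 135 timepoints
cohort <- generateCohort(spec, seed = 7)
cohort
#> Cohort: 60 subjects (MCI=30, NC=30)
#>   116 ROIs x 135 timepoints per subject

fcs <- lapply(seq_len(nSubjects(cohort)),
              function(i) computeFC(subjectTimeseries(cohort, i)))
groups <- cohortMetadata(cohort)$group
gNC <- groupMeanNetwork(fcs[groups == "NC"])   # NC group-level network
net <- thresholdBySparsity(gNC, 0.16)
net
#> ThresholdedNetwork: 116 nodes, 1067 edges (sparsity 0.16)

unlist(globalMetrics(net, nRandom = 100, seed = 1))[1:4]
#>         C         L        GE        SW
#> 0.3670167 6.5583187 0.1881204 2.3244146
```

*SW* ≈ 2.3 > 1: the planted modular network is small-world — much more
clustered than its degree-matched rewired nulls at comparable path length.
Hub detection recovers the planted hub regions (here ROIs 15, 44, 73 and
102), along with a few incidental module-bridging nodes:

```r
BC <- normalizeBC(nodeBetweenness(net))
identifyHubs(BC)        # regions with BC > 2.5
#> ROI015 ROI021 ROI026 ROI042 ROI044 ROI049 ROI057 ROI073 ROI091 ROI098 ...
groundTruth(cohort)$hubs$NC
#> [1]  15  44  73 102

detectModules(net, seed = 1)
#> ModularPartition: 4 modules, Q = 0.6676 (sparsity 0.16)
#> module
#>  1  2  3  4
#> 28 32 28 28
```

The four planted modules are recovered almost exactly (*Q* ≈ 0.67). The
full orchestration — metric sweep, hub tables, modularity permutation test,
group statistics and the nested-CV classifier — runs from a single seeded
configuration:

```r
report <- runFull(runConfig(masterSeed = 42))
report   # per-stage summaries; every number traceable to a stage output
```

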