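# rdisen

Renyi distribution entropy for short-term heart-rate-variability (HRV)
analysis, with a complete coronary-artery-disease (CAD) screening workflow.

Short RR-interval series defeat the classical regularity statistics: ApEn and
SamEn hinge on a tolerance `r` whose choice can flip a clinical conclusion,
and SamEn is often simply undefined on 50-beat windows. Renyi distribution
entropy (RdisEn) sidesteps the tolerance entirely by looking at the whole
empirical distribution of Chebyshev distances between embedded templates
`U(i) = (x(i), ..., x(i+m-1))`:

```
RdisEn(B, m, q) = log2( Σ_t p_t^q ) / ( (1 − q) · log2 B ),
```

where `p_t` are the probabilities of the `B`-bin equal-width histogram of
inter-template distances. The value lies in `[0, 1]`, is exactly invariant
under affine rescaling of the signal, and degenerates to the Shannon
distribution entropy (DisEn) as `q → 1`. The package provides this statistic,
the ApEn/SamEn/DisEn/RenEn baselines, and everything around them: synthetic
generators (logistic-map regimes, ECG with ground-truth R-peaks, two-class RR
series), ECG preprocessing (Fourier resampling, db6 wavelet denoising,
Pan-Tompkins QRS detection, RR extraction, beat segmentation), three-level
wavelet-packet sub-band features, t-test feature ranking, KNN/SVM
classification under repeated stratified cross-validation, and
parameter-sensitivity experiment harnesses. It is aimed at biomedical
signal-processing researchers who want the method end to end, reproducible
from a single seed.

## Worked example

```r
library(rdisen)

# entropy of a chaotic logistic-map orbit
x <- logisticMap(3.8, n = 1000, realizations = 1, x0 = 0.15)[[1]]
rdisEn(x, B = 512, m = 2, q = 0.5)   # 0.9940495
disEn(x, B = 512, m = 2)             # 0.9925602
apEn(x, m = 2, rFrac = 0.2)          # 0.4423484
sampEn(x, m = 2, rFrac = 0.2)        # 0.4448782

# full CAD-detection scheme on generated two-class HRV beats:
# 80 normal-like + 80 CAD-like 500-sample beats, half for feature selection,
# half for 10 x 10-fold KNN evaluation
g <- twoClassRR(n = 1000, recordsPerClass = 40, seed = 11)
beats <- unlist(lapply(seq_along(g$signals), function(i)
  segmentBeats(g$signals[[i]], 500, maxBeats = 2,
               label = as.character(g$labels[i]), recordId = paste0("r", i))),
  recursive = FALSE)
labels <- factor(sapply(beats, function(b) b$label), levels = c("normal", "cad"))
cadPipeline(beats, labels, classifier = "knn", seed = 1)
#> CAD-detection pipeline (basis db1, seed 1)
#> selected features: RdisEn, Ma8, Ma4, Mi3, Mi8
#> KNN, 5 features, 10x10-fold CV (positive class 'cad')
#>   acc = 100.00 +/- 0.00 %
#>   sen = 100.00 +/- 0.00 %
#>   spe = 100.00 +/- 0.00 %
```

The chaotic orbit fills the distance histogram almost uniformly (RdisEn near
1), and the two RdisEn readings agree to ~0.15% because q = 0.5 is close to
the Shannon limit. In the pipeline output, feature selection (run on the
held-out acquisition half) kept RdisEn plus four wavelet-packet statistics,
and the engineered class difference is separable enough that every repeat of
the 10-fold cross-validation classifies all 80 evaluation beats correctly;
on permuted labels the same machinery stays at chance (~50%).

A thin CLI wraps the same functions:

```sh
exec/rdisen simulate --kind rr --n 1000 --records 10 --seed 1 --out rr.csv
exec/rdisen entropy --in rr.csv --estimator rdisen --B 512 --m 2 --q 0.4
```

## Layout

- `R/entropy.R` — RdisEn/DisEn/RenEn/ApEn/SamEn and the distance histogram
- `R/synthetic.R` — logistic-map, synthetic-ECG and two-class RR generators
- `R/preprocess.R` — resampling, denoising, Pan-Tompkins, RR, segmentation
- `R/wavelet.R` — orthogonal filter bank (DWT/IDWT, packet tree, denoise)
- `R/features.R` — 25-feature beat vectors, t-test ranking, selection
- `R/classify.R` — KNN, linear SVM, repeated stratified k-fold, Acc/Sen/Spe, AUC
- `R/experiments.R` — sweeps, stability statistic, q optimisation, assessment
- `R/io.R`, `R/pipeline.R`, `exec/rdisen` — CSV/WFDB adapters, workflow, CLI
- `vignettes/rdisen-methods.Rmd` — model, conventions, design decisions
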