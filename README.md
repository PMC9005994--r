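# m5Cpredict

Sequence-based prediction of RNA 5-methylcytosine (m5C) sites.

5-methylcytosine is one of the most abundant post-transcriptional RNA
modifications: a methyltransferase attaches a methyl group to the C5
atom of cytosine, with roles in rRNA assembly, cellular aging and
cancer. Transcriptome-wide experimental mapping (bisulfite sequencing,
miCLIP, Aza-IP) is expensive and blind to low-abundance RNAs, so
computational predictors that score candidate cytosines directly from
primary sequence are widely used. This package implements such a
predictor end to end, for bioinformaticians who want either a
ready-made site scorer or the individual building blocks (encoders,
feature selectors, evaluation toolkit) as reusable components.

## Method

A candidate site is represented by the window
R<sub>λ</sub>(C) = N<sub>−λ</sub> … N<sub>−1</sub> C N<sub>1</sub> … N<sub>λ</sub>
with λ = 20, i.e. a 41-nt segment whose center is the candidate
cytosine. Each segment is encoded into seven feature families,
concatenated into a canonical 808-dimensional vector:

| block  | features | description |
|--------|---------:|-------------|
| ENAC   | 148 | nucleotide frequencies in a 5-nt window slid 5′→3′ |
| CKSNAP | 96  | frequencies of nucleotide pairs k = 0…5 positions apart |
| ANF    | 41  | accumulated nucleotide frequency (prefix density d<sub>i</sub> = (1/i)·Σ<sub>j≤i</sub> f(S<sub>j</sub>)) |
| NCP    | 123 | 3-bit chemical-property code per position |
| BIN    | 164 | one-hot code per position |
| SCPDNC | 136 | series-correlation pseudo dinucleotide composition: 16 dinucleotide frequencies + λ·Λ tiered correlation factors θ over Λ = 6 physicochemical indices (w = 0.9) |
| W2V    | 100 | mean CBOW embedding of overlapping 3-mers |

Features are ranked by one of three criteria — mean absolute Shapley
attribution Γ<sub>i</sub> of a gradient-boosted tree ensemble (exact
TreeSHAP), the F-score F<sub>i</sub> (between-class separation over
within-class variance), or greedy mRMR
(max I(f<sub>j</sub>, l) − mean I(f<sub>j</sub>, f<sub>i</sub>) over the
selected set) — and the optimal top-n subset is chosen by incremental
feature selection: the n maximizing mean five-fold cross-validated
AUROC. The final classifier is XGBoost tuned by exhaustive grid search
over max_depth × learning_rate × n_estimators (random-forest and RBF-SVM
baselines included), evaluated with Sen, Spe, Pre, Acc, F1, MCC, FOR
and full ROC / precision-recall curves, with decision thresholds either
fixed (0.5) or matched to a target false-positive rate on the training
calibration scores.

Because the published benchmark is an external download, the package
ships a synthetic benchmark generator that plants a class-dependent
positional nucleotide bias of tunable strength into balanced 41-nt
segment sets, giving every pipeline stage a known ground truth.

## Worked example

```r
library(m5Cpredict)

segs <- simulateSegments(nPos = 150, nNeg = 150, effect = 0.6, seed = 11)
emb  <- trainEmbedding(segs, seed = 12)
fm   <- encodeSegments(segs, model = emb)
fm
#> FeatureMatrix: 300 segments x 808 features
#>   blocks: ENAC(148) CKSNAP(96) ANF(41) NCP(123) BIN(164) SCPDNC(136) W2V(100)

rk <- rankByShap(fm, params = list(max_depth = 4, eta = 0.2,
                                   nrounds = 150), seed = 13)
rk
#> FeatureRanking (shap): 808 features
#>   top: BIN_p20_U (1.595), BIN_p24_A (1.541), BIN_p16_G (1.017), ...

sel <- incrementalSelection(rk, featureValues(fm), segmentLabels(fm),
                            nGrid = c(8, 16, 32, 64, 128, 808),
                            cv = cvConfig(5, seed = 14),
                            params = list(max_depth = 3, eta = 0.2,
                                          nrounds = 60))
sel
#> SelectionResult: 6 subset sizes evaluated
#>   best n = 64 with mean CV AUROC = 0.9824

X <- featureValues(fm)[, selectedFeatures(sel)]
model <- trainModel(X, segmentLabels(fm),
                    params = list(max_depth = 3, eta = 0.1,
                                  nrounds = 200),
                    seed = 15, embedding = emb)

probe <- simulateSegments(40, 40, effect = 0.6, seed = 99)
scores <- predictScores(model,
                        encodeSegments(probe, model = emb)[selectedFeatures(sel), ])
evaluateScores(segmentLabels(probe), scores)
#> MetricsReport (threshold = 0.5 )
#>   counts: TP = 35 FP = 6 TN = 34 FN = 5
#>   Sen 0.875  Spe 0.850  Pre 0.854  Acc 0.863  F1 0.864  MCC 0.725  FOR 0.128
#>   AUROC 0.9494  AUPRC 0.9526
```

The top-ranked features are the one-hot indicators of the planted
biased positions (`BIN_p20_U`, `BIN_p24_A`, …), selection shrinks 808
columns to 64 with a gain in cross-validated AUROC, and held-out probe
segments are classified with AUROC ≈ 0.95 at this effect strength.

`runPipeline(outDir)` wires simulate → encode → rank → select → tune →
train → evaluate into one call writing every intermediate artifact, and
`predictFasta()` scores every eligible cytosine of arbitrary FASTA
input. A command-line wrapper with subcommands (`simulate`, `encode`,
`select`, `tune`, `train`, `evaluate`, `predict`, `run-all`) is
installed at `system.file("cli", "m5cpred.R", package = "m5Cpredict")`.

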