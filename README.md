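# sonodescribe

Computer-aided description of breast ultrasound nodules in R: from a
grayscale image to a structured, explained BI-RADS report.

Radiologists characterize breast nodules with the BI-RADS lexicon — shape,
margin, orientation, echogenicity, posterior acoustic features, the
echogenic halo, and, when recognizable, a special-case tumor type
("suggestivity") — and from these assign a malignancy category (2, 3, 4A,
4B, 4C, 5) that determines the clinical intervention. `sonodescribe`
implements that whole workflow as a tested pipeline:

* **ROI detection and standardization** — a pluggable detector (built-in
  fallback, ground-truth oracle, or adapter to an external one-stage
  detector) plus the fixed preprocessing contract: crops larger than the
  target side are rescaled preserving the width-height ratio, then
  zero-padded to a square (450x450 by default).
* **Attention multi-head descriptor network** — a convolutional encoder
  (VGG-style stack, GELU, max pooling) whose feature-space rows
  \(f_i\) are pooled by soft attention, \(a_i = \mathrm{softmax}_i\,
  \tanh(V\cdot f_i)\), \(c = \sum_i a_i f_i\); six descriptor heads read
  the context \(c\), the suggestivity head reads the descriptor outputs
  and \(c\), and the Boolean malignancy head reads both plus the
  suggestivity. Orientation uses two sigmoid neurons with threshold 0.3 so
  round nodules can have *no* orientation. Implemented from scratch
  (RcppArmadillo kernels, analytic gradients, Adam), deterministic under a
  seed; a "tiny" encoder configuration trains in minutes on one CPU.
* **Explainable BI-RADS category** — a ridge-penalized multinomial
  logistic regression over one-hot descriptor values in the symmetric
  parameterization; for every category the active weights plus intercept
  sum exactly to the logit, so each prediction carries a per-feature
  explanation (`plotExplanation()` draws the dot plot).
* **Rule-based fine-tuning and reports** — round implies no orientation;
  simple cyst, complex cyst and spiculated margins force categories 2, 4A
  and 5; deterministic natural-language narratives with lossless JSON
  records and the category-to-intervention table.
* **Near-duplicate detection** — a SIFT-style pipeline (difference-of-
  Gaussian keypoints, orientation-normalized gradient descriptors, ratio
  test, similarity-transform RANSAC) that finds zoomed/rotated copies in a
  dataset, clusters them, and reports label conflicts and a discard plan.
* **Agreement metrics** — Cohen's kappa per descriptor with confusion
  matrices and the accuracy/recall/precision/F1/specificity suite for the
  malignancy decision.
* **Synthetic phantom generator** — speckle-textured ultrasound-like
  images with nodules whose descriptors are exactly known (and rendered:
  anechoic interiors, spiculated spikes, posterior shadowing columns,
  bright halos...), with ground-truth boxes, label tables, planted
  near-duplicates, and burned-in-marker flags. Every experiment below runs
  on these phantoms; no download is needed.

## Worked example

Generate a phantom dataset, train the tiny descriptor network, fit the
category regression, and describe a held-out image end to end:

```r
library(sonodescribe)

makeDataset(750, seed = 42, outDir = "data")
manifest <- readManifest("data")
splits <- splitManifest(manifest, nTest = 150, seed = 7)

net <- trainSyntheticBenchmark(splits$train, seed = 1)   # ~10 min, 1 CPU
mlr <- fitBiradsMLR(splits$train[, c("shape", "margin", "orientation",
                                     "echogenicity", "posterior", "halo",
                                     "suggestivity")],
                    splits$train$birads)

row <- splits$test[6, ]
reports <- describeImage(file.path("data", row$file), net, mlr,
                         detector = "oracle",
                         truth = list(boundingBox(row$x0, row$y0,
                                                  row$x1, row$y1)))
reports[[1]]
```

```
FinalReport: BI-RADS 2 - Normal procedure
  The nodule is oval with circumscribed margins, anti-parallel orientation,
  anechoic echogenicity, posterior enhancement, and no echogenic halo. The
  appearance is suggestive of a simple cyst. BI-RADS category 2 (estimated
  malignancy probability 0.01). Recommended intervention: Normal procedure.
```

Every descriptor and the category match this phantom's ground truth; the
BI-RADS 2 comes from the rule module (a recognized simple cyst is always
category 2), and the probability in parentheses is the malignancy head's
output.

The narrative is a deterministic template fill over the rule-adjusted
descriptors; the matching structured record (`serializeReport()`) is the
machine-readable form. Agreement with the ground truth over the whole test
split comes from `agreementReport(predictManifest(net, splits$test,
flipAverage = TRUE), splits$test)`, which prints one Cohen's kappa per
descriptor and their mean. On this synthetic benchmark six of the seven
descriptors reach kappa of 0.8 or better ("almost perfect" agreement);
margin — the hardest descriptor for human readers too — sits slightly
below (exact values land in `results/acceptance.json` after the script
below).

A command-line wrapper with `simulate`, `dedup`, `train`, `describe` and
`evaluate` subcommands ships in `inst/scripts/sonodescribe.R`:

```sh
Rscript inst/scripts/sonodescribe.R simulate --n 600 --seed 1 --out data/
Rscript inst/scripts/sonodescribe.R describe --image x.png \
    --model model/net.ckpt --mlr model/mlr.json --report out.json
```

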