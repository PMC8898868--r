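# hepaseg

Segmentation and benign/malignant classification of liver lesions on 2-D CT
slices, built for method development and validation on synthetic phantoms
with exact ground truth.

Radiology pipelines for hepatocellular carcinoma screening face two coupled
problems: separating the liver from neighboring structures of similar
attenuation, and then characterizing the lesions inside it.  hepaseg
implements a complete, reproducible chain for single slices:

1. **Preprocessing** — adaptive median filtering for salt-and-pepper
   (impulse) noise and histogram equalization for contrast.
2. **Two-stage liver segmentation** — a coarse mask (Otsu threshold +
   morphology + largest component) refined by a region-based
   **signed-pressure-force (SPF) level set**: with interior/exterior means
   $c_1, c_2$ under an arctan-smoothed Heaviside,

   $$\mathrm{spf}(x) = \frac{I(x) - (c_1+c_2)/2}{\max_x |I(x) - (c_1+c_2)/2|},
     \qquad
     \frac{\partial\phi}{\partial t} = \alpha\,\mathrm{spf}(I)\,|\nabla\phi|,$$

   with Gaussian smoothing of $\phi$ after every sweep in place of
   re-initialization and selective re-binarization to $\pm 1$.
3. **Lesion segmentation** — the same level set restricted to the liver,
   seeded from robust intensity outliers (beyond 2 MADs of the liver median).
4. **Texture features** — gray-level co-occurrence (Haralick) statistics
   (entropy, contrast, energy, homogeneity, correlation; 16 levels, offset 1,
   four angles averaged) plus a dynamic-warping distance of the lesion's
   boundary radius profile against a circle (total path cost, mean and max
   per-step cost).
5. **Classification** — a small convolutional scorer over standardized
   lesion patches (optionally concatenated with the texture features),
   trained so scores land below **2.0** for benign and above **2.0** for
   malignant lesions.
6. **Evaluation** — confusion counts (malignant = positive), sensitivity
   $TP/(TP+FN)$, specificity $TN/(TN+FP)$, accuracy, PPV, exact
   Clopper–Pearson intervals, ROC/AUC, Dice/Jaccard mask overlap.

A phantom generator (`makePhantom()`, `makeDataset()`) produces labeled
abdominal scenes — a bright quasi-elliptical liver over darker background
with smooth low-contrast (benign) or irregular high-contrast (malignant)
lesions, Gaussian plus impulse noise — so every stage is testable without
clinical data.

## Worked example

```r
library(hepaseg)

ph  <- makePhantom(phantomSpec(nLesions = 2, label = "malignant", seed = 11))
amf <- adaptiveMedianFilter(phantomImage(ph))   # impulse removal
pre <- histogramEqualize(amf) / 255             # contrast enhancement

liver   <- segmentLiver(pre)                    # coarse mask + SPF level set
lesions <- segmentLesions(amf, liver)           # restricted level set

overlapMetrics(liver,   liverMask(ph))
#>      dice   jaccard
#> 0.9725534 0.9465731
overlapMetrics(lesions, lesionMask(ph))
#>      dice   jaccard
#> 0.9525862 0.9094650

round(extractFeatureVector(amf, lesions), 3)
#>       entropy      contrast        energy   homogeneity   correlation
#>         3.490         1.859         0.140         0.655         0.097
#>           dvw localDistance     localCost
#>         7.594         0.119         0.335
```

The liver and both lesions are recovered at Dice 0.97 and 0.95 against the
ground-truth masks.  The feature vector shows what the classifier sees: high
co-occurrence contrast (1.86) and a large warping distance (7.59) are the
signature of an irregular, high-contrast — malignant-class — lesion; the same
measurements on a benign phantom lesion (smooth boundary, low contrast) come
out around 1.1 and 3.4.

The full experiment — generate 200 phantoms, segment everything, train the
scorer on 160, evaluate on 40 held-out — is one call:

```r
res <- runPipeline(n = 200, seed = 1)
str(res$metrics[c("accuracy", "sensitivity", "specificity", "auc")])
#> List of 4
#>  $ accuracy   : num 0.975
#>  $ sensitivity: num 1
#>  $ specificity: num 0.95
#>  $ auc        : num 1
```

Held-out accuracy 0.975 (exact 95% CI [0.868, 0.999]), sensitivity 1.00,
specificity 0.95: the thresholded scorer separates the two phantom lesion
classes almost perfectly, and the one error is a benign phantom whose noise
blob scored just above 2.0.

## Command line

A single entry point with subcommands wraps the same functions:

```sh
liverct=$(Rscript -e 'cat(system.file("scripts", "liverct", package = "hepaseg"))')
Rscript $liverct phantom    --n 10 --out phantoms --seed 1
Rscript $liverct preprocess --in slice.png --out pre.png
Rscript $liverct segment    --in pre.png --out-liver liver.png --out-lesion les.png
Rscript $liverct features   --image pre.png --mask les.png --out features.csv
Rscript $liverct train      --dataset phantoms/manifest.json --out model.rds
Rscript $liverct predict    --model model.rds --image slice.png --mask les.png
Rscript $liverct pipeline   --n 200 --seed 1 --out results/
```

Images are PNG/TIFF/NIfTI; masks 0/255 PNG; manifests, configs and metric
reports JSON/YAML.  The `pipeline` subcommand writes a timestamp-free
`metrics.json` that is byte-identical across runs with the same seed.

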