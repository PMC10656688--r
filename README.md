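# autobirads

Rule-based BI-RADS assessment of breast ultrasound sweep videos, in R.

Breast ultrasound is read with the six ACR BI-RADS lexicon categories —
shape (regular/irregular), orientation (parallel/not parallel), margin
(circumscribed/not circumscribed), echo pattern (anechoic/homogeneous/
heterogeneous), posterior acoustic features (none/enhancement/shadowing)
and calcification (none/coarse/punctate) — which are condensed into an
ordinal assessment category (2, 3, 4a, 4b, 4c, 5) and a benign/malignant
call. This package implements that reading as an explicit computation over
a *sweep video* (the cine loop acquired by translating the transducer
through the lesion until normal tissue appears on both ends):

1. **Segmentation** — per-frame lesion masks from a classical dark-object
   engine (robust background floor `median − 3·MAD`, hysteresis growth,
   morphology, posterior-shadow trimming), plus the attention and loss
   operations of learned detectors (SimAM, BCE/focal/CIoU) as pure
   functions with Dice/IoU/precision-recall-specificity metrics.
2. **Features** — per-frame lexicon levels by morphological image
   processing: circularity `4πA/P²` and solidity for shape, bbox aspect
   for orientation, Fourier-descriptor contour smoothness and boundary
   gradient for margin, despeckled interior mean/CV for echo, band/flank
   intensity ratio for posterior features, robust top-hat foci for
   calcification.
3. **Fusion** — per-category frame proportions over lesion frames,
   inclusive proportion thresholds (0.5; calcification 0.2), per-level
   weights summed into a score mapped through rank thresholds
   (≤−1 → 2, 0 → 3, 1–2 → 4a, 3–4 → 4b, 5–6 → 4c, ≥7 → 5; malignant at
   ≥ 4b; simple-cyst override → 2).
4. **Statistics** — confusion-matrix metrics, tie-aware ordinal AUC with
   DeLong variance/CI and the paired DeLong test, Cohen's kappa with
   interpretation bins, McNemar's test (exact/corrected), and
   percent/conditional agreement tables for reader studies.
5. **Phantom** — a speckle phantom generator that renders seeded sweep
   videos with exact ground truth for all fifteen lexicon levels
   (ellipsoidal sweep law, unit-mean gamma speckle, spiculation, margin
   blur, posterior bands, calcific foci), so the whole pipeline is
   testable without clinical data.

See `vignettes/autobirads-methods.Rmd` for the models, assumptions,
parameter defaults and limitations.

## Worked example

```r
library(autobirads)

# a malignant-archetype phantom sweep: irregular, taller than wide,
# blurred margin, heterogeneous echo, posterior shadowing, punctate foci
gv <- generate_video(phantom_malignant(seed = 1))
assessment <- classify_video(gv$video)
assessment
#> BI-RADS 5 (malignant), fused score 10
#>   levels: shape=irregular, orientation=not_parallel, margin=not_circumscribed, echo=homogeneous, posterior=shadowing, calcification=punctate
#>   lesion frames: 18

# a benign solid nodule scores 0 and lands in category 3
classify_video(generate_video(phantom_benign(seed = 1))$video)
#> BI-RADS 3 (benign), fused score 0
#>   levels: shape=regular, orientation=parallel, margin=circumscribed, echo=homogeneous, posterior=none, calcification=none
#>   lesion frames: 18
```

The fused score is the sum of the chosen levels' weights (here
2+2+2+0+2+2 = 10 ≥ 7 → category 5, malignant; the heterogeneous echo of
this archetype is washed out by its blurred margin on enough frames that
the video-level echo falls back to homogeneous — the suspicious score is
carried by the other five categories); the per-category frame
proportions and per-frame labels are carried in the assessment and written
into the JSON report by `write_report()`.

Reader-study arithmetic:

```r
m <- confusion_metrics(tp = 116, fp = 32, fn = 8, tn = 136)
m$percent[c("sensitivity", "specificity", "ppv", "npv")]
#> sensitivity specificity         ppv         npv
#>          94          81          78          94
cohen_kappa(matrix(c(20, 5, 10, 15), 2, 2))$kappa
#> [1] 0.4
```

## Command line

```sh
Rscript inst/cli/birads phantom  --out phantom_dir --seed 4 --archetype malignant
Rscript inst/cli/birads classify phantom_dir/frames --out report.json
Rscript inst/cli/birads segment  phantom_dir/frames --out masks/
Rscript inst/cli/birads eval     ratings.csv --out stats.json --pairs auto:expA
Rscript inst/cli/birads benchmark --out metrics.json --n-seeds 20
```

Cine loops are exchanged as directories of zero-padded PNG frames
(`frame_0000.png`, ...); no video codec is required. Ratings CSVs carry
`lesion_id, truth, rating_<rater>...` with categories in
`{2, 3, 4a, 4b, 4c, 5}`.

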