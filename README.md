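# uglseg — uncertainty-guided coarse-to-fine image segmentation

`uglseg` implements a two-stage ("coarse-to-fine") strategy for segmenting
objects in 2-D biomedical images whose errors concentrate at object
boundaries — the optic cup inside the optic disc on fundus photographs, or
the lung fields on chest radiographs. Instead of changing the network, the
strategy changes what the network sees the second time around.

## The method

1. **Coarse stage.** A compact U-Net-style encoder–decoder `f` produces
   per-object probability maps `P = f(I, φ)` from the image `I`, binarized
   at 0.5.
2. **Boundary uncertainty.** With a circular structuring element `SE_r`
   (discrete ball of radius `r`), the coarse mask yields the *potential
   boundary region* `PBR = dilate(P, SE_r) \ erode(P, SE_r)` — an annular
   band around the coarse boundary where the true boundary is most likely to
   lie. Smoothing the PBR with a truncated normalized Gaussian (window
   `r × r`, SD `r`) gives the *boundary uncertainty map* (BUM); multiplying
   it into the image gives the *background excluded image* `BEI = PBR × I`.
3. **Fine stage.** A second network with the identical architecture and
   recipe is trained on the concatenated `BEI + BUM` channels, spending its
   whole capacity on boundary placement.

Both stages maximize the mean per-object Dice of the probability maps

    L = (1/K) Σ_k  2 Σ p_k y_k / (Σ p_k² + Σ y_k²)

with RMSprop (lr 0.001, batch 8), early stopping on validation Dice, and
joint image/mask augmentation. Evaluation reports Dice (DS), Matthews
correlation (MCC), sensitivity (SEN), and the symmetric Hausdorff distance
(HSD) between boundary point sets, as mean ± SD per object.

The backbone — including the backward pass, the Dice-loss gradient, and the
RMSprop optimizer — is implemented inside the package in RcppArmadillo
(there is no deep-learning framework in the target environment); gradients
are verified against finite differences in the test suite.

## Worked example

No benchmark images ship with the package; a phantom generator provides the
two geometries the method assumes (fundus disc/cup, chest lung fields).

```r
library(uglseg)
ds  <- generate_dataset(30, phantom_spec("lungs", size = 64), seed = 42)
cfg <- train_config(max_epochs = 30, patience = 20, batch_size = 8,
                    r_m = 9,              # 35 * 64/256, the lung-field radius
                    base_filters = 8, depth = 3,
                    augmentation = NULL,  # see the vignette: phantom symmetry
                    seed = 7)
res <- run_ugls(ds, cfg)
print(res$coarse_report)
print(res$fine_report)
```

Output from this exact script (single CPU, ~4 min). First the coarse stage:

```
<metric_report>  (mean +/- SD per object)
  object  n                DS               MCC               SEN                 HSD
  lung_L 10 0.5955 +/- 0.0113 0.5382 +/- 0.0129 0.7818 +/- 0.0310  25.4558 +/- 1.5985
  lung_R 10 0.6126 +/- 0.0165 0.5477 +/- 0.0184 0.7240 +/- 0.0178  22.6854 +/- 1.0917
 Overall 20 0.6041 +/- 0.0163 0.5429 +/- 0.0162 0.7529 +/- 0.0385  24.0706 +/- 1.9480
```

then the fine stage trained on the BEI + BUM channels derived from it:

```
<metric_report>  (mean +/- SD per object)
  object  n                DS               MCC               SEN                HSD
  lung_L 10 0.8651 +/- 0.0397 0.8555 +/- 0.0408 0.7746 +/- 0.0638  3.5944 +/- 0.9310
  lung_R 10 0.9068 +/- 0.0194 0.8921 +/- 0.0213 0.9279 +/- 0.0172  5.9006 +/- 6.6402
 Overall 20 0.8859 +/- 0.0372 0.8738 +/- 0.0368 0.8513 +/- 0.0908  4.7475 +/- 4.7640
```

Each row is one object's test-set mean ± SD. With only ten training images
the coarse pass is genuinely coarse (Dice ≈ 0.60, boundaries ~24 px off);
feeding its boundary-uncertainty band to the second pass lifts test Dice to
≈ 0.89 and cuts the Hausdorff distance to ≈ 5 px — the two-stage effect the
package implements. The `Overall` row pools both objects. (With enough data
and epochs for the coarse stage to converge fully, the margin shrinks; see
the vignette's limitations section.)

The same pipeline is scriptable from the shell (see `inst/cli/ugls`):

```sh
ugls synthesize --kind lungs --n 30 --size 64 --seed 42 -o data/
ugls run-all -i data/ -o out/ --r-m 9 --seed 7 --epochs 30 --no-augment
# or staged:
ugls train-coarse -i data/ -o out/coarse ...
ugls make-bundles -i data/ --model out/coarse/coarse_model.rds -o out/bundles ...
ugls train-fine   -i data/ --bundles out/bundles -o out/fine ...
ugls evaluate     -i data/ --model out/fine/fine_model.rds --stage fine \
                  --bundles out/bundles -o out/eval ...
```

Every run writes a resolved `config.yaml` (including the seed), metric CSVs,
and checkpoint files into its output directory.

## Scope

2-D images; circular structuring elements; PNG masks (0/255) and TSV float
maps. See the methods vignette
(`vignettes/uncertainty-guided-segmentation.Rmd`) for the model's
assumptions, every tunable parameter, the synthetic-data rationale, and the
numerical design choices.
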