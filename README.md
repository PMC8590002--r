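# radguide

Radiomics-guided deep-feature prognosis for CT tumor imaging.

## What it does, and for whom

Image-based prognostic models for solid tumors on CT face a trade-off:
hand-crafted **radiomics** features (shape, intensity histogram, GLCM and
GLSZM texture, margin descriptors) are interpretable but limited, while
features from a **frozen pretrained CNN** are rich but opaque and
uncountable — tens of thousands of activations against a few hundred
patients. `radguide` implements the radiomics-guided middle path for
researchers building prognostic imaging models:

1. compute a fixed 78-feature radiomics signature per tumor
   (14 shape + 18 first-order + 24 GLCM + 16 GLSZM + 6 margin CDF-slope
   features) from a volume/mask pair;
2. extract a 2.5D tumor patch (three axial slices, 128×128, centered on
   the largest-extent slice) and push it through a frozen convolutional
   backbone (a YOLO-v3-style detection backbone whose 1/8-scale
   255-channel output gives 65,280 features per patch; classifier-free
   VGG-19 and DenseNet-201 graphs; or a small seeded test backbone);
3. retain the deep features whose Pearson correlation with some radiomics
   feature exceeds |r| > 0.4 with Bonferroni-corrected p < 0.05 on the
   training cohort — each survivor carries a radiomics interpretation;
4. build a sparse risk score by Cox-LASSO with nested 5-fold
   cross-validated penalty search,
   `RS_i = h0 * exp(sum_j x_ij * beta_j)`,
   and stratify patients at the training-median score (exact median goes
   to the low-risk group);
5. evaluate with Kaplan–Meier curves, log-rank tests, Wald hazard ratios
   and Harrell's C-index, and explain each selected deep feature by its
   correlated radiomics features and their category composition.

A synthetic phantom-cohort generator (textured tumor blobs with
controllable size, heterogeneity and margin sharpness, plus survival times
from a proportional-hazards model on the planted properties) makes the
whole pipeline testable at desk scale without any clinical data. See the
methods vignette (`vignettes/radiomics-guided-prognosis.Rmd`) for the
model, conventions and design choices.

## Worked example

```r
library(radguide)

# a 200-patient synthetic cohort with a strong planted heterogeneity effect
co  <- generate_cohort(survival_spec(n_patients = 200, seed = 7))
cfg <- pipeline_config(seed = 7,
                       extractor = extractor_spec("random_cnn_test"))
run <- run_drs(co$volumes, co$masks, co$cohort, cfg)

run$model
run$evaluations$test
head(run$interpretation$associations, 4)
```

which prints (numbers from this exact seed; about half a minute):

```
<risk_model> 3 selected features, penalty 0.01682 , training median cutoff 0.8163
<stratification_result> 29 high / 31 low risk
  log-rank chi-square 15 p 0.0001076
  HR 18.433 (95% CI 2.3896 - 142.19 )
  C-index 0.846
# A tibble: 4 x 4
  dl_feature          radiomics_feature      category         r
  <chr>               <chr>                  <chr>        <dbl>
1 TestCNN_Latent_1637 Histogram_Maximum      first-order  0.831
2 TestCNN_Latent_1637 Histogram_Percentile90 first-order  0.720
3 TestCNN_Latent_1637 Histogram_Range        first-order  0.715
4 TestCNN_Latent_1637 GLCM_SumSquares        GLCM        -0.690
```

Read: on the 60 held-out patients the learned deep risk score separates
the risk groups (log-rank p = 1.1e-4, hazard ratio 18.4) and orders
survival times well (C-index 0.85), and each selected deep feature is
listed with the radiomics features that explain it, sorted by |r|.

The command-line front end wraps the same functions:

```sh
Rscript inst/cli/radpipe.R simulate --n 50 --seed 1 --out cohort_dir
Rscript inst/cli/radpipe.R run-drs --data cohort_dir --seed 1 --out run_out
```

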