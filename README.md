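# echotype

Quantitative tissue characterization of B-mode ultrasound frames for
typing lower-limb edema as venous, lymphatic, mixed, or absent.

Lower-limb edema of venous and lymphatic origin calls for different
therapy, and the two look different in the subcutis on B-mode ultrasound —
lymphedema shows hypoechoic, vertically oriented "lymphatic lakes", venous
edema a granular mid-brightness texture. A frame carries 256 gray tones
but the unaided eye resolves only about 16, so `echotype` measures the
full grayscale instead:

1. **Calibration.** A user-selected bright fascia band is anchored to
   level 200 by a single multiplicative gain
   `s = 200 / median(fascia ROI)`, each pixel becoming
   `clip(round(v·s), 0, 255)`, so echogenicity bins are comparable across
   frames.
2. **Characterization.** For a region of interest the package computes
   the Gray Scale Median `GSM = median{v_p : p ∈ ROI}`, the mass vector
   `m_i = #{p : v_p ∈ I_i} / |ROI|` over a canonical partition of
   exactly 14 echogenicity intervals `I_1..I_14` covering [0,255]
   (non-echogenic [0,4]; hypoechogenic I–IV over [5,60];
   echogenic I–III over [61,132]; hyperechogenic I–V over [133,210];
   saturation [211,255]), and the lake fraction
   `#{p : v_p ≤ 40} / |ROI|`.
3. **Classification.** Each edema class concentrates mass in a
   characteristic interval span — venous (VEG) in
   hypoechogenic IV–echogenic III, lymphatic (LEG) in
   hypoechogenic II–echogenic I, mixed (MEG) in
   hypoechogenic III–echogenic II, edema-free (NEG) in
   echogenic II–hyperechogenic I. A characterization is scored per class
   by its density-normalized range mass
   `score_c = mass(span_c) / width(span_c) × 256` and classified by
   argmax, abstaining as `INDETERMINATE` when the top two scores are
   within the decision margin.
4. **Pseudocolor rendering** over five color bands, **CSV reporting**,
   and a **group-comparison report** (mean-centered Levene's test gating
   one-way ANOVA + Tukey-HSD vs Kruskal–Wallis + Dunn, α = 0.05) for
   per-limb GSM.

Because clinical frames cannot be shipped, the package includes a seeded
speckle-phantom generator whose class profiles encode the four cohort
distributions (88.31% / 71.73% / 76.17% / 84.87% in the spans above),
complete with lakes, granular texture, and a built-in fascia band — every
stage of the pipeline is testable end to end on synthetic data.

Intended users: vascular/lymphology imaging researchers who want an
objective echogenicity readout from standard B-mode captures, and
methodologists studying brightness-histogram tissue characterization.

## Worked example

```r
library(echotype)

# a synthetic lymphatic-edema frame, then the full analysis pipeline:
# calibrate to the fascia band, characterize the tissue ROI, classify
ph  <- generate_phantom(default_class_profile("LEG", seed = 42))
res <- characterize_and_classify(ph$image, ph$tissue_roi,
                                 calibration_anchor(ph$fascia_roi))
res$characterization
#> <tissue_characterization> GSM 53.0, lake fraction 0.344
res$classification
#> <classification_result> predicted LEG (lake flag set)
#>             VEG    LEG    MEG    NEG
#> evidence 0.4156 0.7145 0.5597 0.0867
#> score    1.2370 2.7715 1.8851 0.3469
```

The GSM of 53 sits in the hypoechogenic IV interval — darker tissue, as
expected for fluid-laden lymphedema. 71.45% of the pixel mass lies in the
lymphatic span (hypoechogenic II–echogenic I), and after density
normalization LEG wins the argmax by a wide margin; 34.4% of pixels sit
at or below brightness 40, tripping the advisory lymphatic-lake flag.

Group-level GSM comparison on two small phantom cohorts:

```r
veg <- characterize_cohort(generate_cohort("VEG", 10, base_seed = 100))
neg <- characterize_cohort(generate_cohort("NEG", 10, base_seed = 400))
compare_groups(list(VEG = veg$gsm, NEG = neg$gsm))
#> <comparison_report>
#>  group n_limbs mean_gsm    sd_gsm
#>    VEG      10     85.9 0.3162278
#>    NEG      10    119.9 0.3162278
#> Levene p = 1 -> ANOVA (p = 5.096e-33), post hoc Tukey-HSD
#> VEG-NEG
#>       0
```

Venous-edema phantoms center near GSM 86, edema-free controls near 120;
Levene's test finds the variances homogeneous, so the ANOVA/Tukey branch
runs and separates the groups decisively.

A thin command-line front end lives at `inst/cli/echotype.R`
(`characterize`, `classify`, `phantom`, `compare-groups` subcommands); a
YAML study config (`inst/extdata/study_config.yaml`) can override the
partition table, classification rule, and reference level.

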