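# ovkit

Characterising the visual system of a reef teleost — the Picasso
triggerfish is the motivating species — takes evidence at four levels:
which opsin genes are expressed and how strongly, what peak absorbance
(λmax) each visual pigment should have given its amino-acid sequence, how
retinal cell densities limit anatomical acuity, and what acuity the animal
actually achieves behaviourally. `ovkit` implements that whole desk-side
pipeline in R, with seeded synthetic-data generators for every stage so
each estimator can be validated against planted truths.

## What it computes

**Spectral tuning.** Opsin sequences are aligned (Needleman–Wunsch,
BLOSUM62, affine gaps) to bovine rhodopsin so every residue gets a bovine
site number (e.g. the retinal-binding K296). A query pigment's λmax is
predicted additively from a characterised reference pigment:

    λmax(query) = λmax(reference) + Σ shifts at known tuning sites

where a shift applies when the substitution is documented exactly, or when
it matches the polarity transition (polar ↔ nonpolar) of a documented
substitution at the same site. Undocumented polarity-changing substitutions
inside transmembrane helices near known sites are flagged as candidates,
never silently applied.

**Expression.** For gene *i* with read count *R_i* and coding length
*L_i*, normalised expression is *R_i / L_i*; the rod proportion is RH1's
normalised count over the total, and within-class proportions (single
cones, double cones) sum to one per class.

**Quantum catch.** Photoreceptor sensitivities come from the Govardovskii
A1 template at a given λmax; the catch of a stimulus is
∫ R(λ) I(λ) S(λ) dλ, reported as a percentage of an ideal white reflector
under the same illuminant. The double-cone luminance output is the mean of
the two member catches — used to check stimulus pairs for isoluminance.

**Retinal topography.** Stereological counting sites (optical
fractionator, section fractions 1 for whole-mounts) give total population
estimates `Σ count × grid² / frame`, a Scheaffer coefficient of error for
sampling adequacy (CE < 0.1), Gaussian-kernel topographic maps with sigma
matched to the grid, and peak densities refined by half-grid subsampling.
Spatial resolving power uses Matthiessen's ratio (focal length = 2.55 ×
lens radius), the angle *a* = arctan(1/f) subtended by 1 mm of retina, and
two ganglion cells per cycle:

    SRP = sqrt(peak density) / (2 a)   [cycles per degree]

**Psychophysics.** Two-alternative grating choices are fitted by Bernoulli
maximum likelihood with a logistic psychometric function (guess rate 0.5,
lapse 0). The acuity criterion is derived from the exact one-tailed
binomial test at the pooled trial count (62% for n = 110 at P < 0.01);
thresholds are interpolated in closed form, with parametric-bootstrap 95%
CIs and permutation tests between treatments.

## Worked example

```r
library(ovkit)

## predict a rod pigment's lambda-max from its sequence
refs <- study_reference_pigments()                  # characterised pigments
q <- make_opsin_variant(refs$RH1$sequence,          # query: S299A variant
                        data.frame(bovine_site = 299, to = "A"))$sequence
predict_lambda_max(q, refs$RH1)
#> <lmax_prediction> variant vs O_latipes_RH1_synthetic (RH1)
#>   reference lambda-max: 502 nm
#>   S299A: -2 nm (documented)
#>   predicted lambda-max: 500 nm

## fit a psychometric function to simulated grating choices
sim <- simulate_scenario("achromatic_acuity", seed = 7)
fit <- fit_psychometric(correct ~ spatial_frequency_cpd, sim$trials)
summary(fit)
#> Logistic psychometric fit (Bernoulli ML)
#>   guess rate 0.50, lapse rate 0.00 (fixed)
#>   location alpha = 3.316 cpd, slope beta = 2.168 per cpd
#>   logLik -392.18, deviance 9.58 on 8 df, 1100 trials
#>   62% threshold: 3.847 cpd
bootstrap_ci(fit, n_boot = 199, seed = 11)
#> 62% threshold: 3.85 cpd (95% CI: 3.61-4.15)

## anatomical acuity from a stereologically sampled retina
retina <- simulate_scenario("ganglion_streak", seed = 3)
peak <- peak_density(retina$sites)
spatial_resolving_power(peak, lens_radius_mm = 1.5)
#> <acuity_estimate> peak 47200 cells/mm^2, lens radius 1.50 mm
#>   focal length 3.83 mm; 1 mm subtends 14.65 deg
#>   spatial resolving power: 7.4 cpd
```

The first block reads: one documented tuning substitution (S299A, −2 nm)
moves the 502 nm reference to a predicted 500 nm rod pigment. The second:
an observer planted at a 3.94 cpd threshold is recovered at 3.85 cpd with
a CI that covers the truth. The third: the peak site density of the
simulated ganglion-cell layer (note the upward bias of a max-statistic
over Poisson counts) and the acuity it implies at a 1.5 mm lens.

## Layout

- `R/` — one file per stage: `opsin-sequences.R`, `spectral-tuning.R`,
  `expression.R`, `visual-models.R`, `retinal-topography.R`,
  `psychophysics.R`, plus `synthetic-data.R` and `scenarios.R`.
- `inst/extdata/tuning_sites.tsv` — the shipped tuning-site table
  (editable; pass your own via `tuning_sites(path)`).
- `vignettes/visual-system-pipeline.Rmd` — models, assumptions, parameter
  choices and limitations.
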