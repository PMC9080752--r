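---
title: "From opsin sequences to behavioural acuity: the ovkit pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From opsin sequences to behavioural acuity: the ovkit pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovkit)
```

`ovkit` chains five desk-side analyses that together characterise a
teleost visual system: spectral tuning of visual pigments, proportional
opsin expression, photoreceptor quantum catch, retinal topography with
anatomical acuity, and behavioural psychometric acuity. This vignette is
the package's account of the models behind each stage, the parameters
that matter, what the synthetic generators do and do not emulate, and the
numerical choices made where the design was open.

## Spectral tuning: additive lambda-max prediction

A visual pigment's peak absorbance is shaped by a modest number of
amino-acid sites in the retinal binding pocket. The prediction model is
deliberately simple and auditable: starting from a reference pigment of
the same opsin class whose λmax is known from in-vitro reconstitution,
every substitution between query and reference at a known tuning site
contributes its documented shift, and the prediction is the exact sum

$$\hat\lambda_{max} = \lambda_{max}^{ref} + \sum_k \Delta_k .$$

Sites are named in bovine rhodopsin coordinates, obtained by global
pairwise alignment (BLOSUM62, gap open 10, extend 1) of each sequence to
the 348-residue bovine scaffold. Pairwise alignment stands in for the
multiple alignment a lab would run; for opsins, which are well over 85%
identical to their references, the bovine-site homology is unambiguous
and the alignment is deterministic.

Two rules decide whether a substitution contributes:

* **documented** — the exact (site, from, to) triple is in the tuning
  table;
* **polarity matched** — a documented substitution at the same site has
  the same polarity transition (polar ↔ nonpolar under a fixed two-class
  scheme) as the query substitution; its shift is borrowed.

Substitutions at known sites with no polarity change contribute nothing.
If several documented rows at one site match the same polarity transition
with different shifts, nothing is applied and the substitution is
reported as ambiguous: an auditable prediction is worth more than a
guessed average. Polarity-changing substitutions inside transmembrane
helices within two sites of a known tuning site are flagged as
candidates (the window is configurable; "close to" is not quantified in
the tuning literature, and two residues spans roughly half a helix turn).

The polarity table treats S, T, C, Y, N, Q, D, E, K, R, H and W as polar
and A, V, L, I, P, F, M and G as nonpolar. Cysteine and tryptophan are
borderline in some schemes; cysteine is kept polar because the tuning
literature it mirrors treats it so. The scheme is an argument, not a
constant.

The shipped table contains only effects with quantified literature
values; two rows (RH1 site 164, SWS2 site 164) carry `NA` shifts and act
purely as "known site" markers for candidate flagging. The package never
invents a shift: classes whose full site tables are not quantified here
(notably SWS2 and the RH2C paralogues) yield predictions that are
documented lower bounds on the information available, and their absolute
values should be read accordingly.

Reference pigments ship with *synthetic* scaffold sequences — the bovine
scaffold with each reference's documented tuning-site residues planted —
because real reference sequences are not redistributable at desk scale.
The scaffolds preserve bovine numbering exactly, which is all the
substitution detector consumes; they are labelled `_synthetic` in their
identifiers.

## Proportional opsin expression

For gene $i$, the read count $R_i$ is normalised by coding length
($R_i/L_i$, reads per bp), removing the length bias of count data. The
rod proportion is RH1's normalised count over the total across all opsin
genes; single-cone and double-cone proportions are computed within their
class. Genes with zero counts are retained at proportion zero — low but
nonzero LWS expression is biologically meaningful and must not be
dropped. Group summaries report mean ± s.e.m. in percent; a group of one
reports s.e.m. 0 with `n = 1` as the flag.

## Quantum catch and isoluminance

Sensitivities are built from the Govardovskii A1 template (alpha plus
beta band) at a given λmax, peak-normalised on a 300–750 nm grid at 1 nm;
measured sensitivity curves can be supplied as spectra instead. The catch
of a reflectance $R$ under illuminant $I$ for sensitivity $S$ is the
trapezoidal integral of $R \cdot I \cdot S$, normalised to the catch of
an ideal unit reflector under the same illuminant — so catches are
percentages of ideal white, illuminant scale cancels, and no von Kries
adaptation step is applied (none is specified by the workflow this
mirrors). The double-cone luminance output is the arithmetic mean of the
two member catches, and the isoluminance gap of a stimulus pair is
$|Q_a - Q_b| / \bar Q$. Published catch values for printed stimuli are
usable directly as scalar inputs to the gap; reproducing them from first
principles would require the unpublished measured spectra.

## Retinal topography and anatomical acuity

Whole-mount counting is two-dimensional, so the optical fractionator's
section and height sampling fractions are 1 and the total population
estimate reduces to $\sum Q \cdot g^2 / f$ (grid step $g$, frame area
$f$). Sampling adequacy uses the Scheaffer coefficient of error in its
systematic/SRS form $\mathrm{CE} = \sqrt{(1 - n/N)/n}\; s/\bar Q$ with
$N = n g^2 / f$ frame placements; designs near 200 sites keep CE well
under the conventional 0.1.

Topographic maps spread each site's fractionator mass as an isotropic
Gaussian with sigma equal to the grid step (sigma adjusted to the grid
size), rasterised at half the grid step and masked to the retina
outline. Each kernel is renormalised over the raster inside the mask —
an edge correction equivalent in effect to reflecting mass at the
boundary — so the map integrates exactly to the fractionator total.
Iso-density contours are drawn in units of 10³ cells mm⁻².

Peak density follows the field protocol: find the provisional peak on
the coarse grid, then take the maximum site density over the half-grid
subsample around it. Being a maximum over Poisson counts, this estimator
is biased upward by roughly $\sqrt{2\ln m}$ count standard deviations
for $m$ candidate sites; tests bound it with an exact Poisson
max-order-statistic envelope rather than pretending it is unbiased.

Spatial resolving power converts the peak ganglion-cell density $D$ to
cycles per degree: focal length $f = 2.55 r$ (Matthiessen's ratio), the
angle subtended by 1 mm of retina $a = \arctan(1/f)$ in degrees, linear
density $\sqrt D$ cells per mm, and two cells per cycle:
$\mathrm{SRP} = \sqrt D / (2a)$. The arctangent form is used because the
small-angle approximation is not exact at teleost focal lengths; the
estimate inverts in closed form (`lens_radius_for_srp()`), and no
displaced-amacrine correction is applied by default (the 0.76 factor is
available as an argument for comparison with older work).

## Psychometric acuity

Choices in a two-passage forced-choice task are Bernoulli with

$$\psi(x) = \gamma + (1 - \gamma - \lambda)\,
  \mathrm{logistic}(-\beta (x - \alpha)),$$

guess rate $\gamma = 0.5$ fixed by the task, lapse $\lambda = 0$.
$(\alpha, \beta)$ are fitted by maximum likelihood on per-frequency
aggregated counts (Nelder–Mead on $(\alpha, \log\beta)$; the
log-parameterisation keeps the slope positive). The fit is on linear
spatial frequency; fits on log frequency can be had by transforming the
covariate. Complete separation caps the slope at 50 cpd⁻¹ with a flag,
and data whose performance rises with frequency are flagged rather than
silently fitted. Deviance against the saturated model is reported; on
well-specified data with ten levels it behaves like $\chi^2_8$, which is
why deviances below ~8.6 are unremarkable.

The acuity criterion is not a convention but a computation: the smallest
correct-choice proportion significantly above chance under the exact
one-tailed binomial test at the pooled per-grating trial count. At
$n = 110$ and $P < 0.01$ that is $68/110 = 61.8\%$, the familiar "62%
threshold". The threshold is the closed-form inversion of $\psi$ at the
criterion; confidence intervals are percentile intervals over parametric
bootstrap resamples (binomial redraws at each frequency from the fitted
curve), bit-reproducible given a seed.

Treatments are compared by permutation: within-fish sign flips when the
design is paired, label shuffles across fish otherwise, with
$p = (1 + \#\{|T^*| \ge |T|\})/(B + 1)$. At four or five fish per group
an exact-style permutation test is more honest than a mixed model's
asymptotics, which is why the package substitutes it for a GLMM.

## What the generators emulate — and what they do not

Every generator returns its data together with a ledger (scenario, seed,
planted truths); recovery tests read truths only from ledgers. Noise
models are the minimal consistent choices: multinomial reads (probability
∝ proportion × length, so normalisation recovers the proportion), Poisson
frame counts, Bernoulli choices, point-substituted scaffold sequences.

Scenario defaults are the documented triggerfish conditions: rod
proportion 68.9%;
double-cone splits at the printed aquarium/field group means; observers
planted at 3.94 (achromatic, 0.5–5 cpd), 1.71 (green–yellow) and 1.89
(pink–purple, both 0.5–3 cpd) with ~110 trials per grating; a retina
with a 38,643 cells mm⁻² temporal peak on a horizontal streak sampled at
~200 sites with a 50 × 50 µm frame. Values without a documented
counterpart were fixed once at field-plausible levels and not revisited: single cones
take 1/3 of cone expression (the share implied by the 2:1 double:single
mosaic), logistic slopes 2–2.5 cpd⁻¹ (giving near-ceiling performance at
the coarsest gratings and chance at the finest, as in real data),
background ganglion density 7,000 cells mm⁻², streak elongation 4 with
1.2 mm vertical extent on a 5 × 4 mm elliptical outline, and opsin CDS
lengths of 1,047–1,074 bp.

The generators are idealisations: no spatial clustering beyond the
streak, no retinal shrinkage or histology artefacts, no session, side
bias or learning effects in the choices, no sequencing error or mapping
ambiguity in the reads, and scaffold rather than real opsin sequences.
Passing recovery tests therefore demonstrates that the estimators are
correct under their stated noise models — not that those models exhaust
real data.

## Problem sizes and numerical choices

Tests and the acceptance script run at desk scale, chosen as the package's
own validation design: 100 replicate observers per behavioural scenario
with 499 bootstrap resamples each (coverage of the 95% CI measured at
91–95%), 200 replicate retinas for fractionator unbiasedness (mean within
1% of truth), 10⁶ reads for expression recovery (within 3 s.e. of the
planted proportion), 1 nm spectral grids (halving the step moves catches
by < 0.1%). Ties in alignment are resolved deterministically; optimiser
tolerances are fixed; all stochastic entry points take explicit integer
seeds and derive any sub-seeds below 2³¹.

## Known limitations

Additive tuning ignores the synergistic site interactions known for SWS2
and RH2 pigments, so absolute predictions for those classes carry the
caveats above even when every quoted shift is applied. The quantum-catch
normalisation reproduces published printed-stimulus catches only in
spirit, since the measured sensitivity and reflectance curves behind them
are not public. The peak-density maximum is upward-biased by design, as
in the field protocol it mirrors. None of these caveats affects the
quantities the package treats as headline results: documented-shift λmax
sums, the binomial criterion, proportional expression, the SRP formula
and its inversion, and psychometric threshold recovery.
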