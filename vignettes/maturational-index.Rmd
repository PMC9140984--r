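---
title: "Maturational-index analysis of sexually divergent brain network development: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maturational-index analysis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maturind)
```

This vignette is the package's account of its statistics: what each stage
assumes, which tunable parameters matter and why their defaults are what
they are, what the synthetic-data generator does and does not emulate, and
the numerical and design choices made where the methodology leaves room.

## 1. From time series to connectomes

Regional fMRI series are assumed to be already parcellated (one series per
region). `normalize_timeseries()` enforces zero mean and unit SD per region;
`bandpass()` retains fluctuations in a frequency band, by default
0.025–0.111 Hz. The default filter is a Daubechies-4 maximal-overlap
discrete wavelet transform implemented in-package: scale $j$ of a series
sampled every `tr` seconds nominally covers $[1/(2^{j+1}\,tr),\,
1/(2^j\,tr)]$ Hz, and the filter keeps exactly those scales whose nominal
support lies inside the requested band (at `tr = 2.42` s these are scales 2
and 3, about 0.026–0.103 Hz). Wavelet filters are not brick-wall, so some
leakage at the band edges is expected; an FFT band-pass with a hard spectral
window over the same band is provided as a cross-check, and both must
attenuate a 0.01 Hz sinusoid by over 90% of variance while retaining the
majority of a 0.05 Hz sinusoid (this is asserted in the test suite).
Boundary handling is circular; perfect reconstruction of the full transform
is tested to 1e-10.

Connectivity is Pearson correlation per region pair, Fisher-transformed
(`atanh`), so edge weights are in SDs of the normal distribution. A
correlation with $|r| \ge 1 - 10^{-12}$ is an error, not a clipped value:
legitimate data should never produce it, and silently clipping would hide a
degenerate input. The diagonal is `NA` and no consumer reads it.

Scan-level quality control (`qc_scans()`) excludes a scan iff mean FD
> 0.3 mm or maximum FD > 1.3 mm (both configurable, in mm). Region-level
quality control (`exclude_low_signal()`) standardises regional mean signal
within each scan and drops a region if its Z falls below −1.96 in any scan.

Between-subject motion correction (`motion_regress()`) regresses each edge
on mean FD across scans and keeps residuals re-centred to the
pre-regression mean — the intercept handling is a package choice: it keeps
Fisher-z units interpretable, and in `by_sex` mode (separate fits per sex,
sensitivity variant) the *group* mean is restored so that between-sex mean
differences survive the correction. A consequence worth knowing: the
cohort-average motion contribution to an edge is retained by construction
(it is indistinguishable from baseline in a single cohort). The regression
is a projection — applying it twice changes nothing beyond 1e-10 — and
`covariate_regress()` applies identical machinery to any per-scan covariate
(intracranial volume, global FC). Global signal regression (`gsr()`)
operates upstream, on time series.

## 2. Developmental trajectories and the maturational index

Each edge or node is modelled per sex as linear in age **centred at 14
years**, with fixed site effects and a subject random intercept. Centring
is a parameterisation choice that makes the intercept equal the baseline
connectivity at 14 (FC₁₄) and the slope the annual rate of change
(FC₁₄₋₂₆, Fisher-z/year). Nonlinear age models are out of scope.

Two engines fit the same mean structure. `engine = "lme"` uses lme4 with a
subject random intercept and is the reference. `engine = "ols"` (default)
drops the random intercept and reports CR1 subject-clustered standard
errors; it is vectorised across all edges at once, which is what makes
~60,000-edge × 2-sex fits routine. The engines agree exactly (point
estimates to 1e-6) when every subject contributes one scan — the random
intercept is then unidentifiable — and in expectation otherwise; both are
tested. Designs with fewer than 3 subjects, fewer than 2 distinct ages, or
a site factor collinear with age are errors.

The maturational index of node $i$ is the Spearman correlation (average
ranks under ties) of FC₁₄ and FC₁₄₋₂₆ across its incident edges. Its
standard error defaults to the classical large-sample form
$\sqrt{(1-\rho^2)/(n-2)}$ with $n$ the number of incident edges; the
methodology leaves this choice open, so a Fisher-z-based alternative
(`se_method = "fisher"`) is provided behind a flag while the classical form
is pinned as the default. Sex differences use
$Z = (\theta_f - \theta_m)/\sqrt{SE_f^2 + SE_m^2}$ with two-sided normal p
values — for MI with the Spearman SEs, for FC₁₄/FC₁₄₋₂₆ with the
regression-coefficient SEs (which already embody the per-sex sample sizes).
The printed form of the parameter-difference denominator in the source
methodology is typographically inconsistent with its own prose; the package
follows the prose (quadrature of coefficient SEs). FDR control is
Benjamini–Hochberg at 5% across the map.

FDR-significant nodes are classified by sign: for ΔMI < 0,
`female_more_disruptive` when MI_female < 0 and `female_less_conservative`
otherwise, mirrored for ΔMI > 0. The boundary rule (which sex's MI sign
splits "more disruptive" from "less conservative") is not fully specified
by the methodology; the package pins it to the sign of the more-extreme
sex's MI as stated, and documents it as a choice.

### Power at small network sizes

The per-node MI standard error is bounded below by
$\sqrt{(1-\rho^2)/(n_\text{edges}-2)}$, which depends on the *atlas size*,
not the number of subjects. At a 60-node network (59 edges/node) each sex's
SE is at least ~0.12 for realistic $|MI| \le 0.5$, so the Z statistic for a
sex difference of 0.3 has mean well below 3 and no FDR-5% threshold yields
high sensitivity — more subjects reduce estimation attenuation but cannot
break this floor. At a 346-region atlas (345 edges/node) the same
difference gives mean Z ≈ 3.9 and comfortable power. The acceptance suite
asserts the small-network sensitivity bound as specified and the resulting
failure is expected and documented; the package's demonstration
configuration plants ΔMI = −0.5 on a 166-region atlas, where detection is
reliable (verified by `scripts/acceptance.R`).

## 3. Spin tests

`spin_rotations()` draws Haar-uniform rotations (QR of a Gaussian 3×3 with
determinant fixed to +1), applies each to one hemisphere and its x-mirror
to the other (preserving left–right correspondence), and converts the
rotation into a *bijective* label permutation by greedy nearest-neighbour
assignment (globally smallest distances first). Greedy assignment, rather
than independent nearest-centroid lookup, guarantees a valid permutation so
every null map preserves the empirical value multiset exactly. Subcortical
regions have no surface coordinates and are permuted uniformly at random,
independently of the cortical spin — a documented choice; passing a
cortical-only map simply uses the cortical spins alone.

`map_correlation()` reports Pearson r, the parametric t-distribution p, and
a spin p computed in both directions (spin map A against empirical B, and
vice versa) with add-one empirical tails, averaged. Add-one means p is
never exactly 0 and the minimal attainable value is $1/(n_\text{perm}+1)$.
Production inference should use 10,000 permutations; the test suite uses
1,000 (and calibration experiments 99–1,000) to keep runtimes proportionate,
with tolerances widened accordingly.

## 4. Transcriptomic mapping and enrichment

With a univariate target the first PLS component has a closed form: gene
weights proportional to the covariance of each standardised gene with the
target. The package computes it directly (and cross-checks against an
independent PLS implementation in the tests). Genes are standardised across
regions by default (`scale_genes = TRUE`, a documented toggle); the
component is sign-anchored so regional scores correlate positively with the
target, and "variance explained" is the squared score–target correlation —
variance in the *target*, not in expression. Significance uses add-one
permutation p values under unconstrained target permutations (`p_perm`) and
spin permutations (`p_spin`).

`rank_genes()` sorts ascending by weight (rank 1 = most negative), breaking
ties alphabetically so the ranking is deterministic.
`median_rank_enrichment()` compares a gene set's median rank against
`n_null` random sets matched in size and gene-length decile
(deciles of log10 length; each null gene drawn from the bin of the
corresponding set gene, with replacement). The p value is the two-sided
add-one tail, and `direction` says whether the set sits at the bottom
(negative-weight) or top end. `chromosome_profile()` applies count-matched
(optionally length-matched) nulls per chromosome; 10,000 null draws is the
default where the methodology leaves the count unstated.

## 5. The synthetic cohort generator

`simulate_cohort()` emulates an accelerated longitudinal study: five age
strata spanning 14–26 with sex-balanced recruitment per stratum (counts
differ by ≤1), 1–3 scans per subject with probabilities 0.36/0.56/0.08 and
follow-ups at +0.5 and +1.5 years, three sites, and mean FD drawn per scan
with a +0.02 mm male shift plus a 5% high-motion outlier tail (so QC has
realistic work to do). Edgewise Fisher-z connectivity follows

$$ z_e = FC_{14,e} + FC_{14-26,e}\,(a-14) + u_{s,e} + u_s + site_{e}
  + \beta_{FD}(FD - \overline{FD}) + \varepsilon $$

with edge-specific and *shared* subject intercepts — the shared component
(default SD 0.05 z) is what limits between-subject global-FC precision,
because edge-specific intercepts average out over thousands of edges; it
was chosen, together with the baseline sex gap of 0.03 z, so that the
global-FC sex effect in a 298-subject cohort lands at a t of roughly 5,
the magnitude typical of adolescent cohorts of this size. The FD confound
is distance-free (identical for all edges) by design, since the pipeline's
correction is edgewise regression, not distance-dependent modelling.

Maturational structure is planted through per-node targets: edge slopes are
$slope_e = \mu_s + g_e\,\tilde z_e + \tau\,\epsilon_e$ where $\tilde z_e$
is the standardised baseline and the loading $g_e = (c_i + c_j)/2$ couples
the two endpoint nodes. Because every edge is shared by two nodes, per-node
correlations cannot be set independently edge-by-edge; the node
coefficients $c$ are instead solved by a damped fixed point so that every
node's expected edgewise Pearson correlation equals $2\sin(\pi\,\rho_s/6)$
— the bivariate-normal Pearson value whose Spearman correlation is the
target MI. The solved loadings are deterministic given the targets; slope
noise is drawn independently per sex so the two sexes' planted MI maps are
independent samples around their targets (this is what makes the null
calibration of the ΔMI Z test meaningful), while the baseline map is shared
up to an additive male shift, mirroring the consistent male > female
baseline difference. A node's *planted* MI therefore scatters around its
target with the usual Spearman sampling SD ($\approx (1-\rho^2)\sqrt{1.06/n}$
over $n$ incident edges) — about 0.07 at 200 edges — and the generator's
calibration test checks unbiasedness and 3-SD coverage rather than a
fixed tolerance that no generator could meet.

In `timeseries` mode the planted Fisher-z matrix is back-transformed,
projected to the nearest valid correlation matrix (eigenvalue floor 1e-6,
diagonal rescaled), and used as the covariance of i.i.d. Gaussian
timepoints; sampling noise then arises from the finite series length, so
the explicit edge-noise term is used only in `fc_only` mode.

What the generator does **not** emulate: spatial autocorrelation of the
planted maps on the cortical sheet (maps used in spin-test experiments are
smoothed separately), distance-dependent motion artefact, non-Gaussian or
autocorrelated fMRI noise, scanner drift, nonlinear trajectories,
hemispheric asymmetries of effect, or realistic expression covariance
between genes (background genes are independent noise; a passing PLS
recovery therefore shows the machinery is correct, not that real panels
behave this way — with a noiseless planted module the variance explained is
far higher than any real transcriptomic fit would be). Passing tests on
this generator demonstrate calibration and recovery of the *statistics*,
not robustness to every artefact of real fMRI.

The expression panel plants a module whose genes have expected correlation
−ρ with the target map (so they land at the negative end of PLS1);
chromosome labels follow approximate human protein-coding counts, gene
lengths are log-normal (median 20 kb), and `x_frac_module` moves module
genes to the X chromosome to plant the X-linked enrichment scenario.
`simulate_casecontrol()` mixes the standardised target with an exactly
orthogonalised noise map so the expected case−control difference correlates
with the target at exactly `r_target`; the default effect size (1 z of
between-region difference against 1 z of between-subject noise) keeps the
empirical t-map's attenuation of that correlation under ~2% at the default
group sizes.

## 6. Reproducibility and problem sizes

Every stochastic function takes a seed; `run_pipeline()` derives all stage
seeds from one master seed via a fixed affine map mod 2³¹−1, so partial
reruns and full reruns agree bit-for-bit. The test suite runs cohorts of
20–300 subjects on 10–60-region atlases, 99–1,000 spin permutations, and
50–200 replicate calibration loops; `scripts/acceptance.R` runs the
demonstration cohort (298 subjects, 166 regions, 1,000 permutations and
nulls) in under a minute. These sizes were chosen so the whole suite
completes in a few minutes while keeping every Monte-Carlo margin wide
relative to its assertion.

## 7. Known limitations

- The OLS engine's clustered SEs are CR1; small numbers of subjects per sex
  would warrant CR2/CR3 or the lme engine.
- The spin test assumes region centroids on a sphere with two hemispheres;
  irregular parcellations with strongly unequal region sizes are only
  approximately exchangeable under rotation.
- Degrees of freedom for mixed-model fixed effects are not estimated
  (Z/t statistics are reported without a small-sample df correction).
- The enrichment null samples genes with replacement within length bins;
  for gene sets comparable in size to a bin this slightly widens the null.
- Subcortical spin handling (independent uniform permutation) is a
  convention, not a spatial null; a cortical-only mode is available by
  passing cortical maps.
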