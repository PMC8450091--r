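---
title: "Methods: quantifying the flanking effect on G-quadruplex topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the flanking effect on G-quadruplex topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4flank)
```

## The problem

Intramolecular G-quadruplexes fold from four G-tracts into parallel,
antiparallel or hybrid topologies, distinguishable by their CD signatures:
parallel folds show a strong positive band near 265 nm, antiparallel folds a
positive band near 290 nm with a negative 265 nm trough, hybrids a blend of
both. Bases flanking the G4 core shift the balance between these forms —
more strongly from the 5′ side — and `g4flank` packages the full analysis
chain for measuring that shift across loop-permutation libraries: sequence
design, conformation-index classification, melting-temperature extraction,
and the pairwise/grouped statistics.

## The conformation index

For a spectrum with ellipticities CD265 and CD290,

$$ r = \frac{\mathrm{CD}_{265}}{|\mathrm{CD}_{265}| + \mathrm{CD}_{290}}, $$

classified with closed thresholds: parallel iff $r \ge 0.5$, hybrid iff
$0 \le r < 0.5$, antiparallel iff $r < 0$. Design choices worth knowing:

* **Point readings, no smoothing.** CD265/CD290 are single-wavelength linear
  interpolations at exactly 265 and 290 nm. Band integration or smoothing
  would silently change $r$; if the grid misses those wavelengths by more
  than the interpolation margin (default 2 nm) the sample errors out rather
  than guessing.
* **Scale invariance.** $r$ is a ratio, so raw mdeg and molar-normalized
  spectra give identical values; the units tag is bookkeeping only.
* **Degenerate denominators.** When $|\mathrm{CD}_{265}| + \mathrm{CD}_{290}$
  is within a *relative* tolerance (`eps_rel`, default $10^{-6}$ of the
  spectrum's maximum absolute signal) of zero, $r$ is undefined and flagged
  `small-denominator`. A strongly negative 290 nm band can make the
  denominator small or negative; rather than clamping, the value is computed
  as-is and flagged (`negative-290`, plus `out-of-range-r` when $|r| > 1$),
  preserving auditability.

## Sequence design

The library grammar is positional: `abc` encodes the loop lengths of
5′-GGG T<sub>a</sub> GGG T<sub>b</sub> GGG T<sub>c</sub> GGG-3′, and
`5'Tk-abc` / `3'Tk-abc` / `DTk-abc` add k thymines at the indicated end(s).
Loop digits are single digits: the model library spans loop lengths 1–6 with
total loop length 7–13, so positional three-digit codes are unambiguous.
Natural sequences that do not fit the grammar enter the pipeline as explicit
sequence strings in the manifest, with flank annotations, and pairing of
bare/flanked variants is always explicit through `pair_id` — never inferred
from name similarity. Sequences with a unique shortest loop of one thymine
are categorised `1bc`/`a1c`/`ab1` by its position, since the flanking
response differs by category. A 5′-terminal phosphate is a manifest flag
only; it never changes the rendered sequence.

## Melting temperatures

Tm is extracted by first-derivative analysis: a centred moving average
(default window 5 points — derivatives amplify noise, and experimental
melting curves are smooth) is differenced centrally, and the transition is
located on $|dA/d(1/T)| = |dA/dT|\,T^2$ with $T$ in kelvin. The inverse
coordinate matters: a two-state transition is logistic in $1/T$, so its
derivative peak falls exactly on the transition midpoint there, whereas the
plain $dA/dT$ peak is biased a few tenths of a degree low. The peak is then
refined off-grid by a least-squares parabola over the contiguous region
within 60% of the maximum, falling back to a three-point vertex when that
region is too narrow. Wide-support fitting is what keeps the estimator
robust: with 0.002 absorbance noise on a 0.5 °C grid, the mean recovery
error over the generator's Tm ∈ (40, 70) °C, ΔH ∈ (−60, −30) kcal/mol
ensemble is below 0.2 °C.

Using the absolute derivative makes the extraction independent of the
transition direction, so the monitored wavelength's sign convention
(hypochromic at 295 nm, the G4 standard and the generator default, vs
hyperchromic at 260 nm) never matters, and Tm is invariant to affine
transforms of the absorbance. Quality flags mark ambiguous transitions
(`multiple-extrema`: more than one separate derivative region reaching 90%
of the peak, with the 70%-valley rule distinguishing true multiphasic
behaviour from noise jitter within one broad peak), `edge-extremum`, and
transition-free curves (`low-amplitude`: peak derivative under three times
the median). ΔTm = Tm(flanked) − Tm(bare), negative for destabilisation. No
thermodynamic parameters are fitted from measured curves; Tm is the only
output.

## Group and pairwise statistics

* Δr = r(flanked) − r(bare), computed per explicit pair.
* Group spread uses the population divisor:
  $\sigma = \sqrt{\sum_i (x_i - \mu)^2 / N}$. This is deliberate — the group
  *is* the complete set of loop permutations, not a sample — even though the
  paired t-test internally uses the usual $n-1$ sample standard deviation.
* Topology proportions and positive-Δr fractions are reported as percentages
  to one decimal; zeros count as non-positive; undefined classifications are
  excluded from the denominator and reported separately.
* Paired two-sided t-tests annotate significance as \*\*\* ($p<0.001$),
  \*\* ($p<0.01$), \* ($p \le 0.05$), ns ($p>0.05$). Zero-variance
  differences are flagged degenerate with $p = 1$ (all-zero) or $p = 0$
  (constant non-zero shift) rather than erroring. No multiple-testing
  correction is applied by default, matching the raw-p reporting convention
  of this analysis style.

## The synthetic-data generator

The generator exists so that every stage has a testable ground truth; it
emulates the *reading* of CD and melting data, not the underlying quantum
chemistry.

**Basis spectra.** Each topology is a sum of Gaussian bands on a 220–320 nm
grid (1 nm step): parallel +1.00 at 264 nm (σ 9) and −0.45 at 242 nm (σ 8);
antiparallel +0.70 at 292 (σ 10), −0.55 at 265 (σ 9), +0.35 at 245 (σ 8);
hybrid +0.65 at 290 (σ 10), +0.55 at 268 (σ 9), −0.35 at 242 (σ 8).
Amplitudes are arbitrary units chosen so each pure basis classifies into its
own class (the constructor enforces parallel $r \ge 0.9$, antiparallel
$r < 0$, hybrid $0 \le r < 0.5$); they carry no claim of spectroscopic
accuracy and are overridable.

**Ensemble mixtures.** Spectra mix linearly with population fractions — the
standard CD assumption — plus i.i.d. Gaussian noise per grid point (default
SD 0.02, i.e. 2% of the parallel band amplitude, a realistic signal-to-noise
for 5 μM strand CD). The fraction-to-$r$ map is internally consistent but
not calibrated to any measured ensemble.

**Flanking-effect model.** Each category has a baseline fraction triple
(parallel, hybrid, antiparallel): `1bc` (0.15, 0.45, 0.40), `a1c`
(0.70, 0.20, 0.10), `ab1` (0.35, 0.45, 0.20), `none` (0.30, 0.40, 0.30),
reflecting that short-central-loop sequences are parallel *per se* while the
other categories start hybrid-to-antiparallel. Per sequence the baseline is
jittered (SD 0.05) and renormalised. Flanks move mass into the parallel
fraction by $(s_5(1-2^{-L_5}) + s_3(1-2^{-L_3})) \times \text{sensitivity}$,
taken proportionally from the non-parallel fractions and clipped to the
simplex. Defaults $s_5 = 0.35$, $s_3 = 0.05$ encode the 5′ ≫ 3′ asymmetry;
the saturation $1 - 2^{-L}$ makes the first nucleotide carry half of the
maximal effect, matching the observation that one 5′ thymine accounts for
most of it (the exact functional form is this package's choice); and the
per-category sensitivity (0.6 for `1bc`, 1 otherwise) encodes the weaker
parallelization when the first loop is shortest. A zero-shift model
($s_5 = s_3 = 0$) is the type-I control: its Δr distribution is pure noise
centred at zero.

**Melting curves.** Two-state van't Hoff model with
$\theta(T) = 1/(1 + \exp[(\Delta H/R)(1/T - 1/T_m)])$, $T$ in kelvin,
$R = 1.987\times10^{-3}$ kcal/(mol·K) and $\Delta S = \Delta H/T_m$ implied,
so $\theta(T_m) = 1/2$ exactly and $\theta$ falls with temperature for
$\Delta H < 0$. Absorbance is the $\theta$-weighted mix of linear folded and
unfolded baselines (defaults 1.0 − 2·10⁻⁴·T and 0.7 + 2·10⁻⁴·T: folded above
unfolded, i.e. hypochromic unfolding at 295 nm, with mild instrument-like
drifts) plus Gaussian noise (default curves in the test-bench use SD 0.002).

**What passing on synthetic data does and does not show.** The generator
covers additive Gaussian noise, baseline drift, ensemble mixing and the
planted asymmetries; it does not emulate wavelength-dependent noise,
scattering artefacts, non-two-state (multiphasic or hysteretic) melting,
aggregation, or any nonlinearity between population fractions and CD. Green
tests therefore demonstrate that the pipeline recovers what the model plants
at realistic noise, not that real spectra are free of those other failure
modes — the quality flags exist precisely because real data will trip them.

## Problem sizes and numerical choices

The bundled analyses use problem sizes chosen to exercise the statistics at
the scale of a real library screen: 90 bare/flanked pairs for the
flanking-effect experiments (comparable to a 91-pair screen), 100 curves for
Tm-recovery ensembles, 50 replicates of 30 pairs for the type-I control,
and 1000 random spectra for the scale-invariance property. All generators
take explicit integer seeds and are bitwise reproducible given one.

Tie-breaks and degenerate inputs are handled conservatively: duplicate
wavelengths are averaged on read; exact grid hits bypass interpolation;
queries just outside the grid (≤ margin) take the endpoint value with an
`extrapolated` flag; classification thresholds are closed ($r = 0.5$ is
parallel, $r = 0$ hybrid); and batch runs never die on one bad file — the
failing rows are collected and reported alongside the results.

## Known limitations

* $r$ is a one-dimensional summary; it cannot resolve mixtures that happen
  to cancel at 265/290 nm, which is why the flag set travels with every
  result.
* No spectral deconvolution into quantitative topology fractions is
  attempted; $r$ is the deliverable.
* The correlation between $r$ and Tm is deliberately left at a plain
  correlation if users compute it; the package fits no model linking
  topology to stability.
* Multi-digit loop lengths are outside the name grammar; such designs must
  be supplied as explicit sequences.
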