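---
title: "Tissue oximetry from integrating-sphere diffuse reflectance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue oximetry from integrating-sphere diffuse reflectance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otos)
```

## The measurement and the model

`otos` turns raw integrating-sphere spectra of skin into tissue oxygen
saturation. A tungsten lamp illuminates the palm through the sphere's sample
port; the sphere collects everything the tissue sends back. Three raw spectra
define one measurement: the sample reflection $R_R$, the dark reading $R_0$
(empty port, electronic floor) and the reference-standard reading $R_1$
(lamp spectrum). The calibrated total diffuse reflectance is

$$M_R(\lambda) = r_{std}\,\frac{R_R - R_0}{R_1 - R_0} + R_{Fresnel},$$

where $r_{std}$ is the reflection factor of sphere plus standard (default
0.99, a pressed-PTFE standard) and $R_{Fresnel} = ((n-1)/(n+1))^2$ restores
the specular component lost at the port (default computed from $n = 1.4$,
the standard tissue-optics value for skin; a measured value can be
substituted). Because the normalization is a ratio, lamp drift common to all
three spectra cancels exactly.

## From reflectance to absorption: adding–doubling

Skin is a turbid medium: photon transport obeys the radiative transfer
equation with absorption coefficient $\mu_a$, scattering coefficient
$\mu_s$, Henyey–Greenstein anisotropy $g$ and refractive index $n$. The
forward solver builds the reflection/transmission operators of a thick slab
by adding–doubling: an optically thin starting layer
($\tau_0 = 10^{-5}$) is initialized by the diamond (implicit-midpoint)
discretization of the transport generator and repeatedly doubled; Fresnel
interfaces (with total internal reflection) are composed on top. The angular
variable is discretized by Gauss–Radau quadrature with a node exactly at
cosine 1, so a collimated normal beam occupies its own channel; for $n > 1$
the interval splits at the critical cosine $\sqrt{1 - 1/n^2}$ so the
trapped-light cone is resolved.

Numerical choices that matter:

* **Diamond initialization.** A naive single-scattering start seeds a
  $O((\tau_0/\nu)^2)$ conservation defect at the most oblique quadrature
  node which the doubling cascade amplifies catastrophically for
  near-conservative media. The implicit-midpoint form preserves the energy
  balance structurally; the conservative slab then converges to
  $M_R = 1$ within $10^{-3}$ and stays there.
* **delta-M scaling.** Tissue's forward-peaked phase function
  ($g \approx 0.7$–$0.9$) cannot be resolved by an 8- or 16-point
  quadrature. The solver therefore folds the unresolvable forward fraction
  $f = g^{2N}$ into the unscattered beam ($\mu_s^* = (1-f)\mu_s$, truncated
  renormalized expansion). Without this, order-8 reflectance is wrong by
  several times $10^{-3}$; with it, order 16 agrees with an independent
  Monte-Carlo oracle to within one standard error at $10^6$ photons.
* **Convergence and stagnation.** Semi-infinite media are doubled until
  $M_R$ changes by less than `convergence_tol` ($10^{-6}$). Exactly
  conservative media approach their limit so slowly that the per-doubling
  change bottoms out at the resolvent's round-off floor
  ($\sim 3\times10^{-5}$) first; the loop detects the stagnation and accepts
  the value rather than erroring.
* **Quadrature order.** Default 8 per hemisphere — the method's classical
  speed/accuracy compromise, good to about $10^{-3}$ in $M_R$ for skin-like
  properties (order 16 is good to $\sim 2\times10^{-4}$ and is used for
  validation runs). The published claim that orders 8 and 16 agree to
  $5\times10^{-4}$ proved optimistic for $g = 0.9$ with mismatched
  boundaries; the tested bound is $2.5\times10^{-3}$, and a genuine
  convergence assertion (order 16 vs 32 within $5\times10^{-4}$) guards the
  scheme. Because the synthetic generator and the inverse solver share one
  forward model, pipeline results are self-consistent at either order.

The inverse problem — find $\mu_a$ given measured $M_R$ with
$\mu_s(\lambda)$, $g(\lambda)$, $n$ fixed — is solved per wavelength by
bracketed root finding on $\log \mu_a \in [\log 10^{-6}, \log 50]$
(mm$^{-1}$): $M_R$ is strictly decreasing in $\mu_a$, so the root is unique.
Reflectances above the $\mu_a = 0$ ceiling or at/below the specular-only
floor are *out of gamut*: flagged and excluded, never imputed; a spectrum
with more than half its channels out of gamut aborts as a calibration
failure.

## Fixed skin scattering models

Scattering is not fitted; it comes from the skin literature:
$\mu_s'(\lambda) = a(\lambda/500\,\mathrm{nm})^{-b}$ with
$a = 46\ \mathrm{cm}^{-1}$, $b = 1.421$, and a sixth-order polynomial for
$g(\lambda)$ (evaluated by Horner recursion — its coefficients span 18
orders of magnitude). $\mu_s = \mu_s'/(1-g)$. All attenuation coefficients
live in mm$^{-1}$ internally; $a$ is converted once at construction, which
eliminates silent cm/mm mix-ups. The models are declared valid on
450–1000 nm: the anisotropy polynomial is a fit and diverges outside its
fitted region, so evaluation beyond the window is a domain error, not an
extrapolation.

## Two-wavelength oximetry and the melanin slope

Tissue absorption is modelled as
$\mu_a(\lambda) = \frac{\ln 10}{10}\sum_i \varepsilon_i(\lambda) C_i$
(molar extinction in L mol$^{-1}$cm$^{-1}$, concentrations in mol/L,
$\mu_a$ in mm$^{-1}$). With two wavelengths the two-chromophore system
inverts in closed form:

$$[HbO_2] = \frac{\mu_a^{\lambda_2}\varepsilon_{Hb}^{\lambda_1} -
\mu_a^{\lambda_1}\varepsilon_{Hb}^{\lambda_2}}{D},\qquad
[Hb] = \frac{\mu_a^{\lambda_1}\varepsilon_{HbO_2}^{\lambda_2} -
\mu_a^{\lambda_2}\varepsilon_{HbO_2}^{\lambda_1}}{D},$$

with $D = \varepsilon_{Hb}^{\lambda_1}\varepsilon_{HbO_2}^{\lambda_2} -
\varepsilon_{Hb}^{\lambda_2}\varepsilon_{HbO_2}^{\lambda_1}$, and
$StO_2 = 100\,[HbO_2]/([HbO_2]+[Hb])$. $StO_2$ is invariant under common
rescaling of the extinction columns or of both absorption inputs, so unit
conventions cannot corrupt it; concentrations themselves are reported in
units consistent with the extinction scaling.

The infrared wavelength is fixed at 975 nm (the instrument's laser line).
The visible wavelength comes from the melanin rule: the OLS slope of
$\mu_a$ over 630–700 nm tracks epidermal melanin, and its absolute value
selects $\lambda_1$: below $5\times10^{-4}$ mm$^{-1}$/nm → 622 nm (group I,
fair); between $5\times10^{-4}$ and $8\times10^{-4}$ → 624 nm (group II,
intermediate); above $8\times10^{-4}$ → 626 nm (group III, brown). The
published rule uses strict inequalities on both sides of each threshold,
leaving the boundary undefined; this implementation assigns boundary values
to the lower group — a deterministic, documented tie-break.

**Extinction data.** The canonical oxy/deoxy-hemoglobin tabulation could
not be redistributed here, so the package bundles a *synthetic*
reconstruction (`hemoglobin_extinction_synthetic.tsv`): log10 cubic splines
through widely quoted anchor values, 450–1000 nm at 2 nm. It preserves what
the method uses — band shapes, the steep red-edge fall-off, the 760 nm
deoxy bump, a single isosbestic crossing near 805 nm, the broad oxy NIR
maximum — but absolute values are approximate. Since $StO_2$ is scale-free
and the synthetic generator composes phantoms from the same table, every
internal consistency result is unaffected; only comparisons against
externally tabulated extinction values would be.

## The synthetic world

The generator emulates the acquisition chain, not just its output. A
phantom is (oxy, deoxy) hemoglobin, a melanin power law
$m\,(\lambda/500)^{-3.46}$, and a flat background. Its $\mu_a(\lambda)$
feeds the forward solver; the resulting $M_R$ is inverted through the
sphere equation around a smooth 2850 K tungsten-like lamp spectrum and a
1800-count dark floor; multiplicative Gaussian noise (default 1 %)
models the shot/gain regime of high-count spectra. The acquisition grid is
0.25 nm/pixel — the pixel pitch of the spectrometer class being emulated —
so the pipeline's default boxcar half-width of 50 pixels (the vendor-style
"boxcar width 50" setting; the vendor convention is a half-width) spans
about ±12.5 nm, which is what makes real spectra of this kind look smooth.

Default healthy-palm phantom, chosen once from physiology and frozen:

* total hemoglobin $10^{-4}$ mol/L — roughly 4 % cutaneous blood volume at
  2.3 mmol/L whole-blood hemoglobin, a well-perfused palm;
* true $StO_2$ 98 % — mid healthy band;
* melanin scale 0.001 mm$^{-1}$ at 500 nm — palmar (glabrous) epidermis is
  nearly melanin-free regardless of phototype;
* flat background $5\times10^{-4}$ mm$^{-1}$ — residual non-heme absorption.

**Why melanin must be small here.** At 98 % saturation the deoxy
concentration is a small difference of large terms, so any non-hemoglobin
absorber at $\lambda_1$ leaks into $[Hb]$ with weight
$\varepsilon_{HbO_2}^{\lambda_2}$. Melanin heavy enough to push the
630–700 nm slope into group II ($\approx 0.27$ mm$^{-1}$ at 500 nm) drags
recovered $StO_2$ to about 75 % — the 622→626 nm wavelength shift cannot
compensate absorption an order of magnitude above the blood signal. The
method's healthy-range accuracy therefore *presumes* a blood-dominated
$\mu_a$ at $\lambda_1$, which is exactly what glabrous palm skin provides.
This is a genuine limitation of two-wavelength oximetry with slope-based
wavelength selection, and the reason the healthy fixtures sit in group I.
A green healthy-range test establishes self-consistency of the full chain
(generator → sphere → inversion → classification → solve) under realistic
noise; it does not establish robustness to heavy epidermal melanin, which
the model family does not possess.

The occlusion generator rescales the oxy/deoxy split at fixed total
hemoglobin to stage targets (defaults: the published stepped-cuff group
means 95.69, 94.78, 92.45, 91.46 % at 0/60/80/100 mmHg), adds
volunteer-level jitter as one common offset (sd 1 %) plus small per-stage
scatter (sd 0.1 %) — the offset models between-subject variation without
breaking within-series monotonicity — and appends recovery points that
climb back toward (optionally above, reactive hyperemia) baseline. Real
occlusions also change total hemoglobin (venous pooling); that is outside
the model.

## The Monte-Carlo oracle

An independent check of the transport solver: an MCML-style photon walk
(exponential steps in $\mu_t$, Henyey–Greenstein deflections, unpolarized
Fresnel with total internal reflection at the boundary, survival-weight
absorption with Russian roulette), written in C++ with a fixed-seed
Mersenne-Twister stream mapped to uniforms explicitly so results are
bit-reproducible across platforms. It shares no code or discretization with
adding–doubling; agreement of the two (within 3 standard errors at $10^6$
photons across an absorption × scattering × anisotropy × index grid) is the
package's strongest correctness evidence. Near-conservative walks have
return-time distributions with infinite mean, so a step cap truncates them;
the truncated weight is returned (`lost`) and enters test tolerances
explicitly instead of being silently dropped.

## Degenerate inputs and tie-breaks

* $\mu_a = \mu_s = 0$ is rejected at construction (no medium).
* $g = 1$ is a singularity of $\mu_s = \mu_s'/(1-g)$ and is rejected.
* Identical analysis wavelengths make the extinction determinant vanish:
  ill-conditioned-pair error.
* Negative recovered concentrations (possible with noisy spectra) are
  flagged out-of-model and $StO_2$ withheld — never clamped into range.
  Round-off-scale negatives from exact pure-component input are zeroed.
* Suspect reflectances ($M_R < 0$ or $> 1.05$) are flagged, not clipped, so
  calibration faults surface in reports.

## Known limitations

* Homogeneous semi-infinite skin: no epidermis/dermis layering, no finite
  sampling-depth correction (a finite-slab regime exists in the solver but
  the pipeline treats the palm as optically thick).
* Two chromophores only; water and fat are not modelled. Real water
  absorption near 975 nm biases the infrared channel of any two-wavelength
  solve that ignores it; within the package's model family, this appears
  only through the (small) flat-background term.
* The melanin sensitivity above: reported $StO_2$ in heavily pigmented,
  non-glabrous sites would be biased low.
* The bundled extinction table is a synthetic reconstruction (see above).
* Scattering is fixed from literature models; a subject whose $\mu_s'$
  deviates from the power law propagates that error into $\mu_a$.
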