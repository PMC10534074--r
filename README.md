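# otos — tissue oximetry from integrating-sphere diffuse reflectance

`otos` estimates **tissue oxygen saturation (StO₂)** — the oxygenated
fraction of hemoglobin in the mixed skin vascular bed — from diffuse
reflectance spectra measured with an integrating sphere. It is aimed at
biomedical-optics groups building or validating non-invasive microcirculation
monitors (e.g. for diabetic-foot screening), and at anyone who needs a
tested, scriptable reference implementation of the full chain:

1. **Sphere normalization** — raw sample/dark/reference counts to total
   diffuse reflectance, `MR = rstd·(RR−R0)/(R1−R0) + R_Fresnel`.
2. **Inverse adding–doubling** — per-wavelength solution of the radiative
   transfer equation for a turbid slab recovers the absorption coefficient
   μa(λ) from MR(λ), with skin scattering fixed from literature models
   (μs′ = a(λ/500)⁻ᵇ, a = 46 cm⁻¹, b = 1.421; polynomial g(λ)).
3. **Melanin slope rule** — the OLS slope of μa over 630–700 nm classifies
   the skin (|slope| < 5×10⁻⁴ mm⁻¹/nm → λ₁ = 622 nm; 5–8×10⁻⁴ → 624 nm;
   > 8×10⁻⁴ → 626 nm; λ₂ = 975 nm).
4. **Two-wavelength solve** — [HbO₂] and [Hb] from the 2×2 extinction
   system at (λ₁, λ₂); StO₂ = 100·[HbO₂]/([HbO₂]+[Hb]).

A synthetic-data module generates realistic palm-skin measurements and
stepped-pressure occlusion series from known ground truth, and an
independent Monte-Carlo photon-transport oracle (C++) cross-validates the
adding–doubling solver. See `vignettes/otos-methods.Rmd` for the models,
defaults and limitations (including why the bundled hemoglobin extinction
table is a clearly-labelled synthetic reconstruction).

## Worked example

```r
library(otos)

# a healthy palm phantom: 98 % saturation, low palmar melanin
ph <- healthy_palm_phantom(sto2 = 98)

# synthesize one noiseless RR/R0/R1 acquisition and analyse it
m   <- generate_measurement(ph, seed = 7, noise_sigma = 0)
rep <- run_otos(m$rr, m$r0, m$r1)
print(rep)
```

```
StO2 report
  StO2            : 97.56 %
  melanin slope   : -1.167e-04 mm^-1/nm  (group I_fair)
  wavelength pair : 622 / 975 nm
  mua(l1), mua(l2): 0.0242, 0.0271 mm^-1
```

Reading: the 630–700 nm absorption slope (1.17×10⁻⁴ mm⁻¹/nm in magnitude)
is below the 5×10⁻⁴ threshold, so the palm is classified group I and the
visible analysis wavelength is 622 nm; the absorption coefficients at
622/975 nm then give 97.6 % saturation, within the 97–99 % healthy band
(the ~0.4-point offset from the 98 % ground truth is the documented
non-hemoglobin-background bias plus boxcar smoothing, both analysed in the
methods vignette).

Occlusion series and the command line:

```sh
otos simulate  --seed 1 --noise 0.01 --out fixtures/     # staged 0/60/80/100 mmHg series
otos occlusion --series fixtures/ --out results/         # StO2 vs stage summary
otos run --rr rr.csv --r0 dark.csv --r1 ref.csv --out results/
```

(The `otos` script ships in `inst/exec/`; equivalently call
`otos::otos_main(c("run", ...))`.) Exit codes distinguish calibration
failures (2), out-of-gamut inversions (3) and I/O errors (4).

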