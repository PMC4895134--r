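# skyspec

Analysis of downwelling illumination across daylight, twilight and night —
for visual ecologists, photobiologists and anyone modelling natural or
light-polluted skylight.

Between midday and moonless night the sky's irradiance spans about eight
orders of magnitude, and its spectral composition shifts from CIE-daylight
behaviour through a strongly blue-enriched twilight (ozone's Chappuis band
filtering green/yellow light) to night spectra dominated by narrow emission
features: the 558 nm atomic-oxygen airglow line at dark rural sites, and
sodium-lamp emission (570–615 nm complex, 819 nm line) under urban light
pollution. The classical CIE daylight model,

    S(λ) = S0(λ) + M1·S1(λ) + M2·S2(λ),

describes daylight well but fails below the horizon. skyspec implements the
full analysis chain for quantifying that failure and repairing it:

* **Calibration** — dark-library subtraction (temperature-interpolated),
  additive wavelength-shift estimation from Hg/Ar lamp lines, radiometric
  correction factors with least-squares splicing of multiple calibration
  sources, conversion to absolute downwelling irradiance (radiance × π),
  and quality control (saturation, zero-clamping, order-8 median filter).
* **Ephemeris indexing** — regime classification by solar elevation θs
  (day / civil / nautical / astronomical twilight / night), dawn–dusk
  splitting, half-open elevation binning, and the rural lunar filter
  (fraction illuminated < 0.3).
* **Colorimetry** — CIE 1931 XYZ/xy, the daylight locus over 4000–25000 K,
  and sRGB swatch rendering of elevation bins with log-intensity scaling.
* **Model fitting** — least squares of L2-normalised spectra on unit-norm
  basis functions; R² reported as the squared Pearson correlation between
  fit and data across wavelengths (the field convention), alongside
  1 − SSE/SST.
* **Basis extension** — the iterative residual procedure that appends the
  normalised mean residual of daylight fits (CIE+1), civil-twilight fits
  (CIE+2), and per-location astronomical-twilight fits, yielding the
  six-component CIE+3R (rural) and CIE+3C (city) models.
* **Synthetic campaign generator** — a seeded two-location, two-instrument
  sky and acquisition simulator (intensity sigmoid over 8 decades, Chappuis
  twilight blue shift, airglow and sodium night floors at a 100× brightness
  ratio, phase-scaled moonlight, dark/read/shot noise, saturation,
  automatic integration times) with complete ground truth, so the whole
  chain is testable without downloads.

## Worked example

```r
library(skyspec)

camp <- generate_campaign(sky_sim_config(seed = 1))   # ~2,100 records
cal  <- calibrate_campaign(camp)
rec  <- lunar_filter(cal$records)
sets <- lapply(split(rec, rec$location_id), function(r)
  list(spectra = cal$spectra[r$record_id], theta_s = r$solar_elevation_deg))

ext <- extend_cie(sets$rural, sets$city)
ext$stages
#>   stage component                      regime n_records
#> 1     1     CIE+1       theta_s >= 0 (pooled)       736
#> 2     2     CIE+2   -6 < theta_s < 0 (pooled)       280
#> 3     3    CIE+3R -18 < theta_s < -12 (rural)       160
#> 4     3    CIE+3C  -18 < theta_s < -12 (city)       160

wl <- ext$cie_plus_3R$wavelength_nm
wl[which.max(abs(ext$cie_plus_3R$components[, "CIE+3R"]))]
#> [1] 560
```

The stage table shows which records built each added component; the final
line locates the dominant feature of the rural stage-3 component at the
airglow line (recovered within the ±2 nm tolerance set by the order-8
median filter's interaction with narrow lines — the injected line is at
558 nm). Fitting the extended versus the plain CIE model with `fit_set()`
shows daylight bins near R² ≈ 1 for both, while below −12° only the
extended models stay high.

A file-based run of the same chain:

```r
write_campaign(camp, "campaign")
run_pipeline("campaign", "report")   # CSV tables + run_log.json
```

or from a shell via the thin CLI: `Rscript inst/cli/skyspec.R simulate
--seed 1 --out campaign` then `... pipeline --in campaign --out report`.

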