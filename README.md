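# oamtwist

Forward models and measurement algorithms for probing media with
orbital-angular-momentum (OAM) light. The package is aimed at biophotonics /
tissue-optics researchers who want to (a) quantify minute refractive-index
changes from the rotation ("twist") of a Laguerre–Gaussian (LG) beam's petal
interference pattern, and (b) study how far the beam's helical phase
survives multiple scattering in turbid, tissue-like media.

## The science in brief

An LG mode of topological charge ℓ carries the helical phase exp(−iℓφ).
Interfered on-axis with a plane reference it produces |ℓ| petals; a phase
retardation ΔΨ = 2πnΔL/λ acquired in a probed medium rotates the petals by

    Θ = ΔΨ / ℓ ,

so a refractive-index change Δn over a d = 3.6 mm cell rotates the pattern
by 2πΔn·d/(λℓ) — about 0.4° for Δn = 10⁻⁶ at ℓ = 5 and λ = 640 nm, which is
resolvable by the petal-centroid tracker. Photon trajectories of the mode
are spirals r(ζ) = r₀√(1+4ζ²), φ(ζ) = ℓ/(2r₀²)·arctan(2ζ) + φ₀; their
lengths (plus Snell refraction at cuvette walls) set ΔL per trajectory.

In a turbid slab of optical depth d/l* (transport mean free path
l* = 1/(μs(1−g))), the beam speckles. A scalar Monte Carlo with
Henyey–Greenstein scattering and semi-analytic detection produces the
speckle field; a *memory index* — the per-pixel regression slope of the
speckle phase against an applied SLM phase offset δ ∈ [−3π/10, 3π/10] —
quantifies how much of the injected phase survives. At d/l* ≈ 2 the memory
is high everywhere; at d/l* ≈ 9.6 it persists only within the beam's
annular footprint. See `vignettes/oam-twist-methods.Rmd` for the model,
its assumptions, and its deliberate simplifications.

## Worked example

```r
library(oamtwist)

bp <- beam_params(wavelength = 640e-9, waist_w0 = 0.45e-3, ell = 5)
bp
#> LG beam: lambda = 640 nm, w0 = 0.45 mm, ell = 5, p = 0
#>   k = 9.81748e+06 rad/m, zR = 0.99402 m, ring radius w0*sqrt(|ell|/2) = 0.7115 mm

# A: refractive-index sensing on a synthetic thermal run
# (7.8 -> 21 degC, total |delta n| = 3.69e-4 across a 3.6 mm cuvette interior)
rep <- run_sensing(sensing_config(ell = 5, n_frames = 32L, n_traj = 8000L, seed = 1))
rep
#> sensing run: 32 frames, twist span 149.46 deg
#>   estimated total delta_n: -0.000369  (true -0.000369, max |error| 1.91e-07)
#>   sensitivity: 2.47e-06 delta_n per degree of twist

# B: phase memory through the multiple-scattering phantom
# (d = 8 mm, mu_s = 6 mm^-1, g = 0.8 -> d/l* = 9.6)
mem <- run_memory(memory_config(source = "mc", d_mm = 8, mus_per_mm = 6,
                                g = 0.8, n_ph = 2e5, seed = 1))
mem
#> phase-memory run: d/l* = 9.6 (intermediate/near-diffuse)
#> memory map over 7 offsets; overall median slope 0.055
#>   inside annulus: 0.664 (n=1186)   outside: 0.041 (n=11117)
```

Reading the numbers: the 25-min thermal run twists the ℓ = 5 petal pattern
by ~149°; inverting the trajectory-model forward map recovers the
programmed refractive-index ramp to ~2×10⁻⁷, and the sensitivity
(≈2.5×10⁻⁶ per degree) supports the 10⁻⁶-level resolvability claim. In the
memory run, the median phase-memory slope is 0.66 inside the annular zone
versus 0.04 outside — the injected SLM phase stays legible only in the
beam's annular footprint at this optical depth.

## Command line

A thin CLI wraps the same pipelines:

```sh
ot=$(Rscript -e 'cat(system.file("exec", "oamtwist", package = "oamtwist"))')
Rscript "$ot" synth-thermal --out run.csv
Rscript "$ot" predict --dn-start 0 --dn-stop 2e-5 --steps 10 --ell 5 --out twist.csv
Rscript "$ot" run-sensing --out sensing.json --seed 1
Rscript "$ot" run-memory  --out memory.json --source mc --d-mm 8 --mus 6 --nph 1e6
```

All tabular outputs are CSV with unit-annotated header comments; images are
ASCII PGM with JSON sidecars; every report embeds a manifest (config,
seeds, versions).

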