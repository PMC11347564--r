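---
title: "Methods: OAM twist refractometry and phase memory in turbid media"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OAM twist refractometry and phase memory in turbid media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(oamtwist)
```

## The physical picture

A Laguerre-Gaussian (LG) beam of topological charge $\ell$ carries orbital
angular momentum through its helical phase factor $e^{-i\ell\phi}$. Two
consequences of that structure drive everything in this package.

First, **twist refractometry**. Interfering the LG beam on-axis with a
(near-)plane reference produces a petal pattern with $|\ell|$ lobes, because
intensity maxima occur wherever $-\ell\phi + \Psi$ matches the reference
phase. Any extra retardation $\Delta\Psi$ picked up inside a probed medium
therefore *rotates* the petal pattern by $\Theta = \Delta\Psi/\ell$. Since
$\Delta\Psi = 2\pi n \Delta L/\lambda$ over a millimetre-scale cell is tens
of thousands of radians, a refractive-index change of $10^{-6}$ already
rotates the pattern by a fraction of a degree -- comfortably above the
centroid noise of the petal tracker. That is the sensing chain:
thermal drift $\to n(t)$ $\to$ petal rotation $\to$ inverted back to
$\hat{\Delta n}(t)$.

Second, **phase memory**. In a turbid slab the beam breaks up into speckle,
yet the phase injected at the spatial light modulator (SLM) can remain
legible in the speckle phase. The package quantifies this with a *memory
index*: the per-pixel regression slope of retrieved speckle phase against
the applied SLM offset $\delta$ (1 = perfect memory, 0 = none), summarized
inside and outside the beam's annular footprint.

## Forward models

### Beam and phase (`beam_optics`)

`lg_field()` samples the normalized paraxial LG mode, including the Gouy
term $(2p+|\ell|+1)\arctan(z/z_R)$, the spherical phase, $e^{-i\ell\phi}$
and $e^{-ikz}$. The associated Laguerre polynomial is evaluated by the
stable three-term recurrence, not factorial ratios, so radial orders up to a
few tens stay usable. `lg_phase()` is the closed-form phase; it agrees with
`Arg(lg_field())` modulo $2\pi$ wherever the polynomial is positive (always
for $p=0$; for $p>0$ the polynomial's sign changes add $\pi$ jumps that the
closed form does not carry -- the tests therefore pin the identity at
$p=0$). On-axis pixels get amplitude exactly 0 for $|\ell|>0$.

### Spiral trajectories and retardation (`trajectory_model`)

Photon trajectories of the LG mode follow spirals
$r(\zeta)=r_0\sqrt{1+4\zeta^2}$,
$\varphi(\zeta)=\ell/(2r_0^2)\,\arctan(2\zeta)+\varphi_0$ in the
dimensionless coordinates $r=\rho/w_0$, $\zeta = z/(k w_0^2)$. The literal
arc-length integrand is transverse-only; the package's default adds $+1$
under the radical so that $\Delta L$ is a 3-D geometric path and the
retardation $\Delta\Psi = 2\pi n \Delta L/\lambda$ reduces to the ordinary
$2\pi n d/\lambda$ for an axial ray. The literal transverse-only integrand
is kept behind `include_longitudinal = FALSE` for fidelity tests.
Refraction at cuvette walls uses the analytic spiral tangent at the
interface (not a finite difference) and Snell's law; at paraxial
inclinations this lengthens $\Delta L$ by parts in $10^{7}$, which is
retained for completeness.

`predict_twist_series()` samples trajectory starts from the analytic
$|LG|^2$ profile (inverse-CDF in radius: $\rho^2$ is Gamma-distributed for
$p=0$; uniform azimuth), accumulates $\Delta\Psi_i$ per refractive-index
step, renders the petal pattern from the azimuthally binned ensemble phase,
and measures its rotation **with the same petal algorithm used on data** --
model and measurement share one definition of "twist". One consequence
worth stating plainly: the petal rotation is $\Theta = \Psi/\ell$, so for a
common geometry the *rotations* of $\ell=3$ and $\ell=5$ beams differ by
exactly $5/3$ while the underlying phase twist $\Psi = \ell\Theta$ is the
$\ell$-invariant quantity; `predict_twist_series()` reports both, and the
cross-charge consistency test compares $\ell\Theta$.

### Monte Carlo transport (`scatter_transport`)

Turbid layers are simulated with a scalar photon-packet Monte Carlo:
exponential free paths at $\mu_t=\mu_s+\mu_a$, weight $\times\,
\mu_s/\mu_t$ per event, Henyey-Greenstein deflections (the single-parameter
tissue-optics default matching $g=\langle\cos\theta\rangle$), Snell
refraction at interfaces, Russian roulette below $10^{-4}$ with survival
boost 10, and a $10^4$ event cap. Detection is semi-analytic: every
scattering vertex contributes directly to the detector with weight
$p_{HG}(\theta_{det})\,d\Omega\,e^{-\tau_{exit}}$, carrying the coherent
phase $k\times$(optical path) plus the launch phase $-\ell\varphi_0$. The
camera is modelled as imaging the slab's back face (the reported setup uses
a 10x objective), so contributions land at their exit-face position under a
numerical-aperture cutoff. Two variance-reduction devices keep the speckle
statistics honest at desk scale ($N_{ph}=10^6$ rather than the full-scale
$10^9$): the detector pixel is importance-sampled $\propto 1/(r^2+b^2)$
around each vertex to tame the local estimator's $1/s^2$ singularity, and
vertices within a few optical depths of the exit face are split into
several sub-samples. With both, the off-annulus amplitude passes a
Rayleigh goodness-of-fit at $10^6$ packets.

### The decoherence model (a deliberate reduction)

The cited full machinery for coherent vector transport (Bethe-Salpeter /
Milne, Jones formalism) is intentionally out of scope; the package declares
a scalar reduction. In any purely coherent scalar model, a global SLM
piston $\delta$ shifts *every* detected phase by $\delta$, so the memory
index would be 1 everywhere and the annular contrast could not exist. The
experimentally observed contrast therefore has to enter through a
decoherence channel. Two candidates were considered:

* **Pathlength-based (depolarization-law) weights.** The reference degree of
  polarization $P = (2L/l_s)\sinh(l_s/\xi_L)\exp(-L/\xi_L)$ with
  $\xi_L=l_s/\sqrt{3\ln(10/7)}$ decays on the scale of the elastic mean
  free path ($\approx 0.17$ mm for the multiple-scattering phantom). All
  transmitted light at $d/l^*=9.6$ has path excess of tens of millimetres,
  so these weights extinguish the coherent component *everywhere*,
  including the annulus -- they cannot reproduce the reported annular
  memory, which by the eigenchannel argument rests on mesoscopic
  (transmission-eigenchannel) correlations that an independent-photon model
  does not contain. $P(L)$ is still evaluated verbatim (with a clipped
  variant, since the closed form tends to 0 at $L=0$ and exceeds 1
  nowhere relevant) and carried on the output as a diagnostic map.

* **Transverse-deviation weights (adopted).** The discussion attributes the
  memory to rotational symmetry: trajectory deviations of similar magnitude
  and direction around the axis leave the helical phase legible. The
  package reduces this to a per-contribution coherent weight
  $C=\exp(-|\Delta\rho|^2/2\sigma_c^2)$, where $\Delta\rho$ is the
  transverse deviation of the exit-face arrival point from the launch
  trajectory's unscattered exit point, and $\sigma_c$ defaults to the
  beam's doughnut diameter $2w_0\sqrt{|\ell|/2}$ -- the scale beyond which
  a deviation can no longer be "similar" to its neighbours around the
  axis. The decohered remainder $\sqrt{1-C^2}$ enters with a frozen,
  $\delta$-independent random phase.

The adopted model reproduces the reported phenomenology from the transport
dynamics alone: at $d/l^*\approx 2$ the transverse spread is small against
$\sigma_c$, so the memory index is high wherever there is light; at
$d/l^*\approx 9.6$ diffuse azimuth mixing scrambles everything except the
contributions that return close to their launch point -- which, by
construction of the launch distribution, lie on the annulus. A smaller
$\sigma_c$ (e.g. the ring half-width) was tried first and wrongly
decohered the weakly scattered halo at $d/l^*=2$; that iteration is
recorded in the project ledger. Because $\delta$ enters only as a piston on
the coherent component, one MC pass yields the field for every offset via
$E(\delta)=E_{coh}e^{i\delta}+E_{frozen}$, which is what keeps the
three-seed acceptance run inside its time budget.

What a green memory test establishes: that the *pipeline* (transport,
speckle formation, retrieval, circular regression, annular masking)
recovers the contrast that the model injects through a mechanism chosen to
mirror the claimed physics. It does not establish the mesoscopic
correlation physics itself -- no independent-photon simulation can.

### Interferograms and camera (`interferogram_synth`)

`interfere()` renders $|E_s+E_r|^2$ against a plane or expanded-Gaussian
reference (Gaussian waist at least 5x the doughnut radius, so it stands in
for the plane wave), with auto-exposure to 60% of full scale, optional
seeded Poisson shot noise (off by default so oracle tests stay exact),
16-bit quantization and a saturation warning above 1% of pixels. The
off-axis carrier defaults to 1/4 of Nyquist so the sideband crop described
below is separable.

## Measurement algorithms

### Petal twist (`twist_analysis`)

Per frame: Otsu threshold over the full histogram (foreground is
`value >= threshold`; manual override honoured), 8-connected labelling,
Moore-Neighbor boundary tracing with Jacob's stopping criterion (stop when
the start pixel is re-entered in a previously seen state -- robust on
one-pixel-wide appendages), retention of the $|\ell|$ largest components,
and centroids of the *filled* components (not just boundary pixels, to
reduce pixelation bias) in polar coordinates about the beam centre (default:
intensity centroid of the time-averaged stack). Frame-to-frame rotation is
the circular mean of per-petal angle differences after minimal
circular-distance assignment, unwrapped across the $0/2\pi$ seam and
accumulated; a twist step of $\pi/|\ell|$ between frames is the aliasing
bound and triggers a warning. Frames with missing petals or count changes
are flagged and interpolated with a gap marker. Both the per-petal series
and the averaged series are kept; either convention is found in practice.

### Off-axis retrieval and memory mapping (`phase_retrieval`)

`retrieve_phase()` takes the 2-D FFT, auto-locates the sideband as the
strongest peak outside a DC exclusion disk restricted to the $f_x<0$
half-plane (the two sidebands of a real interferogram are exact conjugates;
with the package's carrier convention the chosen one returns
$+\arg E_s$), refines the centre to the windowed $|F|^2$ centroid (the LG
sideband is itself ring-shaped, so the raw peak sits off-carrier), crops a
square of side equal to the carrier distance, apodizes the outer 40% of
the crop with a raised cosine, recentres and inverse-transforms. A carrier
closer to DC than twice the exclusion radius raises "carrier too low".

`memory_map()` forms phase differences against the $\delta\approx 0$ frame
on the unit circle, unwraps them along the offset ordering (steps are below
$\pi$ by construction), and fits per-pixel least squares against $\delta$.
Summaries (median slope, IQR) are reported inside and outside the annular
mask, excluding pixels with $r^2$ below 0.2 and pixels darker than 5% of
the mean reference intensity -- phase is only measurable where there is
light; both floors are configurable and excluded pixels stay in the map.

## Synthetic data: the stated world

* **Thermal run**: 25 min at 10 fps (15 000 frames), exponential
  relaxation from 7.8 to 21 deg C. The relaxation time constant is not
  reported; 480 s is used -- a typical value for a few-millilitre cuvette
  equilibrating in air, and it leaves the run >95% complete at 25 min. The
  ethanol-water $n(T)$ tables are deliberately replaced by a linear
  coefficient chosen so the run's total $|\Delta n|$ is exactly the
  reported $3.69\times 10^{-4}$; the sign is negative ($dn/dT<0$ for the
  liquid), and the sensing chain treats the sign symmetrically.
* **Twist stacks** default to 64 frames at 256x256 rather than 15 000
  full-resolution frames, keeping the suite fast; the generator accepts the
  full-scale sizes. Grid pitch puts the doughnut diameter at one third of
  the frame, mimicking the reported detector-plane framing (2.7/3 mm waist
  diameters).
* **Speckle stacks** compose, per region, a memory fraction $m$ of the
  LG field carrying the SLM piston with $\sqrt{1-m^2}$ of a frozen
  band-limited complex-Gaussian speckle (grain set by a Fourier low-pass),
  on an envelope with a 35%-of-peak diffuse halo so the no-memory regions
  still carry light. `grain_px = 1` gives i.i.d. pixels and exact Rayleigh
  amplitudes for the statistics tests.

What the generators do *not* emulate: detector nonlinearity and drift,
interferometer vibration, aberrations of the objective, and any
polarization degree of freedom.

## Numerical choices

* Quadrature: `stats::integrate` at relative tolerance $10^{-10}$ for arc
  lengths; FFTs via `stats::fft`.
* The petal tracker's accuracy on clean 256x256 frames is about 0.03 deg
  RMS, an order below the 0.2 deg acceptance bound; shot noise at default
  camera settings roughly doubles it.
* Inversion $\Theta \to \Delta n$ uses a monotone forward map probed on a
  9-point grid and linear bracketing; a degenerate (near-zero) ramp widens
  the probe span to $2\times10^{-5}$, the range over which the response is
  characterized, so the inversion stays well-posed.
* Monte Carlo desk scale is $N_{ph}=10^6$ (the full-scale $10^9$ is
  configuration only); acceptance properties are formulated to be stable
  there, with three seeds.
* The regime label follows the $d/l^*\gtrsim 10$ guideline; because the
  source itself calls 9.6 "multiple scattering" while printing the
  guideline, the band $6\le d/l^*<10$ is labelled
  "intermediate/near-diffuse" by default and a configuration override is
  honoured.

## Known limitations

* Scalar fields throughout: no Stokes/Jones polarization transport, no
  coherent backscattering, no time resolution.
* The decoherence weight is a phenomenological reduction (see above); the
  memory index magnitudes are model properties, only the qualitative
  contrasts are claimed.
* Gradient-index media are unsupported (piecewise-constant layers only).
* `lg_phase` vs `arg(lg_field)` identity holds for $p=0$; higher radial
  orders add sign-change jumps.
* No 2-D phase unwrapping; all phase comparisons are circular.
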