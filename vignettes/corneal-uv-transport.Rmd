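---
title: "Monte Carlo tissue optics of the cornea in the far UV-C band"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo tissue optics of the cornea in the far UV-C band}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Far UV-C sources (222 nm Kr-Cl excimer lamps, 233 nm LEDs) are attractive
for disinfection in occupied spaces because short-wavelength UV is absorbed
within a few tens of micrometres of tissue. Whether they are safe for the
eye hinges on how deep that radiation actually penetrates the cornea: if
the fluence that reaches the epithelium's germinative basal cells — or the
anterior stroma — is a substantial fraction of the surface fluence, DNA
photoproducts (CPDs) form there. `corneauv` provides the computational
chain needed to answer that question from integrating-sphere measurements
of thin corneal sections:

1. **Forward Monte Carlo photon transport** through a stack of planar
   turbid layers (tear film / epithelium / semi-infinite stroma), giving
   reflectance, transmittance, absorption and a depth-resolved fluence
   profile per wavelength.
2. **Inverse Monte Carlo (iMCS)** estimation of the absorption
   coefficient $\mu_a(\lambda)$ and reduced scattering coefficient
   $\mu_s'(\lambda)$ of a 40 µm tissue section from its measured total
   reflectance and transmittance $(R_{tM}, T_{tM})$.
3. **Penetration analytics**: the depth $z_{10}$ where the relative
   intensity falls to 10%, the $1/e$ depth, relative intensity at layer
   interfaces, and damage-depth intervals under a fluence-threshold
   hypothesis for CPD induction.
4. A **synthetic-data generator** that emulates the spectral structure of
   corneal tissue so the whole chain is testable without laboratory data.

## Transport model

Photon packets are launched at normal incidence onto the stack ($z = 0$ at
the tear surface, $z$ increasing downward; layers are laterally infinite,
so a pencil beam with laterally integrated tallies is equivalent to a broad
collimated beam). The walk is the standard hop–drop–spin scheme for
multi-layered media:

* step lengths $s = -\ln u/\mu_t$ with $\mu_t = \mu_a + \mu_s$;
* at each interaction a fraction $\mu_a/\mu_t$ of the packet weight is
  deposited and the direction is deflected by a Henyey–Greenstein cosine
  with anisotropy $g$ (closed-form inverse CDF; $g = 0$ isotropic);
* unpolarized Fresnel draws at refractive-index mismatches, with total
  internal reflection beyond the critical angle;
* Russian roulette below weight $10^{-4}$ with survival probability 0.1
  (weight divided by 0.1 on survival), which terminates packets without
  biasing the expected energy balance.

The anisotropy of corneal tissue in the far UV is not identifiable from
total R/T of a thin section, so the package operates on the *reduced*
scattering coefficient under the similarity relation by default
($\mu_s = \mu_s'$, $g = 0$); an explicit-$g$ mode exists, and a property
test verifies that $(\mu_s, g)$ and $(\mu_s', 0)$ give R/T within 5% at
albedo $\mu_s'/\mu_a \ge 10$ in the thin-section geometry, provided the
section spans a few reduced mean free paths ($\mu_s' d \gtrsim 3$) — below
that the transport is too ballistic for the similarity approximation and
the discrepancy grows to ~5–8%.

**Fluence estimator.** The depth-binned fluence per unit incident power is
tallied with a weighted track-length estimator: every path segment adds
(weight × length within the bin)/(bin volume). Its expectation equals the
usual deposited-energy estimator divided by $\mu_a$ — the expected deposit
per unit path is $w\,\mu_a$ — but it remains defined in non-absorbing
layers (the tear film is modelled as a pure absorber, but a lossless test
slab is not), and it has lower variance. For a semi-infinite pure absorber
the tallied profile reproduces $e^{-\mu_a z}$ exactly in expectation.

**Boundary modes.** `fresnel` applies the usual escape/internal-reflection
draw at the top surface and is the default for the inversion geometry (a
bare section in air, as mounted in an integrating sphere with the specular
port closed — measured $R_{tM}$ is treated as total reflectance).
`mirror_top` deterministically reflects upward-escaping photons back into
the tissue at the top surface and is the default for the cornea
penetration geometry. A mirror boundary can equally be read as a
top-surface specular return or as a substrate mirror; both readings give
the same operator for a normally illuminated laterally infinite stack, and
the package makes the mode an explicit switch rather than asserting either
reading as canonical.

**Numerical choices.** Depth grid $dz = 1$ µm to $z_{\max} = 0.6$ mm,
half-open bins starting at the tear surface; wavelength grid 200–300 nm in
5 nm bins (the spectral bandwidth of a scanning spectrophotometer with an
integrating sphere), with properties piecewise-linear in $\lambda$;
coefficients in mm$^{-1}$, thicknesses in mm. Runs are bit-reproducible:
the RNG is R's own generator seeded per run, per-wavelength substreams are
derived deterministically from the master seed, and `sim_config()` makes
the seed mandatory rather than defaulting silently.

## The inverse model

`imc_fit()` is the package's central estimator and follows the classic R
modelling idiom: it takes a data frame of observations (wavelength, total
reflectance, total transmittance, geometry), returns a classed object, and
supports `coef()`, `predict()`, `fitted()`, `residuals()`, `summary()` and
`plot()`. Each observation is inverted by minimising the RMS misfit

$$ r(\mu_a, \mu_s') = \sqrt{(R_{pred}-R_{tM})^2 + (T_{pred}-T_{tM})^2} $$

with the forward model evaluated under *common random numbers* (every
evaluation reuses the same seed), making the map
$(\mu_a,\mu_s') \mapsto (R,T)$ deterministic. The search exploits the
problem's structure: $T$ is strictly decreasing in $\mu_a$ at fixed
$\mu_s'$, so a bisection solves the transmittance equation for
$\log \mu_a$; total reflectance (with $\mu_a$ slaved to the measured $T$)
increases with scattering, so an outer bisection brackets $\log \mu_s'$.
A zooming 5×5 log-grid then polishes both parameters at the full photon
budget. A grid was chosen over a Nelder–Mead simplex deliberately: the
common-random-number objective retains piecewise jitter at the $10^{-3}$
level (trajectories decorrelate as parameters move), and in testing a
simplex stalled in that jitter at low-albedo corners of the parameter
space while the zooming grid did not.

A fit is declared converged when the residual falls below
`tol_rt = 5e-3`, roughly twice the Monte Carlo noise floor of the forward
model at the default $5\times10^4$ photons. Solutions within a factor 3 of
a search bound are flagged `at_bound` (a lossless slab legitimately pins
both coefficients at the lower bound). Spectra are inverted bin-by-bin in
wavelength order with warm starts from the previous bin; replicate
sections are inverted independently and pooled *after* inversion as mean ±
SEM per wavelength — pooling before inversion would average a nonlinear
map's inputs rather than its outputs.

## Cornea models

`build_cornea()` assembles the three standard geometries — porcine
(110 µm epithelium), human with thin/non-intact epithelium (26 µm), and
intact human (50 µm) — each under a 5 µm tear film and above a
semi-infinite stroma. The human models are intended to be driven with
porcine layer spectra, mirroring how intact-cornea predictions are made
when only porcine sections can be measured. The tear film is a pure
absorber (its $\mu_a$ derived from a cuvette absorbance via
$\mu_a = \ln 10 \cdot A/\ell$); all layers share one refractive-index
table by default, so inter-layer Fresnel events vanish and only the
air/tear interface reflects. The shipped tear absorbance and $n(\lambda)$
tables are *synthetic* stand-ins with the documented qualitative shape
(strong rise below 240 nm; water-like normal dispersion offset to the
corneal index, linearly extrapolated beyond 250 nm); both are replaceable
CSVs and carry `synthetic` in their filenames.

## Penetration metrics and damage prediction

"Intensity" is implemented as the fluence profile normalised to its first
recorded bin at the surface. (Incident-normalised and flux-based
conventions are computable from the same `transport_result`; the
surface-normalised fluence is the default because the biological
comparisons are ratios to the surface dose.) `depth_at_fraction()` finds
the first downward crossing of a threshold with linear interpolation
between bin centres — first-crossing semantics guard against
non-monotone profiles near backscattering boundaries — and returns
`Inf` when the threshold is never reached within the recorded depth.
`predict_damage_depth()` maps the working hypothesis that 30–40% of the
surface intensity is needed to induce CPD-type DNA damage onto the
profile, returning the interval
$[z(\tau{=}0.4),\, z(\tau{=}0.3)]$ with the tissue layer each edge falls
in; for a homogeneous absorber this reduces to $[-\ln 0.4, -\ln 0.3]/\mu_a$,
which the tests verify to within one depth bin.
`compare_to_observed()` is purely descriptive: it tabulates predicted
intervals against immunohistologically measured CPD depths
(27 ± 4, 53 ± 8, 166 ± 25, 28 ± 5, 71 ± 2 µm across models and sources,
shipped as a fixture) and flags interval overlap, with no statistics.

## What the synthetic generator emulates — and what it cannot show

Ground-truth spectra are a plateau over 240–300 nm plus a logistic rise
below 240 nm,

$$ \mu(\lambda) = \mu_{base} + A \cdot \mathrm{logistic}\!\big((\lambda_0-\lambda)\,k\big), \qquad \lambda_0 = 240\ \mathrm{nm},\ k = 0.15\ \mathrm{nm}^{-1}, $$

which reproduces the qualitative structure of measured corneal
coefficients in this band: roughly flat above 240 nm, steeply rising
below, reduced scattering above absorption throughout, and (in the
default parameterisation) the stroma exceeding the epithelium below
240 nm. The default magnitudes (epithelium: $\mu_a$ 2 → 10,
$\mu_s'$ 12 → 18 mm$^{-1}$; stroma: $\mu_a$ 3 → 21, $\mu_s'$ 16 → 28)
were chosen once so that the 40 µm section's optical depth
$\mu_t d$ spans ~0.1–3, the regime where R/T of a thin slab is sensitive
to both parameters and the inversion is well-posed; they are calibration
choices, not measured tissue values, and no numeric claim about real
corneal coefficients is made anywhere in the package. Measurement noise
defaults to additive Gaussian $\sigma = 0.005$ on both fractions (typical
integrating-sphere repeatability), clipped to the physical simplex
$R, T \ge 0$, $R + T \le 1$ with clips counted.

Passing roundtrip tests on these synthetic data demonstrates that the
estimator is consistent and well-conditioned *under the generator's
assumptions* — smooth spectra, additive Gaussian noise, exact geometry,
a bare slab in air. Real sections add effects the generator deliberately
omits: mounting media and substrate reflections, lateral light loss at
the sphere port, section-thickness variability, chromatic stray light,
and tissue heterogeneity. Recovery percentages reported by the tests
therefore bound the *algorithmic* error, not the experimental one.

## Two attenuation scenarios and the thickness ordering

A structural point the package surfaces explicitly
(`synth_scenario_spectra()`): which layer dominates far UV-C attenuation
determines how penetration depth ranks across epithelial thicknesses.
Under one-dimensional transport, if the stroma's coefficients exceed the
epithelium's below 240 nm (`"stroma_dominant"`, the default generator
ordering, which matches what measured thin sections of the two tissues
show), then replacing epithelium by stroma *earlier* — a thinner
epithelium — can only steepen the attenuation, and $z_{10}$ *decreases*
as the epithelium thins. The frequently described whole-cornea behaviour
— deeper penetration through a thinner, non-intact epithelium, with the
intact human cornea between the thin-epithelium human cornea and the
thick-epithelium porcine cornea — requires the opposite composition: an
epithelium that attenuates faster than the stroma at 222/233 nm
(`"epithelium_dominant"`), consistent with the epithelium's high UV-C
absorption by ascorbate and aromatic proteins. Both scenarios are
first-class generator outputs; the acceptance checks assert the
wavelength ordering $z_{10}(254) > z_{10}(233) > z_{10}(222)$ under
decreasing attenuation, and the thickness ordering
$z_{10}(26\,\mu m) > z_{10}(50\,\mu m) > z_{10}(110\,\mu m)$ under the
epithelium-dominant scenario with identical layer spectra across the
three geometries. The package asserts orderings and mechanics only —
never absolute depth values for real corneas, whose measured inputs are
not publicly available.

## Problem sizes and reproducibility

Default photon budgets are $10^5$ packets for reported forward runs and
$5\times10^4$ per forward evaluation inside the inversion (with a 5×
cheaper budget during bracketing); the test-suite and the acceptance
script scale some sweeps down to $2{-}5\times10^4$ packets and the
plumbing checks further, sizes at which every asserted tolerance still
holds with a comfortable margin. The worked pipeline
(`run_pipeline()`) derives every stage seed from one master seed and
writes byte-identical data files on reruns; the run manifest records the
configuration hash, seeds, versions and input digests.

## Known limitations

* One-dimensional planar geometry: no corneal curvature, no lateral beam
  structure, no eyelid/limbus geometry.
* No polarization, fluorescence, or time-resolved transport.
* $g$ is unidentifiable from total R/T; everything is reported as
  $\mu_s'$. If angularly resolved data were available, explicit-$g$ fits
  would become meaningful.
* The Bowman and Descemet membranes and the endothelium are not separate
  optical layers; the model stops at a semi-infinite stroma.
* The damage-depth prediction is a deterministic threshold mapping; it
  inherits the 30–40% hypothesis rather than modelling dose–response.
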