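---
title: "Modelling light emission from inelastic electron tunnelling in a metasurface biosensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling light emission from inelastic electron tunnelling in a metasurface biosensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lietsim)
```

## The device and the model

`lietsim` models a self-illuminating refractometric sensor: a vertical
metal–insulator–metal tunnel junction whose top contact is a periodic array
of gold nanowire antennas. The stack, top to bottom, is

    [analyte film] | Au wires (50 nm, width 92 or 120 nm, period 400 nm)
                   | Cr adhesion (5 nm, patterned with the wires)
                   | Al2O3 tunnelling barrier (5 nm)
                   | Al bottom electrode (25 nm) | glass

Under a positive bias $V_b$ on the Au mesh, electrons tunnel inelastically
from Al into Cr and can emit a photon of energy $\hbar\omega \le eV_b$.
The emitted spectrum factorizes into an electronic and a photonic part,

$$ I(\omega, V_b) \propto H(\omega, V_b) \times G(\omega), $$

and the two factors are computed independently.

**Electronic factor.** $H$ is the phase-space weight for an inelastic
transition: a joint density of initial states in Al (occupied) and final
states in Cr (empty) whose energies differ by $eV_b - \hbar\omega$,

$$ H(\omega,V_b) = \int \rho^{\mathrm{Al}}(E)\, f^{\mathrm{Al}}(E)\,
   \rho^{\mathrm{Cr}}(E')\, [1 - f^{\mathrm{Cr}}(E')]\, dE,
   \qquad E' = E + eV_b - \hbar\omega, $$

with Fermi–Dirac occupations at $T = 300\,$K and each metal's energy axis
referenced to its own chemical potential. The energy-conservation delta of
the underlying double integral has been integrated out analytically; the
test suite checks the result against a brute-force two-dimensional
integral with an explicit narrow-Gaussian delta to 0.5%. The default
density of states is free-electron-like, $\rho(E)\propto\sqrt{E -
E_\text{bottom}}$, with band bottoms 11.7 eV (Al) and 7.0 eV (Cr) below
the chemical potentials; tabulated $\rho(E)$ tables can be substituted.
$H$ vanishes beyond the quantum cut-off $\hbar\omega = eV_b$ (exactly at
$T\to 0$); at 300 K the edge is smeared by the double-Fermi kernel
$D/(1-e^{-D/k_BT})$, whose 10–90% derivative width is a universal
$\approx 6.2\,k_BT$ — the suite tests that closed form, not a nominal
bound. In-plane momentum conservation is *not* imposed: averaging over
the polycrystalline grain orientations leaves a DOS-only expression.
Tunnelling is modelled Al→Cr only; the Au above the thin Cr is neglected
in the electronic matrix elements.

**Photonic factor.** The inelastic transitions act as point dipoles inside
the Al2O3 gap under the wire, oriented along the surface normal, so they
radiate p-polarized light. The far-field amplitude of a dipole at $x_l$
towards direction $\theta$ is obtained by optical reciprocity: it equals
(up to one global constant) the $z$-component of the field induced at the
dipole position by a unit-amplitude p-polarized plane wave incident from
that direction. Dipoles at different $x$ are mutually incoherent; the
coherent sum along the wire axis collapses to a single term because the
structure is treated as invariant along $y$ (the real mesh's second period
is $\ge 100\,\mu$m, far beyond optical wavelengths). Hence

$$ \mathcal{G}(\omega, \theta) = \sum_l |g(\theta, x_l, \omega)|^2,
   \qquad
   G(\omega) = \int_0^{\theta_\max} \mathcal{G}(\omega,\theta)\,
   \sin\theta\, d\theta, \qquad \theta_\max = \arcsin(\mathrm{NA}). $$

The near fields come from a rigorous coupled-wave (RCWA / Fourier modal)
solver for the 1D lamellar grating in TM polarization, written for this
package: Li's correct factorization rules for the permittivity products, a
Redheffer star-product S-matrix chain that keeps only bounded
exponentials, and interior mode amplitudes for field extraction in the
gap. A planar transfer-matrix solver (TMM) provides the homogeneous-limit
oracle (agreement to $10^{-6}$) and the substrate for the package's
central cross-check: the reciprocity route against a direct
source-in-cavity dipole-radiation calculation, which agree to better than
1% (in practice, machine precision) on the planar stack.

### Collection geometry — a deliberate model decision

The collection cone is $\theta \le \arcsin(\mathrm{NA})$ with $\theta$
measured in the *superstrate (air) half-space* of the solver. Two facts
force this choice. First, the device's reference near-field anchor — the
lattice anomaly excited at 650 nm under p-polarized incidence at
$\theta = 36^\circ$ — is reproduced by this solver exactly at air-side
incidence angles ($36.0^\circ$ at 650 nm for the 92-nm device). Second,
$\arcsin(0.8) = 53^\circ$ matches the angular extent of the reference
angle-resolved maps. A substrate-side (glass) route is available via
`from = "substrate"`; it places the same modes at different angles and is
used for the leakage-radiation picture.

### What the solver reproduces, and what it does not

With the bundled optical constants the model yields, for the 92-nm device
at NA 0.8:

* a dispersive plasmonic lattice mode following the grating equation
  $\lambda = P\,(n_\text{spp} + \sin\theta)$ with $n_\text{spp} \approx
  1.03$, spanning roughly 550–730 nm inside the collection cone (in
  $k_0 = 2\pi/\lambda$ terms, 8.6–11.4 µm⁻¹);
* a short-wavelength emission peak of $H \times G$ at 2.3 V near **720 nm**
  (the reference value is ~650 nm; the 1D reduction weights the
  band edge $\lambda = P(n_\text{spp} + \mathrm{NA})$ rather than
  mid-band, because the anomaly strength grows with angle in this
  geometry);
* a dispersionless gap-plasmon Fabry–Pérot resonance (field maximum inside
  the Al2O3 layer) near **1220 nm** — angle-independent to a few nm, but
  red of the ~1000 nm reference. Its position scales with the gap-plasmon
  index, which is dominated by the barely-metallic Cr facing the gap
  ($\varepsilon_\mathrm{Cr}(1000\,\mathrm{nm}) \approx -3 + 36i$ in the
  bundled table); published Cr datasets disagree strongly, and the
  effective barrier may be thinner than the nominal 5 nm (the device's own
  current–voltage fit suggests 3.2 nm);
* a 45-nm $n = 1.49$ overlayer redshifts the lattice band into the
  collection cone and raises the short-wavelength peak by a factor
  ≈ 2.4 at 2.8 V (reference simulation: 2.13) — the refractometric
  sensing mechanism;
* for the 120-nm (sensing) device the lattice features strengthen but do
  **not** migrate to small angles as reported for the real doubly periodic
  mesh, so the NA 0.3 sensing spectrum of this reduced model is carried by
  the band at small angles (500–575 nm) plus the broad background rather
  than by a 650-nm peak. Band-integrated *differential* responses remain
  monotone in analyte thickness, which is what the sensing readout uses.

The acceptance suite encodes the peak-position discrepancies as honest
failures at their stated tolerances rather than retuning the model; the
numbers above are computed by `scripts/acceptance.R`, not asserted.

## Tunnelling current–voltage model

The barrier is characterized by the intermediate-voltage Simmons formula
for a symmetric mean barrier of height $\bar\varphi$ (eV) and width
$\Delta s$ (nm) with an effective electron mass $0.23\,m_e$:

$$ J(V) = \frac{e}{2\pi h \Delta s^2}
   \left[ \left(\bar\varphi - \tfrac{eV}{2}\right)
   e^{-a\sqrt{\bar\varphi - eV/2}}
   - \left(\bar\varphi + \tfrac{eV}{2}\right)
   e^{-a\sqrt{\bar\varphi + eV/2}} \right],
   \quad a = \frac{2\Delta s}{\hbar}\sqrt{2m}. $$

No image-force barrier rounding is applied. Beyond barrier collapse
($V > 2\bar\varphi/e$) the model switches to a Fowler–Nordheim
field-emission branch with a logged note. Fitting minimizes least squares
in $\ln J$ — the curve spans decades, and log residuals weight the
direct-tunnelling and field-emission regimes evenly — over bounded
parameters ($\bar\varphi \in [0.5, 5]$ eV, $\Delta s \in [1, 8]$ nm), with
a coarse grid search seeding L-BFGS-B so that remote initial guesses
converge. The fitting window default (0.1–2.4 V) is a documented
assumption; the reference work does not state one. The Fowler–Nordheim
representation $(1/V, \ln J/V^2)$ of the fitted forward model has an
interior minimum near 0.79 V; the model minimum is not constrained to
coincide with a measured bend (real junctions carry barrier
inhomogeneities the symmetric model cannot represent). $\ln J$ is concave
($\sim \ln V$) in the ohmic regime and convex only beyond about 1 V, which
is what the suite asserts.

## Sensing readout

* **Differential band signal**: trapezoid integrals of analyte and bare
  spectra over 620–700 nm, $(\!\int\!I_a - \int\!I_0)/\int\!I_0$.
* **Peak fold-change**: ratio of parabolically interpolated peak heights
  in a 550–750 nm window.
* **Limit of detection**: the smallest mass where the piecewise-linear
  interpolation of mean responses crosses $3\times$ the noise level; the
  noise level defaults to the standard deviation of bare-vs-bare replicate
  responses. Non-monotone means trigger an isotonic-regression fallback
  with a warning; crossings below the lowest dose are flagged as
  extrapolated.
* **Mass ↔ thickness**: thickness = mass / (density × area) with defaults
  1.42 g cm⁻³ (crystalline amino-acid scale) and 50 × 50 µm² collection
  area. These are configuration choices of this package, not
  literature-derived; 5–50 pg maps to 1.4–14 nm films.

## Synthetic measurements (the stated world)

Generators are deterministic given `(parameters, seed)` (R's
Mersenne–Twister; every output carries a manifest).

* **Spectra**: Poisson counting noise with a counts-per-unit scale,
  default 200 expected counts per spectral sample at the bare-spectrum
  peak — the count-rate scale of EMCCD emission spectra quantified in
  counts s⁻¹ nm⁻¹, and consistent with visibly noisy raw traces that
  become smooth after the bundled 2.5 nm moving-average convention
  (10 points on a 0.25 nm grid; the window widens to two grid steps on
  coarser simulation grids).
* **I–V curves**: multiplicative Gaussian noise on the Simmons forward
  model.
* **Emission images**: uniform base intensity, optional horizontal dark
  defect lines (the across-wire discontinuity phenomenology of 1D
  meshes), Poisson noise; uniformity is summarized by the coefficient of
  variation, a proxy metric of this package.
* **Dose series**: per mass, the full solver simulates the spectrum with
  a conformal analyte layer (grooves fill from the floor up to the film
  thickness; a planar cap of the same thickness sits on the wires),
  replicates draw independent noise, and the rows feed
  `limit_of_detection()` unchanged.

A green end-to-end sensing test establishes that the pipeline is
monotone, seeded, and self-consistent at a realistic noise floor; it does
not establish the absolute sensitivity of any physical device, which
depends on an experimental noise floor this package only emulates.

## Numerical choices

* Units: nm, eV, V, K; $\hbar\omega$[eV] $= 1239.84198/\lambda$[nm];
  fields use $e^{-i\omega t}$, so passive media have
  $\mathrm{Im}\,\varepsilon \ge 0$.
* Optical constants: tabulated literature-style n,k for Au, Cr, Al with
  log-linear interpolation, strictly no extrapolation; constant indices
  Al2O3 1.76, glass 1.52, PMMA 1.49, generic analyte 1.50 (configurable).
  Resonance positions inherit the (substantial) dataset uncertainty,
  especially for Cr.
* Energy integration for $H$: trapezoid with steps $\le k_BT/2$ (warning
  otherwise).
* RCWA: odd harmonic counts; default 41 for reported numbers (order
  efficiencies change by < 1% against N + 20); eigen-branch
  $\mathrm{Im}\,\gamma \ge 0$; per-layer absorption from Poynting-flux
  differences closes the energy balance to $10^{-6}$.
* Angular quadrature: Gauss–Legendre on $[0, \theta_\max]$; a node
  spacing coarser than 2° warns.
* Peak finding: parabolic interpolation through the three samples around
  a grid maximum; window maxima on a boundary are flagged, and
  `interior_peak()` restricts to genuine interior local maxima.
* Dipole grid: 15 positions across the wire footprint at the barrier
  mid-plane; halving either changes $G$ by well under the quadrature
  error.

## Known limitations

* 1D-periodic reduction: no crossed-wire (doubly periodic) effects, no
  azimuthal integration — $G$ uses the dispersion-plane cut. The
  wire-width-dependent angular migration of the lattice mode seen in real
  meshes is not captured.
* Electronic DOS is a free-electron fallback; only the qualitative shape
  of $H$ is meaningful.
* No absolute photon-count prediction (the product $H \times G$ carries
  arbitrary normalization; all reported comparisons are ratios or peak
  positions).
* No temperature-dependent optical constants, no nonlocal or quantum
  corrections to the metal response, no asymmetric-barrier (Brinkman)
  I–V model.
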