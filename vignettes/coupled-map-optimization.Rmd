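---
title: "Coordinated optimization of orientation and ocular-dominance maps: models, planforms, and numerical choices"
author: "vcmaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinated optimization of orientation and ocular-dominance maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcmaps)
```

## The model

Two order-parameter fields describe the functional architecture of primary
visual cortex on a two-dimensional sheet: a complex field $z(\mathbf{x})$
whose argument encodes the preferred stimulus orientation,
$\theta = \tfrac12\arg z \in [0,\pi)$, and whose modulus $|z|$ is the
orientation selectivity; and a real field $o(\mathbf{x})$ whose sign encodes
ocular dominance ($o>0$ contralateral, $o<0$ ipsilateral).  Zeros of $z$ are
pinwheels; their topological charge is the winding of $\theta$ around the
zero, a half-integer, with $\pm\tfrac12$ for simple zeros.

Each field in isolation relaxes under the gradient descent of a
Swift-Hohenberg energy,
$$\partial_t z = \big(r_z - (k_c^2 + \Delta)^2\big) z - |z|^2 z, \qquad
  \partial_t o = \big(r_o - (k_c^2 + \Delta)^2\big) o - o^3 + \gamma,$$
whose linear spectrum $\lambda(k) = r - (k_c^2-k^2)^2$ peaks on the critical
circle $k = k_c = 2\pi/\Lambda$: for $r>0$ a cellular pattern of wavelength
$\Lambda$ emerges.  The constant $\gamma$ biases ocular dominance toward the
contralateral eye.  Joint optimization adds an inter-map coupling energy
$U$; invariance under translations, rotations, orientation shifts
$z \to e^{i\phi}z$ and eye inversion $o \to -o$ leaves, at lowest order, two
positive-definite candidates,
$$U_{\text{prod}} = c\, o^2 |z|^2, \qquad
  U_{\text{grad}} = c\, |\nabla o \cdot \nabla z|^2,$$
plus their higher-order squares ($c\,o^4|z|^4$, $c\,|\nabla o\cdot\nabla
z|^4$), which the field-level machinery of this package also evaluates and
integrates.  The coupled dynamics is the gradient descent of the summed
energy; the interaction terms are the exact functional derivatives of $U$.

## Bias shift and the OD subsystem

A constant shift $o = \hat o + \delta$ with
$\delta^3 + (k_c^4 - r_o)\,\delta = \gamma$ (the unique real root when
$k_c^4 > r_o$) removes the constant drive and produces a quadratic
interaction: $\partial_t\hat o = (\tilde r - (k_c^2+\Delta)^2)\hat o +
\tilde\gamma \hat o^2 - \hat o^3$ with $\tilde r = r_o - 3\delta^2$ and
$\tilde\gamma = -3\delta$.  Near threshold three modes on the critical
circle with $\mathbf{q}_1+\mathbf{q}_2+\mathbf{q}_3=0$ (triad resonance)
dominate and obey
$$\dot B_1 = \tilde r B_1 + 2\tilde\gamma\,\overline{B_2 B_3}
  - 3\big(|B_1|^2 + 2|B_2|^2 + 2|B_3|^2\big) B_1$$
(cyclic in the indices).  The package evaluates this right-hand side by
exact projection of the nonlinearities onto the active modes, so the
equations are derived, not transcribed.  Stationary branches:

* stripes $B_{\text{st}} = \sqrt{\tilde r/3}$,
* hexagons $B_{\text{hex}} = \big(|\tilde\gamma| +
  \sqrt{\tilde\gamma^2 + 15\tilde r}\big)/15$ with phase sum $0$ or $\pi$
  (the potential minimum selects $\pi$ for $\tilde\gamma<0$, i.e.
  contralateral bias: ipsilateral blobs in a contralateral sea),
* the constant (monocular) state $\hat o = 0$, i.e. $o=\delta$.

Linear stability of the amplitude system gives closed-form borders in the
rescaled bias $\eta = 3|\delta|/\sqrt{r_o}$: hexagons become stable at
$\eta=\sqrt{3/17}$, stripes destabilize at $\sqrt{3/5}$, the constant state
stabilizes at $\sqrt{3}$, and hexagons disappear in a saddle-node at
$\sqrt{15}/2$.  These pure numbers are the vertical lines of the phase
diagrams; the package verifies them against numerically bracketed sign
changes of the Jacobian spectrum (translation zero modes are constructed
from the symmetry generators and projected out, rather than guessed from
eigenvalue magnitudes).  Contralateral area fractions are closed forms:
$\tfrac12 + \arcsin\!\big(\delta/2B_{\text{st}}\big)/\pi$ for stripes and,
for hexagons, one minus the area of the ipsilateral island approximated as
a disc whose radius is the first zero of the field along a symmetry axis
through the minimum.  The disc approximation is known to bias the result by
well under 1% except at the lowest biases of the stability band, which is
exactly what the pixel-count oracle shows.

## Coupled amplitude equations and the crystal planforms

In the unidirectional limit (OD amplitudes much larger than OP amplitudes)
the OD planform is fixed at its stationary branch and the six OP amplitudes
$A_j$, $A^-_j$ on the hexagonal star $\mathbf{k}_j$ (60 degrees apart,
$\mathbf{k}_1$ along $+x$) obey $\dot A = r_z A - P[|z|^2 z] + \text{(coupling)}$,
where $P$ projects onto the active modes.  Both low-order couplings are
linear in $z$, so for a fixed OD planform they contribute a constant
$6\times6$ matrix; the cubic term is a fixed resonance sum.  All
coefficients are produced by the same exact finite-mode convolution engine,
which guarantees that every resonant contribution of the hexagonal
configuration (including the $\delta$-dependent product-type terms) is
present.

With the OD hexagons written so their minimum sits at the origin, the
uniform (equal-modulus) stationary states come in two families:

* sin-type, $z \propto \sum_j e^{ij\psi} \sin(\mathbf{k}_j\cdot\mathbf{x})$
  with $\psi = \pm\pi/3$: a simple zero (charge $\pm\tfrac12$) at the OD
  minimum.  Under the product-type energy this is the stable crystal — the
  ipsi-center pinwheel crystal with amplitude
  $\hat A^2 = (3r_z - c\,r_o)/27$, six pinwheels per unit cell (two at OD
  maxima, one at the minimum, three at saddles) and six overrepresented
  orientations.  The two signs of $\psi$ are orientation-reversal partners
  ($z \to \bar z$) with identical spectra.
* cos-type, $z \propto \sum_j e^{ij\psi} \cos(\mathbf{k}_j\cdot\mathbf{x})$
  with $\psi = \pm 2\pi/3$: a double zero (charge $\pm1$) at the OD
  minimum.  Under the gradient-type energy this is the stable crystal — the
  Braitenberg pinwheel crystal with
  $\hat A^2 = \big(r_z - \tfrac32 c\,k_c^4 B_{\text{hex}}^2\big)/9$, three
  pinwheels per unit cell and three overrepresented orientations.  The
  package constructs the $\psi = +2\pi/3$ chirality, for which the central
  charge is $+1$.

Each energy also possesses the other family as its second, unstable uniform
branch (`hpwc_psi_b`): under the gradient energy the sin-type with
$\hat A^2 = (r_z - 2c\,k_c^4B_{\text{hex}}^2)/9$; under the product energy
the cos-type, whose linear coupling coefficient depends on the bias and is
extracted exactly from the engine rather than written as a formula.  Under
OD stripes the product energy deforms the stripe pair
($a^2 + a^{-2} = r_c$, $a a^- = cB_{\text{st}}^2$,
$r_c = r_z - c(\delta^2+2B_{\text{st}}^2)$) until the amplitudes collapse at
$c = r_z/(\delta^2+4B_{\text{st}}^2)$ into the orientation-scotoma state
$a = a^- = \sqrt{(r_z - c\,r_o/3)/3}$, which represents only two orthogonal
orientations and vanishes at $c = 3r_z/r_o$ — a border independent of the
bias because $\delta^2 + B_{\text{st}}^2 = r_o/3$ identically.  The same
$c = 3r_z/r_o$ is the product-type hPWC existence border.  Branches whose
phases depend on the coupling (stripe-like and rhombic states interacting
with OD hexagons) are followed by pseudoinverse-Newton continuation with
adaptive step halving and a step-jump guard that stops the continuation
instead of hopping onto a neighbouring branch near folds.

Stability is decided from the numerical Jacobian of the twelve-dimensional
real amplitude system (central differences, step $10^{-6}$), with the
orientation-shift generator — and, when the coupling vanishes, the
translation generators — projected out before the eigenvalue test
(tolerance $10^{-8}$).  Numerical Jacobians were chosen over transcribed
perturbation matrices deliberately: they are immune to transcription
hazards, and the bracketing tests against the closed-form borders validate
them.

## Parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `r_op`, `r_od` | distance from threshold | 0.1, 0.2 | near-threshold regime where the amplitude reduction is accurate yet patterns develop in reasonable time |
| `gamma` | OD bias (contralateral > 0) | via `od_gamma_from_eta` | specified through the dimensionless $\eta$; $\eta = 1.2$ is the representative mid-band hexagon value used in fixtures and tests |
| `kind`, `c_coupling` | coupling energy and constant | — | phase-diagram axes use the rescaled coupling: $c\,r_o/(3 r_z)$ (product; suppression border at 1) or $c\,k_c^4 B_{\text{hex}}^2/r_z$ (gradient; borders bias-independent) |
| `kc` | critical wavenumber | $2\pi$ | wavelength $\Lambda = 1$; all lengths in hypercolumn units |

## Grids and synthetic data

Fields live on a periodic rectangle $L_x = n_x^{\text{cells}}\Lambda$,
$L_y = n_y^{\text{cells}}\,2\Lambda/\sqrt3$, chosen so the hexagonal star is
commensurate: the oblique wavevectors have x-index $n_x^{\text{cells}}/2$,
so `make_grid` requires an even cell count in $x$ and rejects anything that
would put a triad mode off the Fourier lattice (this keeps the
synthesize-project round trip exact to $10^{-12}$ and makes per-unit-cell
counts exact rational numbers).  The domain covers
$n_x^{\text{cells}} n_y^{\text{cells}}$ primitive cells by area.  A square
variant (`make_grid_square`) exists for stripe configurations that need
orthogonal wavevector pairs, e.g. the ice-cube configuration of the
gradient energy with OD stripes.

The fixture generator synthesizes every named solution family from the
closed-form amplitudes at the caller's parameter point and refuses, naming
the violated border, outside the existence range.  What the synthetic
planforms deliberately do not emulate: spatial aperiodicity, finite
correlation lengths, detuned OP/OD wavelengths, measurement noise.  Passing
tests therefore certify the model's crystalline optima and the analysis
machinery, not the statistics of biological maps.

## Simulation

Time stepping is first-order exponential time differencing: the diagonal
linear operator is applied exactly in Fourier space, the nonlinear terms
explicitly, with a 2/3-rule spectral mask on the nonlinear products
(near-threshold fields live at $|k|\approx k_c$, far inside the mask; the
mask matters only for the quartic densities).  An energy watchdog evaluates
the decomposition $E_{\text{OP}} + E_{\text{OD}} + E_{\text{coupling}}$
every 20 steps and warns when it rises by more than the tolerance — the
dynamics is a gradient flow, so any sustained increase means the step is
too large.  Initial conditions are zero-mean white noise of RMS $10^{-3}$
with a caller-supplied seed; `relax_to_attractor` integrates in chunks
until the relative $L_2$ change per unit time falls below $10^{-7}$ by
default (tests use $10^{-6}$, which the near-threshold dynamics reaches in
a few thousand time units).

Problem sizes used by the tests: $48^2$–$96^2$ grids on 2x2-cell domains
for unit tests, $128^2$ on 4x4 cells for the full-field consistency and
phenomenology checks, with $r_z = 0.01$ for the amplitude-equation
comparison (attractor amplitudes match the stationary branch to about
$10^{-4}$ relative, far inside the 5% tolerance the tests allow).

## Map geometry

Pinwheels are located as plaquette windings of $\arg z$ with sub-pixel
positions from Newton on the bilinear interpolant; windings closer than
$\Lambda/20$ merge into one defect, which is how the charge-1 zero of the
Braitenberg crystal (winding 2 spread over adjacent plaquettes) is
recovered.  A candidate is accepted only if $|z|$ is bounded away from zero
on a small circle around it: planforms such as the orientation scotoma have
zero *lines*, which produce spurious plaquette windings but fail this
isolation test.  OD critical points reuse the same machinery on the complex
gradient field $\partial_x o + i\,\partial_y o$ (winding $+1$ extrema,
$-1$ saddles, Hessian classification, degenerate cases reported
separately); ridge lines of one-dimensional patterns are removed by the
same isolation test.  Intersection angles are sampled along the
marching-squares zero contour of $o$, but both tangents are taken from the
spectrally evaluated gradients ($\nabla\theta = \mathrm{Im}(\bar z\nabla
z)/2|z|^2$ and $\nabla o$), which is an order of magnitude more accurate
than polyline directions; each sample is weighted by $|\nabla\theta|$ times
the arc length, and angles are folded into $[0^\circ, 90^\circ]$.

A caveat worth stating plainly: on the exact crystal planforms the
pointwise intersection angle along a blob border is not identically
$90^\circ$ — it spans roughly $[82^\circ, 90^\circ]$, with the weighted
histogram mode pinned at the top bin and the weighted mean rising towards
$90^\circ$ with increasing bias.  The "perpendicular intersection"
property of these crystals is a statement about the concentration of the
weighted angle distribution at $90^\circ$, and that is what the tests
assert.

## Phase diagrams

The OD diagram is one-dimensional in $\eta$ and painted from the
closed-form borders, giving the sequence stripes / stripes+hexagons /
hexagons / hexagons+constant / constant with its two bistable transition
windows.  The coupled diagram sweeps (rescaled bias, rescaled coupling);
within the hexagon band the hPWC onset, stripe-like loss and rhombic
borders are located by bisection on the linear-stability verdict (to
$10^{-3}$ in the rescaled coupling by default) at each bias value — once
for all biases in the gradient case, where the rescaling removes the bias
dependence — and cells are labelled from the borders.  The default
resolution is 21x21 cells; border bisection, not cell count, carries the
scientific content, and a denser grid only smooths the painted regions.
Consistency with direct simulation is exercised on a reduced design (four
cells, one seed each, 64^2 grids) because each cell costs a full
relaxation; basin effects are tolerated exactly as in the painted regions.

## Degenerate inputs, tie-breaks, known limitations

* The bias-shift root is unique for $k_c^4 > r_o$; the constructor refuses
  otherwise.
* Uniform crystals are constructed for contralateral bias; ipsilateral
  bias follows by eye inversion, and the constructor says so rather than
  silently flipping conventions.
* Multistability is real and intentional: stripes and the rhombic crystal
  coexist already without coupling, and on small commensurate domains
  random noise reaches either basin.  Tests that depend on a particular
  attractor therefore either start inside the intended basin (the
  phenomenology protocol uses identical pinwheel-free initial conditions
  across bias values) or accept any closed-form attractor.
* The higher-order coupling energies are supported at field level only
  (energies, interaction terms, simulation); their amplitude-equation
  treatment is out of scope.
* The amplitude equations assume equal OP and OD wavelengths and the
  unidirectional limit; full bidirectional amplitude equations are not
  implemented.
* Quantities reported "per unit cell" rely on the commensurate domain; on
  incommensurate or experimental maps only the density per $\Lambda^2$ is
  meaningful.

## A worked example

```{r example, eval = FALSE}
gamma <- od_gamma_from_eta(1.2, 0.2)
p <- model_params(r_op = 0.1, r_od = 0.2, gamma = gamma,
                  kind = "product_low", c_coupling = 0.45 * 3 * 0.1 / 0.2)
g <- make_grid(96, 96, 2, 2)
fx <- fixture("hpwc_ipsi", g, p)
find_pinwheels(fx$op)
classify_pinwheel_positions(find_pinwheels(fx$op), fx$od)$counts
intersection_angles(fx$op, fx$od)
```
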