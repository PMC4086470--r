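---
title: "Modelling an incus-driving piezostack middle-ear actuator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling an incus-driving piezostack middle-ear actuator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ossidrive)
```

## The problem

A middle ear implant (MEI) compensates sensorineural hearing loss by
vibrating the ossicles mechanically instead of amplifying sound. One
attractive architecture anchors a multilayer piezoelectric stack actuator
("piezostack") in the mastoid and couples its tip to the incus body through
a short rod; the stack's expansion then drives the ossicular chain and,
through the stapes footplate, the cochlea. `ossidrive` models this
architecture end to end: the stack as a fully coupled electromechanical
finite element model, the middle ear as a lumped piston chain, the rod as
an axial bar, and the clinically relevant metrics on top.

## The coupled piezoelectric field problem

Each finite element node of the stack carries three displacement DOFs and
one electric potential DOF. In the stress-charge form with constitutive
matrices $c^E$ (stiffness at constant field), $e$ (piezoelectric stress
constants) and $\varepsilon^S$ (clamped permittivity), discretisation
yields the block equilibrium

$$
\begin{pmatrix} M_{uu} & 0 \\ 0 & 0 \end{pmatrix}
\begin{pmatrix} \ddot U \\ \ddot \Phi \end{pmatrix} +
\begin{pmatrix} C_{uu} & 0 \\ 0 & 0 \end{pmatrix}
\begin{pmatrix} \dot U \\ \dot \Phi \end{pmatrix} +
\begin{pmatrix} K_{uu} & K_{u\phi} \\ K_{u\phi}^T & K_{\phi\phi} \end{pmatrix}
\begin{pmatrix} U \\ \Phi \end{pmatrix} =
\begin{pmatrix} F \\ Q \end{pmatrix},
$$

with $K_{uu} = \int B_u^T c^E B_u\,dV$,
$K_{u\phi} = \int B_u^T e^T B_\phi\,dV$,
$K_{\phi\phi} = -\int B_\phi^T \varepsilon^S B_\phi\,dV$ and
$M_{uu} = \rho \int N_u^T N_u\,dV$. Storing the dielectric block with a
negative sign keeps the whole operator symmetric; the price is a symmetric
*indefinite* system, which the solvers factor by sparse LU with diagonal
equilibration (the mechanical and dielectric diagonals differ by roughly
eighteen decades).

Damping is stiffness-proportional, $C_{uu} = \beta K_{uu}$ with
$\beta = 10^{-4}\,$s and $\alpha = 0$, applied uniformly to the ceramic,
the rod and the middle-ear chain: the damping model provides no separate
piezoelectric loss channel, so one coefficient governs all structural
blocks.

### Element and mesh choices

The element is the 8-node trilinear hexahedron with full
$2 \times 2 \times 2$ Gauss quadrature — the simplest element that is
*exact* for the stack's dominant load cases. For a free stack under
uniform field the displacement field is linear in the coordinates, and for
the fully blocked stack it is zero; both are inside the trilinear space,
which is why the free-stroke and blocked-force tests pass at essentially
machine precision rather than merely within the 1 % oracle band. One
element through each layer's thickness is the default; refinement is
configurable per axis.

The multilayer electrical topology is the universal stack-actuator
convention: layers mechanically in series, electrically in parallel.
Interface electrodes alternate between the driven and grounded terminal
and the poling sign alternates between adjacent layers, so every layer
expands for the same terminal voltage and the terminal capacitance is the
sum of the layer capacitances. Internal electrodes are equipotential node
sets collapsed to master DOFs; electrode mass and stiffness, adhesive
layers and dielectric loss are neglected.

### The designed device

The modelled transducer is a PZT-4 prism, $2 \times 2$ mm cross-section,
2 mm total thickness, with $n = 50$ layers of 40 µm. Drive levels are RMS
phasor amplitudes; the safety ceiling of 10.5 V RMS is enforced as a
warning, not an error, so design sweeps may deliberately cross it. The
PZT-4 constants (stiffness 139, 77.8, 74.3, 115, 25.6, 30.6 GPa;
$e_{15} = 12.7$, $e_{31} = -5.2$, $e_{33} = 15.1$ C/m²; relative clamped
permittivities 370 and 635) are shipped both as `pzt4()` and as a YAML
block under `inst/extdata/`. The tabulated permittivities are interpreted
as *relative* clamped values multiplied by $\varepsilon_0$: their
magnitudes (370, 635) are three orders beyond any absolute permittivity in
F/m, so the dimensional reading is unambiguous even where a source table
header says otherwise. Voigt ordering is fixed once, package-wide, to
(11, 22, 33, 23, 13, 12).

```{r}
mat <- pzt4()
derive_strain_constants(mat)[3, 3]   # d33, C/N
```

The derived $d_{33} \approx 291$ pC/N matches the handbook value for
PZT-4, which is a useful end-to-end check on the transcribed constants.

## The middle-ear surrogate

Subject-specific middle-ear geometry (micro-CT based meshes of individual
temporal bones) is not publishable, and none of the downstream metrics
needs it: the stapes transfer function, the equivalent SPL and the rod
penalty only probe the port dynamics at the eardrum, the incus body and
the stapes. The surrogate is therefore a four-mass piston chain
(eardrum – malleus – incus – stapes) with

* springs $k = E A_c / L$ from the literature moduli of the connecting
  tissues (tympanic annulus ligament $4.0\times10^5$, pars tensa
  $1.0\times10^7$, incudomalleolar joint $1.41\times10^{10}$,
  incudostapedial joint $4.0\times10^6$, stapedial annulus ligament
  $4.1\times10^5$ N/m²) and *assumed* connector areas and lengths, all
  visible in `surrogate_config()`, never hard-coded;
* masses from tissue densities times assumed body volumes, chosen to land
  near the literature ossicle masses (malleus ≈ 25 mg, incus ≈ 28 mg,
  stapes ≈ 3 mg);
* a single cochlear damper (default 0.2 N·s/m, the order of magnitude of
  the cochlear input impedance referred to the footplate) on the stapes
  DOF — the cochlear load topology of subject-specific models is never
  published, so this is a free surrogate parameter;
* an effective eardrum piston area (default 32 mm²) converting drive
  pressure to force.

The connector defaults were chosen once so that the undamped primary
resonance falls in the typical middle-ear range of 500–1500 Hz (the
default chain resonates at about 830 Hz) and then frozen. Rotational DOFs
are omitted — the chain is a 1-D piston model, consistent with reporting
scalar stapes displacement magnitudes.

```{r}
net <- build_default_network()
natural_frequencies(net)
```

Structural damping is again $\alpha M + \beta K$; the cochlear damper is
stored separately (`C_structural` + `C_cochlea`), so the proportional-
damping identity remains assertable while the assembled damping matrix
carries the physical load.

What the surrogate does *not* emulate: eardrum modal behaviour, ossicle
rotation and lever ratios, cochlear fluid mechanics, and any specific
temporal bone's resonance pattern. Tests passing on the surrogate
demonstrate correct mechanics and correct metric plumbing, *not* agreement
with any individual's middle-ear response. `randomize_network()` perturbs
every mass and stiffness by unit-mean lognormal factors to emulate
inter-individual spread; rebuilding from the construction table preserves
passivity by construction.

## Coupling and the rod

The coupled model anchors the stack base rigidly (mastoid), ties the tip
plane's axial DOFs into one rigid platen, and connects that platen to the
incus DOF either directly (`with_rod = FALSE`, the reference case that
ignores the rod's structure) or through the rod (`with_rod = TRUE`). Both
cases share identical topology, so their ratio isolates the rod's effect.
The rod (0.5 mm diameter, 2.0 mm length, 6 elements) is modelled with
axial bar elements rather than bending beams: the surrogate ear is a
piston chain, so transverse DOFs would have nothing to couple to. This is
a deliberate reduction; the element count is kept so discretised rod
longitudinal dynamics are represented. Junctions are ideal bonds
(epoxy-grade attachment); imperfect coupling is out of scope.

## Metrics

* **STF** $= 2\pi f D / P_{TM}$, footplate velocity per unit eardrum
  pressure, (m/s)/Pa.
* **Rod penalty** $\Delta H = 20\log_{10}(d_{tr\_rod}/d_{tr})$ dB by
  default. The bare-$\log_{10}$ variant (no factor 20) is exposed behind
  `convention = "literal"` because both forms circulate; drops are
  conventionally quoted in dB of displacement ratio, hence the default.
* **Equivalent SPL** $P_{eq} = L_{ref} + 20\log_{10}(d_{tr}/d_{ac})$ with
  the acoustic baseline $d_{ac}$ taken at $L_{ref} = 100$ dB SPL by
  default (generalised, not hard-coded).
* **Electrical**: layer capacitance $C = n \varepsilon_0 \varepsilon_{33}
  A / t$ ($t$ the single-layer thickness), current
  $I_{rms} = 2\pi f C V_{rms}$, and *two* labelled power figures,
  $P = \tfrac12 I V$ and $P = I V$, because both conventions appear in
  the literature for reactive actuator loads and they differ by a factor
  of two; the package refuses to pick silently.

On capacitance, the model makes a physically important distinction that a
single formula hides. `model_capacitance()` computes the terminal charge
at unit voltage twice: with all mechanical DOFs clamped (the
$\varepsilon^S$ capacitance, 28.1 nF for the designed geometry with
$\varepsilon^S_{33,rel} = 635$) and mechanically free (an effective
$\varepsilon^T$-like capacitance, ≈ 56.5 nF, larger by the piezoelectric
coupling contribution). Reported device capacitances are usually measured
on free samples and therefore sit near the *free* value; an estimate using
clamped permittivities in the layer formula will understate them by a
factor approaching two for a strongly coupled ceramic. Power figures in
`run_power()` therefore accept an explicit measured-capacitance override.

## Numerical choices

* Harmonic solves use the real $2n \times 2n$ augmentation
  $[[A, -B], [B, A]]$ of $(A + iB)x = b$, keeping everything in fast real
  sparse arithmetic.
* Static solves factor the equilibrated free-free block by sparse LU and
  treat a pivot ratio below $10^{-12}$ as singularity; this is the only
  reliable witness, since a floating-point LU of a singular operator
  frequently returns a small-residual answer with an arbitrary rigid-mode
  amplitude.
* Free-stroke solves use a statically determinate 3-2-1 support, which
  removes the six rigid modes without restraining deformation.
* The default frequency grid is 40 log-spaced points over 160–8000 Hz, the
  conventional band for middle-ear transfer functions.
* An undamped resonance hit exactly ($\beta = 0$) raises an error that
  names the frequency and advises damping, rather than returning
  overflow.

Problem sizes: the full 50-layer device at the default refinement has 816
DOFs; unit tests run 2–4-layer stacks, and the design studies sweep
three stack builds over the 40-point grid. All suites run in seconds on a
single core.

## Design decisions that were genuinely open

* **Voigt ordering** and the electrode wiring are nowhere mandated by the
  physics tables; both are declared once and covered by tests (the
  $c_{66} = (c_{11}-c_{12})/2$ identity guards the ordering, the
  layer-parallel capacitance sum guards the wiring).
* **Poisson ratio 0.3** is applied to every isotropic component, including
  the rod, as the conventional soft-tissue/metal compromise used when a
  source states it only for the middle-ear materials.
* **Fixed envelope in the layer study**: when the layer count varies, the
  2 mm total thickness is held fixed (layer thickness $= 2\,\mathrm{mm}/n$)
  — the implant's mastoid pocket constrains the envelope, not the layer
  count. Output then scales essentially exactly as $n$, and doubling the
  layer count adds 6.02 dB of quasi-static stroke.
* **Config format** is versioned YAML with unknown-key rejection; unit
  suffixes (`_mm`, `_um`, `_gpa`) convert at load and everything internal
  is SI.

## Known limitations

* The rod penalties computed on the piston surrogate are small
  (≈ $10^{-3}$ dB): the surrogate's incus port is much more compliant
  than the rod, so only the penalty's *sign and ordering* (softer rod
  costs more; rigid rod costs nothing) are meaningful here. Reproducing
  multi-dB penalties requires a stiff, resonant, subject-specific
  ossicular model of the kind that cannot be shipped.
* Equivalent-SPL magnitudes depend on the surrogate's assumed geometry and
  should be read as demonstrating the pipeline, not as predictions for any
  real ear.
* No dielectric loss, hysteresis, temperature dependence, or geometric
  nonlinearity in the ceramic; no battery or driver electronics in the
  power figures.
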