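---
title: "Methods: bilayer-mediated assembly and gating of MscL lattices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bilayer-mediated assembly and gating of MscL lattices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the physical model, the numerical methods and the
design decisions behind `msclattice`. Code chunks are shown but not evaluated
(several take minutes); the companion script `scripts/acceptance.R`
re-computes every headline number from scratch.

## 1. Physical model

### Elastic energy of bilayer thickness deformations

Mechanosensitive channels of large conductance (MscL) locally deform the
hydrophobic thickness of the lipid bilayer because their hydrophobic belt is
thicker (closed state) or thinner (open state) than the unperturbed membrane.
The package models the half-thickness deformation field $u(x, y)$ (excess over
the unperturbed leaflet thickness $a$) with the standard continuum energy

$$
G = \int \mathrm{d}A \left[
  \frac{\kappa_b}{2} \left(\nabla^2 u\right)^2
  + \frac{K_t}{2} \left(\frac{u}{a}\right)^2
  + \tau \left(\frac{u}{a} + \frac{1}{2}\,|\nabla u|^2\right)
\right],
$$

with bending rigidity $\kappa_b$, thickness-stretch modulus $K_t$,
leaflet half-thickness $a$, and membrane tension $\tau$. The tension couples
both to the thinning $u/a$ and to the excess area of the tilted mid-leaflet
surface. At $\tau > 0$ the far field relaxes to $u_0 = -a\tau/K_t$ with bulk
energy density $e_0 = -\tau^2/(2 K_t)$; all reported energies are *excess*
energies $G - e_0 \cdot \mathrm{area}$, which makes them domain-size
independent. Energies are in units of $k_B T$ at room temperature, lengths in
nm, tensions in $k_B T/\mathrm{nm}^2$.

Each protein imposes Dirichlet conditions on its footprint contour: a fixed
hydrophobic mismatch $u = U$ (one half the difference between the protein's
hydrophobic thickness and the bilayer's) and zero normal slope, the standard
strong-hydrophobic-coupling boundary condition.

### Protein footprints

Footprints are clover-leaf contours
$r(\theta) = R\,[1 + \epsilon \cos s(\theta - \omega)]$ of $s$-fold symmetry:
pentamers ($s = 5$) model the physiological MscL oligomer, tetramers
($s = 4$) the four-fold crystal form, and cylinders ($s = 0$, $\epsilon = 0$)
serve as the analytically solvable reference. Each state (closed/open)
carries its own $R$, $\epsilon$ and mismatch $U$.

Parameter values live in `inst/extdata/mscl_defaults.json`, each with a
`_source` tag describing its provenance class. They are this package's own
choices, informed by the structural and membrane-mechanics literature:
bilayer constants $\kappa_b = 20\,k_BT$, $K_t = 60\,k_BT/\mathrm{nm}^2$,
$a = 1.6$ nm; pentamer closed $R = 2.27$ nm, $\epsilon = 0.22$ and open
$R = 3.49$ nm, $\epsilon = 0.11$; hydrophobic thicknesses 3.8 nm (closed) and
2.5 nm (open), giving $U = +0.3$ and $-0.35$ nm. **Tetramer amplitudes are
flagged as a modelling choice**: the tetragonal structure does not fix
$\epsilon$ directly, so the tetramer reuses the pentamer's state-wise
$\epsilon$ and chooses $R$ to match cross-sectional area state by state
(policy `"matched-area"` in the defaults file). The open–closed area increase
is then identical for both oligomers, $\approx 22\ \mathrm{nm}^2$.

## 2. Finite-element solver

The biharmonic-plus-reaction operator needs $C^1$ continuity for the
$(\nabla^2 u)^2$ term. The package uses the discrete Kirchhoff triangle (DKT)
plate element — 9 degrees of freedom per triangle, $(u, u_x, u_y)$ at each
vertex — for the curvature energy, combined with linear-triangle quadrature
of the $u^2$ and $|\nabla u|^2$ terms and a consistent tension load vector.
Element matrices are assembled in C++ (via Rcpp) and solved with sparse
Cholesky factorization (Matrix package); an L-BFGS path cross-checks the
linear solve.

Verification is oracle-first:

- **Analytic cylinder.** For a single cylindrical inclusion the field is a
  combination of modified Bessel functions $K_0(k_\pm r)$ with
  $\kappa_b k^4 - \tau k^2 + K_t/a^2 = 0$; at default parameters the roots
  are complex ($k = 0.735(1 \pm i)\ \mathrm{nm}^{-1}$), so the package
  evaluates $K_n$ at complex argument by adaptive quadrature of its integral
  representation. The FE energy matches this closed form to $\sim 0.2\%$ at
  default resolution, converging under refinement.
- **Patch tests.** Exact reproduction of quadratic fields, rigid-body
  invariance, rotation invariance of the assembled energy.
- **Quadratic scaling.** At $\tau = 0$ the energy is exactly quadratic in the
  boundary data; scaling $U \to cU$ scales every energy by $c^2$ to $10^{-8}$
  relative.

```{r}
library(msclattice)
p <- bilayer_params()
cyl <- mscl_shape("cylinder", "closed")
analytic_cylinder(p, cyl$R, cyl$U)$energy
cfg <- particle_config(list(cyl), rbind(c(0, 0)))
m <- mesh_patch(cfg, "disc")
solve_field(m, p)$E_excess
```

### Meshing

`mesh_patch()` is a distmesh-style generator: a signed-distance description
of the membrane patch (outer boundary minus protein footprints), a graded
size field ($h$ = contour perimeter / 200 on the contours, $4\times$ coarser
in the far field), and force-equilibrated Delaunay iterations. Contour nodes
are placed exactly on the footprint contours and held fixed. Delaunay
triangulation uses `interp::tri.mesh` with a `deldir` fallback. Outer
boundaries can be a free disc (placed 10 decay lengths
$\lambda = (\kappa_b a^2/K_t)^{1/4} \approx 0.96$ nm beyond the contours), a
mirror-symmetry rectangle, or a periodic rectangle.

### Infinite lattices

Infinite-lattice energies per protein come from rectangular symmetry cells:
the mirror condition (zero normal derivative) is an essential constraint on
the gradient DOFs of boundary nodes, and the cell energy divided by the
number of proteins per cell, minus the isolated-protein energy, is the
binding energy per protein. Cells are provided for square, shifted-square,
hexagonal and honeycomb lattices. Mirror cells require the protein
orientation to respect the cell's reflection symmetry; configurations that
break it (e.g. uniformly oriented pentamers) raise a symmetry-violation
error, and their energetics are computed by pairwise lattice sums instead.
A periodic rectangle (DOF tying) gives an independent cross-check, agreeing
with the mirror cells to $\lesssim 1\%$.

## 3. Pair potentials

`build_pair_table()` tabulates the interaction energy
$E(d, \omega_1, \omega_2)$ — the two-protein FE energy minus two isolated
single-protein energies — on a grid over the center distance $d$ and the two
orientations, each restricted to one symmetry sector $[0, 2\pi/s)$.
Site-exchange symmetry $E(d, \omega_1, \omega_2) = E(d, \omega_2 + \pi,
\omega_1 + \pi)$ halves the number of FE solves. The steric minimum distance
$d_{\min}(\omega_1, \omega_2)$ (contour gap equal to the 1.0 nm lipid
clearance) is found by bisection per orientation pair.

The potential is oscillatory: because the decay roots are complex, the tail
alternates in sign with wavelength $2\pi/\mathrm{Im}\,k \approx 8.5$ nm.
Potentials are attractive at contact (clover-leaf lobes interlocking
face-on), repulsive at intermediate separations, and fall below
$0.05\,k_BT$ in magnitude beyond $d_{\mathrm{cut}} = 13$ nm, which defines
the interaction cutoff.

Lookups round orientations to the tabulated grid and interpolate linearly in
$d$. Two sub-$d_{\min}$ policies coexist deliberately: *strict* (error) for
Monte Carlo trial moves, where sub-steric configurations must be rejected,
and *clamp* (return the contact-row value) for scoring externally
constructed configurations whose spacing sits within rounding of the steric
minimum.

## 4. Monte Carlo annealing

`anneal()` runs Metropolis Monte Carlo in C++ (`mt19937_64`, cell lists with
cell size $\ge d_{\mathrm{cut}}$, minimal-image convention under periodic
boundaries). One step attempts $2N$ single-particle moves (translations and
rotations in shuffled order); temperature cools linearly from $1.5$ to
$0.01$ in units of room temperature. The engine is validated against a
chi-squared test of Boltzmann sampling at fixed temperature (importance
reweighting against an ideal-gas reference) and by exact agreement between
cell-list and direct energy sums.

**Study conditions.** The reference protocol is $N = 1000$ proteins and
$10^6$ steps with 0.1 nm / 0.05 rad moves. The scaled study used in the test
suite and acceptance script ($N = 100$, $10^5$ steps) adjusts two things,
chosen a priori:

- box area fraction 0.2 — denser boxes exceed the jamming limit of the
  sequential random insertion used to create initial gases once the steric
  clearance is added to each footprint;
- move sizes 0.3 nm / 0.15 rad — $\sqrt{10}$ scaling that preserves the
  total random-walk length of the reference protocol; without it, particles
  diffuse less than one lattice spacing in $10^5$ steps and no assembly can
  occur at any density.

Order parameters: $\psi_4$ and $\psi_6$ (modulus of the site-averaged mean
bond-angle phase over the largest cluster), and *row alternation*, the mean
of $\cos s(\omega_i - \omega_j)$ over neighbour pairs — negative when
neighbouring rows are anti-aligned (rotated by $\pi/s$).

## 5. Lattice architectures

Finite clusters (`build_lattice()`, `lattice_energy_finite()`) and infinite
lattices (`lattice_energy_infinite()`, `infinite_pairwise_energy()`) cover
square, shifted-square, hexagonal and honeycomb families plus two distorted
pentamer packings:

- **distorted-A**: hexagonal-like rows with independent row spacing, row
  shift and base orientation, alternate rows rotated by $\pi/s$.
  `max_packing_distorted_a()` maximizes the packing fraction over the row
  geometry under the steric clearance (bisection on the row spacing inside a
  Nelder–Mead search over the remaining parameters). The parameterization
  (`ax`, `ay`, `cx`, `omega0`) is this package's choice of a minimal
  4-parameter family containing both the uniform hexagonal lattice and
  fully alternating rows.
- **distorted-B**: a three-protein face-on motif tiled on a triangular
  superlattice, parameterized by the motif size and tiling distance.

Key results (recomputed by `scripts/acceptance.R`): tetramer $L = 4$
clusters order face-on square < shifted square < hexagonal; infinite
cylinder lattices are hexagonal at contact with honeycomb taking over at
intermediate spacing; pentamers pack denser in distorted-A
($\phi = 0.58$ vs $0.49$ uniform hexagonal) and bind more strongly per
protein there.

## 6. Gating barriers and rates

`activation_barrier()` computes the *interaction-energy* cost of switching
one perimeter protein of a closed-state ground-state cluster into its open
footprint, relaxing the site and its neighbour shell locally (Nelder–Mead
from several deterministic outward-push starts plus randomized restarts,
with a smooth steric penalty replacing the hard constraint during
minimization). The isolated-protein gating energy is excluded by
construction — the barrier isolates the lattice's contribution to gating.
This interaction-only definition is a deliberate design decision: the
isolated gating energetics (protein conformational energy, tension–area
work) are common to all sites and cancel in site and oligomer comparisons.

`barrier_vs_tension()` scans $\tau \in [0.5, 2.0]\,k_BT/\mathrm{nm}^2$ —
spanning sub-gating to near-gating tensions — rebuilding the pair tables at
each tension (the potential itself is tension dependent), and fits
$\Delta G(\tau)$ linearly. `arrhenius_ratio()` converts barrier differences
into activation-rate ratios $\exp(\Delta\Delta G / k_BT)$.

Three caveats, quantified in the decisions ledger accompanying development:
barriers computed from the coarse gating-grade tables carry several-$k_BT$
interpolation noise, so the linearity of $\Delta G(\tau)$ is
resolution-limited (a finer one-shot run gives a monotonic relation with
$R^2 \approx 0.93$); edge sites at contact spacing are *sterically blocked*
(the minimizer retains a residual sub-steric overlap, reported as
`steric_violation`, and the barrier is penalty-dominated) — gating proceeds
from corners; and the tetramer–pentamer corner-barrier difference is large
($\sim 16\,k_BT$ at $\tau = 1.25$), reflecting the tightly bound face-on
square tetramer lattice produced by the matched-area shape choice.

`mixed_state_anneal()` anneals closed/open mixtures and reports a
segregation index (mean same-state neighbour fraction) against the
random-mixing baseline, the modal closed–open contact distance, and whether
the largest cluster is composite. Short (desk-scale) schedules reliably
show segregation well above the baseline but can leave the system trapped
as several small single-state clusters: same-state contacts ($\sim 4\,k_BT$)
nucleate pure clusters early, while the weak closed–open attraction
($\sim 0.3\,k_BT$) needs whole-cluster diffusion — frozen out late in the
schedule — to merge them into one composite cluster. Reaching the composite
state consistently requires schedules of order $10^6$ steps.

## 7. Numerical resolutions

Three resolution tiers are used consistently:

| tier | mesh $h$ (fraction of perimeter) | pair grid | used by |
|---|---|---|---|
| study-grade | 1/200 | $\Delta d = 0.1$ nm, $\Delta\omega = 2°$ | defaults; headline single-protein numbers |
| table-grade | 1/64 | $\Delta d = 0.5$ nm, 4 orientations/sector | pair tables in tests and acceptance |
| gating-grade | 1/48 | $\Delta d = 0.9$ nm, 3 orientations/sector | tension scans (tables rebuilt per $\tau$) |

Table-grade pair energies carry $\sim 0.05\,k_BT$ mesh noise; statements
about the $\le 0.05\,k_BT$ tail are therefore verified at converged
resolution ($h$ = perimeter/160) rather than from the coarse tables. The
coarse orientation grids limit orientational relaxation: a relaxed
orientation is only resolved to half a grid cell ($\sim \pi/16$ for 4
orientations per tetramer sector), which the relevant tests account for.

## 8. Limitations

- Pairwise additivity: lattice energetics by table lookup neglect multibody
  elastic effects; `lattice_energy_finite(mode = "multibody-FE")` and
  `nonpairwise_deviation()` quantify the error on small clusters but are too
  slow for annealing.
- Small-gradient elasticity: the quadratic energy is used at all mismatches;
  `gradient_validity_check()` reports where $|\nabla u|$ exceeds 0.5.
- The clover-leaf contour family is a two-parameter idealization of the real
  protein cross-sections; tetramer amplitudes in particular are a modelling
  choice (Section 1).
- Barriers use local relaxation around the gating site; collective
  rearrangements beyond the neighbour shell are excluded by design.
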