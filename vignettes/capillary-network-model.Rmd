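---
title: "A hybrid Cellular Potts / continuum model of capillary-like network formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid Cellular Potts / continuum model of capillary-like network formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vasculr)
```

## The model

`vasculr` simulates short-term in vitro vasculogenesis: endothelial cells
seeded on a soft collagen biogel reorganize, within about a day, into a
capillary-like network of cords enclosing cell-free lacunae. The package
couples a lattice-based cell model to three continuum fields on the same
periodic grid:

* **Cells** (Cellular Potts model, CPM). Each cell is a set of connected
  lattice sites. A hypothetical system energy combines interface energies
  between cell/cell and cell/medium lattice pairs (first- and second-order
  neighbours, the latter down-weighted) with per-cell restraints on area,
  perimeter, and - for cells that have switched to the elongated
  morphology - a reward for a large head-to-tail length:

  $$H=\sum_{\{x,x'\}}J_{\tau_x\tau_{x'}}\,(1-\delta_{\sigma_x\sigma_{x'}})
  +\sum_{\sigma>0}\left[\lambda_a(a_\sigma-a_0)^2+\lambda_p p_\sigma
  +\lambda_l\,\phi_\sigma/l_\sigma\right]$$

  Dynamics proceed by Metropolis copy attempts: a source site is picked
  uniformly, a target site among its eight neighbours (diagonals selected
  and weighted at 1/2), and the source's cell index is copied onto the
  target with probability $\min\{1, e^{-\Delta H_m}\}$ at unit temperature.
  One Monte-Carlo step (MCS) is one sweep of `nx * ny` attempts and
  represents 2 simulated minutes; 400 cells of 21 sites (2100 um^2) are
  seeded on a 170 x 170 grid of 10-um sites.

* **Haptotaxis.** The copy-attempt energy change is biased by the local
  gradient of gel-bound VEGF,
  $\Delta H_m=\Delta H-\mu_h\,(b_{x'}-b_x)(1-\delta_{\tau_x\tau_{x'}})$,
  active only when source and target differ in occupancy (a form of contact
  inhibition). Extensions up-gradient and retractions from down-gradient
  sites are both favoured, so cells drift toward bound-VEGF maxima.

* **Morphology switch.** Each round cell elongates irreversibly with
  per-MCS probability $\mu_m c_\sigma r_\sigma$, where $c_\sigma$ is the
  soluble VEGF averaged over the cell and $r_\sigma$ the fraction of its
  boundary not touching other cells; a cell inside a cobblestone aggregate
  ($r_\sigma \to 0$) keeps its round shape. The probability is clamped to
  $[0,1]$.

* **Biogel mechanics.** The gel is a viscoelastic sheet with long-range
  fiber elasticity, pulled by isotropic cell traction
  $\sigma_{cell}=\kappa\rho\tau I$ and restrained by friction against the
  dish. The quasi-static force balance
  $\nabla\cdot(\sigma_{cell}+\sigma_{vis}+\sigma_{ela,lin}+\sigma_{ela,lr})=R_{ext}$
  uses Stokes viscosity (shear $\mu_1$, bulk $\mu_2$), Hookean elasticity
  $(E,\upsilon)$, Laplacian-of-strain long-range terms $(\beta_1,\beta_2)$
  and the dish friction
  $R_{ext}=h^{-2}[E/(1{+}\upsilon)(u-\beta_1\nabla^2 u)+\mu_1\,\partial u/\partial t]$.
  Gel density is advected conservatively with the displacement rate, and
  thickness follows the linearized relation
  $h=h_0[(1-3\upsilon)/(1-2\upsilon)+\upsilon/(1-2\upsilon)\,\rho/\rho_0]$,
  whose grouping is fixed by requiring $h(\rho_0)=h_0$.

* **VEGF transport.** Soluble VEGF diffuses and binds reversibly to a
  finite pool of gel binding sites ($\gamma\rho$ minus the mass already
  bound, weighted by the fibronectin/VEGF molecular-weight ratio); bound
  VEGF rides with the deforming gel. Total VEGF is conserved exactly: the
  gel concentrates under cell aggregates, bound VEGF concentrates with it,
  and its gradients feed back on cell migration - the positive feedback
  loop that assembles and stabilizes the network.

Within each MCS the update order is: morphology switch, CPM sweep (reading
the current bound-VEGF field), mechanics step (displacement, density,
thickness), VEGF step (sharing the mechanics step's displacement rate).
This order is a modelling choice; `run_simulation(..., swap_pde_order =
TRUE)` runs VEGF before mechanics instead, and the endpoint network metrics
agree within replicate noise (tested).

## Parameters

Typical values (the package defaults) for HUVECs on air-dried type-I
collagen:

| symbol | meaning | default | units |
|---|---|---|---|
| `J11`, `J10`, `J00` | interface energies | 0.12, 0.06, 0 | a.e.u./um |
| `lambda_a` | area restraint | 1e-4 | a.e.u./um^4 |
| `lambda_p` | perimeter restraint | 1e-2 | a.e.u./um |
| `lambda_l` | elongation restraint | 5e3 | a.e.u. um |
| `a0` | target area | 1960 | um^2 |
| `mu_m` | morphology strength | 1.3e8 | um^3/ng |
| `mu_h` | haptotaxis strength | 1.5e14 | a.e.u. um^3/ng |
| `kappa` | traction strength | 4e9 | Pa um^3/ng |
| `E`, `nu` | Young's modulus, Poisson ratio | 2e4, 0.48 | Pa, - |
| `mu1`, `mu2` | shear/bulk viscosity | 7.4e5, 1e7 | Pa s |
| `beta1`, `beta2` | long-range elastic coefficients | 1e4 | um^2 |
| `D_c` | soluble VEGF diffusivity | 59 | um^2/s |
| `k_on`, `k_off` | binding/unbinding rates | 8.6e5, 3.6e-3 | um^3/(ng s), 1/s |
| `gamma` | binding-site mass ratio | 5e-6 | - |
| `rho0`, `h0` | initial gel density/thickness | 1e-5, 300 | ng/um^3, um |
| `c0` | initial soluble VEGF | 2e-11 | ng/um^3 |

The fibronectin/VEGF molecular-weight ratio defaults to 440/45 (both in
kDa, the standard values); it is a visible, configurable parameter of
`vegf_params()` because the bound-VEGF site capacity scales with it.

## Numerical choices

* **Spatial discretization.** Second-order central differences on the
  periodic grid for every spatial operator; the fourth-order long-range
  terms are nested Laplacians. The checkerboard mode of the composed first
  differences is controlled by the viscous and biharmonic terms.
* **Implicit mechanics step.** The rate terms (viscosity and the friction's
  $\mu_1\partial u/\partial t$) are treated with a backward difference over
  the 120-s step, the elastic terms implicitly, so the step is
  unconditionally stable. The resulting linear operator has constant
  coefficients except for the $1/h^2$ friction factor. It is solved
  spectrally: per-wavevector 2x2 blocks of the constant part (with the mean
  friction) are inverted exactly and act as the preconditioner; the
  friction's deviation from its mean is handled by BiCGSTAB (relative
  tolerance 1e-9, typically 2-6 iterations). On 16 x 16 grids the solution
  is verified against a dense finite-difference assembly built
  independently from Kronecker products.
* **Thickness floor.** The linearized thickness relation has slope
  $12 h_0/\rho_0$ at $\upsilon=0.48$: an 8% density drop drives $h$ to 0.
  Because the relation is only a linearization around $\rho_0$ and the
  friction divides by $h^2$, `h` is floored at `h_min` (default `h0/10`).
  Clamp events are counted in the run ledger.
* **Advection.** First-order upwind in conservative flux form with internal
  CFL sub-stepping: monotone and exactly mass-conserving; adequate at 10-um
  resolution given the small displacement rates (well below 0.1 um/s after
  the initial transient).
* **Binding kinetics.** With the local total `c + b` fixed during the
  kinetics sub-step, the mass-action exchange is a constant-coefficient
  Riccati equation and is integrated *exactly* (closed form via its two
  roots), which preserves positivity, never oversaturates the binding
  sites, and conserves total VEGF to round-off.
* **Cell connectivity.** The elongation restraint rewards a large
  head-to-tail length `l` (the maximum pairwise site distance under the
  periodic minimal image). If cells may fragment, shed fragments drifting
  apart lower $\lambda_l/l$ indefinitely - a ratchet that, in practice,
  tears every elongated cell into pieces and destroys the network (mean
  cell extent grows past the geometric maximum of a connected cell, and
  junction counts collapse). The perimeter restraint alone (at its typical
  value, ~0.2 a.e.u. per pinch-off) cannot prevent this. The engine
  therefore rejects retractions that would split a cell, using the standard
  local arc-counting constraint on the 8-neighbour ring; elongated cells
  then stay whole with lengths around twice the initial diameter, matching
  the observed phenomenology. `potts_params(connectivity = FALSE)` restores
  the unconstrained dynamics.
* **Head-to-tail length.** `l` is floored at one lattice spacing inside the
  energy so a freshly switched single-site-scale cell has finite energy.
* **Second-order neighbours.** Both the interface-energy weight and the
  proposal-selection weight of the four diagonal neighbours default to 1/2,
  with `neighbor_weight_order2 = 1/sqrt(2)` available as the
  inverse-distance alternative.

## Quantification layer

* **Network topology.** The cell pattern is binarized, thinned to a
  one-pixel skeleton (periodic Zhang-Suen), and converted to a graph.
  Redundant diagonal adjacencies (a diagonal step whose orthogonal corner
  pixel is also on the skeleton) are dropped so staircase paths read as
  degree-2 chains. Dead-end branches shorter than the 100-um threshold are
  pruned iteratively as noise and degree-2 chains merged. Junctions are the
  remaining nodes with at least three incident branches; segments are
  counted and measured only when at least 100 um long. Counting junctions
  over all remaining branches - rather than only over the >=100-um ones -
  matters: the skeleton mesh spacing of a developed network is 20-80 um,
  so demanding three 100-um incident segments would leave a handful of
  junctions on patterns that plainly contain well over a hundred. A closed
  loop without branch points counts as a single closed segment.
* **Cell shape.** Roundness is $4\pi a/p^2$ with the lattice area and
  boundary-edge-count perimeter (a perfect lattice disk therefore scores
  below 1; the identity `roundness = 1` holds for the analytic disk).
  The aspect ratio is the square root of the eigenvalue ratio of the
  second-moment tensor of site centres, computed in the periodic minimal
  image; it is 1 for a single-site cell and rotation-invariant.
* **Migration modality.** Per cell and 2-hour window (60 MCS), nonzero
  centroid steps are binned into 12 x 30-degree direction intervals and
  classified sequentially at levels $\alpha_1=\alpha_2=0.1$: first a
  uniformity screen - not rejected means *isotropic*; then, for directional
  cells, Hartigan's dip test of unimodality on the modal-bin-centred
  histogram with the dip null bootstrapped from the uniform 12-bin
  multinomial (10^4 seeded resamples, the least-favourable unimodal null) -
  unimodal means *one-direction*, and bimodal with the two modes in opposed
  bins (circular distance 6 +/- 1) means *head-and-tail*.

  The choice of the uniformity statistic decides the census. The default is
  the Rayleigh resultant length (the standard circular uniformity test),
  Monte-Carlo-calibrated on the same seeded multinomial null. It is blind
  to symmetric back-and-forth oscillation, and deliberately so: elongated
  cells embedded in cords wiggle along their long axis, and a
  concentration-sensitive screen (chi-square, available via
  `uniformity = "chisq"`) flags essentially every such cell as directional,
  flooding the head-and-tail class with hundreds of cells by late times.
  Under the resultant-length screen those oscillating cells read as
  isotropic, head-and-tail remains the smallest class (populated by cells
  with asymmetric two-way movement), and one-direction movers peak in the
  early hours while aggregates drift together - the census structure
  observed in such cultures. Note one boundary case: a perfectly balanced
  50/50 opposed-direction window has zero resultant vector and is therefore
  indistinguishable from isotropic under the default screen.

  A dip statistic alone cannot serve as the uniformity screen (the dip of a
  concentrated unimodal sample is ~0, so one-direction movers would never
  be detected), which is why the screen and the unimodality test use
  different statistics. Binned observations are spread uniformly within
  their bin for the dip computation - the standard treatment of ties -
  identically for data and null. The dip statistic itself is computed from
  its definition (minimal sup-distance to the unimodal cdf class) by
  bisection on a tube-feasibility test with convex-hull checks, with
  candidate modes at support points and support-gap midpoints; unit tests
  pin it to hand-derived exact values (two-atom mixtures, equally weighted
  atoms). Windows with fewer than 10 nonzero steps are labelled isotropic
  and flagged.
* **Dose-response regressions.** Junction-number responses are fitted by
  Levenberg-Marquardt with data-driven multi-starts: saturating exponential
  $a-be^{-cP}$ (VEGF parameters and binding-site ratio), linear (traction
  strength), four-parameter logistic in the gel thickness, and the
  ten-coefficient two-factor time-course model
  $A(1-e^{-B\mu_m-C\mu_h-Dc_0-E k_r})(1-e^{-F\mu_m^G\mu_h^H c_0^I k_r^J t})$
  with $k_r=k_{on}/k_{off}$. The time-course fit internally rescales all
  predictors by their medians (raw scales span ~25 orders of magnitude) and
  maps the coefficients back. Condition comparisons use raw two-sample
  t-tests with the conventional star notation and no multiple-testing
  correction, which is reported alongside the results.

## Synthetic data and what the tests show

The fixture generators (`make_fixture()`) produce the toy inputs every
stage is tested against without running the coupled model: small lattices
with a few cells for the energy-delta oracle, linear bound-VEGF gradients,
bar/plus/ring masks with exactly known network metrics, 60-step
displacement records of prescribed modality, and noiseless dose-response
datasets from stated coefficients. All generators are seed-deterministic.

These fixtures emulate the *geometry and statistics* the pipeline must
measure, not real microscopy: there is no imaging noise, no illumination
gradient, no segmentation error, and trajectories are drawn from idealized
direction distributions. Passing the fixture suite therefore validates the
measurement definitions and their implementation, and the coupled-model
tests validate the emergent behaviour of this model - neither certifies
agreement with any particular wet-lab image-analysis pipeline.

Test problem sizes are deliberately modest where full-scale runs are not
the point: the energy oracle uses 12 x 12 lattices with 3 cells, the dense
mechanics oracle 16 x 16 grids, conservation and co-localization checks
50 x 50 to 100 x 100 grids at the full-scale cell areal density
(400/170^2 cells per site), with durations of 40-180 MCS. The acceptance
checks that reproduce headline numbers run the full 170 x 170, 400-cell,
720-MCS configuration in `scripts/acceptance.R`, and area-scaled versions
(120 x 120, 200 cells) in the routine test suite.

## Known limitations

* Two-dimensional: no cord hollowing, no cell stacking, no 3-D gel
  mechanics.
* No VEGF secretion, consumption or degradation: total VEGF is a conserved
  quantity by construction, which is appropriate only for short cultures.
* Cells neither divide nor die; cytoplasm of touching cells never merges,
  so cell-cell contacts can detach again - transient cords are less stable
  than in cultures where merging occurs.
* The thickness-density relation is a linearization around the initial
  density and is clamped away from its validity limit.
* The skeleton-graph conventions (node merging, diagonal reduction,
  spur threshold) are a documented, deterministic replacement for
  interactive image-analysis tooling; absolute junction/segment counts
  depend on such conventions and are comparable only within one pipeline.
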