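---
title: "Membrane-resolved Monte Carlo models of nanocarrier avidity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane-resolved Monte Carlo models of nanocarrier avidity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`ncavidity` simulates an antibody-functionalized nanocarrier (NC) adhering
to a patch of a live cell membrane, and converts the sampled statistics into
an absolute multivalent association constant and organ-level tissue-targeting
predictions.

**Membrane.** The patch is a dynamically triangulated surface: `N_m`
vertices, `T_m` triangles and `L_m` links over a periodic `L x L` frame
(torus topology, so `N_m + T_m - L_m = 0`).  Its elastic energy is the
discretized Helfrich form
$$H_m = \sum_v \left[\tfrac{\kappa}{2}(c_{1,v}+c_{2,v})^2 A_v
        + \sigma A_v\right],$$
with per-vertex principal curvatures from the cotangent mean-curvature
vector and the angle-deficit Gaussian curvature (both normalized by the
obtuse-safe mixed Voronoi area), and $A_v$ one third of the incident
triangle area so that $\sum_v A_v$ tiles the curvilinear area exactly.
Self-avoidance is imposed through tether bounds on every link length,
$a_0 \le \ell \le \sqrt{3}\,a_0$ with $a_0 = 10$ nm.  The upper bound is
exposed as `link_max_factor`; $\sqrt 3$ is the standard tether-and-bead
choice and keeps the initial grid diagonals admissible.  Fluidity enters
through link flips.  The excess area
$A_\mathrm{ex} = 100\,(A - A_p)/A$ measures the membrane area stored in
undulations beyond the projected frame area $A_p = L^2$.

**Receptors and ligands.**  Receptors are rigid rods of length
$L_{an} = 19$ nm based on mesh vertices (at most one per vertex), tilted by
flexural angles $(\theta, \phi)$ about the local vertex normal with energy
$H_f = \kappa_f \theta^2/2$.  The NC is a rigid sphere of radius 50 nm
carrying $N_{ab}$ radial ligand rods of length 15 nm on a deterministic
Fibonacci lattice.  A receptor-ligand pair with tip-tip distance
$d \le d^*$ can form a Bell bond,
$$H_b(d) = H_0 + \tfrac{\kappa_b}{2}(d-d^*)^2,$$
and contributes nothing beyond $d^*$.  Bond bookkeeping is a partial
matching (each receptor binds at most one ligand and vice versa), and a
formed bond is constrained to $d \le d^*$: since the piecewise potential
makes a "bond" beyond $d^*$ energetically identical to no bond, the
constraint merely removes a degenerate label.

**Units.**  Internally everything is nanometres and thermal energies at the
configured temperature (default 300 K).  SI inputs are converted at the
configuration boundary: $H_0 = -7.98\times10^{-20}$ J $\approx -19.27\,k_BT$,
$\kappa_b = 1$ N/m $\approx 241\,k_BT/\mathrm{nm}^2$, and the receptor
flexural rigidity 7000 pN nm $\approx 1690\,k_BT/\mathrm{rad}^2$.  The
flexural rigidity is quoted in mixed units in parts of the literature; we
adopt the reading that is dimensionally consistent with
$H_f=\kappa_f\theta^2/2$ (energy per squared radian) and expose the value
as an ordinary configuration key.  The reaction range $d^*$ is not well
constrained by the sources; the default is 1 nm, small against both rod
lengths so that "bond" means near-contact of tips, and every workflow
parameterizes it explicitly.

# The Monte Carlo engine

Seven elementary moves evolve the system ("one MC step" = one attempted
move): vertex displacement, link flip, NC translation, NC rotation,
receptor diffusion (a base hop to an adjacent free vertex), receptor
flexure, and bond formation/breakage.  By default half of the attempts are
spread equally over the five canonical moves and the other half over the
two rare-event moves in the ratio 2:5.  Flexure and bond moves use
configurational-bias (Rosenbluth) sampling with `k_trials = 8` trial
orientations:

* Trial orientations are drawn from the flexural Boltzmann density itself
  (a Rayleigh draw with a $\sin\theta/\theta$ rejection step) whenever
  $\kappa_f \ge 5\,k_BT$, so the flexure factor cancels from the
  Rosenbluth weights; for floppy receptors the trials are uniform on the
  hemisphere and the flexure energy stays in the weight.  At the default
  stiffness ($1690\,k_BT$) naive uniform trials would essentially never
  land in the populated $\theta \lesssim 0.05$ cone.
* The bond move regrows the orientation and the bond label jointly: for
  each trial orientation every formable free ligand is enumerated as a
  composite option weighted by its Boltzmann factor, alongside the
  unbonded option.  This is standard configurational-bias Monte Carlo on
  the joint (orientation, bond) state and satisfies detailed balance; the
  suite verifies it against two-state quadrature oracles rather than
  against any particular published construction.

Vertex displacements are an even mixture of height-only and isotropic
proposals with separately tuned amplitudes.  The height-only component is
the Monge-gauge degree of freedom and is unconstrained by the lower tether
bound on a lattice that sits at that bound; the isotropic component relaxes
the in-plane metric.  Step sizes are auto-tuned to 30-50% acceptance during
burn-in only and then frozen (continuous tuning would break detailed
balance).  Pinned vertices (the mean-field cytoskeleton) are excluded from
the vertex-move proposal set but participate in all energies.

The engine maintains per-vertex energies, per-triangle areas and the
order-parameter vertex selection incrementally, with periodic full
recomputation; the residual drift is reported as a diagnostic (typically
$<10^{-2}\,k_BT$ over $10^7$ steps).  Checkpoints serialize the complete
state including the RNG stream and the adjacency container order (which
link flips permute, and which random edge draws and floating-point
summation orders depend on), so a restored run continues bit-for-bit.

## Lattice initialization

A hard-tether network has an entropically preferred link length of roughly
$1.2\,a_0$.  A grid built at spacing $a_0$ (the lower bound) is therefore
compressed by its frame: its area grows and condenses into long-wavelength
buckling, which is exactly the large-excess-area regime, not the taut
regime that spectrum analysis assumes.  Workflows that need a taut membrane
(spectrum fits, the pinning study, the stiff adhesion runs) initialize the
lattice near its rest spacing (`spacing = 12` nm), which keeps the framed
sheet approximately stress-free; the residual effective tension visible in
the fitted spectra is of order $10^{-2}\,k_BT/\mathrm{nm}^2$.
High-excess-area states are instead *prepared*: `ruffled_patch()` folds the
dense lattice into an anti-diagonal corrugation whose amplitude is chosen
by bisection to store a target excess area (default 40%) within the tether
caps.  Stored area relaxes extremely slowly under local moves (it must be
transported through vertex displacements), so over a production window the
excess area is approximately stationary; trajectories record the realized
area so this can be checked.

# Spectrum analysis and pinning

Heights are interpolated barycentrically from the projected triangulation
onto a regular periodic grid (inverted projected triangles are a gauge
error, or are skipped and in-filled under `on_fold = "fill"`), and the
radially averaged spectrum uses the convention
$h_q = N^{-2}\sum h\,e^{-iqx}$, fixed by a Parseval identity test, so that
$$\langle |h_q|^2\rangle = \frac{k_BT}{A_p(\kappa q^4 + \sigma q^2)}.$$
The fit is weighted least squares of $1/\langle|h_q|^2\rangle$ with
inverse-variance weights `n_modes * n_fields * S^2`, over shells from
$1.5\,q_1$ (the lowest shell is frame-constrained) to $\pi/(2 a_0)$
(beyond which discretization dominates).  The estimator is validated by a
generator-estimator closure: fields synthesized mode-by-mode from the
Helfrich spectrum return their $\kappa$ (20 and 160 $k_BT$) within 10%.
Recovering a small tension ($10^{-4}\,k_BT/\mathrm{nm}^2$) to 10% requires
the tension term to dominate the lowest shells, i.e. boxes of a few
micrometres; the closure test uses a 4 um synthetic box for that quantity.
Engine-sampled membranes at $\kappa = 20\,k_BT$ return their bending
rigidity within 15% on a 240 nm patch in about ten seconds of sampling.

Cytoskeletal pinning is modelled at mean field by immobilizing a random
vertex fraction (0-12%, mimicking cortical mesh sizes of roughly 500 down
to 150 nm).  Pinning suppresses long-wavelength undulations, which the
Helfrich fit absorbs mainly as an *increased effective tension*; the
pinning study tabulates $(A_\mathrm{ex}, \kappa_\mathrm{eff},
\sigma_\mathrm{eff})$ against the pinning fraction.

# Free energy along the separation coordinate

The order parameter is $\Delta R = |\mathbf R_{CM} - \mathbf R_{NC}|$ with
$\mathbf R_{CM}$ the centre of mass of membrane vertices within $2 r_{NC}$
of the NC centre (minimum-image).  When that ball is empty (far-separated
windows) the selection falls back to the vertices within lateral distance
$2 r_{NC}$, which keeps the coordinate defined continuously into the
unbound region.  Umbrella windows are spaced 2 nm apart with
$k_{bias} = 2 k_BT/(\delta R)^2 = 0.5\,k_BT/\mathrm{nm}^2$, so one window
of thermal energy spans one window spacing; histograms are recorded every
10 steps.

WHAM combines the window histograms (bin width $\delta R / 10$,
self-consistency tolerance $10^{-8}\,k_BT$, at most $10^5$ iterations, with
a coverage diagnostic on consecutive windows).  The additive constant is
fixed by thermodynamic integration: the mean restraint force
$-k_{bias}(\langle\Delta R\rangle_i - \Delta R_{0,i})$ is integrated along
the window ladder, and the absolute level comes from the free-particle
reference in the outermost window, where the profile is flat and the
biased partition function is known in closed form - this makes the unbound
state the zero of free energy.  A plateau-zero offset is always computed as
an independent cross-check and reported as the anchoring consistency.
The unbound cutoff $r^*$ is the smallest separation beyond which the
anchored profile stays within tolerance of zero (default 0.5 $k_BT$); when
a profile is not resolved the conventional value 100 nm is used downstream.

# Avidity

The association constant of an NC carrying $N_{ab}$ ligands that forms
$n_b$ bonds against $N_{ant}$ receptors is assembled as
$$K_a = \binom{N_{ant}}{n_b}\binom{N_{ab}}{n_b}
  \frac{\Delta\phi\,\Delta\theta\,\Delta\psi}{8\pi^2}
  \left(\frac{A_R^b}{A_R^u}\right)^{n_b}
  \frac{A_N^b}{L_z(L_z - r^*)}
  \int_0^{r^*} e^{-\beta W(r)}\,dr,$$
computed in log space (log-Gamma combinatorics; trapezoid quadrature on the
PMF grid).  Estimator choices, held fixed across all comparisons because
only ratios of $K_a$ are consumed downstream:

* $n_b$ is the modal multivalency of $P(n_b)$ over the bound trajectory
  segment (mean available as an option);
* $A_R^b$ and $A_N^b$ are covariance-ellipse areas
  $\pi c^2 \sqrt{\det\Sigma}$ (coverage $c = 1$ by default) of the
  bound-receptor positions in the tangent plane set by the mean bound
  receptor orientation, and of the NC centre's unwrapped lateral path;
* the rotational volume is the product of the standard deviations of the
  three Tait-Bryan (ZYX) angles of the NC orientation measured relative to
  its mean pose.  That convention is regular at the identity - the angles
  reduce to rotation-vector components for small fluctuations - which is
  the property a fluctuation measure needs; conventions with a polar
  singularity at the reference pose are unusable there.
* $A_R^u = A / N_{ant}$.

$K_a$ is reported in internal nanometre-based units; the printed expression
carries a net length dimension, so all downstream use is through ratios
(density interpolation, $K_d/K_d^\dagger$ normalization, organ-to-lung
$\eta$), where the unit cancels.  Between simulated receptor densities the
binding free energy $F = -\ln K_a$ is interpolated linearly, equivalently
$K_a^{*} = K_{a1}^{(n_2-n^*)/(n_2-n_1)} K_{a2}^{(n^*-n_1)/(n_2-n_1)}$,
with extrapolation gated behind an explicit flag.

The formula is validated against a brute-force configurational-integral
oracle on a one-receptor/one-ligand toy with a prescribed harmonic profile:
the oracle uses exact areas and adaptive quadrature, the implementation the
sampled covariance estimators and the trapezoid, and they agree within 10%
(the budget is dominated by estimator choices, as it should be).

# Tissue targeting

The steady-state uptake score of an organ combines non-targeted
partitioning ($K_p$, measured with IgG-coated control carriers), targeted
endothelial capture ($K_{EC}$) and optional capture by other cells
($K_M$):
$$\%idg \sim \{K_p K_{EC} C_{out} + \phi_{EC} K_{EC} L_{EC,b} D_{EC}
  C_{out}\}\frac{L_{cap}}{L_{EC,b}} + \phi_M K_M L_{M,b} D_M C_{out}
  \frac{L_{cap}}{L_{M,b}}.$$
The printed grouping is ambiguous on its own; the implementation fixes the
reading above and verifies the contract that matters: in the
$K_p$-dominated regime $\eta \to (K_p K_{EC})_{org} / (K_p K_{EC})_{lung}$
within 1%.  All scores are reported as $\eta = \%idg / \%idg_{lung}$, which
cancels the arbitrary $L_{cap}$ and $C_{out}$ scales exactly;
$\eta_{lung} = 1$ by construction, and the uncertainty band evaluates the
scores at $K \pm \Delta K$.  The four model scenarios (flat substrate,
endothelium only, plus resting or activated macrophages) differ only in
which association constants are supplied - there are no hidden per-scenario
constants.  The shipped organ table fills only the values quoted in text
(lung about 2000 and heart about 50 receptors per square micrometre,
$\phi_{EC} = 0.30$, $\phi_M = 0.03$ in the clearance organs); quantities
available only as figure data ($K_p$, the remaining densities) are `NA`
with provenance `user-must-supply`, so figure-read numbers are never
baked in as ground truth.

Model-experiment agreement uses a bootstrap Pearson $r^2$: five sets of
2000 Gaussian replicates per paired value, $r^2$ per set, reported as the
mean over all draws with the standard deviation across sets; the
no-targeting null model (uptake $= K_p$) is compared with a two-sided
unpaired t-test on the per-set $r^2$ values.

# Synthetic data and what passing tests show

All fixtures are generated in code: icospheres and cylinders (analytic
curvature oracles), sinusoid patches (arc-length quadrature oracle),
Gaussian Helfrich fields (generator-estimator closure), an engine-free 1-D
umbrella toy sampled by inverse-CDF draws (WHAM/TI oracle), a two-state
receptor-ligand toy with quadrature occupancy, and prescribed-statistics
trajectories for the entropy estimators.  These emulate the *mechanics* of
real data - they do not contain receptor clustering, glycocalyx effects,
flow, heterogeneous expression, or internalization, so passing tests
establish the correctness of the sampling and estimators under the model's
assumptions, not the fidelity of the model to any particular cell.

# Problem sizes and numerical choices

The default test and acceptance workloads use 240-300 nm patches
(400-900 vertices), $6\times10^6$ steps for membrane-only spectra and
$6\times10^7$ steps for adhesion runs, sizes chosen as a deliberate
desk-scale compromise; experimental-scale settings (510 nm patch,
$9\times10^8$ steps per window, quadruplicate windows) remain plain
configuration.  Two systematic caveats at this scale are documented rather
than hidden: multivalency equilibrates slowly (bond addition
requires cooperative membrane bulging), so the reported mode is taken from
the second half of the run and retains a residual drift and a seed-to-seed
spread of a few bonds at this scale - particularly on prepared
high-excess-area membranes, where the fold pattern the carrier settles into
matters; and those prepared states are themselves quasi-stationary rather
than fully equilibrated, with realized excess areas somewhat below the
prepared value.  Degenerate inputs fail loudly: zero-area
triangles name the triangle, overhanging meshes report the inverted-triangle
count, non-overlapping umbrella windows name the gap, anchoring without an
unbound plateau is an error, and rank-deficient position covariances fall
back to an area floor with a warning.

# Known limitations

No glycocalyx, no shear flow, no internalization kinetics, no adaptive
remeshing or topology changes, no hydrodynamics, and no kinetic
interpretation of Monte Carlo time.  Closed vesicles are test fixtures
only.  The association constant's absolute unit is internal; only ratios
are meaningful outputs.
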