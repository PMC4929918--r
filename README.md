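# ncavidity

Multiscale Monte Carlo simulation of antibody-functionalized nanocarrier
(NC) adhesion to a thermally fluctuating cell membrane, and the downstream
steady-state pharmacokinetics that turn binding avidities into organ-level
tissue-targeting predictions.

The package is aimed at researchers in targeted drug delivery and membrane
biophysics who want to ask: given the *mechanotype* of a target cell
membrane (bending rigidity κ, tension σ, excess area A_ex), its *phenotype*
(surface receptor density N_ant, e.g. ICAM1 on endothelium), and the design
of the carrier (radius, ligand count N_ab), how strongly does the carrier
bind, and how does that translate into organ selectivity?

## The model in brief

* **Membrane**: a dynamically triangulated periodic patch (N_m vertices,
  T_m triangles, L_m links; N_m + T_m − L_m = 0 on the torus) with the
  discretized Helfrich energy
  H_m = Σ_v [κ/2 (c₁,ᵥ + c₂,ᵥ)² A_v + σ A_v], self-avoiding through tether
  bounds a₀ ≤ ℓ ≤ √3 a₀, fluid through link flips.
* **Molecules**: mobile receptor rods (length 19 nm, flexural energy
  H_f = κ_f θ²/2) on the membrane; rigid radial ligand rods (15 nm) on a
  spherical NC (radius 50 nm); receptor–ligand Bell bonds
  H_b(d) = H₀ + κ_b (d − d*)²/2 for tip–tip distances d ≤ d*.
* **Sampling**: a seven-move Metropolis engine (vertex moves, link flips,
  NC translation/rotation, receptor diffusion, and Rosenbluth /
  configurational-bias receptor flexure and bond moves).
* **Analysis**: Monge-gauge height spectra fitted to
  ⟨|h_q|²⟩ = k_BT / [A_p (κq⁴ + σq²)] for (renormalized) κ and σ,
  including a mean-field cytoskeletal-pinning workflow; umbrella sampling
  along the NC–membrane separation ΔR with WHAM reconstruction and
  thermodynamic-integration anchoring of the potential of mean force
  W(ΔR); and the absolute multivalent association constant
  K_a = C(N_ant, n_b) C(N_ab, n_b) · (ΔφΔθΔψ / 8π²) ·
  (A_R^b / A_R^u)^{n_b} · A_N^b / (L_z (L_z − r*)) · ∫₀^{r*} e^{−βW} dr,
  assembled from multivalency statistics, entropy estimators and the
  anchored PMF.
* **Pharmacokinetics**: per-organ uptake scores combining non-targeted
  partitioning (K_p) with targeted capture (K_EC, optionally K_M),
  reported as η = %idg / %idg_lung with bootstrap r² statistics against
  experiment and a no-targeting null model.

See the methods vignette (`vignettes/ncavidity-methods.Rmd`) for the full
account of estimators, numerical choices and limitations.

## Worked example

A single receptor under a single downward ligand, with the bond depth set
to 2 k_BT so the two-state occupancy is informative, sampled with the
Rosenbluth flexure/bond moves and compared against exact quadrature:

```r
library(ncavidity)
params <- load_config(overrides = list(bond = list(H0_J = kBT_to_joule(-2))))
round(c(H0_kBT = params$bond$H0, kappa_f = params$receptor$kappa_f), 2)
#>  H0_kBT kappa_f
#>   -2.00 1690.03

mesh <- flat_patch(120, a0 = 10)
mesh_counts(mesh)
#>  N_m   T_m   L_m euler
#>  144   288   432     0

sys <- build_system(mesh, params, nc = TRUE, n_receptors = 1, seed = 3,
                    ligand_dirs = matrix(c(0, 0, -1), 1),
                    nc_center = c(60, 60, 19.5 + 65))
sys$receptors$vertex <- which.min(colSums((t(mesh$vertices[, 1:2]) - 60)^2))
run <- run_simulation(sys, sim_config(steps = 5e5, burnin = 5e4,
    record_every = 5, seed = 8, move_weights = c(0, 0, 0, 0, 0, 2/7, 5/7),
    tune = FALSE))
c(measured = mean(run$trajectory$n_b),
  exact = toy_binding_system(params, tip_height = 19.5)$p_bound_exact)
#>  measured     exact
#> 0.3693889 0.3703227
```

The measured bound fraction (0.369) agrees with the configurational
quadrature oracle (0.370) within its statistical error — the Rosenbluth
bond move samples the correct equilibrium.

Organ-level targeting from per-organ contexts (K_p and K_EC here are
illustrative; the shipped defaults mark figure-only quantities as
`user-must-supply`):

```r
ctx <- default_organ_table()
ctx$Kp   <- c(2, 20, 3, 1.5, 15)
ctx$K_EC <- c(5e3, 1e2, 4e2, 10, 2e2)
ctx$dK_EC <- 0.2 * ctx$K_EC
eta_with_uncertainty(ctx)
#>    organ     idg         eta      eta_lo      eta_hi
#> 1   lung 7600.00 1.000000000 0.800000000 1.200000000
#> 2  liver  170.00 0.022368421 0.017894737 0.026842105
#> 3 kidney  612.00 0.080526316 0.064421053 0.096631579
#> 4  heart   15.15 0.001993421 0.001594737 0.002392105
#> 5 spleen  330.00 0.043421053 0.034736842 0.052105263
```

η is normalized to the lung (η_lung = 1 exactly) and is independent of the
arbitrary perfusion scales; the band comes from evaluating the scores at
K_EC ± ΔK_EC.

A thin command-line interface wraps the same functions
(`inst/cli/ncavidity`): subcommands `fixtures`, `simulate`, `spectrum`,
`pmf`, `wham`, `avidity` and `pk`, each writing a JSON run manifest next
to its outputs.

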