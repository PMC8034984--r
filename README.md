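# rigidISF

Rigid-body coherent intermediate scattering functions and the accuracy of
the translation–rotation decoupling approximation, for people interpreting
Neutron Spin Echo (NSE) data on anisotropic proteins — monoclonal
antibodies in particular.

NSE measures the normalized coherent ISF, `I(Q,t)/I(Q,0)`, which for a
protein in dilute solution mixes centre-of-mass translation, rotation and
internal motion. Internal motions are usually extracted by subtracting a
rigid-body reference built on the assumption that translation and rotation
decouple:

    I(Q,t)/I(Q,0) ≈ I_com(Q,t) · I_rot(Q,t)
    D_total(Q) ≈ D_com + D_rot(Q)                (centre-of-mass variant)
    D_total(Q) ≈ D_trans(Q) + D_rot(Q),          (structure-weighted variant)
    D_trans(Q) = ⟨|F(QQ̂)|² (Q̂·D_tt·Q̂)⟩_Q̂ / P(Q)

For a Y-shaped ~10 nm particle these are approximations, and since internal
signals are only ~10% of `D_eff(Q)`, their error matters. This package:

* builds rigid one-bead-per-residue models from PDB files
  (`coarse_grain_pdb`) or synthetically (`make_synthetic_mab`,
  `make_spherical_shell`), with Debye form factors (`form_factor`) and
  rigid-body bead-model diffusion tensors (`estimate_diffusion_tensor`:
  Rotne–Prager–Yamakawa friction-supermatrix projection, Kirkwood variant
  included);
* generates thermally driven rigid-body trajectories with a DPD fluid
  (`run_dpd`), an overdamped anisotropic Brownian surrogate (`run_bd`), and
  an inertial Langevin point particle (`run_langevin_point`);
* computes the total, centre-of-mass, rotational and structure-weighted
  translational coherent ISFs from trajectories by the orientationally
  averaged pair sum with the sinc kernel (`isf_total`, `isf_com`,
  `isf_rot`, `isf_trans_weighted`);
* extracts short-time effective diffusion coefficients
  `D_eff(Q) = −(1/Q²) d ln I/dt` (`extract_deff`), evaluates `D_trans(Q)`
  by deterministic spherical quadrature (`dtrans_theoretical`), fits the
  Langevin MSD for the momentum relaxation time (`fit_langevin_msd`), and
  quantifies both decoupling errors with replicate spreads
  (`compare_decoupling`, `run_study`).

## Worked example

Build the synthetic antibody (three lobes, ~100 Å across), give it its
bead-model diffusion tensor scaled to `D0 = 3.7 Å²/ns` (a mAb in a
D2O-based buffer), run one Brownian trajectory and compare the decoupling
approximations:

```r
library(rigidISF)
mab <- make_synthetic_mab(beads_per_lobe = 50)
mab
#> rigid_body_model 'synthetic mAb': 150 beads, diameter 96.1 A, Rg 36.4 A
D <- estimate_diffusion_tensor(mab, D0 = 3.7)
D
#> diffusion_tensor (body frame): D0 = tr(tt)/3 = 3.7, Dr = tr(rr)/3 = 0.001392

tr <- run_bd(mab, D, dt = 1, n_steps = 30000, seed = 101)   # 30 us, ~70 tau_c
curves <- isf_all(tr, mab, Q = c(0.01, 0.05, 0.1, 0.2),
                  lags = c(0, 2, 4, 6, 8, 10), origin_stride = 40)
deff <- extract_deff(curves, fit_window = c(2, 10))
subset(deff, Q == 0.1)
#>  component   Q   Deff     se n_pts
#>        com 0.1 3.8249 0.0482     5
#>        rot 0.1 1.1885 0.0098     5
#>      total 0.1 5.0242 0.0403     5
#>      trans 0.1 3.8250 0.0461     5
compare_decoupling(deff)
#> decoupling report (1 seed):
#>   com+rot    max |err| =  3.15% (signed +3.15%) at Q = 0.2
#>   trans+rot  max |err| =  2.99% (signed +2.99%) at Q = 0.2
```

Reading the numbers: at `Q = 0.1 Å⁻¹` the directly measured total
short-time coefficient (5.02 Å²/ns) already has a large rotational
contribution (1.19 Å²/ns); summing the separately measured parts
overestimates the direct measurement by a few percent, a bias that three
replicate seeds (see `run_study`) resolve cleanly and that shrinks at
small Q. The deterministic quadrature shows how the structure weighting
shifts the translational coefficient away from the isotropic `D0`:

```r
dtrans_theoretical(mab, D, Q = c(0.05, 0.07, 0.1))
#>     Q   Dtrans
#>  0.05 3.649721
#>  0.07 3.600550
#>  0.10 3.689815
```

The dip (−2.7% at `Q ≈ 0.07 ≈ 2π/96 Å⁻¹`) sits at the length scale of the
particle diameter. `run_study(study_config(...))` packages the whole
pipeline — replicate trajectories, all ISF components, MSD, Deff curves,
the decoupling report and a provenance manifest — into one call.

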