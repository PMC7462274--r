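# scaffoldlab

Morphology, stiffness and permeability of TPMS and strut-based bone
scaffolds, computed from their implicit unit-cell equations.

Porous scaffolds for bone repair are designed around a repeating unit cell
— commonly a triply periodic minimal surface (TPMS) such as the Gyroid,
Diamond, Schwarz P, Fischer-Koch S or F-RD, or a strut lattice (Cube,
FD-Cube, Octa). Which topology to choose depends on three property groups,
and `scaffoldlab` computes all of them for an ideal unit cell, with no
external data or meshing tools:

* **Morphology** — porosity `phi` and surface-to-volume ratio `S/V`
  (iso-surface area by marching tetrahedra / nominal cell volume), plus the
  quadratic regression `S/V = a2 phi^2 + a1 phi + a0`.
* **Effective elasticity** — voxel-based periodic homogenization of the
  two-phase cell (Ti-6Al-4V solid, E = 110 GPa, nu = 0.34; soft void
  filler, 1 MPa, nu = 0.45) with trilinear hexahedral elements and exact
  rank-1 laminate stiffness in interface voxels. Cubic symmetry gives the
  engineering moduli `E_e = (C11 - C12)(C11 + 2 C12)/(C11 + C12)` and
  `G_e = C44`, normalized as `E_c = E_e / E_Ti`, `G_s = G_e / G_Ti`.
* **Permeability** — steady Stokes flow of water (mu = 0.001 Pa s,
  superficial inlet velocity 0.1 mm/s) through the tiled void domain on a
  staggered grid with no-slip walls, post-processed with Darcy's law
  `k = Q mu L / (A dP)`, alongside the Kozeny-Carman estimate
  `k* = phi^3 / (2 s^2)`.

The scaling laws used in scaffold design are fitted as classed model
objects with the usual methods (`print`, `coef`, `predict`, `residuals`,
`plot`): the Gibson-Ashby modulus-density law `E* = C1 rho^n + E0` with
bending/stretching classification (`fit_gibson_ashby`, `classify_mode`),
the S/V quadratic (`fit_sv_quadratic`), permeability-porosity model
families (`fit_permeability_model`) and the shear-compression line
(`fit_linear_relation`). `run_study()` sweeps topologies x porosities
through the whole pipeline deterministically and writes CSV/JSON reports;
`inst/cli/scaffoldlab` wraps the package for shell use; `export_geometry()`
writes STL / legacy VTK.

## Worked example

Characterize a Gyroid cell calibrated to 51% porosity (2.5 mm edge):

```r
library(scaffoldlab)

cell <- unit_cell("Gyroid", porosity = 0.51, resolution = 64)
measure_morphology(cell, resolution = 128)
#> porosity 0.5116 | surface 19.3207 mm^2 | S/V 1.2365 mm^-1 | volume 15.6250 mm^3

ct <- homogenize(voxelize(cell, fill = TRUE), phase_materials(),
                 loads = c("xx", "xy"))
ct
#> Effective elasticity tensor (GPa, cubic accessors):
#>   C11 = 28.868  C12 = 12.026  C44 = 10.906
#>   porosity 0.5103, resolution 64^3, cubic residual 5.21e-14
#>   CG iterations per load: 191, 208
effective_moduli(ct)
#> E_e = 21.795 GPa (E_c = 0.19813)
#> G_e = 10.906 GPa (G_s = 0.2657)

flow <- solve_flow(tile(voxelize(cell, resolution = 24), 2))
flow
#> Darcy permeability k = 9.995e-09 m^2
#>   Q = 2.5e-09 m^3/s, dP = 0.05003 Pa over L = 0.005 m (A = 2.5e-05 m^2)
#>   percolating void fraction 0.5104; 53 outer CG iterations
```

Reading the numbers: the cell offers 1.24 mm^2 of attachment surface per
mm^3; its effective compressive modulus, 21.8 GPa, sits in the cortical-
bone range (the published finite-element reference for this cell is
21.59 GPa, within 1%); and a permeability of 1.0e-8 m^2 is at the upper
end of the range reported for trabecular-bone-scale scaffolds, consistent
with the Gyroid's open, connected pores. The Kozeny-Carman estimate for
the same cell, `kozeny_carman(0.5116, 1.2365)` = 4.4e-8 m^2, bounds the
computed value from above, as it does for every topology here.

A full study (all eight topologies, the default five-porosity ladder):

```r
study <- run_study(study_config(output_dir = "reports"))
study$fits$Gyroid$gibson_ashby
study$ranks
```

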