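# ngeni

Coarse-grained generation of protein conformational transition pathways by
**normal mode-guided elastic network interpolation (NGENI)**, with the
conventional elastic network interpolation (ENI) as baseline and
cross-check.

Crystallography and cryo-EM capture proteins in discrete end states — an
open and a closed adenylate kinase, an open and a closed chaperonin ring —
but not the transition between them. Morphing methods bridge the gap by
interpolating between the two end-point structures. `ngeni` is for
structural biologists and method developers who want such pathways from
nothing more than two Cα coordinate sets, with every intermediate
constrained to the physically meaningful collective motions of an elastic
network model.

## The method

A protein with residues at Cα positions `{x_i}` is modeled as an elastic
network: residue pairs within a cutoff (default 12 Å) are joined by
identical Hookean springs with binary linking matrix `k_ij`. The target
distance of every spring at interpolation coordinate α ∈ [0, 1] is

    l_ij(α) = (1 − α) ‖x_i − x_j‖ + α ‖y_i − y_j‖,

between the start distances (`{x_i}`) and the end distances (`{y_i}`).
Each iteration step k of s sets α = k/s and displaces every residue along
a linear combination of the m lowest normal modes of the *current*
intermediate,

    δ_i = V_i C_w,          V_i = [v_i,1 … v_i,m],

choosing the weighting constants `C_w` to minimize the distance-mismatch
cost

    C(C_w) = ½ Σ_ij k_ij ( ‖x_i + V_i C_w − x_j − V_j C_w‖ − l_ij )².

A second-order Taylor expansion of the cost gives a quadratic form
`½ C_wᵀ Λ⁽¹⁾ C_w + ½ Λ⁽²⁾ C_w + Λ⁽³⁾` whose stationarity condition
`Λ⁽¹⁾ C_w + ½ (Λ⁽²⁾)ᵀ = 0` is solved at every step (with a trust-region
guard on the expansion's small-displacement validity region). The number
of steps follows s = round(10 × end-to-end RMSD), so consecutive
intermediates are ~0.1 Å apart.

With the full mode basis (m = 3n − 6) this is the conventional ENI in a
different basis, and the package's direct Cartesian ENI solver reproduces
it to solver precision — the built-in correctness oracle. With m = 30
("optimum" NGENI) the search space shrinks to the lowest collective
motions, cost per step drops from O(n²) to O(n m²), and the pathway still
converges below typical experimental resolution because large functional
transitions are dominated by a few collective modes.

## Worked example

Everything below runs on a bundled synthetic fixture — two compact
64-bead domains joined by a flexible 3-bead neck, with the second domain
rotated by 80° in the end state — so no structure download is needed:

```r
library(ngeni)

pair <- make_pair(fixture_spec("hinge"))
#> <structure_pair hinge-n128-start -> hinge-n128-end: n = 128, resolution = NA A>

full <- run_ngeni(pair, modes = "full")
#> <transition_pathway [ngeni]: 43 conformations, n = 128, final residual 0.0000 A>
opt <- run_ngeni(pair, modes = 30)
#> <transition_pathway [ngeni]: 43 conformations, n = 128, final residual 0.2669 A>

compare_pathways(opt, run_eni(pair))
#> <pathway_comparison: 43 steps, average RMSD 0.2229 A, max 0.3485 A>

profile_correlation(mode_profile(full), mode_profile(opt), 30)
#> [1] 0.997747
bond_geometry(opt)$max_bond_dev
#> [1] 0.01755306
```

Reading the numbers: the end-to-end RMSD is 4.2 Å, so the schedule takes
s = 42 steps (43 conformations including the start). The full-mode run
reaches the end structure exactly (residual ~1e-14 Å); the 30-mode run
ends 0.27 Å away — well below a typical 2 Å crystallographic resolution,
the method's convergence condition. Its pathway deviates from the
conventional ENI pathway by 0.22 Å on average, the per-mode weighting
profile of the 30-mode run correlates at 0.998 with the full run over the
first 30 modes, and the mean Cα–Cα pseudo-bond length never drifts more
than 0.018 Å from its end-point value: the intermediates stay
geometrically realistic.

Real structures go through the same interface:

```r
pair <- pair_structures(read_calpha("4ake.pdb", chains = "A"),
                        read_calpha("1ake.pdb", chains = "A"),
                        resolution = 2.0)
pw <- run_ngeni(pair, modes = 30)
write_pathway(pw, "adk_pathway.pdb")     # multi-model PDB trajectory
write_metrics_csv(pw, "adk_metrics.csv", weights = TRUE)
```

Command-line wrappers live in `inst/cli/`:

```sh
Rscript inst/cli/ngeni_pathway.R start.pdb end.pdb --modes 30 --output-prefix run
Rscript inst/cli/ngeni_sweep.R start.pdb end.pdb --modes-list 5,10,20,30,full --resolution 2.0
```

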