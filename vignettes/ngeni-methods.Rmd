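---
title: "Normal mode-guided elastic network interpolation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normal mode-guided elastic network interpolation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`ngeni` generates coarse-grained transition pathways between two known
end-point conformations of a protein. The representation is one bead per
residue at the Cα position; the physics is an elastic network model
(ENM): residue pairs closer than a cutoff are joined by identical
Hookean springs.

Two networks play different roles and deliberately follow different
contact rules:

* **Normal-mode network** — contacts of the *current* intermediate,
  rebuilt at every iteration. Its 3n × 3n stiffness matrix (per-spring
  super-element $dd^T/\lVert d\rVert^2$, uniform spring constant 1) is
  symmetric positive semidefinite with exactly six zero modes (rigid
  translations and rotations) when connected; the m lowest non-rigid
  eigenvectors form the step's search basis.
* **Cost network** — the union of contacts present in *either* end
  point, held fixed along the pathway. Only this rule guarantees that
  every spring has a defined distance in both end structures, so the
  per-spring target
  $l_{ij}(\alpha) = (1-\alpha)\lVert x_i - x_j\rVert + \alpha\lVert y_i - y_j\rVert$
  is always well posed. Whether the cost network should instead be
  rebuilt per iteration is genuinely open; the fixed union rule is the
  package's documented choice because it keeps the objective a single
  continuously deformed function of $\alpha$.

Each step displaces residue $i$ by $\delta_i = V_i C_w$, a linear
combination of the current modes, with the weighting constants chosen to
minimize the distance-mismatch cost
$C = \tfrac12\sum_{ij} k_{ij}\,(\lVert x_i + \delta_i - x_j - \delta_j\rVert - l_{ij})^2$.
A second-order Taylor expansion in the displacement yields a quadratic
model $\tfrac12 C_w^T\Lambda^{(1)}C_w + \tfrac12\Lambda^{(2)}C_w +
\Lambda^{(3)}$, assembled per spring from the transverse projector
$A(x) = E_3 - xx^T/\lVert x\rVert^2$. The constant term is defined here
as the exact cost at zero displacement,
$\Lambda^{(3)} = \tfrac12\sum k_{ij}(r_{ij}-l_{ij})^2$, which makes the
model's value, gradient and the exact cost mutually consistent (the
package's tests verify the gradient against central finite differences
of the exact cost and the zero-displacement identity exactly).

## The iteration schedule

The step count is $s = \mathrm{round}(10\times\mathrm{RMSD})$ of the end
points, giving intermediates about 0.1 Å apart. The scale factor is
$\alpha = k/s$ for $k = 1,\dots,s$: the final step is *driven* at
$\alpha = 1$, so the pathway terminus is the computed conformation whose
spring lengths match the end structure's — not the verbatim end
coordinates. With the full mode basis the terminus coincides with the
end structure to solver precision (~1e-14 Å on the shipped fixtures);
with a truncated basis the remaining residual is the method's
convergence figure, compared against the pair's experimental resolution
by `convergence_check()`. RMSD is Cα-only, mass-unweighted, after
optimal (Kabsch) superposition, everywhere in the package; intermediates
are re-superposed before every reported RMSD, while raw coordinates are
propagated untouched (mode bases exclude rigid directions, so drift is
negligible; superposition only makes the reported curves comparable).

## Solving for the weights

The stationarity condition $\Lambda^{(1)}C_w = -\tfrac12(\Lambda^{(2)})^T$
is solved by symmetric eigendecomposition. Two numerical guards wrap the
bare solve; both matter in practice and both are the package's own
choices:

* **Degeneracy policy.** Eigenvalues below 1e-12 of the spectral radius
  — and all non-positive curvature directions — are excluded from the
  inverse (a pseudo-inverse solve, logged via `message()`).
* **Trust region.** The quadratic model is a small-displacement
  expansion; when its stationary point lies outside a displacement norm
  of $0.15\sqrt{n}$ Å (1.5× the nominal 0.1 Å-per-step schedule), the
  Levenberg–Marquardt-regularized solution on that boundary is used
  instead. Without this, an ill-conditioned $\Lambda^{(1)}$ occasionally
  produces steps far outside the expansion's validity, with exactly the
  catastrophic cost increases the quadratic model cannot see.

Each iteration may apply up to `refine = 6` such solves, re-expanding
the quadratic about the partially displaced conformation with the same
mode basis, accepting only exact-cost-decreasing iterates within a
shared displacement budget. The first inner iterate is the plain
single-solve scheme, which `refine = 1` recovers. An optional
`safeguard` additionally halves any step that still increases the exact
cost (off by default: the bare iteration is the reference behavior).

## The ENI baseline and the equivalence oracle

The conventional ENI solves the same per-step quadratic over all 3n
Cartesian degrees of freedom with the six rigid-body directions
projected out — no mode truncation. Because the full non-rigid mode
basis spans exactly that subspace, full-mode NGENI and ENI are the same
minimization in different bases; the package exploits this as a
correctness oracle (`compare_pathways()` average RMSD below 1e-13 Å on
all shipped fixture kinds). The ENI solver is projected
Jacobi-preconditioned conjugate gradients on the sparse cost matrix;
when CG detects indefiniteness or non-convergence, or the solution
leaves the trust region, it falls back to the *identical*
eigendecomposition-based policy as the mode-space solve, applied in the
Cartesian basis. The fallback is what keeps the two routes equivalent
even on stressed steps where the minimizer is not unique.

## Eigensolvers

`compute_modes()` uses a dense symmetric eigendecomposition for small
problems (3n ≤ 600, or when nearly all modes are requested) and a
sparse shift-invert Lanczos iteration (ARPACK, with a sparse Cholesky
factorization of $H + \sigma I$, $\sigma$ = 1e-6 of the Gershgorin
bound) otherwise. The number of eigenvalues below 1e-8 of the spectral
scale is hard-checked to be exactly six — a violated check means the
structure contains an under-braced sub-framework (a first-order
mechanism) and the model's premises do not hold. Eigenvector signs are
fixed by making each mode's largest-magnitude component positive, so
runs are bit-reproducible across solvers; mode-contribution profiles
additionally use $|c_k|$ averages, making them invariant to the
residual sign ambiguity (how signs were handled upstream of published
weighting-constant plots is unknowable, so correlations are computed on
absolute profiles).

## What the synthetic fixtures emulate — and what they do not

`make_pair()` builds two-conformation pairs from a deterministic
geometry: two compact serpentine lattice domains (consecutive beads
exactly 3.8 Å apart, densely 3D-connected under the 12 Å cutoff) joined
by a three-bead non-collinear neck that keeps the domain faces beyond
the cutoff. This reproduces the structural logic of two-domain hinge
proteins: internally stiff domains, a soft inter-domain rotation as the
lowest normal mode, and a dense contact map that pins conformations to
their distance sets. Hinge and twist motions rotate the second domain
rigidly about the neck (preserving every pseudo-bond); shear slides it
with the displacement ramped across the neck; random-perturb adds
seeded Gaussian jitter (default s.d. 0.35 Å, inside the elastic
regime).

Design history worth knowing: a plain helical chain — the obvious
simpler fixture — is quasi-one-dimensional, so its distance sets
under-determine the conformation and a hinge kink spreads over many
modes; truncated-mode runs then plateau around 1–3 Å. That behavior is
informative (it mirrors the non-converged entries reported for real
proteins at small m) but it is not the regime the 30-mode default is
designed for. The shipped domain fixture is the realistic analogue of
the proteins the method targets.

What passing tests on these fixtures do **not** show: performance on
real proteins with irregular packing densities, chain breaks, or
residue-numbering mismatches; behavior when the two end states differ
by internal rearrangements rather than rigid sub-motions; and any
thermodynamic meaning of the intermediates (the pathway is a geometric
morph, not a minimum-energy path).

The `domain_width` parameter (4 = globular default; 2 = slender)
exists because complexity experiments need a family with
size-independent per-residue contact counts: the scaling tests run
slender fixtures at n ∈ {50, 100, 200} under the automatic schedule and
fit log–log slopes of per-step operation counters (Lanczos operator
applications × matrix/factor nonzeros plus assembly flops for NGENI;
CG iterations × matrix nonzeros for ENI), observing ~n¹ for 30-mode
NGENI and ~n² for ENI.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `cutoff` | 12 Å | contact distance for both network rules; the common Cα-ENM choice. Results at truncated m are topology-sensitive, so this is surfaced everywhere |
| `modes` | 30 | mode count of the truncated basis; 30 is the count at which convergence below experimental resolution is typically reached, and `"full"` (3n − 6) reproduces ENI |
| `steps` | `"auto"` | round(10 × end-to-end RMSD), ~0.1 Å per step |
| `refine` | 6 | maximum inner quadratic solves per step; 1 = bare scheme |
| `safeguard` | off | halve steps that increase the exact cost (max 5 halvings) |
| spring constant | 1 | uniform and dimensionless; only ratios of eigenvalues matter to the pathway |

Degenerate inputs are rejected loudly rather than repaired: fewer than
three common residues, disconnected networks (with component sizes
named), coincident bonded beads, more or fewer than six rigid modes,
non-finite coordinates.

## Problem sizes in the shipped tests

The test suite runs entirely on generated fixtures: unit tests on 10-
and 20-bead pairs, equivalence and metric checks on 20–128 beads,
scaling on 50–200 beads. The full suite takes about a minute on one
CPU. The benchmark table bundled in `inst/extdata/benchmark_pairs.csv`
records published end-to-end RMSDs and resolutions for nine two-state
proteins; it feeds the iteration-count rule and gives real-data
defaults for `pair_structures(resolution = )`, but no external
structure files are bundled or downloaded.

## Known limitations

* Truncated-mode convergence depends on how collective the transition
  is; motions with substantial localized (high-mode) content accumulate
  residual error, and the monotone-approach invariant can be violated by
  small plateau oscillations (flagged with a warning and
  `monotone = FALSE`, never silently accepted).
* Interpolated distance sets are generally not exactly embeddable;
  on strongly stressed steps the quadratic model is indefinite and the
  computed pathway depends on the documented degeneracy policy.
* Spring constants are uniform; distance- or sequence-weighted variants
  and rigid-cluster decompositions are out of scope.
* All-atom detail, side chains, and energetics are outside the model:
  intermediates are Cα traces satisfying distance constraints.
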