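---
title: "Models and methods behind epduq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind epduq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The physical model

During the ST segment of the cardiac cycle the tissue is electrically
passive, and the extracellular potential $\phi_e$ in a slab of ventricular
myocardium obeys the passive bidomain equation

$$\nabla\cdot(\mathbf M_i + \mathbf M_e)\nabla\phi_e
  = -\nabla\cdot \mathbf M_i \nabla\phi_m,$$

where $\mathbf M_p = \mathbf A\,\mathrm{diag}(g_{pl}, g_{pt}, g_{pn})\,
\mathbf A^T$ ($p = i, e$) are the intracellular/extracellular conductivity
tensors, $\mathbf A$ rotates the fibre frame into global coordinates, and
$\phi_m$ is a prescribed transmembrane potential.  The slab is
16 cm x 16 cm x 1 cm with the epicardium at $z = 0$; a 25 cm blood mass
($\nabla^2\phi_b = 0$, conductivity $g_b$) lies beneath the endocardium.
Side walls and the epicardium are insulated, $\phi_b = 0$ at the bottom of
the blood, and potential and current are continuous across the endocardium.
Fibres lie in the $x$--$y$ plane, along $x$ on the epicardium, rotating
linearly with depth by a total angle ROT at the endocardium; sheets remain
parallel to the epicardium, so the tensors have an $xy$ cross term but no
$xz/yz$ coupling.

Subendocardial ischaemia enters through the separable plateau source

$$\phi_m(x,y,z) = \Delta\phi_p\,\Psi(x)\,\Psi(y)\,\Psi(1-z),$$

with $\Delta\phi_p = -30$ mV, footprint half-widths $a_x = a_y = 2$ cm, the
$z$ half-width equal to the ischaemic depth (a fraction of the 1 cm wall,
measured from the endocardium), and border-zone steepness
$\lambda = 0.01$ cm in every direction, i.e. a sharp, ~1 mm interface.
`psi()` evaluates the profile in a rearranged form because the textbook
$\sinh/\cosh$ expressions overflow at $a/\lambda = 200$.

The epicardial potential distribution (EPD) is the $z = 0$ slice of the
solution.  Its scalar features are the central extrema cminV/cmaxV (over
the footprint $|x|,|y| \le 2$), the outside minimum ominV, the orientation
of the depression pattern (ellipse angle), and the angles angmin/angmax
from the origin to the outside minimum / maximum in the upper half-plane.
EPDs are classified as ST depression type 1 ($c_{minV} \le o_{minV} < 0$),
type 2 ($o_{minV} < c_{minV} < 0$) or ST elevation ($c_{maxV} > 0$).

# Discretization

The operator is assembled on tensor-product hexahedral meshes by a
symmetric Galerkin scheme on trilinear elements.  The three diagonal
tensor contributions use reduced edge-midpoint quadrature, which collapses
to the classic 7-point vertex-centred finite-volume flux stencil for
diagonal tensors on uniform grids; the $xy$ cross term arising from fibre
rotation is integrated exactly.  Both pieces discretize the same symmetric
bilinear form $\int \nabla v \cdot \mathbf M \nabla u$, and because the
reduced rule over-integrates the diagonal part, the assembled operator is
symmetric positive definite after the bottom Dirichlet row is eliminated.
The right-hand side applies the identical bilinear form (intracellular
tensor only, tissue cells only) to the nodal $\phi_m$, so the source flux
is suppressed across insulated boundaries together with the diffusive
flux, and the intracellular contribution at the endocardium is retained on
the tissue side and balanced against the blood flux.  Manufactured
solutions (diagonal and full tensors) converge at second order; see
`test-solver.R`.

Systems are solved by sparse supernodal Cholesky factorization (CHOLMOD
via Matrix), the appropriate direct method at the mesh sizes used here; a
Jacobi-preconditioned conjugate-gradient path exists for meshes too large
to factor.

## Meshes

Nodes are clustered around the ischaemic border ($x, y = \pm 2$ cm,
geometric grading, a node pinned exactly at the border) and the blood is
stretched geometrically away from the endocardium.  Tissue $z$ spacing is
uniform with a layer count divisible by 10 so that decile ischaemic depths
place the sharp source border exactly on a node plane; misaligned borders
otherwise quantize the effective depth.  Presets:

| preset | x,y cells | tissue z | blood z | nodes | role |
|--------|-----------|----------|---------|-------|------|
| mini   | 16 | 10 | 6  | ~4.9k  | unit tests |
| small  | 24 | 10 | 8  | ~11.9k | emulation studies |
| medium | 32 | 10 | 16 | ~28k   | classification study |
| coarse | 32 | 20 | 12 | ~35.9k | collocation sweeps |
| full   | 60 | 50 | 50 | ~376k  | full-resolution replication |

The full preset reproduces the reference resolution (360,000 hexahedral
volumes, ~2.7 mm average in-plane spacing, 0.2 mm tissue z spacing) and is
exposed for completeness; the desk-scale studies below use the smaller
presets.  A convergence sweep (single runs at mean parameters) gave cminV
at 10% depth of -1.351 / -1.335 / -1.327 / -1.322 mV at 24 / 32 /
40 / 48 in-plane cells, and cmaxV at 60% of 1.043 / 1.112 / 1.122 / 1.124
mV, so the 32-cell presets are within ~0.02 mV of the resolved values
while the 24-cell preset carries a few-hundredths bias toward shallower
extrema.  That bias matters most for the classification-fraction study
(the class boundaries are potential signs/orderings), which therefore uses
the medium preset; a convergence probe of the class fractions also showed
sensitivity to the blood-mass resolution (the geometrically stretched
return path through the blood), so the medium preset carries 16 blood
layers where the other desk presets use 6-12.

# Uncertainty quantification

**Sampling ranges.**  The eight varied inputs are fibre rotation
(60/100/140 degrees), blood conductivity (3.25/6.5/9.75 mS/cm) and the six
bidomain conductivities at mean +/- 50%: g_il, g_el 1.2/2.4/3.6; g_it
0.12/0.24/0.36; g_et 0.8/1.6/2.4; g_in 0.05/0.1/0.15; g_en 0.5/1.0/1.5
(all mS/cm).  Inputs are normalized to $[0,1]$ linearly; designs are plain
seeded stratified-random Latin hypercubes (`lhs::randomLHS`), matching the
stated design type without a maximin criterion, whose use is not
documented for the original study.

**Stochastic collocation.**  Uncertainty in the six conductivities is
propagated with Smolyak sparse grids of nested Clenshaw-Curtis points
(1-D growth 1, 3, 5, 9, ...), the only standard rule family whose level-2
and level-3 grids in six dimensions contain 85 and 389 nodes.  Mean and
standard-deviation EPD fields are the weighted sums
$\bar\phi = \sum_j w_j \phi^{(j)}$ and
$(\sum_j w_j(\phi^{(j)} - \bar\phi)^2)^{1/2}$; tiny negative variance
accumulations (possible because Smolyak weights may be negative) are
clipped to zero before the square root.  Level agreement is scored by the
Pearson correlation and the relative error $\|a-b\|_2/\|a\|_2$ between
mean EPDs; the source of the original relative-error definition is not
reprinted there, so the metric is documented here and kept configurable.

**Gaussian-process emulation.**  Scalar features are emulated with a
squared-exponential kernel (independent per-dimension length-scales), a
linear mean basis $h(x) = (1, x)$, and hyperparameters by maximum marginal
likelihood with 5 seeded restarts (the reference software's estimation
method is not reprinted; MLE with restarts is the standard contract).  The
nugget is estimated jointly with the length-scales (bounded within
$[10^{-8}, 0.5]$): although the simulator is deterministic, the extracted
features carry mesh-scale extraction noise, and with a fixed $10^{-8}$
nugget the emulator is overconfident — Mahalanobis validation rejects it
on the potential outputs.  A fixed-nugget mode
(`estimate_nugget = FALSE`, with tenfold escalation on Cholesky
failure) is retained.  90% of runs train, 10% validate via the
Mahalanobis distance $D = r^T C^{-1} r$ under the Student-t predictive
covariance, compared with a reference distribution of mean $m$ (the test
size) and variance $2m(m+n-q-2)/(n-q-4)$; the emulator is then refit on
all points with the verdict frozen.  Main effects $E\{f|x_w\}$ (others
$N(0.5, 0.04)$) and main-effect indices
$\mathrm{Var}[E\{f|x_w\}]/\mathrm{Var}[f]$ (all inputs $N(0.5, 0.02)$) use
closed-form Gaussian-kernel integrals — the normals are not truncated to
$[0,1]$, consistent with treating +/-0.2 sd as good coverage of the unit
interval — and the closed forms are unit-tested against Monte Carlo.
Indices are computed by default as posterior expectations under the fitted
GP (numerator and denominator include the emulator's predictive
variance/covariance contributions, the convention of probabilistic
sensitivity analysis of emulated simulators); a plug-in variant using the
posterior mean alone is available and, on the well-fitted emulators here,
differs by under a percent.

**PLS.**  Outputs are also regressed on standardized inputs (and on seven
conductivity ratios) by NIPALS partial least squares with all
$\min(p, 8)$ components retained, since the original component count is
unstated and full retention makes the fit deterministic and equal to the
least-squares solution in the well-conditioned designs used here.
Coefficients are interpreted only relative to other coefficients of the
same output.  For the two-input angle study, `run_angmin_study()` reports
both the standardized coefficients and the plain input–output
correlations: with near-orthogonal designs the two agree to a few
hundredths, but full-rank coefficients are jointly bounded by $R^2$, so
correlation-type summaries of such studies sit slightly higher.

# Study pipelines and desk-scale sizes

* `run_pc_sweep()` — collocation mean/std EPDs across ischaemic depths at
  fixed ROT and g_b (coarse preset, 85 solves per depth).
* `run_level_compare()` — level-2 vs level-3 mean EPDs at 50% depth,
  ROT 120, g_b 6.7 (small preset; 389 unique solves, nested nodes cached).
* `run_scenario()` — LHC design at the scenario depth (type 1: 10%,
  type 2: 30%, elevation: 60%), classification, truncation to the first
  n_keep rows of the target class in generation order, GP + PLS analysis.
  Desk scale uses 120-200 design points instead of 250-750.
* `run_angmin_study()` — ROT (60-140) and depth (30-80%) co-varied at mean
  conductivities; PLS of angmin on the two standardized inputs (n = 80-100
  instead of 250).

The synthetic-data module supplies an analytic mock simulator with the
same qualitative hooks (class transitions with depth, anticlockwise
rotation with ROT, deepening with g_in) so every downstream stage is
testable in milliseconds; it is not calibrated to physical magnitudes.
Surrogate response functions with closed-form index vectors validate the
emulation stages independently of the solver.

# Numerical choices and degenerate inputs

* Ellipse orientation: principal axis of the area-weighted second moments
  of the region $\{\phi \le 0.5\,c_{minV}\}$.  The fitted contour level of
  the original analysis is unstated; 0.5 is the package default, is
  equivariant under rotation (tested), and the reported angle changes by
  under a degree for levels 0.4-0.6 on solver EPDs.  A near-circular
  region is flagged through the eigenvalue ratio attribute.
* Outside extrema must be strict 8-neighbour local extrema; their
  locations are refined by per-axis quadratic interpolation before the
  angle is computed, which suppresses most of the angle stepping that a
  stepped grid otherwise produces.  Ties between equal extrema break
  toward the smaller angle.  A missing qualifying extremum yields NA (an
  undefined-feature signal), never an error.
* Angles are reported in $[0, 180)$ degrees; the point symmetry
  $\phi(x,y) = \phi(-x,-y)$ of the model makes the upper half-plane
  representative.
* The rotation sign convention (anticlockwise positive, viewed from
  outside the epicardium) was validated against the qualitative behaviour
  it must reproduce: sweeping ROT 60 to 140 degrees rotates the EPD
  anticlockwise and increases angmin.

# What the tests do and do not show

Unit and property tests run the full pipeline on the mock simulator and
surrogates, and the solver itself at mini/small scale; acceptance-style
checks reproduce the study's headline numbers at the desk-scale sizes
above, within documented coarse-mesh tolerances.  They do not exercise
realistic ventricular or torso anatomy, sheet inclination, border zones
wider than ~1 mm, or full-resolution (376k-node) replication of the
coefficient tables — the pipeline supports the latter through
`mesh = "full"` but it is hundreds of large factorizations.  Stochastic
checks (class fractions, emulator indices) are seeded and compared within
sampling error; they validate the machinery, not clinical claims.

# Known limitations

* The exact node-clustering law of the reference mesh is unpublished; only
  its averages and counts are reproducible, and the printed node total is
  internally inconsistent with a tensor-product lattice (the cell count
  and resolutions are matched exactly).
* Whether intracellular current may cross the endocardium is not stated in
  the source description; the standard weak form used here retains the
  intracellular flux on the tissue side.  Alternatives differ only in
  boundary layers.
* The Mahalanobis reference distribution is implemented from the cited
  methodology (mean equal to the test size); its exact family is not
  reprinted in the source.
* Main-effect integrals ignore truncation of the normal input weights to
  $[0,1]$ (consistent with the stated distributions), so indices can shift
  by a few hundredths against a truncated-normal convention.
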