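---
title: "From a single Turing pattern to kinetic parameters: models, features and predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From a single Turing pattern to kinetic parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A reaction–diffusion system whose homogeneous equilibrium is stable for the
reaction alone but destabilised by diffusion at finite wavenumbers (a Turing,
or diffusion-driven, instability) settles into a stationary spatial pattern —
spots, stripes, labyrinths.  The inverse problem addressed by `turingfit` is:
given a **single** observed steady-state pattern, predict the kinetic
parameters that generated it.  The difficulty is that the arrangement of local
structure depends strongly on the (unknown) initial conditions, so raw fields
from the same parameters look very different.  The package therefore (i)
simulates training patterns itself, (ii) replaces each field by an
almost-invariant descriptor — the resistance distance histogram (RDH) — and
(iii) learns the map from descriptors to parameters with kernel methods or
small feedforward networks.

# The kinetic model

The shipped kinetics are the dimensionless two-species Gierer–Meinhardt
activator–inhibitor model

$$
f(u) = \begin{pmatrix}
a - b\,u_1 + \dfrac{u_1^2}{u_2\,(1 + c\,u_1^2)} \\[4pt]
u_1^2 - u_2
\end{pmatrix},
\qquad
D = s \begin{pmatrix} 1 & 0 \\ 0 & \delta \end{pmatrix},
$$

with basal production $a$, degradation $b$, saturation $c$, diffusion ratio
$\delta$ and an overall diffusion scale $s$ that sets the pattern wavelength
without affecting whether an instability exists.  The homogeneous equilibrium
satisfies $u_2^* = (u_1^*)^2$ with $u_1^*$ the unique positive root of the
strictly decreasing scalar function $a - b u_1 + 1/(1 + c u_1^2)$; we bracket
it on $(0, (1+a)/b + 10]$ — the $c = 0$ root bounds the general one because
the saturating term never exceeds $1$ — and solve with Brent's method.

Linearising around $u^*$ with a plane-wave perturbation gives the dispersion
relation: the eigenvalue real parts of $J(u^*) - \lVert q\rVert^2 D$ as a
function of the squared wavenumber.  The instability test checks that (i) all
real parts are negative at $q = 0$, (ii) some finite $q^2$ has a positive
real part, and (iii) short wavelengths are damped again.  For strictly
positive diagonal diffusion (iii) holds automatically; we still assert it at
the upper end of the wavenumber grid.  The grid is a geometric ladder of 400
points on $[10^{-4}, 50]$ plus zero — the cutoff $q^2 = 50$ corresponds to
wavelengths far below anything resolvable on the grids used here (up to
$128^2$), so it is a safe stand-in for $q^2 \to \infty$.  Eigenvalues are
computed with the general dense solver even though the $2\times 2$ case has a
trace/determinant closed form; the closed form serves as a cross-check in the
test suite, not as the implementation.

# Simulating patterns

The domain is a doubly periodic $n_r \times n_r$ torus with unit grid
spacing.  Time integration uses the implicit Euler scheme; each step solves
its nonlinear equation by the fixed-point iteration

$$
v \leftarrow (I - h\,\delta_i L)^{-1}\bigl(v_{\text{old}} + h\,f(v)\bigr)
\quad\text{per species},
$$

where every linear solve is a pointwise division in Fourier space: the
backward-Euler diffusion operator on the torus is block-circulant, with
symbol $1 + h\delta\,(4 - 2\cos(2\pi k/n_r) - 2\cos(2\pi l/n_r))$.  The two
species share a single complex FFT per direction by packing the two real
right-hand sides into one complex field and separating the spectra through
Hermitian symmetry; since the symbols are real the separation stays in real
arithmetic.  This compiled path implements the Gierer–Meinhardt kinetics; a
plain-R reference path accepts any `kinetic_model` and the two are compared
step-by-step in the tests, alongside an FFT-versus-dense-solve equivalence
check on small grids.

Operating point (defaults of `sim_config()`): step $h = 0.2$; inner
fixed-point tolerance $10^{-3}$ on the relative Euclidean change of the
stacked species state; steady-state criterion
$\lVert f(v) + \delta L v\rVert_\infty \le 10^{-6}$ evaluated every 100 time
units; final time 2000 for grids up to $64^2$ and 5000 for $128^2$.  Two
norm conventions were left open by the scheme as written for one species: we
evaluate both the inner convergence norm and the steady-state residual on
the **stacked** vector of all species, which reduces to the single-species
convention at $N = 1$ and treats the coupled system as one fixed-point
problem.  Analytic step bounds based on Lipschitz estimates of the
saturating kinetics are very loose, so instead of deriving $h$ we keep
$h = 0.2$ and monitor the inner iteration: if it fails to converge within 50
iterations or produces non-finite values, $h$ is halved and the step
retried ( `step_size_bound()` documents the analytic bounds for reference).

Initial conditions draw every grid point and species independently from the
uniform window $\pm 10\%$ around the homogeneous equilibrium; each pattern
records its seed, so datasets are reproducible from a single base seed.

# Resistance distance histograms

The pattern representation works on the weighted *pattern graph*: every
torus edge gets weight 1 when both endpoints lie on the same side of the
field mean, and a small weight $\epsilon_w = 0.003$ when it crosses the mean.
The effective (electrical) resistance between nodes, computable from the
graph Laplacian as $R_{vv'} = K_{vv} + K_{v'v'} - 2K_{vv'}$ with
$K = (J_m + L_G)^{-1}$, is a nonlocal distance: it decreases with every
additional path, so it encodes region shapes and connectivity rather than
pixel positions.  $\epsilon_w$ trades off resolution of large-scale against
small-scale geometry; 0.003 keeps interface crossings costly (factor
$\approx 333$) without saturating long-range resistances.

The RDH collects, for every source node (undersampling factor $t$, default
1 = no undersampling) and every node within toroidal Euclidean distance $r$,
the resistance between the two, drops values above a calibrated edge
$R_{\max}$, and bins the rest uniformly on $[0, R_{\max}]$ into $B = 12$
bins, normalised to the probability simplex.  The radius $r$ (8 or 32 in
the studies reproduced here) sets the spatial scale being summarised.
$R_{\max}$ is calibrated per batch as the maximum over patterns of the
per-pattern 99% quantile of collected values: rare huge resistances
(numerical artefacts of nearly isolated regions) would otherwise stretch
the support and empty most bins.  Because the histogram pools over all
sources of a torus, the RDH is exactly invariant under cyclic shifts,
transposition and quarter-turn rotations of the field, and empirically
stable under changes of the random initial condition — the property that
makes single-pattern parameter prediction possible.

Two deliberate conventions: the pairing radius uses the **toroidal**
minimal-image Euclidean distance (consistent with the periodic domain), and
bins are half-open with the last bin closed at $R_{\max}$.

Two scalar features break the symmetries the RDH cannot see.  The maximal
concentration $c_m$ is the centre of the right-most local-maximum bin of a
25-bin histogram of field values, where a peak must hold at least 1% of the
pixels — the floor discards isolated numerical outliers; $c_m$ restores the
absolute concentration scale.  The component count $n_c$ counts connected
components of the subgraph on nodes at or above the field mean; it breaks
the range-reflection symmetry (inverting a pattern about its mean leaves
all edge weights, hence the RDH, unchanged, but swaps spots for holes).
Both the 1% floor and the mean threshold are package choices where only the
qualitative rule ("ignore outliers", "nodes of high concentration") is
prescribed by the construction.

**Computation.**  For a generic graph, `resistance_matrix()` inverts
$J_m + L_G$ exactly as defined.  For the $64^2$-node pattern graphs this
dense inverse is the bottleneck, so the production path grounds one node and
solves the reduced sparse Laplacian with a supernodal Cholesky
factorisation, 512 right-hand sides at a time; resistances are gathered
offset-by-offset without ever assembling the full $m \times m$ matrix.  The
grounded route and the $(J_m + L_G)^{-1}$ definition agree to $10^{-14}$ and
both are checked against the Moore–Penrose pseudoinverse construction in the
tests.  A $64\times 64$ pattern featurises in roughly 2–6 s on one core.

# Kernels on histograms

Histograms are compared with the symmetric $\chi^2$ kernel
$\sum_i x_i x_i'/(x_i + x_i')$ (no scale parameter; $0/0$ summands are 0,
the limit of the expression), its exponential variant
$\exp\!\bigl(-\tfrac1\gamma \sum_i (x_i - x_i')^2/(x_i+x_i')\bigr)$, and the
Wasserstein kernel $\exp(-d_W^2(x,x')/\gamma)$.  The squared Wasserstein
distance uses the ground cost $C_{ij} = (i-j)^2$ on **bin indices** — so
distances are in units of squared bins — and is evaluated exactly by the
1-D closed form: the two cumulative distributions are merged and each
segment of mass contributes (mass) $\times$ (index difference)$^2$, which is
the quantile-function form of the optimal transport cost and equals the
linear-programming optimum (asserted against a simplex LP oracle on 200
random histogram pairs).  Zero-mass segments are skipped, which is exactly
the monotonicity guard the discrete quantile inversion needs.  The Gaussian
kernel $\exp(-\lVert y - y'\rVert^2/\gamma)$ serves as the smooth
output-space kernel of the joint predictor.

# Predictors

**Scalar SVR.**  One parameter at a time is learned by
$\varepsilon$-insensitive support vector regression without an offset term,
exactly the quadratic program

$$
\min_{\alpha, \xi}\; \textstyle\sum_i \xi_i +
\tfrac{\lambda}{2}\alpha^\top K_n \alpha
\quad \text{s.t.}\quad \xi \ge 0,\;
\xi_i + (K_n\alpha)_i \ge y_i - \varepsilon,\;
\xi_i - (K_n\alpha)_i \ge -y_i - \varepsilon .
$$

The absence of a bias is mitigated by max-normalising targets into $[0,1]$.
The solver optimises the equivalent box-constrained dual
($d \in [-1,1]^n$, $\alpha = d/\lambda$, an $\ell_1$ term from the tube) by
exact soft-threshold coordinate updates and stops on the duality gap
($10^{-8}$ relative); the attained primal objective is verified against a
generic interior-point QP solver in the tests.  The tube width defaults to
$\varepsilon = 0.01$ on normalised targets — a value the protocol leaves
open — and is exposed as a hyperparameter.

**Joint prediction with operator-valued kernels.**  All parameters are
predicted jointly by regression in an output-kernel feature space.  With
input Gram matrix $K_n$ (Wasserstein) and output Gram matrix $L_n$
(Gaussian on normalised targets), the method needs the context matrix
$T_n = L_n - (K_n + n\epsilon I)^{-1} K_n L_n$ (ridge $\epsilon = 10^{-4}$
by default; only $0 < \epsilon \ll 1$ is prescribed), the solution of the
$n^2$-dimensional system $(K_n \otimes T_n + n\lambda I)\,u =
\mathrm{vec}(I_n)$, and per test point the vector
$v = \mathrm{vec}(T_n\,\mathrm{unvec}(u)\,k_x)$.  The Kronecker system is
solved matrix-free by a restarted global GMRES (Krylov bases of matrices
under the Frobenius inner product; restart 50, tolerance $10^{-8}$, at most
200 cycles), never forming the $n^2 \times n^2$ operator.  The prediction
itself is the pre-image $\hat y = \arg\min_y\, l(y,y) - 2\,l_y^\top v$,
a weighted Gaussian-mixture landscape minimised by gradient descent with
backtracking line search; we initialise at the training target with the
largest context weight — the dominant bump's basin — with ties broken by
lowest index.  The intermediate covariance-operator formulation is folded
analytically into $T_n$; only $K_n$, $L_n$, $T_n$ are ever materialised.

**Feedforward networks.**  Small ReLU networks (linear output layer) map
RDH vectors, optionally with $c_m$ appended, to one or four normalised
parameters.  Training is minibatch Adam (batch 32, learning rate $10^{-3}$
— both unstated in the protocol and fixed here) on the mean squared error,
with inputs standardised by training-split statistics.  The step/patience
schedule follows the dataset-size rule $(4\times10^5, 10^5)$ for 20–50
points, $(2\times10^5, 5\times10^4)$ for 100–2000, $(10^5, 2\times10^4)$
beyond; the weight snapshot with the lowest validation loss along the
trajectory is returned.  The architecture search space (depths 0–3, widths
8–128) is part of the protocol because the best published architectures are
only available as figure panels.

# Evaluation protocol

Accuracy is the normalised root-mean-square error: RMSE over all test
entries divided by the mean of the true (nonnegative) targets; below 0.2
counts as good, below 0.05 as excellent in terms of visual pattern
similarity.  Every dataset is split 60/20/20 into train/validation/test;
hyperparameters ($\gamma$, $\lambda$, and for the joint method the output
scale) are chosen by validation NRMSE on a grid, ties resolved toward the
first grid point, and the test split is consulted exactly once.  Because
small-sample NRMSE is noisy, a pool of $P$ points is partitioned into
$\lfloor P/m \rfloor$ disjoint subsets of size $m \le 500$, each subset is
processed independently and the NRMSE values averaged ($m > 500$: a single
subset).  Default grids: $\gamma \in \{0.01, 0.03, 0.1, 0.3, 1, 3, 10,
30\}$ — extended beyond unity because squared Wasserstein distances on
12-bin histograms live on a scale of up to $(B-1)^2 = 121$ squared bins, so
sub-unit scales alone would make the kernel nearly diagonal —
$\lambda \in 10^{-4..0}$ (5 log-spaced points), output scale
$\in \{0.01, \dots, 1\}$ on $[0,1]^d$ targets.

# Dataset generation and clustering

`generate_dataset()` samples parameter vectors from a sweep (the
single-parameter study varies $c \sim U[0, 1.15]$ at
$a = 0.02, b = 1, \delta = 100, s = 0.25$; the four-parameter study varies
$a, b, c, \delta$ uniformly on $[0.01, 0.7] \times [0.4, 2] \times
[0.02, 7] \times [20, 200]$ at known $s = 0.4$) and rejects vectors without
a Turing instability.  Rejection uses the linear stability test rather than
the simulated amplitude: it is cheap, deterministic, and every accepted
vector is re-validated by the recorded pattern amplitude in the manifest.
Candidate draws come from one seeded stream and pattern $j$ uses
initial-condition seed $\text{base} + j$, so a manifest is reproducible
from its sweep specification alone.

Pattern collections are clustered by connecting two patterns whenever the
squared Wasserstein distance between their RDHs is at most $\tau = 0.05$
and reading off connected components; the published behaviour (about 84% of
a 1000-pattern $c$-sweep inside the six largest components) is a
qualitative benchmark for this construction.  All-pairs distances use the
$O(n^2 B)$ closed form; no pruning is needed at $n \approx 10^3$.

# What the synthetic data does and does not emulate

All training and test data are produced by the package's own simulator from
random initial conditions — exactly the study conditions, since the method
is designed for settings where labelled real patterns are unavailable.  The
generator reproduces: steady-state concentration fields of the stated
sweeps, unknown initial conditions (the only stochasticity), and the
amplitude structure of patterned solutions.  It does **not** emulate
measurement noise, non-periodic boundaries, spatially varying parameters,
or model mismatch — a pattern produced by different kinetics.  Passing
tests therefore demonstrate recoverability of parameters *within* the
model class from ideal observations, not robustness to experimental
imaging artefacts.

# Problem sizes and numerical choices

The test suite and the acceptance script run scaled-down versions of the
published studies, chosen as the smallest sizes at which the qualitative
claims are measurable: trend checks use pools of 20–60 patterns on
$32\times 32$ grids, and the headline quantities use a pool of 100 patterns
on $64\times 64$ (subset size 20, five subsets) plus a 30-pattern
four-parameter sample.  At these sizes the SVR NRMSE at $m = 20$ is
directly comparable to the published small-sample value ($\approx 0.2$),
while its subset-to-subset spread is naturally larger than with a
1000-pattern pool.  Degenerate inputs are handled explicitly: constant
fields give a single-bin concentration histogram (returning the constant),
an all-high mean threshold keeps the full torus (one component), an
$R_{\max}$ below every collected value is an error rather than an empty
histogram, and a mass mismatch beyond $10^{-9}$ between histograms is
rejected instead of silently renormalised.

# Known limitations

Resistance distance histograms discard some pattern information by design —
notably the steepness of transitions between high and low regions — which
bounds achievable accuracy in the large-data limit.  The SVR solver is a
small-to-medium-$n$ primal/dual method (thousands of points, matching the
regime where kernel methods are competitive), not an SMO-style large-scale
solver.  The compiled simulator is specific to two-species
Gierer–Meinhardt kinetics; other models run through the slower reference
path.  Featurisation cost is dominated by the sparse factorisation of the
pattern-graph Laplacian and grows superlinearly with the grid side; $128^2$
grids are supported but noticeably slower.
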