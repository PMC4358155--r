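---
title: "Second derivatives of population growth rates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Second derivatives of population growth rates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demhess)
```

This vignette documents the model, the matrix-calculus machinery, the
numerical choices, and the design decisions behind `demhess`, in the
spirit of a methods section: what is computed, under which assumptions,
and what the validation suite does and does not establish.

## The model and its growth rates

A stage-structured population is projected by a nonnegative matrix
$\mathbf{A}$, decomposed where biology permits as
$\mathbf{A} = \mathbf{U} + \mathbf{F}$ (transitions/survival and
fertility). Three growth measures are differentiated:

* $\lambda$, the dominant eigenvalue of $\mathbf{A}$;
* $r = \log\lambda$, the invasion exponent;
* $R_0$, the dominant eigenvalue of the next-generation matrix
  $\mathbf{R} = \mathbf{F}\mathbf{N}$ with fundamental matrix
  $\mathbf{N} = (\mathbf{I}-\mathbf{U})^{-1}$, defined when
  $\rho(\mathbf{U}) < 1$.

Assumptions: $\lambda$ must be a *simple* (algebraically isolated) real
eigenvalue. Strict modulus dominance — ergodicity — is a separate
property: an imprimitive matrix such as the two-stage semelparous model
`matrix(c(0, .5, 2, 0), 2, 2)` (eigenvalues $\pm 1$) has perfectly
well-defined eigenvalue derivatives at its simple Perron root even
though populations cycle forever. The package therefore errors only on
non-simplicity (repeated eigenvalue within relative tolerance
$10^{-8}$) and merely warns on imprimitivity and on reducibility.

## Derivative conventions

Everything is laid out in the column-major vec convention: the
$(i,j)$ entry of an $n\times n$ matrix occupies vec position
$(j-1)n+i$; user-facing labels are 1-based, e.g. `a[3,1]`. The
Jacobian of an $m$-vector in an $s$-vector is $m\times s$; the
"stacked Hessian" of a vector-valued map is the $ms \times s$ matrix
holding the $s\times s$ Hessians of the components as consecutive row
blocks. The commutation matrix $\mathbf{K}_{m,n}$ (built sparse;
`commutation_matrix()`) and Roth's identity
$\mathrm{vec}(\mathbf{XYZ}) = (\mathbf{Z}^\top\!\otimes\mathbf{X})\,
\mathrm{vec}\,\mathbf{Y}$ are the bookkeeping primitives.

## The Hessian of $\lambda$

With right and left eigenvectors scaled as
$\mathbf{e}^\top\mathbf{w} = 1$ and $\mathbf{v}^\top\mathbf{w} = 1$,
the first differential is
$d\lambda = (\mathbf{w}^\top \otimes \mathbf{v}^\top)\,
d\,\mathrm{vec}\mathbf{A}$ — the classical sensitivity
$\partial\lambda/\partial a_{ij} = v_i w_j$ with unit denominator.
Differentiating again (the second differential of
$\mathrm{vec}\mathbf{A}$ vanishes when the entries themselves are the
variables) gives

$$d^2\lambda \;=\; d\,\mathrm{vec}^\top\!\mathbf{A}\,
\Big[(\mathbf{I}_n \otimes \mathbf{v})\, D[\mathbf{w}] +
(\mathbf{w} \otimes \mathbf{I}_n)\, D[\mathbf{v}]\Big]\,
d\,\mathrm{vec}\mathbf{A},$$

and the identification of Hessians from second differentials yields
$H[\lambda;\mathrm{vec}\mathbf{A}]$ as the symmetric part of the
bracket. The eigenvector Jacobians $D[\mathbf{w}]$, $D[\mathbf{v}]$
solve the bordered systems obtained by differentiating
$\mathbf{A}\mathbf{w} = \lambda\mathbf{w}$ and
$\mathbf{A}^\top\mathbf{v} = \lambda\mathbf{v}$ subject to the two
scalings; the bordered matrices are nonsingular exactly when $\lambda$
is simple (a pseudo-inverse fallback with a warning covers
near-singular cases). The differentiated scalings
$\mathbf{e}^\top d\mathbf{w} = 0$ and
$\mathbf{v}^\top d\mathbf{w} + \mathbf{w}^\top d\mathbf{v} = 0$ hold to
machine precision and are asserted in the tests.

Two exact structural identities follow from degree-1 homogeneity of
$\lambda$ and are used as free invariants:
$H[\lambda;\mathrm{vec}\mathbf{A}]\cdot\mathrm{vec}\mathbf{A} = 0$ and
$H(c\mathbf{A}) = H(\mathbf{A})/c$.

The raw analytic Hessian is symmetric to rounding error only;
`demhess` asserts near-symmetry (relative $10^{-8}$, warning beyond)
and then symmetrizes as $(H + H^\top)/2$, because downstream quadratic
forms would otherwise accumulate the asymmetry.

## Lower-level parameters: the Hessian chain rule

For a differentiable map $\theta \mapsto \mathbf{A}(\theta)$ with
Jacobian $J$ and stacked Hessian $H[\mathrm{vec}\mathbf{A};\theta]$,

$$H[\lambda;\theta] = J^\top H[\lambda;\mathrm{vec}\mathbf{A}]\,J
+ \sum_k \frac{\partial\lambda}{\partial(\mathrm{vec}\mathbf{A})_k}\,
H[(\mathrm{vec}\mathbf{A})_k;\theta].$$

`parameter_map` objects carry $J$ and the stack; `custom_map()` fills
missing derivatives by central differences (announced, with the step
logged) so that any user map is usable, while the built-in maps are
analytic. The identity map reproduces the matrix-entry Hessian to
machine precision — a cheap self-test.

The workhorse built-in is the survival parameterization
(`survival_map()`): $\mathbf{U} = \mathbf{G}\,\mathrm{diag}(\sigma)$
with $\sigma$ the column sums of $\mathbf{U}$ and $\mathbf{G}$ the
transitions conditional on survival. Under a prebreeding census
$\mathbf{F}$ does not depend on $\sigma$, the map is linear, its
stacked Hessian is exactly zero, and the chain rule collapses to the
quadratic form $B^\top H[\lambda;\mathrm{vec}\mathbf{A}] B$. A column
with $\sigma_j = 0$ leaves $\mathbf{G}$'s column undefined (0/0); it is
set to $\mathbf{e}_j$ with a warning, which keeps the map total without
altering $\mathbf{U}$ — derivatives with respect to such a $\sigma_j$
are one-sided. Trait covariation is expressed the same way: a
constraint such as "fertility proportional to survival,
$F_i = c P_i$" becomes a one-parameter `custom_map()`, and the
resulting scalar Hessian is the *total* curvature including the
constraint.

Postbreeding designs, where fertility does depend on survival, are not
a special case of `survival_map()` but are fully expressible through
`custom_map()` with a $\theta$-dependent $\mathbf{F}$.

## $r = \log\lambda$

Differentiating $D[r] = D[\lambda]/\lambda$ gives the exact transform
$H[r] = H[\lambda]/\lambda - D^\top D/\lambda^2$ (and identically for
any parameter vector). The package computes $H[r]$ from the already
computed $H[\lambda]$ and $D$ rather than re-deriving differentials:
one code path for the hard part. Homogeneity gives the test identity
$\mathrm{vec}^\top\!\mathbf{A}\; H[r]\;\mathrm{vec}\mathbf{A} = -1$.

## $R_0$

Because $R_0$ is an eigenvalue of $\mathbf{R}$, the $\lambda$ machinery
applies with $\mathbf{R}$ in place of $\mathbf{A}$; the work is in the
derivatives of $\mathbf{R}$ through
$d\mathbf{N} = \mathbf{N}\,d\mathbf{U}\,\mathbf{N}$:

* in $\mathbf{U}$: $D[\mathrm{vec}\mathbf{R};\mathrm{vec}\mathbf{U}]
  = \mathbf{N}^\top \otimes \mathbf{F}\mathbf{N}$, and the component
  form $\partial^2 R_{ij}/\partial u_{ab}\partial u_{cd} =
  (\mathbf{FN})_{ia} N_{bc} N_{dj} + (\mathbf{FN})_{ic} N_{da} N_{bj}$.
  Since the eigenvalue gradient is rank one
  ($D_{ij} = v_i w_j$), the contraction of the gradient with the
  $n^4\times n^2$ stacked Hessian reduces to outer products of
  $\alpha = (\mathbf{FN})^\top\mathbf{v}$, $\mathbf{N}$, and
  $\beta = \mathbf{N}\mathbf{w}$ — evaluated directly in $O(n^4)$
  memory without materializing the stack.
* in $\mathbf{F}$: $\mathbf{R}$ is linear, so only
  $(\mathbf{N}\otimes\mathbf{I})\,H[R_0;\mathrm{vec}\mathbf{R}]\,
  (\mathbf{N}^\top\!\otimes\mathbf{I})$ survives.
* in $\theta$ through $(\mathbf{U}(\theta), \mathbf{F}(\theta))$: the
  bilinear second differential
  $\partial^2\mathbf{R}_{pq} = \mathbf{F}_{pq}\mathbf{N}
  + \mathbf{F}_p\mathbf{N}\mathbf{U}_q\mathbf{N}
  + \mathbf{F}_q\mathbf{N}\mathbf{U}_p\mathbf{N}
  + \mathbf{F}(\mathbf{N}\mathbf{U}_{pq}\mathbf{N}
  + \mathbf{N}\mathbf{U}_p\mathbf{N}\mathbf{U}_q\mathbf{N}
  + \mathbf{N}\mathbf{U}_q\mathbf{N}\mathbf{U}_p\mathbf{N})$
  is assembled per parameter pair ($O(s^2 n^3)$), then contracted with
  the gradient and combined with the quadratic form in
  $D[\mathrm{vec}\mathbf{R};\theta]$.

**Offspring conventions.** With a single offspring type (one nonzero
row $o$ of $\mathbf{F}$), $\mathbf{R}$ has one nonzero row and
$R_0 = R_{oo} = \mathbf{e}_o^\top\mathbf{F}\mathbf{N}\mathbf{e}_o$ —
*linear* in $\mathbf{F}$, so $H[R_0;\mathrm{vec}\mathbf{F}] \equiv 0$,
and no eigenvector machinery is needed anywhere
(`method = "entry"`). The general eigenvalue path
(`method = "eigen"`) remains available, and the two agree to near
machine precision on single-offspring models (asserted at $10^{-9}$
relative); the package cross-validates them rather than trusting
either alone. The convention is *frozen at the base point* in the
finite-difference oracle maps: a perturbed $\mathbf{F}$ with a stray
second row must not silently switch the definition mid-stencil, which
would put a kink through the probe points.

## Sensitivity of the stochastic growth rate

For i.i.d. environments with mean matrix $\bar{\mathbf{A}}$ and entry
covariance $\mathbf{C}$ ($n^2\times n^2$, vec order, supplied as a
primitive — never estimated from data by this package), the small-noise
approximation is

$$\log\lambda_s \approx \log\bar\lambda -
\frac{\mathbf{D}\mathbf{C}\mathbf{D}^\top}{2\bar\lambda^2},$$

with $\mathbf{D}$ the sensitivity row vector at $\bar{\mathbf{A}}$.
Differentiating in $\bar{\mathbf{A}}$ at fixed $\mathbf{C}$ (writing
$\tau^2 = \mathbf{D}\mathbf{C}\mathbf{D}^\top$ and
$H = H[\lambda;\mathrm{vec}\bar{\mathbf{A}}]$):

$$\frac{d\log\lambda_s}{d\,\mathrm{vec}\bar{\mathbf{A}}} =
\frac{\mathbf{D}}{\bar\lambda} + \frac{\tau^2}{\bar\lambda^3}\mathbf{D}
- \frac{1}{\bar\lambda^2}\,\mathbf{D}\mathbf{C}H.$$

The decisive internal consistency check is that this printed gradient
equals the central finite differences of the approximation itself
(`log_lambda_s_of_vecA()` is the unclamped oracle form); the $C = 0$
limits recover $\log\bar\lambda$ and $\mathbf{D}/\bar\lambda$ exactly,
and the noise term is linear in $\mathbf{C}$.

The Monte-Carlo validator (`stochastic_growth_sim()`) draws i.i.d.
matrices with mean $\bar{\mathbf{A}}$ and covariance approximately
$\mathbf{C}$: multivariate normal perturbations clipped at zero
(default; the clipping fraction is reported) or independent entrywise
lognormals matched to mean and variance (cross-covariances ignored —
stated, not hidden). Simulations start at the stable structure of
$\bar{\mathbf{A}}$ to shorten transients; the standard error uses batch
means (batch length 50) because one-step log growth rates are serially
correlated through the population structure. Draws are reproducible
under a seed, and scaling $\mathbf{C}$ at a fixed seed scales the same
normal draws — common random numbers, which the variance-scaling test
exploits. The approximation is asymptotic in the noise level: the test
suite checks that a $2\times 10^5$-step simulation at entry variance
$10^{-4}$ brackets the approximation within three standard errors, and
that halving $\mathbf{C}$ approximately halves the penalty
$\log\bar\lambda - \log\lambda_s$.

## Selection classification

Reading a growth rate as fitness, diagonal Hessian entries are
quadratic selection gradients — concave/linear/convex for
negative/zero/positive — and off-diagonal entries give the sign of
correlational selection. "Zero" needs a band: the default is 5% of the
largest absolute diagonal entry, an explicit and overridable choice
(`classify_selection(H, tol = ...)`). `ess_stability()` applies the
same sign logic to the curvature of invasion fitness at a singular
strategy. The helper `selection_gradient_root()` finds candidate
singular strategies by root-finding on the first derivative; it is a
convenience, not part of the second-derivative method. Classification
reports regenerate identically from exported Hessian files.

## The finite-difference oracle

Every analytic formula above is checked against an independent oracle
(`fd_gradient()`, `fd_hessian()`) that shares no code with the analytic
paths: central differences, per-coordinate steps scaled by the
coordinate magnitude with an absolute floor of 1. Defaults are the
central-scheme optima — $\varepsilon^{1/3}$ (gradients) and
$\varepsilon^{1/4}$ (Hessians) relative steps. Probes do **not**
enforce nonnegativity: the growth rates are defined in a neighbourhood,
and clamping would corrupt one-sided derivatives at structural zeros.
Only the transience boundary $\rho(\mathbf{U}) < 1$ is a hard domain
edge.

Eigenvalue targets can be numerically *stiff*: a small spectral gap, or
a next-generation matrix whose dominant eigenvalue is small, inflates
third and fourth derivatives so that no single step size serves both
these and smooth large-$\lambda$/small-curvature targets. The
validation suite therefore uses `fd_hessian_auto()`: a descending
ladder of base steps, each paired with its half step for Richardson
extrapolation $(4H_{h/2}-H_h)/3$; the within-pair stencil difference
monitors the error, the descent stops when rounding noise takes over,
and the best-converged pair wins. Step-halving convergence at
$O(h^2)$ is itself a tested property of the plain stencil.

## The synthetic data generator

`random_lefkovitch()` emulates size/stage-classified perennial life
cycles: conditional transitions biased toward stasis and single-stage
growth with some shrinkage, stage survivals uniform on (0.05, 0.95),
lognormal fertilities from the oldest fraction of stages into the
offspring stage(s), irreducibility enforced by a small loop when
needed, fully reproducible under a seed. Draws whose net reproductive
rate falls outside $[0.1, 10]$ are rejected and redrawn: unconstrained
chains of low survivals can yield life cycles in which offspring
recruit with probability $10^{-3}$ or less per generation — no
persisting population looks like that, and the corresponding
growth-rate curvatures (reaching $10^{11}$) have perturbative radii
below what double precision can probe, making them meaningless for
either biology or validation.

What the generator does *not* emulate: density dependence, temporal
trends or autocorrelation, sampling error in estimated rates,
correlated fertility-survival structure beyond the explicit covariation
maps, and the extreme fertility/survival magnitudes of, say, marine
broadcast spawners. Passing the oracle suite on these models
establishes the correctness of the formulas and their implementation on
well-conditioned stage-structured matrices; it does not certify
behaviour on models violating the simplicity assumption, nor the
demographic realism of any particular application.

## The case-study fixture

The demonstration fixture is an 8-stage *Calathea ovandensis*-style
model (seed bank, seedling, juvenile, pre-reproductive, four
reproductive sizes; single offspring type, prebreeding census). It is
a clearly labelled **synthetic stand-in** constructed once from
plausible vital rates for an understory herb near demographic
stationarity; the package does not redistribute the published
field-estimated weighted-mean matrix for the species. Its dominant
eigenvalue is 0.9677. The published matrix has dominant eigenvalue
0.9923, and `calathea_matrix(path = ...)` loads a user transcription
and fails loudly if the eigenvalue checksum differs by more than
$5\times10^{-4}$ — transcription errors in a 64-entry table are
otherwise easy to miss. Consequently the numbers produced by the demo
workflow (and by three comparisons in the acceptance tests, which are
expected to fail on the stand-in) are illustrative of the workflow, not
reproductions of the published case-study values.

## Numerical choices, degenerate inputs, problem sizes

* Simplicity tolerance $10^{-8}$ (relative) on the eigenvalue spacing;
  error rather than returning garbage Hessians.
* Symmetrization after asserting relative asymmetry $\le 10^{-8}$.
* Text exports: 10 significant digits for Hessians; full 17-digit
  precision for matrices so write/read round trips are bit-identical.
* Degenerate inputs handled explicitly: $\sigma_j = 0$ columns
  (one-sided, warned), reducible matrices (warned), imprimitive
  matrices (warned), non-transient $\mathbf{U}$ (error),
  $\lambda \le 0$ for $r$ (error), non-PSD covariance (error).
* Test and acceptance problem sizes: 20 random models of 2–8 stages
  (a quarter with two offspring types) for the oracle suite; 5-stage
  models for the structural identities; a 2-stage,
  $2\times10^5$-step simulation for the stochastic bracket. These
  sizes exercise every code path while keeping the full suite around a
  minute.

## Known limitations

Second derivatives of subdominant eigenvalues, complex dominant
eigenvalues, temporally autocorrelated or density-dependent
environments, and third-order expansions are out of scope. The
second-order Taylor expansion `delta_lambda_second_order()` is a
convenience whose accuracy is *not* guaranteed to beat the linear
approximation for finite perturbations — second-order terms can
degrade it — and it is documented as such. Hessians over all $n^2$
entry pairs include structural zeros; reports can mask them
(`nonzero_mask()`), but the derivatives there are real one-sided
quantities, not artifacts.
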