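# demhess

Second derivatives (Hessian matrices) of population growth rates for
stage-structured matrix population models.

## The problem

A matrix population model projects a stage-abundance vector forward by a
nonnegative matrix **A**, often decomposed as **A** = **U** + **F** into
survival/transition and fertility parts. Three growth-rate measures
summarize such a model:

- λ — the dominant eigenvalue of **A** (per time-step growth),
- *r* = log λ — the invasion exponent (continuous-time growth, the
  fitness measure of invasion analysis),
- *R*₀ — the dominant eigenvalue of the next-generation matrix
  **R** = **F**(**I** − **U**)⁻¹ (per-generation growth).

First derivatives of these rates (sensitivities, selection gradients)
are standard tools. Their **second** derivatives answer questions the
first derivatives cannot:

- how a sensitivity itself responds to perturbations (second-order
  sensitivity analysis; robustness of management recommendations),
- whether selection on a trait is concave, linear or convex, and whether
  selection on a pair of traits is positively or negatively
  correlational (quadratic selection gradients),
- whether an evolutionary singular strategy is stable (∂²λ/∂y² < 0) or a
  branching point (∂²λ/∂y² > 0),
- the sensitivity of Tuljapurkar's small-noise approximation to the
  stochastic growth rate, which is built from the first and second
  derivatives of λ at the mean matrix.

`demhess` computes these Hessians by matrix calculus. With the
eigenvectors scaled so that **e**ᵀ**w** = 1 and **v**ᵀ**w** = 1, the
first differential of λ is dλ = (**w**ᵀ ⊗ **v**ᵀ) dvec **A**;
differentiating once more and substituting the Jacobians of **w** and
**v** (obtained from bordered linear solves) yields the n² × n²
symmetric Hessian *H*[λ; vec **A**]. A Hessian chain rule propagates
second derivatives through any differentiable parameterization
θ ↦ **A**(θ):

H[λ; θ] = Jᵀ H[λ; vec A] J + Σₖ (∂λ/∂(vec A)ₖ) H[(vec A)ₖ; θ],

with J = D[vec A; θ]. The invasion exponent follows by the exact
transform H[r] = H[λ]/λ − DᵀD/λ², and *R*₀ by applying the eigenvalue
machinery to **R** (or, with a single offspring type, by the linear
entry form R₀ = e₀ᵀ**FN**e₀, which needs no eigenvectors at all).
Every analytic formula is validated against an independent
finite-difference oracle.

## Worked example

The package ships an 8-stage *Calathea ovandensis*-style model (seed,
seedling, juvenile, pre-reproductive, and four reproductive size
classes). It is a **synthetic stand-in** built from plausible vital
rates, not the published field-estimated matrix (`?synthetic_calathea`;
a transcription of the published matrix can be loaded and
checksum-validated with `calathea_matrix(path = ...)`).

```r
library(demhess)
sm <- synthetic_calathea()
es <- dominant_eigensystem(sm)
print(es, digits = 4)
#> Dominant eigensystem: lambda = 0.9677 (damping ratio |l2|/|l1| = 0.754)
#> w (stable stage distribution, e'w = 1):
#>     seed seedling juvenile prerepro    small   medium    large   xlarge
#>   0.8726   0.0480   0.0199   0.0181   0.0165   0.0103   0.0084   0.0063
#> v (reproductive values, v'w = 1):
#>     seed seedling juvenile prerepro    small   medium    large   xlarge
#>   0.1502   1.8560   5.0377   6.3961   9.5193  13.7356  17.5896  18.9078
```

λ = 0.9677: the synthetic population declines slowly. Seeds dominate
the stable structure; reproductive value rises steeply with size.

```r
H <- growth_hessian(sm, rate = "lambda", wrt = "A")
summary(H, top = 3)
#> H[lambda; A]: 64 x 64, relative asymmetry before symmetrization 3.5e-16
#> diagonal (pure second derivatives) in [-168.8, 1146]
#> largest-magnitude entries:
#>     row    col     value
#>  a[8,1] a[8,1] 1146.4211
#>  a[7,1] a[8,1]  842.6963
#>  a[7,1] a[7,1]  575.7499
```

The largest curvatures involve the (unobserved) seed-to-adult
transitions a[7,1], a[8,1]: λ would respond convexly if such shortcuts
through the life cycle opened up. Hessians over stage-specific survival
probabilities σ (the column sums of **U**, via the conditional
transition matrix **G** with **U** = **G** diag σ) read directly as
quadratic selection gradients:

```r
Hs <- growth_hessian(sm, rate = "lambda", wrt = "sigma")
classify_selection(Hs)
#> Selection classification (rate: lambda, zero band: +/- 0.02016)
#> per-trait (quadratic selection gradients):
#>   trait          d2   class
#>  sigma1 -0.14167241 concave
#>  sigma2 -0.40326968 concave
#>  ...
#>  sigma8  0.33651374  convex
```

For this synthetic life cycle, selection on early survival is concave
(stabilizing-like) and on adult survival convex, with negative
correlational selection between early and late survival (e.g.
σ₁ × σ₈ = −0.135): selection acts to decouple juvenile from adult
survival. The same interface provides `rate = "r"` and `rate = "R0"`
with `wrt` ∈ {A, U, F, sigma, theta}, arbitrary parameter maps
(`custom_map()`, with analytic or finite-difference inner derivatives),
the small-noise stochastic growth rate and its sensitivity
(`log_lambda_s_approx()`, `dlogLambdaS_dvecA()`, with a Monte-Carlo
validator `stochastic_growth_sim()`), and ESS curvature classification
(`ess_stability()`).

## File formats and CLI

Matrices are delimited text (comma default, whitespace tolerated, `#`
comments, optional stage-label header). All vectorized objects use the
column-major vec convention: entry (i, j) of an n × n matrix occupies
vec position (j − 1)n + i; labels are 1-based, e.g. `a[3,1]`. Hessians
export as square CSV, long format
(`row_i,row_j,col_i,col_j,value` / `param_row,param_col,value`) or
JSON (`write_hessian()` / `read_hessian()`).

A command-line interface is installed at `exec/demhess`:

```sh
demhess hessian --rate lambda --wrt sigma --model-u U.csv --model-f F.csv --out H.csv
demhess classify --hessian H.csv --out report.json
demhess stochastic-sens --mean Abar.csv --cov C.csv
demhess validate --model-u U.csv --model-f F.csv   # FD-oracle suite
demhess demo-calathea --out-dir out/
```

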