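---
title: "Methods: an explicit scheme for the fuzzy time-fractional tumor model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an explicit scheme for the fuzzy time-fractional tumor model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzyfdm)
```

## The model

`fuzzyfdm` solves a one-dimensional reaction–diffusion model of tumor cell
concentration $u(x, t)$ in which the time derivative is fractional and the
data are fuzzy:

$$\frac{\partial^\alpha \tilde u}{\partial t^\alpha}
  = \frac{\partial^2 \tilde u}{\partial x^2} - \tilde k(x, t)\,\tilde u,
  \qquad 0 < \alpha \le 1,\; (x, t) \in [0, L] \times [0, T],$$

with fuzzy initial data $\tilde u(x, 0) = \tilde f(x)$ and fuzzy Dirichlet
boundary values. The coefficient $\tilde k$ is the *net killing rate* of
tumor cells — the balance of cell death (therapy, immune response) against
proliferation at position $x$ and time $t$. The fractional order $\alpha$
interpolates between strongly history-dependent dynamics (small $\alpha$)
and the classical memoryless diffusion equation ($\alpha = 1$); the
derivative is taken in the Caputo sense, so constant states have zero
fractional derivative and classical initial conditions remain meaningful.

The biological motivation for fuzziness is measurement uncertainty: initial
tumor-cell densities and killing rates are estimated quantities. Each
uncertain quantity factors as a *triangular fuzzy scale* times a crisp
kernel, e.g. $\tilde k(x,t) = \tilde\tau_1\, s_1(x,t)$ and
$\tilde f(x) = \tilde\tau_2\, s_2(x)$, where a triangular number
$(\ell, c, u)$ has membership rising linearly from $\ell$ to the core $c$
and falling to $u$ (`tri_fuzzy()`).

## Double parametric form

A fuzzy quantity is handled through its r-cuts
$[\underline{v}(r), \overline{v}(r)]$ — the interval of values with
membership at least $r$. Rather than propagating interval pairs, the
solver uses the *double parametric form*

$$\tilde v(r, \beta) \;=\; \beta\,\bigl(\overline{v}(r) -
  \underline{v}(r)\bigr) + \underline{v}(r),
  \qquad (r, \beta) \in [0,1]^2,$$

which collapses each interval family into a single scalar family:
$\beta = 0$ traces the lower branch, $\beta = 1$ the upper, and $r = 1$
collapses to the crisp core (`double_param_value()`). Every
$(r, \beta)$ sample therefore yields an ordinary crisp PDE, and
`solve_fuzzy()` is a loop of crisp solves over the sample grid. $\beta =
0.5$ is the *inflection value* at which the family passes from
lower-branch to upper-branch behaviour; nothing special is computed
there, it is simply the midpoint of the parametrisation.

The extension-principle (min/max) construction of fuzzy membership is
deliberately not implemented: for the scalar-times-kernel data used here
the parametric family already spans exactly the same solutions, because
the scheme below is linear in the data.

Triangular shape with linear cuts is an assumption of this package. It is
the standard minimal choice when only a support and a most-plausible value
are known, and the symmetric scale $(-1, 0, 1)$ with
$\phi(r,\beta) = \beta(2 - 2r) + (r - 1)$ is the one the validated worked
example uses.

## The explicit scheme

On the node-centered grid $x_i = i\,\Delta x$, $t_n = n\,\Delta t$
(`grid_spec()`), the Caputo derivative is discretized by the L1-type sum
with memory weights

$$b_j = (j+1)^{1-\alpha} - j^{1-\alpha}, \qquad j = 1, 2, \ldots$$

(`caputo_weights()`), and the second space derivative by the centered
difference at the known level $n$. Writing
$\rho = \Delta t^{\alpha}\,\Gamma(2-\alpha)$ and the fractional diffusion
number $s = \rho / \Delta x^2$ (`scheme_coefficients()`), the interior
update is

$$u_i^{n+1} = s\,(u_{i+1}^n + u_{i-1}^n) + (1 - 2s)\,u_i^n
  - \rho\,k(x_i, t_n)\,u_i^n
  - \sum_{j=1}^{n} b_j\,(u_i^{n+1-j} - u_i^{n-j}).$$

Two numerical conventions are worth stating because the continuous
formulation leaves them open:

* **Reaction time level.** $k$ is evaluated at $(x_i, t_n)$ — the same
  explicit level as every other term. An implicit evaluation would change
  the method family.
* **Full memory.** The memory sum runs over the entire history; no
  short-memory truncation is applied. This costs $O(N^2)$ work per node
  but is exact for the discretization, and all validated runs are desk
  scale (tens to hundreds of steps).

`explicit_step_regrouped()` implements the telescoped form

$$u_i^{n+1} = s\,u_{i+1}^n + (1 - 2s - \rho k - b_1)\,u_i^n +
  s\,u_{i-1}^n - \sum_{j=1}^{n-1} (b_{j+1} - b_j)\,u_i^{n-j} +
  b_n\,u_i^0,$$

which is algebraically identical and is the form manipulated by the
stability analysis; the test suite asserts agreement of the two forms to
$10^{-12}$ relative on random histories. A deliberately naive scalar
reference (`direct_history_oracle()`) re-derives the solution with
unvectorized loops for cross-checking, and an independently coded
classical FTCS loop in the test helpers anchors the $\alpha = 1$ limit,
where all $b_j$ vanish.

Because the scheme is linear and all fuzzy data share the scale family,
the fuzzy solution of the worked example factors exactly as
$\phi(r, \beta) \times$ the crisp run. The package still solves each
$(r, \beta)$ sample independently — the factorisation is then available
as a strong internal consistency *check* rather than a shortcut.

## Stability

Two sufficient bounds on $s$ are computed (`stability_report()`):

* the proposition-form bound
  $s \le \tfrac14\,(1 - \rho\,k_{\max} - b_1)$, the operative check in
  this package, and
* a companion theorem-form expression whose printed statement reads
  $s \le 1/(4 - s\,\Delta x^2\, k)$. Read literally it conflicts with
  the first bound whenever $b_1 > 0$; it is evaluated under that literal
  reading and reported side by side, for comparison only.

$k_{\max}$ is taken as $\max |k(x,t)|$ over all grid nodes and time
levels of the run, at the upper fuzzy branch ($\beta = 1$) when $k$ is
fuzzy — the worst case. The solver computes the report before every run
and **warns rather than refuses** when the bound is violated, so that
instability experiments remain runnable; a run that produces non-finite
values aborts with the offending time level named.

The Fourier-mode derivation behind these bounds is a proof device, not
data; the package verifies the conclusion empirically instead.
`perturbation_probe()` solves the model twice — once from $f$, once from
$f + \delta$ with $\delta$ a seeded uniform perturbation of the interior
nodes — and tracks
$\lVert \varepsilon^n \rVert_2 / \lVert \varepsilon^0 \rVert_2$ in the
$h$-weighted discrete norm
$\lVert \varepsilon \rVert_2 = \bigl(\sum_i h\,\varepsilon_i^2\bigr)^{1/2}$
(`l2_error_norm()`). For a linear scheme this difference evolves exactly
as the round-off error recursion, so the probe is equivalent to evolving
the error itself while reusing the tested solver. Inside the bound the
ratios must never exceed 1 (the suite asserts $\le 1 + 10^{-9}$); a
classical run at $s = 0.6$, beyond the explicit limit, shows growth.

One identity in the usual statement of the weight properties deserves a
note: the telescoping sum $\sum (b_{j+1} - b_j)$ equals $1 - b_n$ only
when the sum starts at $j = 0$ with $b_0 = 1$; the package asserts (and
tests) that $j = 0$-based form.

## The validation example and its reference solution

The validated scenario (`preset_worked_example()`) is the time-dependent killing
rate $k(t) = t^2$ with fuzzy initial condition
$\phi(r, \beta)\, e^{k x}$, solved at $\alpha = 0.9$, $\Delta x = 0.5$,
$\Delta t = 0.01$ to $t = 0.05$ and evaluated at $x = 4$. The reference
is the truncated series

$$C(x, t) = e^{kx}\Bigl(1 + \frac{k^2 t^{\alpha}}{\Gamma(1+\alpha)} +
  \frac{k^4 t^{2\alpha}}{\Gamma(1+2\alpha)}\Bigr),
  \qquad \tilde u_{\text{ref}} = \phi(r, \beta)\, C(x, t),$$

implemented by `exact_crisp()` / `exact_fuzzy()`. Three conventions of
this scenario are not pinned down by its published description and are
resolved here as package defaults, all overridable:

* **Exponent $k = -1$.** The magnitude of the reference values at
  $x = 4$ is of order $e^{-4}$, consistent with a decaying profile and
  inconsistent with $k = +1$.
* **Domain $[0, 8]$**, so that the evaluation point $x = 4$ is interior.
* **Boundary values from the series reference** ("from-oracle" Dirichlet
  data) at $x = 0$ and $x = L$, since the boundary data are otherwise
  stated only abstractly. $\phi$ multiplies the *entire* series: the
  solution and its error must vanish identically at $r = 1$, which pins
  the bracket placement.
* **$\Delta t = 0.01$**, so that $t = 0.05$ is reached in five whole
  steps.

The truncated series is *not* the true solution of the model: it omits
killing-rate corrections of order $t^{\alpha+2}$ and beyond. It is a
small-$t$ validation reference, and the absolute errors the package
reports against it (about $2 \times 10^{-5}$ at the tabulated point)
mix genuine discretization error with that truncation. This is also why
third-decimal agreement with any independently printed error column
cannot be expected in general; the package reports what it computes.

## Experiments and the synthetic fixtures

`run_error_table()` reproduces the error-table layout over
$r \in \{0, 0.2, \ldots, 1\}$, $\beta \in \{0, 0.4, 0.6, 1\}$;
`sweep_alpha()` re-runs the crisp upper branch for
$\alpha \in \{0.5, 0.7, 0.9, 1\}$ (accuracy against the series reference
improves monotonically toward $\alpha = 1$); `grid_refinement()` runs a
ladder of $(\Delta x, \Delta t)$ pairs. The default ladder is parabolic,
$\Delta t \propto \Delta x^2$ — $(1, 10^{-2})$, $(0.5, 2.5\times10^{-3})$,
$(0.25, 6.25\times10^{-4})$ — which keeps $s$ nearly constant, stays well
inside the stability bound, and shrinks both error components together;
ladders that refine space while holding $\Delta t$ fixed quickly become
time-error dominated and are not informative about convergence. Pairs
violating the bound are refused unless forced, and forced runs report
blow-up or growth instead of propagating non-finite values.

`generate_fixture()` provides the study conditions as code: the worked
example (`"worked_example"`), the classical heat benchmark (`"classical_heat"`,
$\alpha = 1$, $\sin(\pi x)$ initial data, closed-form solution
$e^{-\pi^2 t}\sin(\pi x)$), a seeded random triangular-scale instance
(`"random_tri_ic"`) and a deliberately unstable classical run
(`"unstable_classical"`, $s = 0.6$). The random fixture emulates fuzzy
uncertainty in a smooth initial profile with a constant killing rate; it
does **not** emulate features of clinical data — spatial heterogeneity,
nonlinearity of real growth, measurement noise in time series — so
passing tests demonstrate correctness of the numerics, not fidelity of
the model to any particular tumor.

## Numerical choices and degenerate inputs

* All arithmetic is double precision; algebraic-identity assertions use
  $10^{-12}$ relative tolerance.
* $\Gamma$ is base R's `gamma()`; no bespoke approximation.
* Requested evaluation points must coincide with grid nodes within
  $10^{-9}$; the package never interpolates (`solution_at()` errors
  instead).
* `grid_spec()` requires $L/\Delta x$ and $T/\Delta t$ to be whole
  numbers within rounding tolerance.
* $\beta = 0$ and $\beta = 1$ return the branch endpoints *exactly*
  (assigned, not reconstructed through floating-point arithmetic), so
  band checks at machine precision are meaningful.
* Degenerate triangular scales ($\ell = c = u$) reproduce the crisp
  solver bitwise; identically-zero data stay identically zero.
* The perturbation probe requires a strictly positive magnitude; a zero
  perturbation would make the norm ratio undefined.

## Problem sizes

The validated runs are small by construction: the worked example is a
$17 \times 6$ grid (five time steps), the refinement ladder peaks at
$33$ nodes $\times$ $80$ steps, and the property tests use grids of at
most a few hundred nodes, so the full suite and the scripted validation
complete in seconds. The memory-faithful stepper is $O(M N^2)$; for
substantially longer horizons a short-memory or fast-convolution variant
would be the natural extension, and is out of scope here.

## Known limitations

* One space dimension, explicit stepping only; no implicit or
  Crank–Nicolson variants, no $\alpha \in (1, 2]$.
* Only the time-dependent killing-rate scenario is validated end to end;
  generic crisp $k(x, t)$ is supported but validated only through
  internal consistency (oracle equivalence, classical limit).
* The sufficient stability bounds are not sharp; runs slightly beyond
  them may still look stable on short horizons.
* General fuzzy arithmetic (sums/products of fuzzy numbers via the
  extension principle) is out of scope; only scale-times-kernel data are
  represented.
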