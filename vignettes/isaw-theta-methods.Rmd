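---
title: "Locating the ISAW theta point from exact enumeration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating the ISAW theta point from exact enumeration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isawtheta)
```

## The model and the estimator

The interacting self-avoiding walk (ISAW) on the simple cubic lattice is the
minimal model of a flexible polymer with short-range monomer attraction: a
self-avoiding walk of $N$ unit steps whose energy is $-\epsilon$ per
*contact*, a nonconsecutive nearest-neighbour monomer pair. With
$\epsilon = k_B = 1$ and fugacity $x = e^{1/T}$, everything the package
computes derives from two exact integer polynomials,
$$Z_N(x) = \sum_{m=0}^{M} c_m x^m, \qquad
  R^2_N(x) = \sum_{m=0}^{M} \Big(\sum_{R^2} R^2\, c_{m,R^2}\Big) x^m,$$
where $c_{m,R^2}$ is the exact density of states over contact number and
squared end-to-end distance. The mean-square end-to-end distance is
$\langle R^2\rangle_N(T) = R^2_N(x)/Z_N(x)$.

At the collapse (theta) temperature the chain is marginally ideal,
$\langle R^2 \rangle \sim N$, so the per-step quantity
$\langle R^2\rangle_N / N$ decreases with $N$ below $T_\theta$ and increases
above it. The finite-size estimator $T^*(N)$ is the temperature at which the
$(N{+}1)$- and $(N{-}1)$-step curves cross:
$$\frac{\langle R^2\rangle_{N+1}(T^*)}{N+1}
  = \frac{\langle R^2\rangle_{N-1}(T^*)}{N-1}.$$
The two lengths share a parity because odd- and even-step walks terminate on
disjoint sublattices of $\mathbb{Z}^3$; mixing parities produces a visibly
staggered series. This is implemented as the residual function
`crossing_residual()` and the solver `solve_t_star()`.

A formulation note: the crossing must be taken in the *mean-square* distance
per step. With the root-mean-square convention $R_N/N$, both sides decay
with $N$ at every temperature (since $R_N \sim N^{\nu}$ with $\nu < 1$
everywhere), and the residual never changes sign — there is no crossing to
solve. $\langle R^2\rangle_N / N$ changes its monotonicity in $N$ at the
theta point and yields a well-defined crossing; this package therefore works
with mean squares throughout and exposes `rms_r()` only as a convenience
wrapper.

An optional normalisation $D(n) = n\,(1 - \frac{37}{363 \ln n})$ replaces
$n$ under `correction = "log"`. This is the leading field-theoretic
logarithmic correction at the theta point (a tricritical point in three
dimensions, where mean-field exponents carry log corrections). Two readings
of the correction were possible — natural or decadic logarithm, applied to
the mean square once or squared; the implementation uses the natural
logarithm applied once to the per-step normalisation, the reading under
which the crossing temperatures computed from exact small-$N$ polynomials
agree with the published reference series to their printed precision
(e.g. $T^*(11) = 2.5421$).

## Exact enumeration

`enumerate_isaw()` performs an exhaustive depth-first search in C++ with the
first monomer at the origin and the second fixed at $(1,0,0)$; totals are
therefore $1/6$ of the free self-avoiding-walk count. The remaining
eightfold point-group symmetry is removed by canonical orientation: the
first step leaving the $x$ axis must be $+y$, and the first step leaving
the $xy$ plane must be $+z$. A completed walk contributes its orbit weight —
1 if it never leaves the axis (the straight rod), 4 if confined to the
plane, 8 otherwise. Contacts are accumulated incrementally (each newly
placed monomer adds its count of occupied non-bonded neighbours), and
direction order is fixed, so the enumeration is deterministic.

`isaw_prefixes(depth)` lists one canonical prefix per orbit with its weight
(the 22 four-step prefixes are the classic parallel decomposition);
`enumerate_prefix_job()` completes a prefix, and `merge_coef_tables()`
recombines jobs with exact weighted sums. The merged result is identical to
single-pass enumeration for every prefix depth — this is a tested contract,
not an expectation.

Two independent implementations guard correctness: a deliberately naive pure
R enumerator (`enumerate_isaw_naive()`, no symmetry reduction, contacts
recomputed from scratch per walk) must agree entry-by-entry with the reduced
C++ enumerator for all $N \le 8$, and totals are checked against the known
self-avoiding-walk counts through $N = 13$.

Counts are stored as R doubles. Every count the package can produce at desk
scale is an exact integer far below $2^{53}$, and the constructor validates
this; the TSV interchange format writes full decimal integers. A genuinely
arbitrary-precision store would only matter beyond roughly 20 steps, far
past what a single machine can enumerate anyway.

One empirical subtlety: the contact spectrum can have holes just below its
maximum. At $N = 11$ there is no 8-contact configuration although 584
nine-contact ones exist. `contact_polynomials()` therefore fills absent
contact numbers with zero coefficients rather than assuming a gapless
spectrum.

## Solving for the crossing

`solve_t_star()` scans the residual on 200 points across the bracket,
requires exactly one sign change (raising an explicit error for zero or
several — never returning an arbitrary root), and polishes with Brent's
method to `tol = 1e-10`. The default bracket is $[0.5, 20]$
$\epsilon/k_B$. Same-parity pairs develop a second, collapsed-phase crossing
at low temperature (for the 13/11 pair it sits near $T \approx 0.50$, just
inside that default), so the series builder `crossing_series()` uses a
theta-region bracket $[1, 20]$: every desk-scale collapsed-phase crossing
lies below $T = 0.5$ except those of $N = 11, 12$ at $0.45$–$0.50$, all
safely below 1. Reported series are kept at full precision; rounding to the
conventional four decimals is left to output layers.

Polynomial evaluation uses Horner's scheme in double precision. Over the
relevant range ($T \ge 0.5$, so $x \le e^2$) the terms are all positive and
no cancellation occurs; an extended-precision (long double) path exists and
the test suite confirms the double path agrees with it to below $10^{-12}$
relative. The temperature derivative $d\log R_N/dT$ used for the crossover
exponent is computed analytically from the derivative polynomials — no
numerical differencing anywhere.

## Extrapolation and the $\omega$ scan

The finite-size series are extrapolated in the scaling variable
$h = N^{-\omega}$. `extrapolate_series()` implements two tableau recursions
with points ordered by increasing $N$ (strictly decreasing $h$):

* **Neville** (polynomial): $T_{i,j} = T_{i+1,j-1} +
  (T_{i+1,j-1}-T_{i,j-1}) / [(N_{i+j}/N_i)^\omega - 1]$, the Lagrange
  interpolating polynomial evaluated at $h = 0$.
* **Bulirsch–Stoer** (rational): the same update with the bracket replaced
  by $(N_{i+j}/N_i)^\omega (1 - \frac{T_{i+1,j-1}-T_{i,j-1}}
  {T_{i+1,j-1}-T_{i,j-2}}) - 1$, with the pre-column $T_{i,-1} = 0$.

The quoted uncertainty is $\epsilon = |T_{0,k-2} - T_{1,k-2}|$, the spread
of the two deepest subtableau extrapolants. If the inner denominator or the
full bracket of the rational update degenerates (magnitude below
$10^{-300}$), the cell falls back to the polynomial update — the continuity
limit of the rational formula as its correction factor tends to one.

Two numerical facts about these recursions shaped the tests. First, the
rational recursion with a zero pre-column is *not* an exact rational
interpolant: on data lying exactly on $T + a h$ it leaves a residual of
order $10^{-8}$ (8 points), and on $(a+bh)/(1+ch)$ of order $10^{-5}$ —
reproduced identically at 60-digit precision, so this is a property of the
recursion, not of floating point. Second, its advantage over Neville is real
but regime-dependent: decisive when the data's pole lies near the sampled
$h$ range (50–65$\times$ smaller error in the package's pole-dominated test
case), marginal when the data is nearly polynomial over the sampled range.

`scan_omega()` extrapolates the odd and even parity series separately at
each $\omega$ and scores the row by the combined error
$\sqrt{\epsilon_I^2 + \epsilon_{II}^2}/2$; the estimate is the parity
average $(T_I + T_{II})/2$. Requiring one $\omega$ to stabilise both parity
series simultaneously is the point of the construction — it constrains
$\omega$ far more than a single series could. `refine_omega()` runs the
protocol used for all headline numbers: a coarse grid of step $0.01$ over
$[0.1, 3.0]$, then repeated tenfold refinement around the current minimum
down to a step of $10^{-4}$. Ties break toward smaller $\omega$. The
crossover exponent defaults to derivatives at $T_\theta = 3.713$
$\epsilon/k_B$ (the package's log-corrected headline estimate), overridable
everywhere.

## The reference series and its precision limit

`reference_t_star()` and `reference_phi()` embed published 16-value
finite-size series (odd $N = 11$–$25$, even $N = 12$–$26$, from exact
enumeration to 27 steps) so that the extrapolation stack can run and be
tested with zero enumeration cost. The package regenerates the small-$N$
entries from its own enumeration: the test suite checks $T^*(11)$,
$T^*(12)$, $T^*(13)$ (plain and log-corrected) and $\phi(11), \phi(12)$
against them. One wrinkle: the full-precision $T^*(12) = 2.37105186$ shows
that the stored value 2.3710 was truncated rather than rounded, so
agreement is asserted to one unit in the last stored digit.

These stored values carry only four decimals, and that matters for deep
extrapolation. The test suite computes the gradient of the 8-point rational
extrapolant with respect to single inputs at $\omega = 0.82$ and finds
magnitudes above 100 (several hundred at the central points); a $5\times
10^{-5}$ rounding perturbation can therefore move the extrapolant by several
times $10^{-2}$, and the combined-error landscape over $\omega$ becomes
jagged, with accidental near-zeros of $\epsilon$ far from the physical
exponent. Consequences, all visible in the acceptance tests:

* At fixed $\omega = 0.820$ the rounded series gives $T_I = 3.7390$,
  mean $3.7300$ — within $0.7\%$ of, but not equal to, values computed from
  full-precision inputs.
* The scan minimum over $\omega$ can lock onto a rounding artefact, so the
  scan-based headline numbers are not reproducible from the four-decimal
  series at all. Reproducing them requires the unrounded $T^*(N)$, which
  exist only beyond desk-scale enumeration ($N > 13$ here; the full series
  needs $N$ up to 27).

The acceptance tests assert the published values at printed precision and
are expected to fail on the scan-based quantities for exactly this reason;
they document the gap rather than hiding it. Anyone extending the package
should extrapolate full-precision series only.

## What the built-in data does and does not exercise

The reference fixtures exercise the entire tableau/scan stack against
realistic, smooth, parity-split series — but they are *rounded* published
values, so (as above) they cannot validate the scan's behaviour on
full-precision data. That part of the pipeline is instead validated on
synthetic series constructed in the tests: parity pairs converging to a
common limit with known $\omega$, data exactly linear in $h$, rational
series with controlled poles, and constant series. Those constructions have
exact known answers but lack two features of real crossing series: slowly
drifting effective exponents (multiple correction terms) and shared
systematic error between parities. Passing them shows the recursions and
the scan are implemented correctly, not that $\omega$ scanning recovers the
true exponent for arbitrary real data.

## Problem sizes and costs

Enumeration is exponential, about $4.7\times$ per added step. The package's
own test and acceptance runs use: brute-force oracle comparison to $N = 8$
(about 5 s, pure R), reduced enumeration to $N = 13$ (under half a second in
C++, $1.57\times 10^8$ weighted configurations), and extrapolation of the
16-point reference series (milliseconds). Chains to $N \approx 16$ are
comfortable on one core ($\sim$minutes); the 27-step series behind the
reference data is a cluster-scale computation ($4.3\times 10^{17}$
configurations) and is out of scope for regeneration.

## Known limitations

* Desk-scale enumeration only ($N \lesssim 16$ in practice); no
  transfer-matrix, length-doubling, or Monte Carlo (Wang–Landau) counting.
* Counts must stay below $2^{53}$ (validated); irrelevant below $N
  \approx 20$.
* Only $N' = N - 2$ crossings are implemented; other spacings and
  fugacity-space renormalisation schemes are not.
* The $\omega$-scan objective is the combined parity error alone; with
  noisy (e.g. rounded) input series its global minimum can be an artefact,
  as analysed above. The per-parity errors are reported in every scan row
  so users can apply stricter stability judgement.
* No heat-capacity or gyration-radius observables; the analysis chain is
  end-to-end-distance based.
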