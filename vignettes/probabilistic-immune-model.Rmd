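---
title: "A probabilistic model of innate-adaptive immune communication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A probabilistic model of innate-adaptive immune communication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probimmune)
```

## The model

The innate immune system (IIS) detects danger — infection, tissue damage —
and communicates with the adaptive immune system (AIS) by presenting
antigens on antigen-presenting cells (APCs). Crucially, the danger signal is
not physically linked to the antigen that caused it: the APC presents the
target antigen together with whatever else the microenvironment contains,
and the AIS must pick its target under uncertainty. `probimmune` implements
a minimal probabilistic model of this communication channel and of the two
control mechanisms that make it reliable: central tolerance (negative
selection) and a threshold form of peripheral tolerance.

**Antigenic environment.** Each antigen $A_i$ carries an *effective
abundance* $a_i$: the normalized product of concentration, accessibility to
APCs, and MHC-peptide affinity. Like molar fractions, the $a_i$ sum to one,
so $a_i$ is the probability that a randomly chosen MHC-peptide complex
displays $A_i$. A pathogen of total effective abundance $p$ rescales every
self abundance to $(1-p)a_i$; over-expression of one antigen by a factor
$k$ multiplies its abundance by $k$.

**Central tolerance.** During maturation a self-reactive lymphocyte clone
witnesses $t_0$ presentations, each showing $A_i$ with probability $a_i$,
and is deleted on first encounter with its cognate antigen. The
presentation count is binomial, and for rare antigens effectively Poisson
with rate $a_i t_0$; with $m$ naive clones per antigen, the antigen is
*tolerated* (all clones deleted) with probability
$$f_i = \left(1 - e^{-a_i t_0}\right)^m.$$
Abundant self antigens are reliably tolerated; rare ones retain reactive
clones. Given an activated IIS, the probability that an untolerated self
antigen is erroneously targeted is
$$\Pr\{A_i\} = 1 - \left(1 - a_i(1 - f_i)\right)^m
 \;\xrightarrow{m=1}\; a_i\,e^{-a_i t_0},$$
maximal near $a^{max} = 1/t_0$ (the package's `riskiest_abundance()`
returns the compact scale $1/(t_0 m)$; numerically the $m>1$ maximizer
sits at $\approx 1.21/t_0$ for $m=2$, an $O(1)$ shift the tests record).

**Peripheral tolerance.** Activation requires at least $n^*$
MHC-peptide-TCR complexes on one APC carrying $N$ complexes. The count is
Poisson-like with rate $a_i N$, so the probability of *efficient
presentation* is the Poisson survival function
$1 - e^{-a_i N}\sum_{j<n^*}(a_i N)^j/j!$, rising sharply around the
threshold $a^* = n^*/N$. The closed forms downstream replace this rise by a
Heaviside step at $a^*$ (`presentation_mode = "step"`, the default); the
exact Poisson form remains available everywhere (`"exact"`).

**Derived quantities.** With both mechanisms in force:

* the *correct targeting ratio*
  $R = p\,/\,\{(1-p)[1-(1-a^*(1-f^*))^m]\}$ compares targeting the
  pathogen against the riskiest self antigen (the one at $a^*$); for
  $m = 1$, $R = p\,e^{a^* t_0}/[(1-p)a^*]$, and in the least favorable
  case $p = a^*$, $R \approx e^{K s n^*}$ with $t_0 = KNs$. Conservative
  estimates ($n^* = 5$, $s = 0.05$, $K = 200$) already give
  $R = e^{50} > 10^{20}$.
* the *minimum detectable increment* $\mathrm{MDI} = a^*/a^{max}
  = a^* t_0 = K s n^*$ is the fold rise needed to make the most-sensitive
  self antigen detectable — the elementary model of tumor-antigen
  detection.
* the *discrimination ability*
  $\Delta = (e^{\mathrm{MDI}-1}-1)/(e^{\mathrm{MDI}-1}+1)$ (for $m = 1$;
  an odds form covers $m > 1$) quantifies the certainty that detecting a
  self antigen reflects a true abundance change rather than chance
  presentation. It depends on no parameter but the MDI.

```{r headline}
lower_bound_ratio(K = 200, s = 0.05, n_star = 5)
minimum_detectable_increment(K = 200, s = 0.05, n_star = 5)
discrimination_gap(50)   # 1 - Delta at MDI = 50
```

## Parameters and defaults

| parameter | meaning | typical value |
|---|---|---|
| `t0` | presentations during maturation ($= KNs$) | $10^3$–$10^4$ |
| `N` | MHC-peptide complexes per APC | $10^3$ |
| `n_star` | complexes needed for activation | 5–10 |
| `K` | APCs scanned during maturation | hundreds–thousands |
| `s` | fraction of APC surface scanned | 0.05 (conservative) |
| `m` | naive self-reactive clones per antigen | 1 |

All abundances are dimensionless fractions; `t0`, `N`, `n_star`, `K` are
counts; `s` is a fraction of surface area. `m = 1` is the default because
every worked example and the compact closed forms live there; the
$m$-clone generalizations are implemented and unit-tested, but note that
the $\Delta$ odds form for $m>1$ discards terms of order $(a^*)^2$ and the
$1/(t_0 m)$ scale is no longer the exact risk maximizer.

## Numerical choices

* **Log-space ratios.** $R$ spans $e^{50}$–$e^{500}$; all ratio functions
  compute in log space (`log = TRUE` returns the log without overflow).
  The quantity $1-(1-a(1-f))^m$ is evaluated through `log1p`/`expm1` with
  an asymptotic branch once $e^{-a t_0}$ underflows, so e.g. the
  self-targeting probability $a e^{-a t_0}$ keeps full relative precision
  down to $10^{-300}$ rather than dying at the $\sim\!10^{-8}$ relative
  error a literal $1-f$ subtraction produces.
* **Degenerate inputs.** $a_i t_0$ beyond the underflow point returns the
  exact limits ($f = 1$, targeting $0$) instead of raising.
* **$1-\Delta$ without cancellation.** `discrimination_gap()` computes
  $2/(e^{\mathrm{MDI}-1}+1)$ directly; at MDI $= 50$ the gap is
  $\sim\!10^{-21}$, far below the resolution of `1 - delta`.
* **Efficient presentation** is the Poisson survival function via
  `stats::ppois(..., lower.tail = FALSE)`, not a naive partial sum.
* **Tie-breaks.** The step mode uses $a_i \ge a^*$ (threshold inclusive),
  region classification uses half-open intervals with inclusive lower
  bounds, and the "ratio of three" worked example uses round-half-even.

## The Monte-Carlo layer

The simulator is deliberately built on the *exact* distributions — binomial
presentation counts during maturation, multinomial APC slot counts — so it
can validate the Poisson approximations the analytic layer uses.

One replicate of `run_scenario()` is: (1) maturation of every clone on the
*basal* environment (tolerance always precedes abundance changes);
(2) the scenario's change (pathogen insertion, over-expression with
renormalization — a sampler needs a distribution, so the Monte-Carlo side
always renormalizes, accepting the $O(k a_i)$ offset from the analytic
convention); (3) one response decision.

A response decision engages one *candidate* antigen with probability equal
to its current effective abundance, and mounts a response iff the candidate
is efficiently presented (slot count $\ge n^*$ on a sampled APC in exact
mode; abundance $\ge a^*$ in step mode) and retains a surviving reactive
clone. This rule was chosen over alternatives (e.g. choosing among all
simultaneously eligible antigens in proportion to slot counts) because it
reproduces the analytic per-antigen marginals exactly for $m = 1$ — the
closed forms are marginals, and a competition rule distorts them precisely
in the regimes where several antigens are presentable at once. Each
replicate still targets exactly one antigen or none.

Problem sizes used in the tests and the acceptance script — $10^6$
maturations, $10^5$ APC draws, $10^6$ infection replicates — put three
binomial standard errors at roughly the percent level, which is what the
oracle comparisons need; they run in seconds thanks to vectorized
`rbinom`/`rmultinom` draws, which are distributionally identical to a
slot-by-slot simulation.

One boundary effect deserves note: the reference self antigen of the
targeting ratio sits *at* $a^*$, exactly where the Heaviside approximation
is worst (the true efficient-presentation probability at threshold is
$\approx 0.5$, the step says $1$). Monte-Carlo oracle comparisons for the
ratio therefore use the exact-presentation quotient (the step-free product
form), to which the simulator converges; the step-form ratio is recovered
analytically once both antigens sit well above threshold.

## The synthetic environment generator

`generate_environment()` draws abundances log-uniformly (default) or
log-normally over a decade range (default $10^{-6}$–$10^{-2}$) and
normalizes, emulating the many-decade spread of real effective abundances.
It does **not** emulate correlated abundance fluctuations, tissue
compartments, MHC-allele structure, or commensal (non-pathogenic foreign)
antigens — passing tests on generated environments therefore demonstrates
the probability machinery, not fidelity to any measured peptidome.

## Design choices on genuinely open points

* The efficient-presentation probability is implemented as the Poisson
  survival function in $a_i N$; that is the only reading under which the
  expression is a probability.
* When a pathogen contributes several antigens, `p` is interpreted as the
  pathogen's *total* effective abundance, split equally — the only
  convention consistent with rescaling self abundances by $(1-p)$.
* $\Delta$ is a parameter-level quantity (a function of MDI and $m$ only),
  not a property of a concrete environment; `figure_data("fig4")`
  tabulates it directly.
* Region boundaries of the MDI trade-off default to $(3, 20)$ — avowedly
  conventional; they place "just over 10-fold" in the optimal-detection
  region 2 and MDI $\approx 100$ in region 3.
* The exact ratio quotient is the default; the truncated
  $p\,e^{a^* t_0}/[(1-p)a^* m^2]$ form is exposed separately
  (`truncated_targeting_ratio()`) because its validity range for $m > 1$
  is not characterized.

## Limitations

The model is static: no lymphocyte population dynamics, memory, affinity
maturation, or time-resolved infection. Peripheral tolerance is a fixed,
unspecific threshold ("peripheral ignorance"), not an active regulatory
process. Multi-APC response aggregation is not modeled (scanning of $K$
APCs enters only through $t_0 = KNs$). Commensal antigens are out of
scope. All conclusions are order-of-magnitude statements about a
deliberately minimal communication channel, not quantitative immunology.
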