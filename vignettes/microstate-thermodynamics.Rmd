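---
title: "Microstate thermodynamics of multiprotic ionization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate thermodynamics of multiprotic ionization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micropka)
```

## The model

An *n*-site molecule has 2^*n* protonation microstates, indexed by binary
occupancy vectors (1 = protonated, site 1 written leftmost). Each
microstate carries a relative free energy `g` in log10 units, defined as
the sum of micro-pKa values along any deprotonation path from the fully
protonated reference (`g = 0` for the all-ones state). The definition is
self-consistent only when every closed thermodynamic cycle on the
hypercube sums to zero; `edges_to_energies()` checks exactly this when a
system is supplied as an edge list, by breadth-first accumulation from
the reference followed by a residual scan over all supplied edges.

At proton activity 10^(−pH), a microstate that has lost `d` protons has
statistical weight 10^(d·pH − g). All observables are ratios of such
weights:

- microstate populations: base-10 softmax of the log weights;
- macrostate populations: sums over equal-`d` classes;
- apparent (macroscopic) pKa of step `j`: `S_(j-1) − S_j`, where
  `S_j = log10 Σ_{d=j} 10^(−g)` is the log binding-polynomial
  coefficient;
- average bound protons (the Bjerrum function):
  `nbar = Σ (n − d_m) p_m`.

The per-group quantities are the package's reason to exist. For group G:

- ASP (averaged site protonation), the probability that G is protonated:
  `ASP_G = Σ_{m: G protonated} p_m`. It is the site titration curve and
  satisfies `Σ_G ASP_G = nbar` identically.
- ASPA (averaged single-proton acidity):
  `ASPA_G = [H+] · Σ[G-deprotonated] / Σ[G-protonated]`, a function of
  pH because numerator and denominator mix charge states. ASP and ASPA
  obey `ASP = [H+] / ([H+] + ASPA)` pointwise, the multiprotic analogue
  of the monoprotic fraction-protonated formula.
- pK50, the single-proton midpoint: the pH at which `ASP_G = 1/2`,
  equivalently the intersection of the pASPA profile with the identity
  line. It is a pH-independent per-group constant, equal to the pKa for
  a monoprotic acid and to the intrinsic pKa for uncoupled sites.

Two limits of pASPA are available in closed form and are computed
analytically, never from a grid: at low pH the molecule is essentially
fully protonated, so pASPA converges to the group's microconstant in the
fully protonated macrostate, `g(all-ones minus G)`; at high pH the
G-protonated population is dominated by the microstate in which only G
is protonated, so pASPA converges to the one-proton microconstant,
`g(all-zeros) − g(only G protonated)`.

## Assumptions and scope

Each site carries exactly one dissociable proton; groups with several
must be modeled as several sites. Macrostates are keyed by bound-proton
count (formal charges are derived display bookkeeping from the per-site
`charge_protonated` field). Activities, ionic strength, temperature
dependence, tautomers and conformers are out of scope, as are kinetics:
`branching_probabilities()` returns equilibrium population ratios of the
product microstates, not rates. Systems are enumerated explicitly and
capped at n = 20 sites; no implicit representation is attempted.

## Numerical choices

- All exponentials are base 10 and pass through a shifted log-sum-exp,
  so populations remain finite and normalized for |pH| up to 100 and
  energies up to several hundred log10 units. ASP and pASPA are formed
  from log-domain differences of the protonated/deprotonated partition
  sums; pASPA therefore stays finite even where ASP saturates at 0 or 1
  in double precision.
- pK50 is located by scanning `ASP − 0.5` on a coarse grid (default
  window pH −5..20, step 0.05, both configurable), bracketing every sign
  change and refining all brackets simultaneously with a vectorized
  bisection to |ΔpH| ≤ 1e−9. Bisection was chosen over derivative
  methods because ASP evaluations are cheap and the bracket guarantees
  convergence. If ASP crosses 0.5 more than once — which genuinely
  happens for strongly coupled systems, see below — all crossings are
  reported, `pk50` is set to `NA`, and strict mode raises instead of
  silently picking one. No crossing inside the window is an error that
  advises widening it.
- Gauge invariance: populations depend only on energy differences, so
  energies supplied in another gauge are shifted to the all-ones
  reference with a warning at construction.
- Cycle-closure tolerance for edge input defaults to 1e−6 log10 units
  (well below any experimental microconstant precision, well above
  accumulated double-precision error); strict mode turns a violation
  into an error, lenient mode attaches the report.
- Deterministic canonical ordering everywhere (proton-loss count `d`
  ascending, then bitstring), and CSV output with 12 significant digits,
  so repeated runs are byte-identical.

## On the monotonicity of ASP

Writing `ASP = 1/(1 + 10^(pH − pASPA(pH)))` shows that ASP decreases
with pH exactly where the slope of pASPA is below 1. For anticooperative
(repulsive) coupling, pASPA is non-decreasing — average acidity can only
fall as neighboring deprotonation progresses — but its slope can exceed
1 in strongly coupled regions, and there ASP locally *increases*: a site
transiently re-protonates because deprotonation of a repulsive neighbor
raises its proton affinity faster than the proton activity drops. The
test suite therefore asserts monotone pASPA for the anticooperative
generator family, monotone ASP only for weakly coupled examples, and
monotone `nbar` (total binding) always, which is a theorem. This is also
why multiple ASP = 0.5 crossings are possible and the midpoint search
refuses to resolve such ambiguity silently.

## The synthetic-system generator

No generative model is implied by the microstate formalism itself — any
cycle-consistent `g` is admissible input — so the generators exist to
provide ground truth for testing. The pairwise (Ising-like) model sets
`g(D) = Σ_{i∈D} pKa_i + Σ_{{i,j}⊆D} c_ij` for deprotonated set `D`, with
a symmetric, zero-diagonal coupling matrix. It is cycle-consistent by
construction, reproduces the context dependence of microconstants (the
micro-pKa of site `i` is `pKa_i + Σ_{j∈D} c_ij`, rising as neighbors
deprotonate), and its parameters are exactly recoverable from the
engine's outputs: the pASPA asymptotes of site `i` are
(`pKa_i`, `pKa_i + Σ_j c_ij`). Special cases: `symmetric_system()`
(all sites equivalent — all pK50 equal; exact statistical factors
`pk + log10(j/(n−j+1))` when uncoupled) and `monoprotic()`.

`random_system()` draws intrinsic pKas uniformly on 1..12 (the span of
common ionizable groups in water) and couplings uniformly on 0..3 log10
units (zero to strong repulsion, the range seen between proximal charged
groups); seeds are mandatory arguments applied in a local RNG scope.
What the generator does not emulate: tautomerism, site-count ambiguity,
measurement noise in microconstants, and cooperative (negative)
couplings are not in the default family — tests passing on this family
show internal consistency of the thermodynamics, not robustness to
experimental error in real microconstant sets.

## Problem sizes in the test and acceptance suites

Property suites run on random systems of 2–6 sites (up to 64 microstates
and 192 edges), 200 systems for the oracle-equivalence battery, 1000
shuffled edge orders for path independence, and 1000 anticooperative
diprotic systems for the pK50-versus-macro-pKa proximity trend; profile
grids use steps of 0.1–0.5 pH units over windows wide enough to contain
every midpoint (generator family bound: intrinsic pKa plus total
coupling). These sizes give machine-precision or 1e−9..1e−10 agreement
on every identity while enumerating nothing beyond what the explicit
formalism requires.

## Known limitations

- The pK50 of a group whose ASP never reaches 0.5 inside the scan
  window (e.g. extremely acidic or basic sites) requires widening the
  window explicitly.
- Macroscopic pKa values are reported in dissociation order without
  sorting; under strong cooperativity they can be non-monotonic, which
  is flagged with a warning rather than reordered.
- `aspa()` on the linear scale can underflow to 0 (or overflow) for
  extreme pH; use `paspa()` where log-scale values are meaningful.
- Populations, not concentrations: no molar scale is ever materialized,
  only fractions and ratios.
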