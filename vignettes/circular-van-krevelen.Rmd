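---
title: "Circular van Krevelen maps: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circular van Krevelen maps: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarvk)
```

## The coordinate system

Classical van Krevelen diagrams place a compound at (H:C, O:C), the
hydrogen-to-carbon and oxygen-to-carbon atom ratios of its molecular
formula. Because the position derives from the formula alone, no layout
optimization is involved and the same compound lands on the same point in
any dataset. polarvk builds pathway maps on this principle, with two
modifications.

First, the y-coordinate can be a *mass-weighted heteroatom ratio* instead of
plain O:C:

$$\mathrm{NOPS{:}C} \;=\; \frac{n_N m_N + n_O m_O + n_P m_P + n_S m_S}{n_C\, m_C},$$

with nominal integer masses $m_N=14$, $m_O=16$, $m_P=31$, $m_S=32$,
$m_C=12$. For C~26~H~43~NO~5~ this gives
$(1\cdot14 + 5\cdot16)/(26\cdot12) = 0.301$, against O:C $= 0.192$.
Folding N, P and S into one axis spreads biological compound classes over a
wider range than O:C alone, which matters for space utilization once many
compounds share one map. Because the weights are masses, the metric extends
directly to isotope-labelled species: an isotope-qualified atom (written
`[13C]`, `[15N]`, or `D`/`T` for heavy hydrogen) counts as its parent
element in the plain atom ratios but contributes its own mass number to the
weighted terms.

Second, the map can be circularized. In polar mode,

$$\theta = \theta_0 + \delta \cdot 2\pi\,\frac{\min(\mathrm{H{:}C},\,h_{max})}{h_{max}},
\qquad r = \mathrm{NOPS{:}C} \text{ (or O:C)},$$

with $\delta = \pm 1$ for counterclockwise/clockwise. The circular form has
a fixed outer boundary (a constant space in which every compound has its
place), compounds of equal H:C line up on radial spokes that act as visual
landmarks, and connector edges cross less empty space than on an open
plane.

### Assumptions and what the model does *not* encode

Positions encode elemental composition only. Structural isomers share a
formula and therefore a coordinate ("cohabitant" compounds); the package
keeps them as distinct nodes and separates their markers geometrically (see
overlap resolution below) rather than merging them. Nothing about reaction
mechanism, stoichiometric cofactors or enzyme identity affects placement;
an edge is a straight connector between its two endpoints' fixed positions.

## Tunable parameters

All knobs live in `layout_config()`; positions depend on nothing else.

* `hc_max` (unitless H:C, default **4.0**). The angular full scale. A fixed,
  data-independent scale is what makes coordinates comparable across maps,
  so the default is anchored at the saturated extreme of CHNOPS chemistry
  (methane, H:C = 4) rather than at any dataset's observed range. Compounds
  with H:C above the scale saturate at the full-scale angle and are flagged
  `hc_saturated`; wrapping is never used, because it would alias chemically
  distant compounds onto one angle.
* `y_ratio` (`"nops"` or `"oc"`, default `"nops"`). Radial/vertical ratio.
* `r_max` (unitless, default unset). Optional radial clip; when set it also
  fixes the outer boundary circle independent of the data, which is what a
  multi-panel figure should use so all panels share one scale.
* `theta_origin` (radians, default 0) and `direction` (default
  counterclockwise): the standard mathematical polar convention. Both are
  configurable because published figures may use other conventions.
* `min_sep` (fraction of the outer radius, default **0.01**). Collision
  threshold and displacement budget for overlap resolution: 1% of the
  boundary radius separates markers at typical figure sizes while keeping
  displaced positions chemically honest.
* `max_iter` (default 25): pass cap for the resolver; `seed` is reserved
  for stochastic strategies (the built-in one is deterministic).

## Overlap resolution: contract and a geometric bound

Nodes closer than $s = \texttt{min\_sep} \cdot r_{max}$ are processed in
compound-id order, clustered by proximity, and fanned out with small
angular offsets placed symmetrically around the cluster's original angle.
Two guarantees are absolute:

1. **radius is preserved** — the radial coordinate keeps its exact chemical
   meaning, only the angle moves;
2. **per-node Euclidean displacement never exceeds $s$** — a displaced
   marker is never more than one separation threshold away from its true
   coordinate.

These guarantees impose a hard geometric ceiling. A node at radius $r$ may
move at most $2\arcsin(s/2r)$ radians before its chord displacement exceeds
$s$, and two nodes on that circle need an angular gap of at least the same
quantity to be $s$ apart. An arc of half-width one gap can hold exactly
three gap-separated points, so **at most three mutually separated nodes can
share one coordinate** under a radius-preserving, displacement-bounded
contract. For larger cohabitant groups the resolver distributes the nodes
at reduced spacing — every node still gets a distinct, deterministic
coordinate within the budget — and reports the number of remaining
sub-threshold pairs as `residual_collisions` instead of silently violating
either bound. We chose to keep both bounds hard and report residuals
because a bounded lie about position degrades gracefully, whereas an
unbounded one quietly destroys the map's central property. Pie-chart
composite nodes for large isomer groups are a possible future alternative;
they are out of scope here.

Determinism is part of the contract: clusters and fan order are id-sorted,
so permuting input rows permutes, but never changes, the output, and two
runs are bit-identical.

## Numerical and degenerate-input choices

* Ratios are stored at full double precision; the 3-decimal figures seen in
  displays are rounding at the presentation layer only.
* Carbon-free formulas (water, ammonia) have no defined ratio; they raise a
  typed error in `compute_ratios()`, and batch readers exclude them with a
  warning and a count in `metadata$carbon_free_excluded`. A reaction edge
  touching an excluded compound is a referential-integrity error, not a
  silent drop.
* A node at $r = 0$ cannot be separated angularly at all; coincident nodes
  there stay put and are counted as residual collisions.
* Charge annotations are stripped as "one optional magnitude digit plus
  sign(s)" (`"+"`, `"2-"`). `NH4+`-style ions are ambiguous under this
  grammar and should be written with explicit counts; hydrate dots and
  adduct notation are rejected outright.
* The mass table says "weighted"; the default weights are nominal integer
  mass numbers (12/14/16/31/32), and the table is explicit and overridable
  so monoisotopic masses can be substituted without code changes.
* SVG output uses fixed `%.3f` coordinate formatting and no timestamps, so
  identical scenes are byte-identical files — the property the rendering
  tests assert.

## What the synthetic generators emulate

`make_demethylation_chain()` produces degradation chains that lose one CH~2~
per step, the motif of methylated-metabolite catabolism (e.g. caffeine to
xanthine): H:C falls monotonically whenever the start has H < 2C, and the
generator *computes* the realized trend into
`metadata$hc_monotone_decreasing` instead of assuming it.
`make_homologous_series()` adds a repeating unit (default CH~2~), the
fatty-acid/lipid family pattern; note that saturated series C~n~H~2n~O~2~
sit exactly on the H:C = 2 fixed point, while unsaturated heads approach 2
strictly from below. `make_random_graph()` draws CHNOPS formulas
constrained to H ≤ 2C + 2 and heteroatoms ≤ C — plausible ratio ranges, not
plausible molecules.

What passing tests on these fixtures shows: parsing, the ratio algebra, the
fixed-coordinate property, overlap behaviour and rendering accounting are
correct on inputs with the right elemental statistics. What they cannot
show: behaviour on real genome-scale models (thousands of compounds, heavy
cofactor hubs, formula conventions in the wild) or any claim about real
metabolite identity — the bundled caffeine and aminosugar pathways are
illustrative hand-curated tables, not curated biochemistry.

## Problem sizes in the shipped tests

The suite exercises 200 random graph pairs for the fixed-coordinate
property, 1000 random element counts against a brute-force ratio oracle,
500 formula and 20 pathway round trips, coincident groups of size 2–10,
and full renders of the two demo pathways in all four mode × ratio styles.
These sizes make every property run comfortably while still giving the
property tests real coverage; all are plain constants in the test files.

## Known limitations

* Coordinates are only as good as the formulas; charge/adduct normalization
  is the caller's job.
* No cofactor filtering: hub metabolites present in the input tables are
  drawn like any other node.
* Label placement is a radial offset with bounds-based suppression, not a
  global overlap optimizer; dense maps should use selective labels.
* Isomer groups larger than three at one coordinate cannot be fully
  separated within the displacement budget (see above).
* Static SVG/PNG only; interactive navigation of -omics-scale maps is out
  of scope.
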