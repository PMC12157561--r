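# polarvk

Circular van Krevelen maps for metabolic pathways.

Metabolomics and exposomics now report far more compounds than any manually
drawn pathway chart can absorb, and automated graph layouts put the same
metabolite in a different place every time they run. polarvk takes a
different route: every compound's position is computed **from its chemical
formula alone**, so the coordinate is fixed — the same compound lands on the
same point in every pathway, dataset and figure. The package is for
metabolomics / systems-biology researchers who need consistent,
scriptable pathway maps from plain tables, with quantitative overlays.

## The coordinate system

For a formula with atom counts *n*<sub>C</sub>, *n*<sub>H</sub>,
*n*<sub>N</sub>, *n*<sub>O</sub>, *n*<sub>P</sub>, *n*<sub>S</sub>:

* **H:C** = *n*<sub>H</sub>/*n*<sub>C</sub>, **O:C** =
  *n*<sub>O</sub>/*n*<sub>C</sub> — the classical van Krevelen axes;
* **NOPS:C** = (14 *n*<sub>N</sub> + 16 *n*<sub>O</sub> + 31 *n*<sub>P</sub>
  + 32 *n*<sub>S</sub>) / (12 *n*<sub>C</sub>) — a mass-weighted heteroatom
  ratio that spreads biological compounds over a wider range than O:C and
  extends naturally to isotope-labelled species.

For C₂₆H₄₃NO₅: H:C = 43/26 = 1.654, O:C = 5/26 = 0.192, NOPS:C =
(1·14 + 5·16)/(26·12) = 0.301.

On the **circular** map, H:C maps linearly onto the angle (full scale
`hc_max = 4`, the saturated extreme of CHNOPS chemistry) and NOPS:C (or
O:C) is the radial distance. Reactions are drawn as directed edges between
the fixed positions; isomers sharing one formula are separated by a
deterministic, displacement-bounded angular fan.

## Worked example

```r
library(polarvk)

compute_ratios(parse_formula("C26H43NO5"))
#> <ratio_set> H:C 1.654  O:C 0.192  N:C 0.038  NOPS:C 0.301

g <- demo_pathway("caffeine")        # 14 curated compounds, 16 reactions
g
#> <pathway_graph> 14 compounds, 16 reactions — caffeine demo pathway

cfg <- layout_config()               # polar, NOPS:C radius, hc_max = 4
l   <- resolve_overlaps(polar_layout(g, cfg))
head(tibble::as_tibble(l)[, c("compound_id", "formula", "hc", "theta", "r", "displaced")], 5)
#> # A tibble: 5 × 6
#>   compound_id formula      hc theta     r displaced
#>   <chr>       <chr>     <dbl> <dbl> <dbl> <lgl>
#> 1 caf         C8H10N4O2  1.25  1.96 0.917 FALSE
#> 2 px          C7H8N4O2   1.14  1.78 1.05  TRUE
#> 3 tb          C7H8N4O2   1.14  1.80 1.05  FALSE
#> 4 tp          C7H8N4O2   1.14  1.81 1.05  TRUE
#> 5 1mx         C6H6N4O2   1     1.56 1.22  TRUE

render_map(g, l, style_spec(label_mode = "all"), "caffeine_map.svg")
#> <render_report> caffeine_map.svg
#>   nodes 14  edges 16  labels 14 (suppressed 0)
#>   clipped 0  residual collisions 0  carbon-free excluded 0
```

Reading the numbers: caffeine (C₈H₁₀N₄O₂) sits at angle 1.96 rad (its H:C
of 1.25 on the 0–4 angular scale) and radius 0.917 (its NOPS:C). Its three
demethylation products share the formula C₇H₈N₄O₂, hence one chemical
coordinate; the resolver fanned two of them (`displaced = TRUE`) by less
than 1% of the outer radius so all three markers are visible, while `tb`
kept the exact position. The report confirms every input row was drawn.
Attach per-compound values with `attach_overlay()` (numeric values get a
diverging blue–white–red scale symmetric about zero; labels get a
categorical palette), and compare pathways side by side with
`render_panel()`, which shares one radial scale across panels.

A command-line interface wraps the same pipeline
(`inst/cli/polarvk ratios|layout|plot|demo ...`); see `cli_main()`.

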