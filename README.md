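# cartivscreen

Design and sort-seq analysis of CARTIV synthetic promoter libraries.

CARTIV promoters (chimeric antigen receptor tumor-induced vectors) are
short synthetic promoters built from tandem GAS (STAT1/IFN-γ) and κB
(NF-κB/TNF-α) binding elements in front of a minimal TK core, intended to
switch a therapeutic payload on inside the tumor microenvironment and off
outside it. Optimizing the key bases inside those elements is done by
screening a degenerate library — IUPAC codes at 16 positions, a design
space of 2¹⁶ = 65,536 promoters — through repeated rounds of FACS
sorting (stimulate, keep the brightest; withdraw stimulation, keep the
dimmest) followed by binned sorting and deep sequencing of six
populations: low/med/high × activated/non-activated.

`cartivscreen` implements the full computational side of such a screen,
for researchers building inducible synthetic promoters or analysing
sort-seq selections generally:

* **Library design** — parse IUPAC degenerate templates, compute
  complexity, enumerate or sample the variant space
  (`parse_template()`, `complexity()`, `enumerate_variants()`,
  `sample_variants()`, the bundled `cartiv_template()`).
* **Screen simulation** — a seeded generative model of the whole screen:
  log-normal reporter expression with basal, per-cytokine and synergistic
  components, quantile-gated ON/OFF sorting over three rounds, six final
  populations, Dirichlet-multinomial sequencing counts, FASTQ emission
  with substitution errors (`screen_library()`, `screen_config()`,
  `run_screen()`, `emit_fastq()`).
* **Read counting** — template-anchored extraction of the variable
  positions turns reads into variant keys with an explicit rejection
  ledger (`extract_variant_key()`, `count_population()`,
  `count_screen_fastq()`, `merge_counts()`).
* **Candidate selection** — the 150-read cutoff and the cross-population
  "x-trend" ranking: a variant whose frequency rises low→med→high in the
  activated arm, or falls in the non-activated arm, is a switch candidate,
  ranked by the symmetric log-ratio score
  `S = log2((f_am + f_ah) / (2 f_al)) + log2((2 f_nl) / (f_nm + f_nh))`
  (`filter_low_count()`, `normalize_frequencies()`, `trend_scores()`,
  `select_candidates()`).
* **Activity scoring** — fold induction `x(c)/x(none)`, background
  `x(none)/ref(none)`, synergism `x(GK)/(x(G)+x(K))`, and the composite
  potency index `x(GK)/bg(GK) − x/bg + x(GK)/(xG+xK)` from per-condition
  geometric-mean fluorescence (`fold_induction()`, `background_ratio()`,
  `synergism()`, `potency()`, `score_panel()`).
* **Composition reporting** — per-variable-position base frequencies of a
  candidate set with per-element summaries in both ratio orientations
  (`position_profiles()`, `element_summary()`).

Everything is tibble-in/tibble-out and pipe-friendly; screen results
support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Simulate a 1,000-variant screen with 20 planted improved variants, select
candidates, and profile their composition:

```r
library(cartivscreen)
library(dplyr)

tpl <- cartiv_template()
tpl
#> <degenerate_template> 174 bp, 16 variable positions, complexity 65,536

lib <- screen_library(tpl, n_variants = 1000, n_planted = 20, seed = 1)
scr <- run_screen(lib, screen_config(seed = 2))
glance(scr)
#> # A tibble: 1 × 6
#>   n_variants n_planted rounds read_depth total_reads n_observed
#>        <int>     <int>  <int>      <int>       <int>      <int>
#> 1       1000        20      3      22368      134208        583

cand <- select_candidates(scr$counts, n_top = 17)
head(select(cand, key, total, score, rank, activated_trend, relaxed_trend), 5)
#> # A tibble: 5 × 6
#>   key              total score  rank activated_trend relaxed_trend
#>   <chr>            <dbl> <dbl> <int> <lgl>           <lgl>
#> 1 CGGTCGAGGTTGAGCC   201 1.41      1 TRUE            FALSE
#> 2 CGGCCGGAACCGAGTC  3228 1.30      2 TRUE            TRUE
#> 3 TCGCCGAAATCGGACT  3517 1.10      3 TRUE            TRUE
#> 4 TCACCAAAATCAGACT  3623 0.873     4 FALSE           TRUE
#> 5 CGACCAGGGCTGGACT  2618 0.866     5 FALSE           TRUE

sum(cand$key %in% lib$key[lib$planted])
#> [1] 16
```

Of the 17 shortlisted candidates, 16 are planted improved variants: out of
1,000 library members the trend analysis pulls back almost exactly the
variants that were given low basal expression, strong combined-cytokine
response and high synergy. The composition report shows that no variable
position is locked to one base among the selected candidates:

```r
element_summary(position_profiles(cand, tpl))
#> # A tibble: 4 × 6
#>   element orientation n_positions   min  mean   max
#>   <chr>   <chr>             <int> <dbl> <dbl> <dbl>
#> 1 GAS     alternate             6 0.412 0.441 0.471
#> 2 GAS     designated            6 0.529 0.559 0.588
#> 3 kappa   alternate            10 0.294 0.488 0.765
#> 4 kappa   designated           10 0.235 0.512 0.706
```

Both ratio orientations are always reported (designated allele = first
base of the IUPAC expansion alphabetically: Y→C, S→C, R→A).

To score individually validated promoters from flow-cytometry geometric
means, lay them out long (`promoter`, `condition`, `geomean`, with
`minitk` and optionally `uninfected` reference rows) and call
`score_panel()`; see the methods vignette
(`vignettes/cartiv-screen-methods.Rmd`) for the model, parameter
rationale and limitations.

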