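---
title: "Designing and analysing CARTIV promoter sort-seq screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analysing CARTIV promoter sort-seq screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartivscreen)
library(dplyr)
```

## The problem

CARTIV promoters (chimeric antigen receptor tumor-induced vectors) are
short synthetic promoters assembled from tandem transcription-factor
binding blocks — GAS elements read by STAT1 downstream of IFN-γ, κB
elements read by NF-κB downstream of TNF-α, optionally hypoxia elements —
in front of a minimal TK core. The goal is a promoter that is quiet at
baseline, switches on strongly when tumor-microenvironment cytokines are
present, and switches off again when they are removed.

Because the effect of individual bases inside the binding cores is not
predictable, optimization proceeds by screening: a degenerate oligo fixes
the scaffold and varies a handful of key positions through IUPAC codes, the
resulting library is transduced into reporter cells at low MOI (at most one
construct per cell), and cells are put through repeated rounds of FACS
sorting — stimulate and keep the brightest cells (ON sort), withdraw
stimulation and keep the dimmest (OFF sort). After the last round the pool
is split into a stimulated and an unstimulated arm, each arm is sorted into
low/medium/high fluorescence bins, and all six populations are deep
sequenced. A variant whose read frequency rises across the bins of the
stimulated arm and falls across the bins of the unstimulated arm (the
"x" pattern when the two frequency profiles are overlaid) behaves as a
switch and is a candidate for individual validation.

`cartivscreen` implements this entire computational pipeline: library
design arithmetic, a faithful stochastic simulator of the screen, read
counting, candidate selection, per-position composition reporting, and the
activity metrics used to score validated promoters.

## Library model

A degenerate template is an IUPAC DNA string; every non-ACGT code is a
variable position carrying its allowed-base set (Y = C/T, S = C/G,
R = A/G, ...). The bundled `cartiv_template()` is the GK library oligo: two
13-base GAS cores `AYTTCCSGGAART` separated by a fixed linker and two κB
cores `GGRRRTTYYC` separated by a fixed linker, with fixed cloning flanks
and the minimal-TK side fixed. (A 14-base GAS core ending in `...ARTG` is
sometimes quoted for the STAT1 consensus; the bundled template follows the
13-base core of the synthesized oligo, which is authoritative for the
library actually built.) It has 16 two-fold degenerate positions, so the
design space is

$$\prod_{j=1}^{16} |A_j| = 2^{16} = 65{,}536$$

distinct promoters. A variant is identified by its 16-character allele
string (its *key*), not by the full 174-base sequence; keys are unique
within a template and make alignment trivial (see below). Coordinates are
0-based; case in the input carries no meaning.

## The screen simulator

The simulator exists so that every downstream stage is testable end to end
without any external data, at the scale of the real experiment.

**Expression model.** A cell carrying variant $v$ under stimulation
indicators $(g, k, h)$ fluoresces

$$X = \mu_v \, e^{\varepsilon}, \qquad
\mu_v = b_v\,(1 + g\,a^G_v + k\,a^K_v + h\,a^H_v + g\,k\,s_v), \qquad
\varepsilon \sim \mathcal N(0, \sigma_v^2),$$

i.e. multiplicative log-normal noise around a linear-in-indicators mean:
$b_v$ is the basal level (arbitrary fluorescence units), $a^G, a^K, a^H$
the single-cue response coefficients, $s_v$ the synergy active only under
combined IFN-γ + TNF-α, and $\sigma_v$ the log-scale cell-to-cell spread
(default 0.8, matching the roughly one-decade spread of reporter
distributions on a flow cytometer). The geometric mean of a large sample is
$\mu_v$, which is why geometric means are the measurement statistic
throughout.

**Library conditions.** `screen_library()` assigns parameters. Every
library member is a functional promoter variant — the 16 positions tune a
working scaffold rather than break it — so the background is a continuum:
$b \sim \mathrm{LogNormal}(0.5, 0.8)$, $a^G \sim U(0,2)$,
$a^K \sim U(0,6)$ (the TNF-α response dominates the IFN-γ response in this
promoter family), $s \sim U(0,6)$. Planted "improved" variants sit at the
favorable extreme: $b = 1$, $a^G = 2$, $a^K = 6$, $s = 12$ — low basal,
strong induction, synergy above the background range. Under these
conditions a simulated 1,000-variant screen retains roughly 160–250
variants past the read filter, the same order of diversity the real screen
retained, rather than collapsing onto the planted set.

**Sorting.** Each round draws `cells_per_round` cells (default $10^5$)
from the current variant abundances, simulates fluorescence with cytokines
and keeps the top `positive_gate` fraction (default 15%), then simulates
without cytokines and keeps the bottom `negative_gate` fraction (default
30%). Gates are quantiles of the realized fluorescence distribution, not
fixed thresholds — FACS gates are drawn per plot, and quantile gating is
the reproducible equivalent. The OFF gate is split at its median into a
"returned to background" half and a "low expressing" half pooled with
configurable weights (default 50/50, i.e. uniform across the gate), because
both kinds of cells are collected in practice and the exact pooling is an
experimental choice. Untransduced cells (the other 70% at MOI < 0.3) are
carried as an autofluorescent pseudo-variant; the first positive gate
removes them and they are never sequenced. A gate that empties the
population is a hard error naming the round. Slow-OFF behaviour is not
modelled kinetically; variants with high basal simply survive OFF sorts
poorly, which reproduces the phenomenon at the selection level.

**Final split and sequencing.** After `rounds` rounds (default 3) the pool
is split into an activated and a non-activated arm; each arm's cells are
binned by the tertiles of the arm's fluorescence distribution into
low/med/high. Each of the six populations is sequenced at `read_depth`
reads (default 22,368, the average per-sample depth of the screen this
package models). Counts are Dirichlet-multinomial: bin abundances are
perturbed by a Dirichlet draw with concentration `overdispersion`, then
reads are multinomial. The concentration models the PCR template
bottleneck — amplification starts from roughly as many genomes as cells
were sorted into the bin — so the default is 30,000, about one final bin's
cell count at the default configuration; `Inf` recovers a plain
multinomial. (A much smaller concentration would reduce the effective
sequencing depth to a few hundred reads and erase the biological signal; a
value tied to the physical bottleneck keeps depth and noise in the regime
the experiment operates in.)

`emit_fastq()` writes the reads with i.i.d. per-base substitution errors
(default 0.001) and constant placeholder qualities; everything is
reproducible from the single integer `seed` in `screen_config()`.

**What the simulator does not emulate**: cytometer optics and
compensation, doublets, PCR chimeras, indels, context-dependent error
profiles, explicit ON/OFF kinetics, and any sequence–function relationship
(activity parameters are assigned to keys, not computed from sequence).
Passing tests therefore demonstrate that the *analysis* recovers what the
*model* plants — they do not certify performance on real FACS data with
artifacts outside this model.

## Read counting

Because all true library members differ only at the 16 known positions,
single-base resolution needs no denoising or alignment:
`extract_variant_key()` anchors each read by exact match of a 12-mer seed
from the template's invariant prefix (falling back to offset-0 alignment
for reads already template-length, so errors inside the seed do not lose
reads), tolerates up to `max_fixed_mismatches` substitutions at fixed
positions (default 2), and reads the variable-position bases verbatim as
the key. Reads whose variable base falls outside the designed set are
rejected as `disallowed_allele` under the strict default; a permissive
mode keeps them under their observed (off-design) keys. Reverse
complements are tried before rejecting. Indels are not handled: a read in
which the template does not fit is rejected as `length`, which is the
honest behaviour for fixed-length amplicon sequencing without inventing an
aligner the procedure does not specify. Per-population rejection ledgers
(reason × count) accompany every count column, so assigned + rejected
always equals reads processed.

## Candidate selection

Variants with fewer than `min_total = 150` reads summed across the six
populations are removed. (The cutoff is read as a *sum* across the six
populations; requiring 150 in *each* population would discard nearly
everything at realistic depths.) Counts are converted to within-population
frequencies with a pseudocount (default 0.5, Anscombe-style) so log-ratios
stay finite:

$$f_{v,p} = \frac{c_{v,p} + \tfrac12}{N_p + \tfrac12 n}.$$

The trend flags are direct transcriptions of the selection pattern:
*activated trend* if $f_{\text{act,low}} < \min(f_{\text{act,med}},
f_{\text{act,high}})$, *relaxed trend* if $f_{\text{non,low}} >
\max(f_{\text{non,med}}, f_{\text{non,high}})$; a variant qualifies if
either holds (`mode = "or"`, the published criterion; `"and"` is a
stricter option). Qualifying variants are ranked by the score

$$S_v = \log_2\!\frac{f_{\text{act,med}} + f_{\text{act,high}}}
{2 f_{\text{act,low}}}
+ \log_2\!\frac{2 f_{\text{non,low}}}
{f_{\text{non,med}} + f_{\text{non,high}}},$$

which is 0 for a flat profile, positive for the "x" pattern, and negates
under swapping the arms. The score is this package's operationalization —
the selection it mimics was stated as criteria plus ranking "by
abundance", without a formula — so ties are broken deterministically by
total read count and then key, and the shortlist defaults to the top 17.
Frequencies (not raw counts) are ranked because sorted populations are
sequenced at different effective depths.

## Activity scoring

Validated promoters are measured per condition (`none`, `G`, `K`, `GK`,
optionally with `H`) as geometric-mean fluorescence, alongside two
reference populations: cells carrying the miniTK core alone and
non-infected cells. The metrics are

* fold induction $= x(c)/x(\text{none})$;
* background $= x(\text{none}) / \text{ref}(\text{none})$, with the
  reference selectable (`minitk` or `uninfected`) because both conventions
  are in use and they answer different questions (leakiness of the added
  elements vs. leakiness of the whole cassette);
* synergism $= x(GK) / (x(G) + x(K))$, 1 at exact additivity;
* potency $= \dfrac{x(GK)}{bg(GK)} - \dfrac{x}{bg} +
  \dfrac{x(GK)}{x(G)+x(K)}$, where $bg$ is the miniTK geometric mean under
  the matching condition.

At the fixed point — a promoter identical to miniTK with an exactly
additive GK response — potency is $1 - 1 + 1 = 1$. Whether $x$ in the
first two terms is a raw geometric mean (the dimensionally consistent
reading: the $bg$ division does the normalizing) or is itself first
normalized to the promoter's own unstimulated level is genuinely
underdetermined by the published summaries, so both are exposed
(`x_mode = "raw"` default, `"fold"` alternative); they agree at the fixed
point and under global rescaling. All metrics are invariant under a global
multiplicative recalibration of the cytometer, which every test of them
asserts.

## Composition reporting

With fixed-length keys, the "multiple sequence alignment" of selected
candidates is positional by construction. `position_profiles()` tallies
per-position base frequencies and the frequency of the *designated*
allele, defined here as the alphabetically first base of the IUPAC
expansion (Y→C, S→C, R→A). Which orientation a published per-position
"ratio" refers to is ambiguous in general, so `element_summary()` always
reports both the designated ratio and its complement per element
(GAS/κB); for two-fold degenerate positions the two orientations are exact
complements, and collapsing to one would silently absorb the ambiguity.

## Numerical and testing choices

* All randomness flows through explicit integer seeds via `withr`,
  leaving the caller's RNG state untouched; identical configurations give
  byte-identical outputs.
* Enumeration refuses templates beyond `limit` (default $2^{16}$) and
  points to sampling, preventing accidental combinatorial blowup.
* Dirichlet draws use gamma sampling; a degenerate all-zero draw (possible
  at tiny concentrations) falls back to the modal variant rather than
  dividing by zero.
* The selection-neutrality test compares final counts to input frequencies
  with a variance-adjusted chi-square: sequential cell sampling through
  $S$ sorting stages keeping $m_s$ cells inflates count variance by
  $F = \frac{N + A}{1 + A} + N \sum_s \frac{1}{m_s}$ ($N$ read depth, $A$
  Dirichlet concentration), a design-based null computed from the
  simulator's own stage log, not a fitted tolerance.
* Test problem sizes are chosen to exercise the study-scale conditions
  while staying quick: the neutrality property runs 20 seeds of a
  200-variant neutral screen at full default depth, the recovery property
  10 seeds of a 1,000-variant screen with 20 planted variants (requiring
  at least 16 of 20 planted in the top 40 in *every* seed), and the
  round-trip property one full-depth screen re-counted from error-free
  FASTQ, byte-exactly.

## Known limitations

* Published wet-lab reference values for this promoter family (e.g. fold
  inductions of 7.66/11.92, synergism 1.46/2.28, backgrounds 1.04–15.29,
  potency 11.38/6.96, a 497-sequence enriched pool filtering to 161) stem
  from unpublished raw FACS/NGS measurements and are therefore not
  recomputable here; they serve as reference phenotypes for the scales the
  simulator targets, and the property-based suite covers the claims
  instead.
* The no-indel assumption makes counting blind to insertion/deletion
  artifacts; such reads are rejected, not recovered.
* The trend score is a ranking device, not a test statistic; no
  differential-abundance model or multiple-testing control is attempted,
  because the selection it implements is a deterministic ranking.
* Activity parameters are attached to variants independently of their
  sequence; the package cannot say *why* a given allele combination is
  strong, only whether the screen and scoring machinery would find it.
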