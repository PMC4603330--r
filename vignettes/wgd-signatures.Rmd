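---
title: "Superblock multiplicity signatures of ancient whole-genome duplication"
author: "wgdsig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Superblock multiplicity signatures of ancient whole-genome duplication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdsig)
```

## The problem and the model

After a whole-genome duplication (WGD), every gene is present in two (or,
for a triplication, three) copies. Fractionation — the gradual loss of
redundant duplicates — then erodes the paralog signal inside the descendant
genome `W`, so self-comparison underestimates old events. Comparison with a
related reference genome `R` is more sensitive: fractionation rarely removes
*both* members of a duplicate pair, so each surviving copy still has an
ortholog in `R`. Two regions of `W` that were once duplicates of each other
may share almost no paralogs yet both align, gene by gene, to the *same*
region of `R`.

`wgdsig` operationalises this as follows:

1. **Syntenic blocks.** Homolog anchors between `W` and `R` are chained into
   collinear blocks (minimum `minL` anchors, maximum inter-anchor gap
   `max_gap` genes on both genomes). All coordinates are 1-based gene
   ordinals along chromosomes: the method counts genes, not base pairs.
2. **Superblocks.** Per reference chromosome, two blocks *overlap* when
   their reference footprints share at least `T` genes. Connected components
   of the overlap graph with two or more members are superblocks; the
   multiplicity `B` of a superblock is its number of member blocks.
3. **Tail fit.** The empirical distribution `f(B)` is fitted with
   `f(B) = a exp(-cB)` by unweighted ordinary least squares of `ln f(B)` on
   `B`, restricted to `B >= B_min` with `f(B) > 0`. Only the decay rate `c`
   is retained: it is markedly more stable than `a` across tail definitions
   (a property the test suite checks on resampled geometric tails).
4. **Panel ranking.** `c` is computed for every (target, reference) pair,
   `minL` in {3,4,5} and cutoff `B_min` in {2,3,4}. For each genome pair
   {G, H}, wins of `c(G) > c(H)` are counted over all shared conditions
   (references exclude G and H themselves, which is why a 15-genome panel
   gives 13 x 3 x 3 = 117 comparisons per pair). Genomes are ranked by the
   number of opponents they beat head to head: rank 1 has the largest `c`
   profile and the least WGD signal.

## Parameters that matter

| parameter | default | meaning and rationale |
|---|---|---|
| `minL` | 5 (sweep 3–5) | anchors needed to validate a block; 4 and 3 remain credible and the panel sweeps all three so no single choice dominates |
| `max_gap` | 20 genes | maximum interspersed run of unmatched genes inside a block, on both genomes; block spacing is not directly part of the signature, so it is exposed but not swept |
| `T` | 5 (optionally 10) | reference-footprint overlap, in genes, for two blocks to group; 5 and 10 behave almost identically, below 5 multiplicities become artifactually high, above 10 superblocks are missed — values outside [5,10] warn |
| `B_min` | sweep 2–4 | tail cutoff of the fit; `f(2)` and `f(3)` are inflated relative to a pure exponential and depend strongly on the genome pair, so fits with and without them are aggregated |
| `lambda` | 1 per time unit | simulator fractionation rate; with the default timeline a duplicate born one time unit ago survives with probability `exp(-1)` |

## Numerical and design choices

- **Log-linear fit.** Natural logarithm, unweighted OLS, closed-form normal
  equations — deterministic and exactly reproducible. Weighting by counts
  would change estimates; the unweighted form is the plainest reading of a
  "log-linear fit" and is documented so results can be reproduced. Zero
  counts are *excluded*, never imputed (plotting conventions that display
  `f = 0` as `f = 1` do not feed the regression). A fit needs at least two
  positive points; otherwise the analysis cell is recorded as missing and
  simply drops out of the win counting.
- **`c` via raw counts.** `f(B)` stores counts, not proportions; `c` is
  invariant to positive rescaling, so the choice is observationally neutral
  (`a` is not, which is one more reason only `c` is used).
- **Overlap as connected components.** "Blocks spanning a contiguous
  region" is formalised as connected components under pairwise >= `T`-gene
  overlap. Components are order-independent and make the union span
  contiguous in coverage. The alternative — the maximum number of blocks
  stabbing a single point — would bound `B` differently; the pairwise
  definition was chosen because overlap is defined between two blocks, and
  the component reading follows from chaining those pairwise overlaps.
  Overlap is strand-agnostic: an antiparallel block occupies the same
  reference footprint.
- **Chaining.** Scoring by anchor count with summed similarity as
  tie-break, iterative best-chain extraction, deterministic tie-breaks
  (parallel before antiparallel, smallest predecessor index). Chains
  extracted with anchor count >= L are identical whether the chainer stops
  at `minL = L` or at any smaller threshold, so the pipeline chains once at
  the smallest `minL` of a sweep and re-filters — verified by test.
- **Ties and missingness in ranking.** Exact ties in `c` count for neither
  genome; cells with undefined fits are skipped. Dominance is head-to-head
  (beat more opponents), with total wins and then lexicographic id as
  tie-breaks; totals are reported alongside.

## What the simulator emulates — and what it does not

`simulate_pair()` / `simulate_panel()` generate a stated world: an ancestor
of 2000 genes on 10 chromosomes; a star split at time 1; scripted WGD or
triplication events per lineage; exponential fractionation with rate
`lambda = 1` acting between events and to the present; 30 inversions and 10
translocations per lineage; homolog similarity decaying as
`100 exp(-0.21 t)` with truncated Gaussian noise (sd 1.5), so orthologs from
the split have a mode near 81% and pre-split homeologs sit lower (near 73%
for a divergence of 2 units) — echoing the shape of real similarity
histograms.

Two modelling decisions deserve emphasis:

- **Fractionation is "protected-copy".** For each ancestral gene with more
  than one copy, one uniformly chosen copy is immune and every *other* copy
  survives an interval `t` independently with probability `exp(-lambda t)`.
  This realises both constraints at once: the surviving-duplicate fraction
  is exactly `exp(-lambda t)` (binomially, which the calibration test
  checks), and no gene ever loses its last copy — loss of both members of a
  pair is lethal. Loss is unbiased between post-WGD subgenomes and acts
  gene by gene (no segmental deletion).
- **Panels share an ancestral WGD.** The decay rate `c` is undefined when
  `f(B)` is empty, and a lineage with literally no duplication anywhere in
  its history produces (almost) no superblocks at all. Real panels do not
  have such genomes: all flowering plants, for instance, share ancient
  polyploidy, which is why a basal unduplicated lineage shows a *large* `c`
  rather than a missing one. Panel scenarios therefore place one shared
  duplication in the common ancestor (default time 1.3); "0, 1, 2 WGDs"
  always refers to lineage-specific events on top of that background.

The simulator does **not** model sequence evolution (similarities are a
parametric decay, not alignments), tandem duplication, transposition noise,
biased subgenome fractionation, gene conversion, or more than one split
time per panel (the phylogeny is a star). A green end-to-end test therefore
establishes that the pipeline recovers *relative* WGD history from
gene-order signal under exponential, unbiased loss — not that it is robust
to assembly artifacts or to phylogenetic structure in the reference panel,
both of which shape real rankings.

## Degenerate inputs and edge behaviour

Empty homolog tables yield empty block sets; empty block sets yield an empty
`f(B)`; every fit on fewer than two positive points is an explicit
missing-cell condition rather than a number. Histogram bins for similarity
summaries are half-open `[lo, lo + w)` with the top bin closed so a
similarity of exactly 100 is representable. Interval overlap requires
`lo <= hi` and errors otherwise. Tandem duplicates are not collapsed before
chaining — a known limitation; heavily tandem-expanded families can inflate
anchor counts.

## Limitations

- The chainer is a deliberate simplification of SynMap/DAGchainer (no
  gap-length penalties, no syntenic-depth quotas, no Ks filtering);
  imported DAGchainer-style block text is the recommended path for real
  data, and both paths produce identical downstream objects.
- `c` conflates WGD count with event timing, fractionation rate and
  rearrangement intensity; the panel sweep neutralises reference and
  threshold biases, not these biological confounders. In real data, clade
  membership can explain `c` about as well as WGD count — rankings are
  evidence, not proof.
- No confidence intervals on `c` are produced; the win-counting design is
  the intended way to compare genomes, not the raw values.
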