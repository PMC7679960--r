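---
title: "Consensus-mutagenesis construct design: model, conventions and validation"
author: "consmut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus-mutagenesis construct design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consmut)
```

## The problem and the model

Flexible or unstable proteins — unliganded human membrane transporters are a
notorious case — often cannot be purified at the concentrations that
structural work demands. Consensus mutagenesis exploits the observation that
the residue most prevalent at a position across evolutionary homologs tends
to be stabilizing: replacing a rare wild-type residue by the column
consensus, at many positions at once, can raise thermostability enough to
rescue purification.

`consmut` operationalizes this as a per-position score. Let the wild-type
(reference) sequence be embedded in an alignment of homologs. For reference
residue $i$ sitting in alignment column $c$, with column frequencies $f_a(c)$
over the 20 standard amino acids,

$$\mathrm{score}(i) \;=\; \frac{f_{\mathrm{cons}}(c)}{f_{\mathrm{WT}}(c)},
\qquad f_{\mathrm{cons}}(c) = \max_a f_a(c),$$

and a construct at threshold $t$ applies **every** substitution with
$\mathrm{score}(i) > t$ whose position lies inside a user-supplied region
mask (for membrane proteins, typically the transmembrane segments; soluble
loops and termini are left untouched). Sweeping a ladder of thresholds gives
a panel of constructs with graded mutation loads; which member of the panel
behaves best is an experimental question (fluorescence-based thermostability
screens), not one this package answers.

The model's assumptions are worth stating plainly: columns are treated
independently; frequency is used as a proxy for stability with no explicit
energy model; and the alignment is taken as given, so alignment errors and
taxon-sampling bias propagate directly into the scores. The score is also
asymmetric by construction — it only ever proposes moving *toward* the
consensus, never away from it, and a position where the wild type already is
the (co-)consensus scores exactly 1 and is never selected.

## Parameters that matter

* **`threshold`** (dimensionless, strict inequality, no default in the CLI's
  `design` subcommand). The useful cutoff is protein-specific; a value that
  yields a ~20 % load on one target may yield almost nothing on another,
  which is why `sweep` over a descending ladder (e.g. `3, 2.22, 1.5`) is the
  intended entry point and why defaulting silently would mislead.
* **`pseudocount`** (counts, default 0). Added to all 20 residue counts
  before normalization. At 0 the score is the raw frequency ratio; a
  positive value regularizes columns where the wild-type residue is absent
  (otherwise scored $+\infty$, see below). It never changes the frequency
  *ordering* within a column.
* **`weighting`** (`uniform` default, `position` optional). Position-based
  sequence weights damp redundant homologs (a column residue shared by $k$
  of the sequences among $r$ types contributes $1/(rk)$ to each). The
  default is uniform because the score is defined on raw frequencies;
  weighting is an explicit, non-default analysis choice.
* **`includeReference`** (default `TRUE`). The reference is itself a homolog
  and counts toward the frequencies. Excluding it mainly matters in small
  alignments, where its single count can turn an absent wild type (ratio
  $\infty$) into a weakly present one.
* **Region mask.** 1-based inclusive residue ranges on the ungapped
  reference; overlaps are merged on ingest. Mutation load is nonetheless
  reported as a percentage of the *full* reference length, so panel labels
  remain comparable across masks.

## Numerical conventions and degenerate inputs

* **Coordinates.** Alignment columns and reference residues are both
  1-based (R convention and standard mutation notation, `V123L`). The
  mapping between them drops columns where the reference is gapped.
* **Gaps and ambiguity codes.** `-` (and `.` on input) plus B/Z/X/U/O are
  absence of evidence: they contribute to a column's gap fraction, never to
  its counts. Frequencies are therefore a distribution over amino acids
  actually observed. A column with no standard residue at all is flagged;
  its positions carry `NA` ratios, are never selected, and are listed as
  skipped positions in the panel report.
* **Absent wild type.** With no pseudocount, $f_{\mathrm{WT}} = 0$ makes the
  literal formula undefined; such a position is maximally non-consensus, so
  it is scored $+\infty$ and exceeds every finite threshold, rather than
  being silently dropped. TSV output serializes this as the token `inf`.
* **Ties.** If the wild-type residue ties for most frequent, the consensus
  *is* the wild type (score 1): never mutate a position already at
  (co-)consensus. Otherwise the alphabetically first tied residue wins —
  deterministic, if arbitrary.
* **Strict inequality.** Selection uses `ratio > t`; a position scoring
  exactly the threshold is excluded.
* **Rounding.** Mutation loads are rounded half *up* to one decimal
  (`floor(10x + 0.5)/10`, not banker's rounding), because construct names
  embed the printed percentage and `x_20.2` must mean 20.2, not sometimes
  20.1.
* **Monotonicity.** Because selection is a strict filter on a fixed score
  set, the mutation set at $t_2 \ge t_1$ is always a subset of that at
  $t_1$; the test suite asserts this over random score sets, and duplicate
  thresholds in a sweep collapse with a warning.

## The synthetic-alignment generator

`generateMSA()` draws each homolog row independently: per column, first a
gap with the column's gap probability, otherwise a residue from the
specified distribution. Conditional on being non-gap, every column's residue
distribution is therefore *exactly* the specification, so
`expectedScores()` can state the analytic $f_{\mathrm{cons}}$,
$f_{\mathrm{WT}}$ and ratio that an infinite alignment would give. One
integer seed governs the whole alignment.

What this emulates is the statistical signal the scorer consumes — column
residue frequencies around a known consensus. What it deliberately does
**not** emulate: phylogenetic correlation between rows (real homologs are
not i.i.d.), insertion/deletion structure beyond i.i.d. gaps, covariation
between columns, and alignment error. Passing the recovery tests therefore
demonstrates that the estimator converges to the intended quantity under the
model's own assumptions — not that frequency ratios from any particular real
alignment predict thermostability; that validation was and remains
experimental.

Validation problem sizes, chosen to make sampling error negligible relative
to the tolerances while keeping the suite quick: exact-equivalence checks
against an independent brute-force scorer run on 500 random alignments of up
to 20 rows by 30 columns; statistical recovery uses 5,000-row alignments
over 20 columns and requires empirical ratios within 10 % of the analytic
values for true ratios at most 5 (above that, the wild-type frequency is so
small that its relative sampling error dominates); the worked 501-residue
example uses a 10-row alignment with exact engineered column compositions
(ratios 5, 3 and 1), where thresholds 4 and 2.22 select exactly 71 and 101
substitutions — mutation loads of 14.2 % and 20.2 %.

## Design choices that were genuinely open

* **Load denominator.** A masked design mutates only, say, the
  transmembrane 60 % of the protein, but the reported percentage divides by
  the full reference length: the label describes the construct (how far
  from wild type it is overall), not the mask.
* **Reference inclusion default.** Counting the reference row keeps the
  frequencies those of "the homolog set including the target", makes
  $f_{\mathrm{WT}} > 0$ whenever the reference column is a residue, and is
  the choice that needs no extra information; the flag exists for users who
  consider the target an outsider to the homolog set.
* **Panel naming.** `prefix_<load>` (e.g. `xCT_20.2`) rather than
  `prefix_<threshold>`, because loads are what differ visibly between panel
  members and what downstream screening records; `nameByThreshold` provides
  the alternative.
* **Profiles cover all columns.** The mask acts only at selection time, so
  one profiling pass serves any number of masks and the score table always
  describes the whole protein.

## Limitations

* No prediction of ΔΔG, expression, or function: the paper trail for
  consensus constructs shows they can lose transport activity even while
  gaining stability, and nothing in a frequency ratio guards against
  mutating a catalytic or substrate-binding residue that evolution varies
  for functional reasons. The mask is the user's tool for excluding such
  regions.
* Scores inherit every bias of the input alignment (paralog contamination,
  uneven taxon sampling, misalignment); position-based weighting mitigates
  only redundancy.
* Ambiguity codes are discarded rather than fractionally assigned (B could
  count half D, half N); at realistic alignment sizes this is negligible.
* The tool does not build alignments; homolog search and alignment quality
  are upstream concerns.
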