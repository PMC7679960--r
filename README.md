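# consmut

Consensus-mutagenesis construct design for protein engineering, from a
homolog multiple sequence alignment.

Many proteins — human membrane transporters in particular — are too unstable
to purify or image. Consensus mutagenesis stabilizes a target by replacing
individual wild-type residues with the residue most prevalent at that
position across evolutionary homologs. `consmut` implements the
frequency-ratio formulation of this approach for anyone designing
thermostabilized constructs for structural or biochemical work: it scores
every position of a wild-type reference, combines high-scoring substitutions
into mutant constructs, and emits the graded construct panels that are then
winnowed by wet-lab screening (e.g. FSEC-TS).

## The score

Given an alignment of homologs containing the wild-type sequence, each
reference position *i* (alignment column *c*) is scored by

```
score(i) = f_cons(c) / f_WT(c)
```

where `f_cons` is the frequency of the most frequent standard amino acid in
the column and `f_WT` the frequency of the wild-type residue, both computed
over non-gap, non-ambiguous residues. A construct at threshold *t* combines
**all** substitutions with `score(i) > t` (strict), optionally restricted to
a region mask such as the transmembrane segments. Mutation load is reported
as a percentage of the full reference length; a 501-residue transporter
carrying 101 substitutions is a "20.2 %" construct, and sweeping several
thresholds yields a panel named `prefix_14.2`, `prefix_20.2`, ... by load.

Edge conventions (documented defaults, see the methods vignette): gaps and
ambiguity codes are absence of evidence, not a 21st residue; if the
wild-type residue ties for most frequent, the position scores 1 and is never
mutated; other ties break alphabetically; a wild-type residue absent from
its column scores `+Inf` unless a pseudocount is set.

## Worked example

A 25-sequence synthetic homolog alignment of a 90-residue reference ships
with the package, together with a three-segment "transmembrane" mask:

```r
library(consmut)
aln <- system.file("extdata", "synthetic_homologs.fasta", package = "consmut")
tm  <- system.file("extdata", "synthetic_tm_mask.tsv", package = "consmut")

msa    <- readMSA(aln)                      # MSA with 25 sequences x 90 columns
scores <- scoreAlignment(msa, "xCT_demo")   # one row per reference residue
head(as.data.frame(scores)[, 1:6], 5)
#>   residueNumber wtResidue consensusResidue  fWt fCons ratio
#> 1             1         G                G 0.72  0.72   1.0
#> 2             2         M                D 0.40  0.44   1.1
#> 3             3         C                C 0.84  0.84   1.0
#> 4             4         C                C 0.48  0.48   1.0
#> 5             5         P                P 0.84  0.84   1.0

mask    <- readMask(tm, refLength = 90)
mapping <- mapReference(msa, "xCT_demo")
panel   <- sweepThresholds(scores, c(3, 2.22, 1.5), mask,
                           referenceSequence(msa, mapping),
                           namePrefix = "demo")
panel[[2]]
#> ConstructDesign 'demo_13.3': 12/90 residues mutated (13.3%), threshold 2.22
#>    I10S V11C T14K Y17K F18A W23V S28L C42G A48R A49H R54G H75C

writePanelReport(panel, "panel_summary.tsv")
#> PanelReport: 3 construct(s), 0 skipped position(s)
#>   construct threshold mutation_count mutation_percent
#> 1  demo_5.6      3.00              5              5.6
#> 2 demo_13.3      2.22             12             13.3
#> 3 demo_18.9      1.50             17             18.9
```

Reading the output: at the 2.22 cutoff, 12 of 90 residues (13.3 % mutation
load) are replaced by their column consensus, all inside the masked
segments; lowering the threshold admits more, weaker consensus signals and
raises the load. `writeConstructFasta()`, `writeMutationTable()` and
`writeAnnotatedAlignment()` export the sequences, the per-mutation table
(with `f_wt`, `f_cons` and the ratio for each substitution) and a text
alignment with `*` under every mutated column.

The same workflow from a shell:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts", "consmut.R", package = "consmut"))') \
  sweep --alignment homologs.fasta --ref-id xCT_demo --mask tm.tsv \
  --thresholds "3,2.22,1.5" --out-prefix demo
```

Subcommands: `score`, `design` (single threshold, deliberately a required
flag — the useful cutoff is protein-specific), `sweep`, and `simulate`
(synthetic alignments with exactly specified column distributions, for
validation).

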