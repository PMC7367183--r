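---
title: "Methods: Hi-C misjoin detection, completeness scoring and phase evaluation"
author: "scaffcheck"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Hi-C misjoin detection, completeness scoring and phase evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffcheck)
```

## Scope

`scaffcheck` implements the bespoke computational QC stages of a
single-individual hybrid genome-assembly workflow, in a form that can be
exercised on synthetic data with known ground truth:

1. **Misjoin detection** from Hi-C contact pairs via an insulation score
   with an empirical false-join null.
2. **Assembly-layout handling** (AGP), coordinate lifting and break
   application.
3. **Library QC**: PCR duplication rate, depth overdispersion, predicted
   fold coverage.
4. **Completeness by annotation class**: per-feature base-by-base coverage
   against a capture threshold.
5. **Phasing evaluation** for an F1 heterozygote: parental polarization
   and switch/mismatch error decomposition.
6. **Synthetic generators** for all of the above.

The package deliberately consumes the *outputs* of external tools
(aligners, scaffolders, variant callers, phasers) through standard text
formats — AGP v2.1, 4DN `.pairs`, BEDGRAPH (`-bga`), GFF3, phased VCF,
PAF with `cs` tags — and never re-implements them.

## Coordinate model

Internally every interval is 0-based and half-open; the 1-based inclusive
conventions of AGP, `.pairs`, GFF3 and VCF are converted exactly once at
the I/O boundary. This removes the most common class of off-by-one errors
in assembly tooling, at the cost of a conversion that is tested by
round-trip identities (`parse_agp()` then `write_agp()` reproduces a
normalized AGP byte for byte, and likewise for `.pairs` and BEDGRAPH).

Breaking a scaffold inside a gap removes the gap and splits there — the
behaviour of a scaffolder severing an unsupported join. Breaking inside a
contig span splits the underlying contig into deterministically named
pieces (`<name>.1`, `<name>.2`), so repeated runs produce identical
output. Non-gap bases are conserved under any break set, which the test
suite asserts as an invariant.

## Insulation score and the false-join null

For a focal point $p$ on a scaffold of length $L$ with flank $W$ (default
1 Mb), the insulation score is the raw count of contact pairs with one end
in $[\max(0, p-W), p)$ and the other in $[p, \min(L, p+W))$. The score is
*not* normalized into a boundary-strength ratio: the decision rule only
ever compares the same statistic between observed junctions and simulated
false joins, so a common raw scale suffices and avoids inventing a
normalization. Windows are truncated at scaffold ends rather than
skipping near-end points; truncation is recorded in the result so callers
can filter if they prefer.

The null distribution answers: *what score would this junction have if it
were a false join?* Each of `n_null` (default 1000) draws picks an
ordered pair of distinct contigs lying in different scaffolds ("unlinked"
contigs, for which the assembly asserts no linkage), forms a virtual
junction from the right end of the first to the left end of the second,
and counts pairs with one end within $W$ of each junction side. Only
contacts bridging two scaffolds can contribute, so the null measures the
background (trans) contact rate in end-window geometry — exactly the
signal a genuine misjoin would show. Contig orientation is not
randomized: with end-window counting the counted set is orientation
invariant.

A junction is flagged when its score is at or below the empirical
`flag_quantile` (default 0.95) order statistic (inverse-ECDF,
`quantile(..., type = 1)`) of the null sample: its Hi-C support is
statistically indistinguishable from that of a false join. The quantile,
window and null size are parameters rather than constants because
"aberrantly low" admits several operationalizations; the default makes
the rule conservative towards flagging (a true junction in a
contact-rich assembly scores orders of magnitude above any false join, so
specificity is insensitive to the choice).

### The planted-misjoin benchmark

The test suite exercises the full pipeline on a synthetic assembly
designed to mimic the composition of a real draft: one scaffold formed by
fusing two unlinked 3-Mb contigs (the planted misjoin), one truly
contiguous 6-Mb region laid out as two linked 3-Mb contigs (the control
junction), and two 1.5-Mb singleton contigs completing the unlinked pool
from which the null samples, as real assemblies always carry shorter
leftover contigs. Contacts are simulated at uniform per-base cis density
(about 200,000 distance-decay pairs per 3 Mb) with a 1% trans background.

The short singletons matter: under a trans model that is uniform across
reference pairs, a 1-Mb end window covers two thirds of a 1.5-Mb contig,
so null junctions built from them concentrate more background than the
3-Mb fusion point does. The empirical null threshold therefore sits well
above the planted junction's score, and detection is a stable property of
the configuration rather than a borderline quantile event, while the
control junction (five-figure spanning counts) remains orders of
magnitude above the threshold. In a typical run the planted junction
scores ~110 against a null 95th percentile of ~420 and a control score of
~12,000.

## Library QC statistics

*Duplication.* A PCR duplicate is a record identical to another on both
endpoints and strands — exact equality, no positional fuzz, which is the
reproducible default when no tolerance is specified. The rate is
duplicates removed over total records; deduplication is idempotent.

*Depth.* `depth_stats()` computes the base-weighted mean and *population*
variance of per-base depth (the track is the full population of bases,
not a sample) and the dispersion index (variance/mean), which is 1 in
expectation under uniform random sampling of reads and rises with
amplification bias. The statistics are invariant to how the run-length
encoding splits intervals.

*Predicted coverage.* The usual base-count identity
$\text{fold} = n_\text{reads} \times \ell \times (2\ \text{if paired}) /
G$, returned unrounded; display rounding is the caller's concern. For a
long-read library of ~2.05 M reads of 3,541 bp median length on a 120 Mb
genome this gives 60-fold.

## Completeness by annotation class

Each annotated span is scored base by base against an
assembly-to-reference alignment depth track supplied as BEDGRAPH (the
alignment itself is out of scope — any aligner plus
`bedtools genomecov -bga` produces the input). An element is *captured*
when at least a fraction $\tau$ (default 0.90) of its bases have depth
$\ge 1$. The report groups by the GFF3 type label only; spans are the
unit of counting (discontinuous spans sharing an ID are not merged,
since a merging policy would be an invention). Strand is ignored because
depth is strandless. `coverage_bimodality()` summarizes the
characteristic all-or-nothing capture pattern of short-read assemblies:
a 10-bin histogram of covered fractions plus the mass at the extremes
($\le 0.1$ or $\ge 0.9$).

## Phasing evaluation

Evaluation needs truth haplotypes. For an F1 of two known parents, each
heterozygous allele can be assigned a parent of origin
("polarization"): either from a truth table (the synthetic route) or
from a parent-to-assembly PAF alignment with `cs` tags, where a match
run implies the assembly allele and a substitution supplies the parent
base directly. Sites in unaligned, multiply-aligned or deleted regions
stay unpolarized and are excluded from rate denominators — errors are
only definable against truth. Inconsistent sites (neither allele matches
the parent base) are excluded and tallied separately as a diagnostic.

Heterozygous call sets are first depth-filtered: sites strictly below the
empirical 10th or strictly above the 90th percentile of observed depth
are removed (linear-interpolation percentiles, `quantile` type 7; the
convention is stated because "bottom 10%" does not pin one down).

*Switch/mismatch decomposition.* Within each block the assigned
haplotype sequence is compared to truth under the better of the two
global orientations (minimum total error; ties resolved towards the
orientation agreeing at the first site — flipping every assignment in a
block leaves the counts unchanged). Disagreements are classified by
maximal runs:

* an isolated single-site disagreement is **one mismatch** (a flip
  error);
* a run of $\ge 2$ contiguous disagreeing sites contributes **one switch
  per phase change bounding it** — two for an interior run, one when the
  run reaches a block edge.

Counting change-points rather than runs is what makes the statistic an
unbiased estimator of a per-adjacency switch process: an interior wrong
run is entered *and* exited by a phase change, and collapsing it to one
event would halve the recovered rate. The package's evaluator is checked
exhaustively against a brute-force orientation-enumeration oracle on
every disagreement pattern of blocks up to 12 sites.

*Block statistics and the join estimator.* `block_stats()` reports mean
variants per block, mean spans, and the fraction of phased sites in the
largest block (overall and per reference, since chromosome-scale phasing
concentrates nearly all variants in one block per chromosome).
`join_switch_fraction(rate, mean_len)` estimates the fraction of
short-read blocks whose joining by long-range data introduces a switch:
each block contributes about one join, so joins per site is roughly
`1/mean_len` and the fraction is the per-site switch-rate increase times
the mean block length. With a 0.0126/site increase and 14-variant blocks
this gives 0.1764, i.e. ~17% of joined blocks.

## Synthetic generators

The generators emulate the data regime the QC stages are meant for; their
defaults are fixed study conditions, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| heterozygosity θ | 0.005 | typical divergence between distinct inbred *Drosophila* strains |
| decay exponent α | 1 | standard proximity-ligation decay regime; separation density ∝ s^−α above 1 kb |
| trans rate t | 0.01 | low-background in-situ Hi-C library |
| duplicate rate d | 0.12 | modest amplification of a low-input library |
| depth (μ, v) | (39.7, 1038) | strongly overdispersed amplified long-read library; negative binomial, Poisson when v = μ |
| block length | 14 variants | short-read-only phase blocks |
| switch / mismatch rates | 0.0126 / 0.00147 per site | the long-range-join and short-read error regimes |

Depth is simulated i.i.d. per base rather than by placing reads: the
consumers only use moment structure, and read placement would add
complexity without testing anything new. F1 differences are SNP-only so
parental coordinate systems coincide and truth is exact; an indel mode
would require lift-over bookkeeping and is left as an extension point.
All generators run under an internal seed guard that restores the
caller's RNG state, and identical seeds give byte-identical output files.

What the generators do *not* emulate — and hence what passing tests do
not establish about real data: mapping error and mapping-quality
filtering, restriction-fragment structure and ligation-junction
chemistry, reference bias in variant calls, indel heterozygosity,
structural variation between parents, and biological trans-contact
enrichment (e.g. somatic chromosome pairing, which in real dipteran
Hi-C inflates inter-homolog contacts and is precisely why phasing from
Hi-C needs the cautions quantified here).

## Numerical choices and degenerate inputs

* Empirical null quantile: `type = 1` (a pure order statistic of the
  sample); depth percentiles: `type = 7` (linear interpolation). Each
  choice is stated where it is used.
* `spanning_count` windows are half-open on both sides; a far end exactly
  at `position + W` is excluded.
* Zero-length depth tracks, empty null samples, breakpoints at 0 or at
  scaffold length, and layouts with fewer than two unlinked contigs are
  errors, not silent results. An empty break list, an empty contact set
  and an all-equal depth vector are valid degenerate inputs with defined
  results.
* Blocks with fewer than two truth-labeled sites contribute sites to
  denominators but no errors.

## Problem sizes used by the test suite

Unit tests run the misjoin benchmark at 200,000 pairs over three seeds;
the acceptance-style suite runs the full 1,000,000-pair configuration
across 20 seeds, the phase evaluator on 100,000–200,000 simulated sites,
and moment-recovery checks on 1-Mb depth tracks. These sizes were chosen
so that planted-parameter recovery operates comfortably inside its
3-standard-error bands while the whole suite completes in a couple of
minutes on a single core.

## Known limitations

* The misjoin scanner tests contig-contig junctions (plus an optional
  fixed-stride scan); it does not build matrix-based insulation profiles
  or call chromatin domains.
* Completeness reproduces the *procedure* of annotation-class capture
  scoring; reproducing published capture percentages would require the
  external reference annotation and alignments.
* The PAF polarization route resolves SNVs only; indel sites are
  polarizable through the truth-table route.
* No contact-matrix normalization (ICE/KR) and no restriction-fragment
  assignment; the toolkit operates on raw pair counts throughout.
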