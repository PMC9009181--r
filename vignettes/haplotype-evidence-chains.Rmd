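---
title: "Haplotype evidence chains for flavonoid hydroxylase genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype evidence chains for flavonoid hydroxylase genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavhap)
library(dplyr)
```

## The problem

Flavonoid 3′5′-hydroxylase (F3′5′H, the CYP75A family) is the cytochrome
P450 that commits flavonoid precursors to the delphinidin branch of
anthocyanin synthesis; its loss shifts flower pigmentation from purple
toward pink or white. In natural populations the gene accumulates coding
haplotypes — SNPs, small insertions and deletions — and the case that a
particular candidate gene *is* the hydroxylase controlling a color locus
rests on a chain of sequence-level inferences: each non-functional
haplotype should disrupt a region the enzyme cannot do without, the
haplotypes should form a coherent mutational network around the dominant
functional allele, and apparent hybrids between lineages should be
explainable as intragenic recombinants. `flavhap` packages that chain as
reusable, testable components.

## Sequence model and coordinates

All coordinates are 1-based and closed on both ends: nucleotide positions
index the CDS, residue positions index the protein, and codon $i$ spans
nucleotides $3i-2 \ldots 3i$ (`nt_to_codon()` is `ceiling(p/3)`).
Translation uses the standard genetic code only; ambiguity codes are
rejected rather than guessed, a trailing partial codon (the debris of a
frameshift) is ignored, and a stop codon before the final codon marks the
protein `terminated_early`.

Pairwise global alignment uses affine gap scoring. For nucleotides the
defaults are match +2, mismatch −3, gap open −8, gap extend −1 (a gap of
length $k$ costs $8 + k$): chosen so that a contiguous 14-nt deletion
scores better than any scattered-gap alternative, which is what the
variant caller needs to see natural deletion alleles as single events.
Proteins use BLOSUM62 with open −11 / extend −1, the standard protein
scheme. After alignment every indel is shifted to its leftmost
score-equivalent placement; this normalization is mandatory so that
variant coordinates are reproducible across implementations, and both the
caller and the synthetic-data truth records use the same convention (an
indel is reported at the reference base immediately left of the
normalized event).

## Domain map and functional rules

The domain map records the conserved P450 anatomy on the reference
protein: the six substrate recognition sites SRS1–SRS6 in order, the
I-helix inside SRS4, the K-helix with its ExxR signature, the
ERR-triad/PERF motif, the heme-binding motif (consensus `PFGAGRRICAG`)
and the N-terminal transmembrane anchor. Every region except the
transmembrane anchor is *essential*: the essential set is the union of
the features whose loss recurs across documented null alleles of this
enzyme family, and it is configurable per call.

Three rules turn domain status into biology:

- **Heme motif**: substitution-only fuzzy matching with a default
  tolerance of 2 mismatches. Gapped matches are pointless to chase — a
  deletion inside the motif fails the completeness filter anyway.
- **Completeness**: a protein is domain-complete when every essential
  region projects onto it with no deletion, truncation or absence.
- **SRS6 class rule**: Ala or Ser at the SRS6 rule position means
  F3′5′H; Thr means F3′H; anything else (or a gap, or a missing SRS6) is
  unknown. Published statements of this rule disagree between "position
  8" and "position nine" of SRS6, so the index is a parameter
  (`rule_index`, default 8) rather than a constant.

Functional classification is deliberately coarse:
`null_truncation` when any essential domain is wholly lost downstream of
a premature stop or internally deleted; otherwise
`impaired_substitution` when a missense change hits a critical residue
(defaults: the invariant SRS1 glycine at 114, SRS2 valine 210, SRS3
histidine 245, SRS4 asparagine 302, the arginine 428 beside the PERF
motif, and the SRS6 rule residue); otherwise `functional`. Compound
haplotypes take the most severe class. The prediction is about the
*enzyme*; flower color also depends on the rest of the pathway, so color
itself is out of scope.

For haplotypes whose edit structure is known, domain status is derived
arithmetically from the premature-stop position and the indel codon
spans rather than from a protein alignment: a 14-nt deletion followed by
a divergent frameshift tail gives the aligner freedom to smear the tail
across domain boundaries, whereas the arithmetic is exact. Alignment
projection (`project_domains()`) is reserved for external query proteins
in the screen, where nothing but the sequence is known.

## The synthetic reference and the nine-haplotype panel

The package needs a reference enzyme whose coordinate anatomy supports
all the documented haplotype arithmetic simultaneously. The generator
builds a 510-residue protein (1,533-nt CDS with terminal stop): 510 is
the unique length making the frameshift arithmetic of the most complex
haplotype internally consistent (divergence from residue 358 over 28
residues, stop at codon 386, truncation by 125). Domain coordinates are
anchored to the residues the functional rules name (e.g. heme-binding at
460–470, SRS6 at 487–496 with the rule residue at 494).

Codon choices are the engineering core: default codons never end in T,
so a shifted reading frame can only terminate where a T-ending codon is
planted deliberately. Four such stops are planted — for the +1 insertion
frame at codon 386, the 14-nt-deletion frame at codon 430, the +4
insertion frame immediately after codon 438, and the single-nt-deletion
frame at codon 457 — and the generator asserts every expected
consequence against the translation engine before the panel is released
(a mismatch is a hard error, not a warning).

The panel comprises the reference plus eight derived haplotypes: a
7-SNP + C-insertion null; a two-SNP impaired allele carrying R428M; its
descendants with an additional 4-nt insertion and a further SNP (both
null); a 14-nt-deletion null; the recombinant combining one lineage's 5′
end with the other's deletion; a single-T-deletion null with its stop 16
codons downstream; and an in-frame 15-nt deletion inside the heme motif.
Two placements are fixture choices where the biology gives no
coordinate: the recombination breakpoint (nt 900) and the in-frame
deletion location (residues 461–465); both are recorded in the truth
records and never treated as externally validated values.

One spec-level coordinate was corrected during design: a "synonymous SNP
at nt 500" is impossible (nt 500 is a codon second position, and no
second-position change is synonymous), so the panel's synonymous SNP
sits at nt 501. The extra SNP of the G5686-type haplotype is placed at
nt 450, upstream of the shared lineage SNP; with no documented location
this is the placement under which the recombination scan's tie-breaking
reproduces the documented parent pair (see below).

## Median network

Characters are binary: every segregating substitution column and every
distinct indel event (one character regardless of length, as in standard
mutation-event networks) with identical presence patterns condensed
under a summed weight. Multi-allelic sites split into one character per
derived allele, which keeps the majority operation well-defined. The
median closure adds the coordinatewise majority of every triple until a
fixed point; for binary states the closure is unique, so the iteration
order cannot matter, and a guard refuses matrices wider than 25
condensed characters (the closure can grow exponentially). Edges connect
closure vectors at condensed Hamming distance 1. On the nine-haplotype
panel this yields one inferred median node and places the reference
haplotype as the hub, with each haplotype's path to the hub spelling out
exactly its planted mutations.

## Recombination scan

Within a gene, a recombinant child is a mosaic: the 5′ portion of one
parent and the 3′ portion of another. Over the informative sites (where
the parents differ) a binary child always matches exactly one parent, so
the minimal number of crossovers is simply the number of parent-label
changes along the coordinate-ordered sites; an exhaustive
switch-assignment oracle verifies this in the tests.

The subtle part is deciding *which* children are recombinant at all. A
naive "minimize breakpoints over all pairs" rule degenerates: any child
is explained with zero breakpoints by a pair consisting of a near-match
parent and anything else, because the child's private mutations are
simply not informative for that pair — and every intermediate haplotype
on a mutational path looks like a one-crossover mosaic of its
neighbours. The scan therefore requires a valid parent pair to

1. explain the child at **every** character — no "unexplained" site
   where the parents agree and the child differs; and
2. contribute **derived** (non-reference) material on both sides of the
   crossover.

Condition 1 removes the near-match degeneracy (direct descent plus
private mutation is then the better explanation); condition 2 removes
path intermediates, whose second "parent" only ever contributes
ancestral states. Among valid pairs the scan minimizes breakpoints, then
prefers the pair with more informative sites, then lexicographic ids.
On the panel exactly one child survives these conditions — the known
recombinant, assigned its documented parents with one crossover — and on
simulated chimeras with well-populated flanks the true parent pair is
recovered in ≥95% of cases.

Support for a call comes from a permutation test: shuffle the order of
the informative sites and count how often the shuffled child needs no
more crossovers than observed, with $p = (1 + \#\{k_{perm} \le
k_{obs}\})/(n+1)$. Informative-site counts in real panels are tiny, so a
parametric null would be indefensible; with only four informative sites
the panel's own recombinant is — correctly — not significant, and the
test earns its keep on simulated data (type-I error at nominal 0.05 is
controlled, verified over 1,000 null simulations).

## Proteome screen and logos

The screen applies the three rules in order and records every
intermediate outcome per protein, so nothing is silently dropped:
heme-motif hit and position, completeness with the failing domains
listed, SRS6 residue and class, and the final pass flag. The cascade is
monotone — relaxing the mismatch tolerance or shrinking the essential
set can only admit more proteins — and that invariant is tested.

Logo information content per column is $\log_2 20 - H$ with $H$ the
Shannon entropy of the observed residue frequencies. Gaps keep their
column fraction but carry no frequency mass (the common display-tool
behaviour); the small-sample correction $e_n = \frac{1}{\ln 2} \cdot
\frac{19}{2n}$ is available but off by default, since survey-scale
analyses rarely state whether it was applied.

## Synthetic data: what it does and does not emulate

The random panel generator plants SNPs (default rate 0.002/nt) and
indels (default 2×10⁻⁴/nt, lengths 1–6) on the reference, resampling any
substitution that would create an in-frame stop within its own codon so
that premature termination arises only from frameshifts. Truth records
store every edit (left-normalized) and a label derived from the edits
alone by the same classification *rules* — translation of the edited
sequence plus domain arithmetic — while the engine being tested must
recover them through alignment. These defaults give a realistic handful
of variants per 1.5-kb haplotype, comparable to the natural panel.

What the generator does not emulate: sequencing error, alignment
ambiguity from long repeats (the reference is low-repeat by
construction), heterozygosity, splice variation, or regulatory-region
alleles. Passing tests therefore demonstrate the correctness of the
inference chain on clean haploid CDS data, not robustness to noisy
assemblies.

## Problem sizes and numerical choices

The shipped tests run the oracle equivalences at: 1,000 random
sequences for translation; the complete pair set over {A,C} up to
length 4 plus fixed-seed random pairs to combined length 16 for
alignment optimality; 50 random matrices (≤6 haplotypes × ≤12
characters) for the median closure; 40 random triplets (≤12 informative
sites) for breakpoint minimization. Recovery properties use 20 × 10 =
200 random haplotypes, 100 planted chimeras and 1,000 permutation-null
simulations — sizes chosen to make the binomial bounds in the
acceptance thresholds meaningful on a single CPU.

Tie-breaks are deterministic throughout: leftmost window for motif
matches, mismatch-over-gap and left-normalization for alignments,
lexicographic parent ids in the scan. The pipeline writes byte-identical
outputs on rerun (the GML writer's timestamp line is stripped for this
reason).

## Limitations

- Domain projection for external proteins depends on a global alignment;
  highly diverged homologs (below ~30% identity over the N-terminal 200
  columns) are reported `unalignable` rather than guessed at.
- The recombination scan assumes binary characters and detects single-
  to few-crossover mosaics; gene-conversion tracts and multi-method
  consensus calling are out of scope.
- Enzyme classification is rule-based; it does not model quantitative
  activity, and the critical-residue set is a configurable default, not
  an exhaustive mutagenesis map.
- The reference and panel are synthetic constructions for exercising the
  method chain; they are not substitutes for deposited gene models.
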