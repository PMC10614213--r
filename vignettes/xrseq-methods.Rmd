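---
title: "Simulating and analysing excision-repair sequencing libraries"
author: "xrseq package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing excision-repair sequencing libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xrseq)
library(GenomicRanges)
```

## Background

Nucleotide excision repair (NER) removes bulky DNA lesions — above all the
UV-induced cyclobutane pyrimidine dimer (CPD), which forms at adjacent
pyrimidines (TT, TC, CT, CC; chiefly TT) — by incising the damaged strand
on both sides of the lesion. The released damage-containing oligomer is
about 12–13 nt long in prokaryotes and 24–30 nt (peaking at 26–27) in
eukaryotes. XR-seq captures these excision products, sequences them, and
aligns them back to the genome, giving a strand-resolved, single-nucleotide
map of where repair happened.

On small substrates (plasmids, single genes) the key derived statistic is
transcription-coupled repair (TCR): the preferential repair of the
transcribed strand (TS; the template strand, opposite the annotated sense
strand) of an expressed gene. It is quantified as a ratio of ratios,

$$\mathrm{TCR} \;=\;
\frac{(\mathrm{TS}/\mathrm{NTS})_{mfd^{+}}}
     {(\mathrm{TS}/\mathrm{NTS})_{mfd^{-}}},$$

the TS/NTS read-count ratio in a library from cells (or extract) with the
transcription-repair coupling factor Mfd, divided by the same ratio without
it. TCR > 1 indicates Mfd-dependent coupling; the mfd⁻ denominator cancels
sequence-composition asymmetries (different numbers of TT sites on the two
strands) that affect both libraries equally.

This package provides (i) a generative simulator for such libraries with
full ground truth, and (ii) the complete analysis chain: raw-read
deduplication, UMI/adapter trimming, exact-match alignment,
damage-position filtering, subsampling, strand-resolved repair maps,
length/positional-composition profiles, and per-gene TCR tables.

## The generative model

`simulateLibrary()` draws, for each of `nMolecules` molecules:

1. **A damage site**, from all dipyrimidine sites of the configured kinds
   on both strands (`enumerateDipyrimidines()`). Site weights are the kind
   weights, multiplied — for sites on a gene's transcribed strand inside
   the gene — by that gene's TCR enrichment factor $e$, then normalised
   (`siteWeightTable()`). With TT-only damage and uniform weights,
   the expected TS/NTS count ratio inside a gene is $e$ times the gene's
   TT strand ratio, so the downstream TCR estimate has expectation $e$.
2. **A product length** from `lengthWeights`, and the read placement such
   that the dimer's 5′ base sits at the configured 1-based offset within
   the read. Placements running off a linear reference are resampled and
   counted; circular references wrap.
3. **Degradation**: with probability `degradationFraction` the product is
   emitted as a 5′-truncation of uniform length 4–11 keeping the 3′ end —
   reproducing the sub-12-nt nucleolytic tail without modelling
   exonuclease kinetics. These fail the length filter downstream.
4. **Library structure**: a random UMI prefix (`umiLength` bases), the
   insert, and the 3′ adapter; then $k \sim \mathrm{Poisson}(\texttt{pcrDupMean})$
   extra byte-identical PCR copies per molecule, flagged in the truth
   table.

Defaults are the study conditions of the in-vitro/in-vivo *E. coli*
system: prokaryote lengths {12: 0.05, 13: 0.85, 14: 0.10} with dimer
offsets {8, 8, 9}, TT-only damage (the 13-mers carry TT at positions 8–9
essentially always), an 8-nt UMI, and `pcrDupMean = 1`. The eukaryote
preset uses lengths 24–30 peaked at 26–27 with the dimer seven
nucleotides from the 3′ end (offset 19 for a 26-mer) and no UMI.
`degradationFraction` defaults to 0.05 — a visible but minor sub-12 tail.
The 3′ adapter is an Illumina small-RNA-style sequence; the true library
layout is configurable and shared between simulator and trimmer, since
the real adapter/UMI geometry is a property of the library kit rather
than of the method.

There is no sequencing-error model by default: mismatched reads are
discarded by the exact-match aligner anyway, and an error-free generator
makes every pipeline contract exactly testable (`maxMismatch` in the
trimmer exists for completeness).

## Analysis chain and its conventions

**Coordinates.** All R-level coordinates are 1-based closed, the
GRanges/Bioconductor convention; BED and bedGraph files are read and
written in their native 0-based half-open convention via `rtracklayer`,
which converts at the boundary. A minus-strand dipyrimidine site's
`pos5` is the plus-strand coordinate of its 5′ base *on its own strand*,
i.e. the rightmost plus-strand base of the pair.

**Deduplication.** Duplicates are removed on the raw reads, before
trimming, while the UMI is still part of the sequence — so identical
inserts with different UMIs (genuine repeated repair at one site)
survive, and only byte-identical PCR copies collapse. A post-alignment
UMI-aware mode (`dedupAlignedUmi()`, key = start/strand/length/UMI) is
provided for layouts without a raw-level UMI.

**Trimming.** The adapter is located as the leftmost exact occurrence
after the UMI, falling back to the longest adapter prefix
(≥ `minOverlap` = 5 nt) flush with the read end. Leftmost wins ties:
inserts cannot contain the full adapter under the generative model, and
leftmost is the conservative choice for real data. Every read is kept or
assigned a discard reason, so `input = kept + Σ discarded` holds exactly
in every run.

**Alignment.** Only exact full-length matches are produced, on either
strand, using a per-length hash of all reference substrings (lazy-built;
junction-spanning windows included for circular references). Gapped or
mismatch-tolerant alignment is deliberately out of scope: the analysis
discards any mismatched read, so exact matching is the entire contract,
and it is checked against an independent naive full-scan oracle in the
tests. Multimapping inserts are discarded by default (counted), with a
seeded `random_one` alternative.

One interaction is worth knowing: on references small enough that a
13-mer can recur, the `discard` policy censors *specific* sequences, and
deterministically (if mildly) distorts base-composition statistics such
as the 5′-flank frequencies. Composition nulls — e.g. checking that the
flank distribution under uniform site weighting equals
`flankBackground()` — are therefore evaluated under `random_one`, which
retains those reads; the default policy is unchanged for repair maps and
TCR, where positional censoring is the conservative behaviour.

**Damage filter.** The canonical read selection keeps only reads of one
exact length with a dipyrimidine at fixed read positions — 13-mers with
positions 8–9 (prokaryote) or 26-mers with 19–20 (eukaryote). The check
uses the read's own sequence, identical to the reference under exact
alignment and usable pre-alignment. The default accepts all four
dipyrimidine kinds, with a TT-only switch for CPD-focused analyses.
(For eukaryotic 26-mers, positions 19–20 sit 7–8 nt from the 3′ end
counting inclusively; descriptions placing the dimer "5–6 from the 3′
end" correspond to offsets 21–22 and are available through
`damageFilterSpec()` — both are configurations, the 19–20 setting is the
default.)

**Damage-site coordinate.** One convention throughout: the reported
position is the 5′ base of the dinucleotide. For a plus-strand read
starting at $s$ with first dipyrimidine position $d$, that is $s + d - 1$;
for a minus-strand read of length $L$ it mirrors to $s + L - d$.

**Subsampling** (uniform, without replacement, seeded; default 200,000
after filtering) equalises depth between libraries before track
building, as is customary.

**TCR counting.** A read belongs to a gene iff its damage-site
coordinate lies in the gene interval — single-position assignment avoids
double counting at gene edges (the footprint-overlap rule is a
documented alternative the package does not default to). TS/NTS and the
TCR cross-ratio $(ts^{+} nts^{-})/(nts^{+} ts^{-})$ are kept at full
precision; tables round to two decimals for display; zero denominators
propagate as `NA` rather than aborting a whole table. The optional
TT-frequency normalisation divides each library's TS/NTS by the gene's
TT strand ratio and cancels exactly in the TCR — reported ratios are
unnormalised by default.

## What the simulations do and do not establish

The simulator emulates the *structure* of excision-product libraries:
length mixtures, damage-anchored read geometry, UMIs, PCR duplication,
strand-asymmetric site weighting, degradation tails, and deterministic
seeding. It does not model UV dose–response, immunoprecipitation
efficiency, ligation or sequence-context bias, (6-4) photoproducts, or
sequencing errors. Passing recovery tests therefore demonstrates that
the analysis chain is an unbiased, correctly-plumbed estimator of the
quantities the generator encodes — not that real libraries satisfy the
generator's assumptions. In particular, published flank preferences
(~45–63% A 5′ of the dimer against ~22–25% backgrounds) are properties
of real repair data; the package's corresponding check is the *null*
consistency — under uniform site weighting the read-level flank
frequency must equal the sequence background.

## Validation problem sizes

The package's own validation uses: TCR recovery on a 7 kb circular
synthetic plasmid with a 1 kb gene at 200,000 molecules per library for
the point recoveries ($e = 2.5$ and $e = 6$), and 20 seeded replicate
pairs of 20,000 molecules for the null calibration ($e = 1$, mean TCR
within 5% of 1) — at these depths the per-replicate TCR standard error
is ≈ 0.02–0.06, so the acceptance bands are comfortably wider than the
estimator's noise. Aligner equivalence is checked against the naive
oracle with 1,000 queries of length 4–26 on 500-nt linear and circular
references, including reverse-complement and junction-spanning cases.

## Worked example

```{r example, eval = FALSE}
ref   <- syntheticReference(7000, seed = 1)              # circular plasmid
gene  <- geneAnnotation(ref, 3001, 4000, "bla", "+")
res   <- runPipeline(pipelineConfig(e_plus = 2.5, seed = 42))
res$tcr
#>   gene ratio_plus ratio_minus     tcr
#> 1  bla    3.00293    1.172392 2.56137
```

The mfd⁻ TS/NTS (1.17) is this plasmid's composition baseline (the
gene's TT strand ratio); the cross-ratio recovers the simulated
enrichment of 2.5 up to sampling noise.

## Known limitations

* Exact matching only; real reads with sequencing errors would need an
  upstream error-tolerant mapper, after which the same filtering and
  counting apply.
* The exact-occurrence index materialises all substrings per query
  length — appropriate for plasmid/gene-scale references (≤ ~100 kb),
  not for genomes.
* `NA` TCR values (zero NTS counts) are propagated, not modelled; the
  seeded bootstrap (`tcrBootstrap()`) gives percentile intervals but no
  significance machinery is provided.
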