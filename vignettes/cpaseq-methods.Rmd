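---
title: "Terminus- and methylation-aware small RNA sequencing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Terminus- and methylation-aware small RNA sequencing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpaseq)
```

## The problem

Standard small RNA sequencing only captures molecules that end in a
5'-monophosphate and a 3'-hydroxyl, because both adapter ligations require
those chemistries. A large part of the small RNA population — tRNA and rRNA
fragments with 5'-OH, 3'-P or 2',3'-cyclic-P ends, capped snRNA/lncRNA
fragments, 5'-triphosphorylated species, aminoacylated tRNA halves — is
invisible. On top of that, m1A, m3C and m1G marks make reverse
transcriptases stall, so methylated fragments are depleted even when their
ends are ligatable.

CPA-seq style protocols fix this enzymatically: deacylation removes 3'-aa;
Cap-Clip (an acid pyrophosphatase) converts caps and 5'-ppp to 5'-P; T4 PNK
phosphorylates 5'-OH and removes 3'-P/3'-cP; an AlkB demethylase mix erases
m1A/m3C/m1G; and TGIRT reads through residual marks, leaving
misincorporation signatures. Comparing a fully treated library against
libraries that each omit one enzyme turns chemistry into a differential
detection signal.

This package implements both halves of that logic as testable software: a
generative simulator of the bench workflow, and the analysis pipeline that
recovers — from reads alone — each species' class, terminus chemistry,
methylation sites and stoichiometries, and tissue statistics.

## The generative model

A simulated molecule is a species sequence plus a terminus state (one of
5 x 4 = 20 combinations of 5' {P, OH, m7G-cap, m3G-cap, ppp} and 3'
{OH, P, cP, aa}) and a set of methyl sites, each with a per-site
stoichiometry (the fraction of molecules carrying the mark).
`simulate_library()` composes:

1. **Molecule draws** proportional to per-condition abundance weights.
2. **Enzyme treatments** (`apply_treatments()`), in the fixed bench order
   deacylation, Cap-Clip, PNK; AlkB then erases each methyl mark
   independently with `alkb_efficiency`. Conversion probabilities default
   to 1 because the enzymes are near-quantitative on the bench; they are
   configurable for robustness experiments.
3. **Ligation selection**: molecules failing `is_ligatable()` — anything
   not (5'-P, 3'-OH) — are discarded and *not* redrawn, so library depth
   itself carries the treatment signal.
4. **Reverse transcription** (`reverse_transcribe()`): at each residual
   methyl site the enzyme independently aborts with `stop_rate` or
   misincorporates with `misinc_rate`. A stop is modelled as loss of the
   molecule, not as a truncated read: the truncated cDNA never acquires
   the 5'-adapter complement, and library PCR primes on both adapters.
   Misincorporation substitutes a uniformly chosen different base, since no
   substitution spectrum for TGIRT is assumed.
5. **Library synthesis**: 5'/3' UMIs (6 nt each by default), the 3' adapter,
   geometric PCR duplication (`pcr_dup_mean` is the mean copy count on
   {1, 2, ...}, so 1 means no duplication), per-base sequencing error, and
   constant Q37 qualities. A configurable fraction of reads is emitted at
   uniformly low quality to exercise the quality gate.

All randomness flows from one mandatory seed; each (plan, condition)
library uses a documented derived sub-seed, so any library is reproducible
in isolation.

### The default scenario

`default_scenario()` fixes the study conditions: 132 species (12 per class
across miRNA, rsRNA, tsRNA, pre-tsRNA, piRNA, snsRNA, snosRNA, lncsRNA,
mt-tsRNA, mRNA-derived and other), toy references per class including a
random genome with embedded tRNA loci, every one of the 20 terminus states
in at least one species, and m1A/m3C/m1G sites at stoichiometries 0.25,
0.5 and 1.0 (two species per combination). Abundances follow a log-normal
model (median weight 100, sdlog 0.6 between species, 0.4 between tissues)
over five tissues, with one single-tissue species per class so that
tissue-specificity identities can be verified. Methyl sites are placed
only at parent positions no sibling species overlaps: a methylation mark
belongs to a parent position, and an overlapping unmethylated species
would otherwise dilute the site's mismatch frequency with molecules the
mark does not apply to.

Default rates are chosen once, as study conditions: sequencing error
1e-3 per base, misincorporation 0.6 and RT stop 0.95 at a residual site.
The stop rate follows from a closed-form requirement: in a no-AlkB
library the canonical sequence of a fully methylated species is retained
with probability (1 - stop) x (1 - misinc), and for the 30-fold depletion
rule to fire at misinc 0.6 the stop rate must exceed 11/12. Methylome
quantification runs set `stop_rate = 0`, because the mismatch-frequency
estimator is defined on surviving molecules and stops are a separate,
coverage-based signal.

What the simulator does *not* model — and what green tests therefore do
not show about real data: ligation sequence bias, RNA secondary structure,
NAD caps, TGIRT's true substitution spectrum, non-uniform quality
profiles, and reference redundancy at genome scale (toy references are
collision-free by construction; real annotation must contend with
paralogs and multimapping).

## The analysis pipeline

**Preprocessing.** The 3' adapter is located as the leftmost full-length
occurrence (mismatch-tolerant at 15%) or a >= 5 nt adapter prefix at the
read end; reads with no hit are kept and then removed by the length gate,
which salvages short inserts whose adapter carries errors. "QC < 30" is
interpreted as mean Phred below 30 over the read — the statistic is not
otherwise pinned down. The insert gate is 15-40 nt (16-40 is available via
configuration). UMI deduplication is exact-match on the (insert, UMI)
pair: edit-distance UMI clustering exists in reference tools but exact
matching is deterministic, and with 12 UMI bases the collision probability
at these depths is negligible. `unique_count` — distinct molecules per
insert sequence — is the abundance unit everywhere downstream.

**Annotation cascade.** Reads are tried against reference classes in a
fixed order (miRNA, rRNA, cytosolic tRNA, tRNA precursor, piRNA cluster,
mitochondrial tRNA, lncRNA, snRNA, snoRNA, mRNA, other ncRNA, genome);
the first stage with a hit wins. The miRNA stage accepts only 16-28 nt
reads at zero mismatches — a deliberate asymmetry that keeps tRNA
fragments sharing miRNA-like sequences from being misannotated — and the
piRNA stage only 24-32 nt; all other stages allow one mismatch. Matching
is sense-strand only. Exact placements come from a substring index;
one-mismatch placements from a pigeonhole split (one half of the read must
match exactly, candidates are verified by Hamming distance). Where an
aligner would return an arbitrary hit, the cascade is deterministic:
fewest mismatches, then earliest reference in input order, then leftmost
start. Mature tRNA references get CCA appended unconditionally (genomic
tRNA references conventionally lack it) and histidine tRNAs a 5' G;
precursors span 100 bp on each side of the locus, clipped at contig edges.

**tRNA fragment typing.** With the anticodon loop taken as the anticodon
span widened by 2 nt per side: fragments anchored at the 5' end (within
1 nt, tolerating the His G-1) are 5' halves if they end inside the loop
and tRF-5 otherwise; fragments anchored at the 3' end (within the last
3 nt, the CCA) are 3' halves if they start inside the loop and tRF-3 if
after it; everything else is internal. Precursor fragments overlapping the
upstream flank are 5' leaders, the downstream flank 3' trailers. These
tolerances are this package's concretization of anticodon-anchored typing
and are configurable.

**Quantification.** RPM uses all cascade-annotated reads (including the
genome stage) as the mapped denominator; this is configurable. Because
miRNAs have low terminus multiplicity, their totals should agree across
enzyme treatments, so the `mirna_norm` layer rescales each library to a
miRNA total of one million ("miRNA-million" scale — the natural scale is
not otherwise defined) and makes treatment groups comparable. The greedy
parental grouping repeatedly takes the highest-count unassigned sequence
as a representative and absorbs all sequences related to it by substring
containment; containment is one reading of an under-specified procedure
and is documented as such.

**Responsive calling.** With pseudocount 0.5,
`FC = (full + 0.5) / (reduced + 0.5)` on the `mirna_norm` layer; a
sequence is responsive when full >= 10 and FC > 30. The pseudocount and
the minimum-abundance guard protect against zero denominators and
shot-noise calls; the 30-fold threshold is the protocol's own convention.
The chemistry label depends only on which enzyme the reduced library
omits — PNK-responsive (5'-OH or 3'-P/cP; the assay cannot distinguish
these), Cap-Clip-responsive (cap or ppp), AlkB-responsive (methylation).

**Methylome.** Pileups accumulate abundance-weighted depth and per-base
mismatch counts from the <= 1-mismatch alignments (a methylated read with
an additional sequencing error is lost — a small downward bias). A site
is called when the reference base is A, C or G, depth reaches 50 in both
the AlkB-omitted and fully treated groups, the no-AlkB mismatch frequency
reaches 0.10, and demethylation reduces it at least 3-fold; the defaults
are stated choices, all configurable. Stoichiometry is reported as
`delta = f_noAlkB - f_withAlkB`, a misincorporation-confounded lower
bound whose expectation under the generative model (stop rate 0) is
stoichiometry x misinc_rate — the simulator documents the exact
relationship so tests can divide the rate out. RT stops are invisible to
the caller in this model (stopped molecules are lost before PCR); stop
signals appear instead as coverage drop-off in `coverage_profile()`.

**Tissue statistics.** TSI = (N - sum(x)/max(x)) / (N - 1) on per-tissue
RPM: 1 for single-tissue expression, 0 for uniform, scale-invariant.
Tissue enrichment requires TSI > 0.95 plus a class-specific expression
floor (mt-tsRNA 70, lncsRNA 50, snsRNA 50, snosRNA 30, default 20 RPM in
at least one tissue). Clustering prefilters rows at > 20 RPM in at least
one tissue, log2(x + 1) transforms (the +1 handles zeros, which the bare
"log2 of unique reads" convention leaves open), computes Euclidean
distances per class and applies average-linkage agglomeration; rows are
sorted by identifier first so the trees are order-invariant. Differential
detection between replicate groups uses a two-sided Welch t-test on
log2(RPM + 1) — "t-test" alone does not fix the variance assumption, and
the unequal-variance form is the safer default — gated at P < 0.05 and a
linear mean fold change > 2.

## Numerical and design notes

- Fold-change and frequency ratios use pseudocounts or explicit 0/0
  handling; a 0/0 frequency ratio is never a methylation call.
- Ties everywhere break deterministically (lexicographic sequence order,
  reference input order, leftmost coordinate), so rerunning any stage on
  the same input is byte-identical.
- The "untreated" plan applies deacylation by default; whether a bench
  "untreated" control is deacylated is exposed as a flag because either
  reading is defensible.
- Sequences are handled in the DNA alphabet throughout (reads are cDNA;
  references are conventionally stored as DNA).
- Enzyme efficiencies below 1 are supported per molecule; the truth table
  a library reports describes the deterministic (efficiency 1) limit.

## Problem sizes

The bundled verification suite exercises the full four-plan study at
200,000 molecules per library for terminus recovery, the two-library
methylome comparison at 200,000 molecules with stop rate 0, a 50,000-read
error-free library for cascade accuracy, 1,000 randomized read/reference
instances for the alignment oracle, and smaller clean libraries for
UMI-accounting identities. These sizes give every methylated site
depth in the hundreds-to-thousands and make binomial uncertainty on
frequency estimates small compared to the tested tolerances.

## Known limitations

- Stoichiometry estimates are lower bounds confounded by the (unknown, in
  real data) misincorporation rate, and are further biased down by the
  one-mismatch alignment cap.
- The cascade has no multimapper handling; with toy references this is
  moot, with real references the first-stage-wins rule absorbs all
  ambiguity into the stage order.
- Detection-based chemistry inference cannot separate 5'-OH from 3'-P/cP
  (both are PNK substrates), nor m7G from m3G caps or caps from ppp (both
  are Cap-Clip substrates).
- The atlas statistics are exercised on synthetic multi-tissue tables;
  no claim is made about biological tissue atlases.
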