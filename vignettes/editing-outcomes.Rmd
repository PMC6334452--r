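---
title: "Quantifying genome- and base-editing outcomes in amplicon sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying genome- and base-editing outcomes in amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crispredit)
```

## The analysis

`crispredit` quantifies the outcomes of targeted genome editing from
single-end amplicon sequencing reads, with the comparisons that matter when a
Cas9 nuclease and a cytidine base editor (BE3-style) are aimed at the same
protospacer: how much editing occurred, what kinds of alleles were produced,
which of them abolish protein function, whether editing-window C→T conversion
dominates the substitution signal, whether candidate off-target sites show
treated-versus-control differences, and whether junction-spanning reads
indicate chromosomal translocations between two cut loci.

The pipeline follows the conventional amplicon-quantification recipe:

1. **QC** — keep reads whose arithmetic-mean Phred score is at least 33
   (the boundary is inclusive).
2. **Alignment** — global Needleman–Wunsch against the reference amplicon
   with affine gaps (match +2, mismatch −4, gap open −10, gap extend −1 per
   base). Reads under 60% identity over the amplicon are flagged
   unalignable and counted separately.
3. **Windowed allele consolidation** — reads are grouped by their sequence
   within a window centered on the predicted cleavage site (30 bp at the
   default half-width of 15). Deleted window columns are marked `-`;
   insertions belong to the allele when their left reference neighbor lies
   inside the window. Edits outside the window never split alleles.
4. **Frequency floor** — alleles with frequency strictly below 0.01% are
   excluded; their summed mass is reported as `excluded_lowfreq_mass`
   rather than silently renormalized away.
5. **Consequence calling** — each allele is spliced back into the amplicon
   and translated from a reading-frame anchor; classes are reference,
   silent, missense, in-frame indel, frameshift, and nonsense. Null alleles
   are frameshifts and nonsense alleles.
6. **Base-editing profile** — a per-protospacer-position substitution
   matrix on the protospacer strand, plus the targeted-transition fraction
   (editing-window C→T share of all substitution mass).
7. **Off-target panel** — candidate sites with at most 3 mismatches to the
   guide and at least one editing-window cytosine are kept; per-site edited
   counts are compared between treated and control groups.
8. **Translocations** — balanced and acentric fusion templates between two
   cut loci, exact-match in-silico PCR, and junction-spanning read counts.

## Coordinate conventions

Internally every interval is 0-based half-open on the amplicon plus strand;
all report output is 1-based inclusive and carries a
`coords=1-based-inclusive` header token. Protospacer positions run 1..L in
either PAM-distal numbering (position 1 at the protospacer 5′ end) or
PAM-proximal numbering (position 1 beside the PAM); the two are related by
the involution p′ = L + 1 − p. Both conventions appear in practice —
the same gMH/human mismatch is "position 11" proximal and "position 10
distal" — so every table names its numbering and `convert_position()`
moves between them.

The cleavage site is the canonical blunt SpCas9 cut 3 bp 5′ of the PAM,
between protospacer positions 17 and 18 (distal numbering). Protospacers of
20 or 21 nt are supported — printed guide sequences are sometimes 21 nt
where a transcription-start G may or may not be part of the spacer, and the
package takes the sequence as given; numbering uses L rather than a
hard-coded 20.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_mean_quality` | 33 | mean-Phred QC threshold (inclusive) |
| `allele_freq_floor` | 1e-4 | strict lower frequency bound (0.01%) |
| `top_n_alleles` | 10 | alleles translated/reported per sample |
| `quant_halfwidth` | 15 | half-width of the quantification window (bp) |
| `edit_window` | 4–8 | base-editing window, PAM-distal positions |
| `max_mismatches` | 3 | off-target panel mismatch ceiling (inclusive) |
| `min_flank` | 15 | exact-match bases on each side of a fusion junction |

The editing window defaults to protospacer positions 4–8 (PAM-distal), the
canonical BE3 deamination window; it is configurable per target because
deaminase variants shift it.

## The simulator and what it emulates

`simulate_reads()` draws each read from a reference amplicon or from one
allele of an editing profile, then applies substitution-only sequencing
error and normally distributed Phred qualities (mean 37, sd 2, clipped to
[2, 41]). Profiles:

* `cas9_profile()` — NHEJ-style deletions of 1–9 bp centered on the cut
  plus a 1-bp insertion. Default weights put about 70% of the edited mass
  in frameshifting lengths, in line with the frameshift-dominated
  null-allele shares reported for nuclease editing at this kind of locus.
* `be3_profile()` — all non-empty subsets of editing-window cytosines
  converted C→T on the protospacer strand (emitted as G→A on the plus
  strand when the protospacer is on the minus strand), with small
  non-C→T byproduct and indel remainders (defaults 0.90 / 0.05 / 0.05).
  The pure mass is split equally among the subsets; with two window
  cytosines this makes double conversions as likely as each single one,
  a deliberate simplification rather than a fitted bystander model.
* `simulate_fusion_library()` — full-length copies of a balanced or
  acentric fusion template mixed into reads from the two intact loci.

Default editing rates (`p_edit = 0.25`) sit inside the 10–38% range typical
of in vivo liver editing experiments of this design. Simulated read depth
defaults to 10,000 per sample in the pipeline; the test suite uses 50,000
where binomial envelopes need to be tight and a few hundred where they do
not. These are desk-scale choices made once, not tuned quantities.

Every simulation returns a truth table (read id → source allele, applied
edits, fusion flag), which is what makes parameter-recovery testing
possible: at error rate 0 every read maps back to its source allele
exactly, so recovered allele frequencies can be compared against both the
realized truth counts and the spectrum probabilities.

What the simulator does **not** emulate: PCR duplicates and chimeras,
paired-end structure, adapter read-through, coverage nonuniformity,
indel-type sequencing errors, and guide-independent deamination. Passing
tests therefore demonstrate that the analysis recovers what it claims from
reads matching these assumptions; they do not certify performance on real
libraries with those artifacts.

## Numerical and design choices

* **Alignment scoring** (+2/−4/−10/−1) makes a 2-bp indel strictly
  preferable to two mismatches, so small NHEJ indels are never absorbed as
  substitution pairs. Tie-breaking is delegated to the alignment library's
  deterministic traceback, which keeps reruns byte-identical.
* **Frequency denominator** — frequencies are relative to reads that pass
  QC, align, and span the window. The conservation identity
  `QC-discarded + unalignable + non-spanning + usable = total` is asserted
  exactly in the tests, and retained frequencies plus excluded mass sum
  to 1 within 1e-9.
* **Floor semantics** — "less than 0.01%" is honored literally: an allele
  at exactly 0.01% is retained.
* **Window edge insertions** — an insertion whose left reference neighbor
  is the last window base belongs to the allele; one whose left neighbor
  precedes the window does not. Half-open logic keeps allele identity
  unambiguous at both edges.
* **Class precedence** — frameshift > nonsense for mixed alleles: a stop
  reached through a shifted frame is a frameshift consequence. This keeps
  the mutation-type categories disjoint. How mixed substitution+indel
  alleles should be binned is genuinely underdetermined; the precedence
  rule is a documented choice.
* **Relative null percentage** — the denominator is edited, non-silent
  allele mass. Including silent substitutions would make the ratio depend
  on sequencing error rates rather than editing outcomes; the choice is
  recorded in the output.
* **`novel_residue_count`** counts mutant residues strictly before the
  first stop, compared position-wise against the reference peptide from
  the frame anchor. A clean targeted stop (e.g. TGG→TAG at a tryptophan
  codon) scores 0 — the mechanism by which base-edited null alleles avoid
  introducing new amino acids, in contrast to frameshifted tails.
* **Substitution-matrix denominators** — positions under a deletion leave
  that position's denominator instead of counting as non-edits, so
  indel-rich nuclease samples do not dilute per-position substitution
  percentages. Because the appropriate normalization is arguable, both
  per-covered-read and per-substitution frequencies are emitted.
* **Off-target test** — two-sided Fisher exact test on pooled
  edited/total counts per site with Benjamini–Hochberg correction across
  the panel (q < 0.05). Exact tests behave at the near-zero counts
  expected of clean off-target sites. A per-sample Wilcoxon option exists
  behind `method = "rank"`; neither is claimed to be what any particular
  historical analysis used, and unadjusted p-values are always emitted.
* **Acentric geometry** — the acentric fusion joins the two upstream
  segments head-to-head, which is what makes a pair of locus-forward
  primers convergent. The arrangement is an inference from primer
  orientations and is labeled an assumption in report headers.
* **Exact-match PCR and junction detection** — primers and junction
  flanks (15 bp each side) match exactly. The assay is presence/absence;
  mismatch tolerance would manufacture bands. Expected product sizes
  (e.g. 327/492 bp) are configuration inputs, since they depend on primer
  and intron sequences that live outside any amplicon reference.

## A worked fixture

The test fixture embeds the reverse complement of the gMH guide in a short
amplicon so that the two editing-window cytosines (protospacer positions 7
and 8) map onto the G bases of a plus-strand TGG tryptophan codon:

```{r fixture}
amp <- paste0("ACGTACGTCCA", "AGAGCATCCCATGGAACCTG", "GATCTAGGCATCGGATTACA")
t <- guide_target("toy", amp, protospacer = "CAGGTTCCATGGGATGCTCT",
                  pam = "TGG", strand = "-", protospacer_start = 11,
                  frame_anchor = 1, cds_bounds = c(1, 49),
                  quant_halfwidth = 12)
cut_site(t)
quant_window(t)
```

Pure C→T conversion at either or both cytosines turns TGG into TGA, TAG, or
TAA — a targeted stop with no novel residues:

```{r mechanism}
sim <- simulate_reads(t, be3_profile(t, p_edit = 0.3), error_model(0),
                      n = 5000, seed = 1)
tab <- build_allele_table(sim$reads, t, run_config())
calls <- classify_alleles(tab, t)
calls[, c("class", "is_null", "carries_targeted_stop",
          "novel_residue_count", "frequency")]
null_allele_stats(tab, calls)[c("absolute_null_frequency",
                                "relative_null_percentage")]
```

## Known limitations

* Single-end, full-amplicon reads only; no trimming, merging, or UMI
  handling.
* The translator requires the reading-frame anchor to sit outside the
  quantification window; alleles are spliced at the window boundary, so
  edits outside the window are invisible to translation by design.
* Off-target candidate discovery (CIRCLE-seq, GUIDE-seq, bioinformatic
  search) is upstream; the panel arrives as a TSV.
* The in-silico PCR is exact-match by design and says nothing about primer
  thermodynamics.
* Statistical calibration of the off-target comparison is verified under
  the simulator's null; real off-target panels with per-animal
  overdispersion should prefer the rank method and more samples.
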