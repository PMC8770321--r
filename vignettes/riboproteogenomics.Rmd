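---
title: "Calling TIS and classifying N-terminal proteoforms with riboNterm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling TIS and classifying N-terminal proteoforms with riboNterm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboNterm)
```

# Scope and model

riboNterm chains six analyses that together attribute a protein
N-terminus to its biological origin:

1. **footprint processing** — aligned ribosome footprints to P-site
   count tracks;
2. **TIS calling** — paired initiation (LTM) and elongation (CHX)
   tracks to a categorized set of translation-initiation sites;
3. **proteoform database construction** — called TIS to an in silico
   translated search database;
4. **N-terminus classification** — N-terminal peptide-spectrum matches
   to origin-labelled protein N-termini under the enzymatic rules of
   iMet excision (NME) and N-terminal acetylation (NTA);
5. **NTA stoichiometry** — light/heavy acetyl precursor pairs to
   percent in vivo acetylation;
6. **cleavage annotation** — neo-termini to predicted transit-peptide
   cleavage sites, primary-cleavage representatives and motif matrices.

A seventh, first-class module simulates all inputs with planted ground
truth. `runPipeline()` orchestrates the chain and writes a JSON report;
every stage is equally usable as a standalone function, which is the
intended interface of this package (there is no shell wrapper beyond
`scripts/acceptance.R`).

# Footprints and P-sites

Footprints of 26–34 nt are accepted; the P-site sits +12, +13 or +14 nt
from the 5′ end for length classes 26–30, 31–33 and 34. The offset is
applied along the transcription direction; on the minus strand the 5′
end is the rightmost genomic coordinate and the offset runs toward
decreasing coordinates. When transcript models are available the offset
is applied in transcript coordinates, so a footprint whose P-site falls
across an exon–exon junction resolves to the correct spliced position;
without models the arithmetic is purely genomic. Each alignment record
contributes one count — multimapping reads are not down-weighted,
matching the positional-score definition of the track.

Internally all coordinates are 1-based inclusive, the native convention
of GRanges/Biostrings on which the package is built; the 4-column
alignment dialect (chrom, 0-based 5′ end, strand, length) is converted
at the I/O boundary and all reports are 1-based.

Metagene profiles divide each gene's counts by the mean count over the
CDS plus 20 leader positions on either side, require at least 20 mapped
footprints per gene in the treatment, and average per-gene normalized
values aligned on the CDS start. Nucleotide bins are the default;
`codonBins = TRUE` sums frame-anchored 3-nt bins first.

# TIS calling

A candidate TIS is an LTM peak that

* carries the maximal LTM count within a 7-nt window (±3 nt);
* lies within ±1 nt of the first nucleotide of an ATG or of one of its
  nine single-nucleotide neighbours (CTG, GTG, TTG, AAG, ACG, AGG, ATA,
  ATC, ATT), to which it is anchored;
* passes its category's thresholds on the attributed count and on
  `R_LTM − R_CHX`, with `R_k = (X_k / N_k) × 10`.

Defaults are 5 counts / 0.01 for annotated starts (dbTIS), 10 / 0.05
for 5′- and 3′-leader and intergenic TIS, and 15 / 0.15 for TIS internal
to a CDS. Two reading choices deserve explanation because the
positional-score definition leaves them open:

* **Attributed count.** `X_k` is the P-site count summed over the
  anchored codon's first nucleotide ±1 nt — the same ±1 window used for
  anchoring — rather than the single peak position. With 1-nt peak
  jitter this attributes all initiation evidence of a codon to it and
  makes the count threshold insensitive to how the jitter happens to
  split reads.
* **`N_k`** counts P-site-assigned reads on the transcript (not raw
  alignments). Intergenic candidates have no transcript; they are
  normalized over a ±500 nt pseudo-transcript around the peak
  (configurable).

Tie-breaks are deterministic: a peak that is itself a codon start
anchors there (offset 0 preferred); otherwise an ATG beats a
near-cognate, then the most 5′ position wins. Equal-count peaks inside
one 7-nt window collapse to one candidate by the same preference, so at
most one TIS is called per window and strand. A transcript with zero
reads in one treatment scores that treatment's `R` as 0 instead of
being dropped, which keeps strong LTM-only signals visible.

"Elongating ribosome occupancy" for rescuing failing annotated starts
is operationalized as ≥ 10 CHX P-sites within the CDS
(`rescueMinChx`, exposed in `tisThresholds()`); the notion has no
standard quantitative definition, so the threshold is configurable.
Candidates supported by several transcripts of one gene are collapsed
to the record with maximal `R_LTM − R_CHX`.

The caller is verified against a brute-force oracle — an independent
position-by-position reimplementation with naive loops — on randomized
small genomes, plus planted-truth recovery at zero noise.

# Proteoform database

Alternative proteoforms are translated from each called, non-annotated
TIS to the first in-frame stop; near-cognate initiators decode as Met,
so residue 1 is always M. Relations recorded per entry: `annotated`,
`truncated_dTIS` (in-frame CDS-internal; sequence is a suffix of the
parent up to residue 1), `extended` (5′-leader TIS in frame with and
reading into the CDS), `leader_ORF`, `internal_ORF` (out-of-frame
CDS-internal) and `intergenic_ORF`. ORFs without an in-frame stop are
emitted with a no-stop flag rather than dropped, and both leader
classes are kept, flagged by relation, since there is no principled
reason to exclude them from a search space. Entries shorter than 7
residues are dropped (mirroring the typical minimum identifiable
peptide length); exact duplicate sequences collapse with a
cross-reference so the FASTA stays non-redundant while the mapping
table preserves every genomic origin.

# N-terminus classification

PSMs are filtered at q ≤ 0.01; N-termini with fewer than 2 PSMs are
flagged low-evidence but kept, because acetylation status needs only
one light-acetyl PSM. Peptides sharing a protein start but differing at
their C-termini (enzymes, missed cleavages) collapse to the longest
variant; disagreeing residues at a shared start are an error, not a
silent merge.

The NME rule: Met aminopeptidases excise the iMet iff residue 2 is
small — {A, C, G, P, S, T, V}, the canonical MetAP specificity set,
exposed in configuration. Consequently an N-terminus at iMet+1 is
compliant iff its first residue is small, and a retained-iMet
N-terminus is compliant (strict mode, the default) iff residue 2 is
*not* small; lenient mode accepts every retained iMet. Strict is the
default because in the curated 68-row dTIS evidence shipped with the
package every retained-Met N-terminus has a non-small residue 2.

NAT classes: exposed A/S/T/V/G/C → NatA; retained M + D/E/N/Q → NatB;
retained M + L/I/F/W/Y/K/H/R/M → NatC/E/F; Pro at the mature first
position or at residue 2 behind a retained Met → refractory; everything
else → none. MP is classed refractory rather than none, following the
biochemical evidence that Pro in the second position blocks
acetylation. Refractory N-termini observed acetylated are *flagged*
(`ntaFlag`), not rejected: the rules act as a biological filter for TIS
assignment, not as grounds to discard measured spectra.

Origin precedence: protein start 1 or 2 of an annotated entry → dbTIS
(dbTIS wins when a start could also be read as another entry's dTIS);
a called in-frame dTIS matched at its iMet or iMet+1 *and*
NME-compliant → dTIS, or dual_dTIS_cTP when a predicted transit-peptide
cleavage matches the same start; cleavage match only → cTP_neo/mTP_neo;
otherwise internal_neo. A positional dTIS match that fails NME (for
example a near-cognate start exposing a bulky residue) is demoted to a
neo-terminus — such cases are more plausibly proteolytic. Acetylated
N-termini matching mitochondrial cleavages are flagged since no
mitochondrial NTA machinery is known; they may reflect mispredicted or
ambiguous targeting peptides.

# NTA stoichiometry

In vitro heavy (¹³C₂D₃) acetylation labels in vivo free N-termini, so a
light/heavy precursor pair (Δ5 Da) measures the in vivo acetylated
fraction: degree = 100·L/(L+H). The bounded percentage form (not the
raw ratio L/H) is used because reported degrees are percentages in
[0, 100]. Per N-terminus, intensities are summed across contributing
pairs before the ratio (default), which weights pairs by signal;
per-pair averaging is available (`method = "mean"`), and per-pair
degrees with their spread are always reported. Pairs with both
intensities zero are skipped and counted. Class summaries suppress
groups with fewer than 5 observations.

# Cleavage annotation

An N-terminus matches a predicted transit-peptide cleavage when its
start lies within the P5–P5′ region: |start − P1′| ≤ 5 with
P1′ = predicted presequence length + 1. The inclusive ≤ 5 window is the
default — the P5–P5′ region naming implies inclusion — and the strict
`< 5` reading is available via `inclusive = FALSE`, since both phrasings
circulate. Deviations are signed, negative upstream of P1′. Because
aminopeptidases trim stromal neo-termini, starts within 5 residues
link transitively into one cluster and the most upstream member is the
representative, presumed primary, cleavage product. Motif matrices
count residues at P5..P1, P1′..P5′ over representative sites, pad
positions outside the protein with a gap symbol, and normalize each
column to 1; a background frequency vector yields log2 enrichments.

# The synthetic-data generator

`simConfig()` fixes the study conditions; `simulateGenome()`,
`simulateFootprints()` and `simulatePsmTable()` are deterministic given
the seed (footprints and PSMs use seed+1 and seed+2 so the three
streams are independent but reproducible, and byte-identical outputs
for identical configs are a tested invariant).

Genes are built in transcript space — 5′ leader, ATG-initiated CDS,
3′ leader — and projected through an exon map onto a single chromosome
with genes on alternating strands; a fraction of genes receives one
GT..AG intron inside the CDS so junction arithmetic is exercised.
Planted features: in-frame dTIS (ATG with probability 0.7, else a
near-cognate) in half the genes by default; uORFs; one intergenic ORF;
chloroplast/mitochondrial presequences with a planted
(V/I)-X-(A/C)↓A cleavage motif followed by planted S/V/T residues at
the trimming positions; and, in half the genes carrying both a dTIS
and a presequence, a *dual* configuration in which the predicted P1′
coincides with the iMet-excised dTIS N-terminus.

Default condition values: 20 genes; CDS 300–900 nt; leaders 60–120 /
40–100 nt; 100 LTM reads per TIS and a leaky fraction of 0.3 (so a
dTIS draws ~30 initiation events binomially); 200 CHX reads per gene
with frame-0 weight 0.8 and exponential 5′→3′ decay 0.002 per nt;
read lengths 26–34 peaked at 29; intensity CV 0.1. Planted NTA degrees
per co-translational class (NatA 90, NatB 95, NatC/E/F 20, refractory
0, none 10) and per stromal residue (A 34.9, S 36.3, V 60.3, T 50)
echo the magnitudes reported for Arabidopsis co- vs post-translational
acetylation, so recovery tests operate in a realistic regime. No noise
level is reported for real libraries; the off-target read fraction
defaults to a placeholder 0.02 and the LTM jitter probability to 0.1,
both exposed in the config, and tests that assert exact recovery set
them to 0 as their stated condition.

What the generator does *not* emulate — and therefore what passing
tests do not show about real data: sequencing error and mapping
ambiguity, rRNA/tRNA contamination, spectral identification error
beyond a q-value column, retention-time or ionization effects, missed
cleavages, transcript-isoform diversity beyond one model per gene, and
genuine biological variability of NTA degrees around their class
means. Enzymes are limited to trypsin and Glu-C (cleavage after K/R
and E/D, no missed cleavages): two enzymes with different cut sites
are sufficient to exercise multi-enzyme collapsing.

# Numerical and degenerate-input choices

* Ties in TIS anchoring and windows: deterministic (offset 0, then
  ATG, then most 5′), chosen to be conservative toward annotated-style
  AUG initiation.
* Zero-denominator guards: `normalizedScore()` refuses `n = 0`
  (callers substitute 0 for a treatment with no reads); metagene genes
  with zero window mean are excluded and reported; intensity pairs
  summing to zero are skipped and counted.
* `degree` is exact at the boundaries: planted 100% emits heavy
  intensity exactly 0 and recovers exactly 100.
* Motif columns always sum to 1 including the gap symbol, so
  early-protein sites do not silently renormalize.
* Problem sizes in the shipped tests: oracle equivalence runs 100
  random 2-gene genomes (a few kilobases each); recovery suites use
  15–40 genes. These sizes give the property suites full coverage of
  strands, junctions, categories and tie-breaks while keeping the
  default test run fast.

# Known limitations

* The dbTIS rescue criterion (total CDS CHX P-sites ≥ 10) is one
  defensible operationalization of "elongating occupancy"; a
  length-normalized criterion would behave differently on very long
  CDSs.
* `N_k` for intergenic candidates depends on the pseudo-transcript
  width; 500 nt is a pragmatic default.
* Shared peptides are assigned to annotated entries first and
  otherwise parsimoniously; a full protein-inference model is out of
  scope.
* The classifier trusts the upstream search engine's q-values and
  modification assignments; no spectral rescoring is attempted.
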