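---
title: "Two-round, haplotype-aware SNP calling for low-coverage long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-round, haplotype-aware SNP calling for low-coverage long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the method it implements: the
model and its assumptions, the parameters that matter, what the bundled
simulator does and does not emulate, the numerical choices, and the
design decisions that were genuinely open.

## The calling problem and the two-round model

On low-coverage (~16×) long-read data with per-base error in the 4–15%
range, the evidence at a single site is weak: a heterozygous SNP is
expected to show the alternative base in about half the reads, but at
depth 16 the binomial spread is wide, and recurrent errors reach 2–5
reads easily. The pipeline therefore works in two rounds.

**Round one** sees only local pileup counts. Candidate sites pass a
depth filter (`depth > d`, default 6) and an alternative-allele
frequency filter (`f_b > e`, default 0.12), where `f_b` is the largest
count of any non-reference symbol in {A, C, G, T, I, D} divided by the
site depth (counts pooled over strands; depth counts every read whose
alignment spans the site, including those with a deletion there —
otherwise a deletion-rich site could have `f_b > 1`). Each candidate
becomes a `(2w+1) x 16` image of raw per-strand counts and maximum
indel lengths. A two-layer bidirectional LSTM (the field's standard
sequence model for pileup columns) reduces the image at its middle time
step — the candidate's own column, with flanking context folded in by
the recurrence — and two softmax heads predict the genotype (21
unordered symbol pairs) and the zygosity (3 classes).

The image deliberately contains **no reference channel**: the unordered
genotype pair is inferable from the counts alone, and the reference base
is reintroduced only when a record is written (a pair equal to
{ref, ref} is homozygous reference, not a variant). One consequence,
visible in training diagnostics, is that the zygosity head must
distinguish "nearly pure column = homozygous variant" from "mostly
reference with errors = homozygous reference" purely from the count
pattern, which makes it the quality bottleneck at marginal depth.

**Round two** adds the long-range haplotype evidence. Heterozygous
first-round calls with quality at least 14 are phased, reads are
haplotagged, and each candidate is re-examined through the 26-feature
combined vector per position (counts and frequencies over {A,C,G,T,D},
base-quality sums/means and mapping-quality sums/means over {A,C,G,T}),
computed for four alignment subsets (original, haplotype 1, haplotype 2,
unphased) and concatenated to 104 channels. The short-range image spans
`[b-w, b+w]`; the long-range image spans the `t = 5` nearest qualifying
het sites on each side of the candidate. Two BiLSTM branches (one per
image), reduced at their middle time steps, are combined by a fully
connected layer and feed 10-class genotype and 3-class zygosity heads.
For a true het SNP, the haplotype-split channels separate cleanly — one
haplotype block nearly pure alternative, the other nearly pure
reference — which is exactly the signal the first round lacks.

**Merge.** Quality is the smaller of the two head scores under the
log-odds Phred transform `q(P) = (10/ln 10) ln(P/(1-P))`, clipped to
[0, 60]. A site enters the final VCF from the haplotype model if its
quality exceeds `delta = 14`, else from the pileup model under the same
test, else not at all; both inequalities are strict, and the output is
SNP-only (first-round I/D genotypes never reach the VCF).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_depth` (d) | 6 | reads | candidate depth filter (strict >) |
| `min_af` (e) | 0.12 | fraction | candidate allele-frequency filter (strict >) |
| `w` | 16 | bases | flanking size of pileup images |
| `t` | 5 | het sites | flanking het sites per side, long-range image |
| `het_qual` | 14 | Phred-like | het-site selection for phasing (>=) |
| `delta` | 14 | Phred-like | merge threshold (strict >) |

`w` trades local context against input size; `t` trades long-range reach
against the number of reads spanning all selected het sites. The het
threshold is applied inclusively (>= 14) — the boundary case is not
fixed by the merge rule's strict inequalities, and is configurable.

## Network profiles

The published-scale configuration ("full" profile) uses hidden size 128,
fully connected width 512, batch 2000 / lr 1e-4 / 200 epochs with label
smoothing 0.1 for the pileup model, and batch 512 / lr 1e-5 / 30 epochs
for the haplotype model, with Adam plus a lookahead wrapper (k = 5,
alpha = 0.5). That configuration assumes GPU-scale training on millions
of candidates.

The "desk" profile — the default, and what the test suite runs — is the
package's scaled-down configuration for a single CPU: hidden 32, fully
connected 64, batch 16, 30 epochs, lr 1e-2 with a 10x decay over the
second half of the epochs, plain Adam, label smoothing 0.01, negatives
downsampled to 1.5 per positive, and a sixfold static allele-permutation
expansion of the training set.
Three of these choices deserve explanation:

* **Smoothing 0.01 instead of 0.1.** Label-smoothed cross entropy caps
  the attainable top-class probability at `1 - s + s/K` per example at
  convergence; for `s = 0.1, K = 21` that is 0.905, i.e. a maximum
  quality of ~9.8 — *below* the merge threshold of 14. A desk-scale
  model that actually converges on its small training set would then
  emit nothing. A full-scale model never reaches per-example convergence,
  so the inconsistency is invisible at that scale. With `s = 0.01` the
  cap is ~20, comfortably above the threshold, while retaining the
  regularising effect.
* **Plain Adam with lr decay.** Under a tight step budget the lookahead
  wrapper roughly halves effective progress; it remains available (and
  on in the full profile). The late lr decay settles head probabilities
  near their smoothed optimum, which is what pushes correct calls over
  the quality threshold.
* **Allele-permutation expansion.** The calling problem is exactly
  symmetric under relabelings of {A, C, G, T}: permuting the base
  channels of every image and the genotype labels in the same way yields
  an equally valid training example (zygosity is pattern-based and
  unchanged). At desk scale (~150–200 planted SNPs) some of the 16
  het/hom allele combinations are rare; a static expansion of the
  training set by a few fixed random permutations covers them without
  changing the simulated study conditions. Per-batch *random*
  relabeling, by contrast, destabilised early training and is not used.

## The simulator: what it emulates and what it does not

`generate_diploid()` plants SNPs (default 1/kb, the human genome-wide
average; two-thirds heterozygous, matching the human het:hom ratio of
roughly 2:1) and short 1–5 bp indels (0.2/kb) on two haplotype copies,
with variants spaced so alleles never overlap. `simulate_reads()` draws
log-normal read lengths (mean ~9 kb), alternates haplotypes, assigns
strands 50/50, places reads uniformly *with edge overhang* — the contig
is treated as a window of a larger genome, so mean depth is uniform
rather than ramping down over a read length at each boundary — and
injects substitution/insertion/deletion errors at configurable rates
(study default 4%/1%/1%, the low end of the nanopore error range). Base
qualities come from two Beta-scaled Phred bands (correct bases ~Q30,
error bases ~Q13) so quality features carry signal; mapping qualities
are drawn from a 60-biased discrete distribution. Reads are emitted at
their true coordinates with exact CIGARs, which makes feature-extractor
oracles exact and keeps aligners out of the test loop (a FASTQ path
exists for realigning externally if wanted).

Not emulated: pore-level signal, homopolymer-dependent error structure,
chimeric/supplementary alignments, mapping ambiguity in repeats,
reference bias, and structural variants. Passing tests on this
simulator therefore demonstrate that the pipeline's machinery —
candidate search, feature extraction, phasing, the two networks, and
the merge — recovers planted variants under idealised alignment, not
that the shipped desk-profile weights would transfer to real flow-cell
data; real use requires training on real alignments at the full profile.

## Numerical and algorithmic choices

* **Quality transform.** The log-odds Phred form with clipping to
  [0, 60] and probability clipping at 1e-10; `q(0.5) = 0` and
  `q(P) = -q(1-P)` before clipping.
* **Head disagreement.** When the zygosity head disagrees with the
  zygosity implied by the genotype head's pair, the genotype head wins,
  the zygosity is recomputed from it, and the record is flagged
  (`head_conflict`); the record quality still uses both heads' scores.
* **Input scaling.** Fixed per-channel divisors (counts /25, indel
  maxima /10, quality sums /750, quality means /40, mapping sums /1500,
  mapping means /60) bring all channels to order one; they are constants,
  not data-dependent statistics, so calling is stateless.
* **Phasing.** Exact MEC search when a block has at most 2^12
  enumerable phasings; otherwise a position-ordered greedy pass with
  incremental per-read conflict counts, then single-site flip refinement
  to a local optimum (bounded passes). The first site of each block puts
  its first allele on haplotype 1 — the global labelling within a block
  is arbitrary and this tie-break fixes it deterministically. Blocks are
  never stitched across gaps with no spanning read. Haplotagging
  requires a strict majority; ties stay unphased, which the feature
  extractor represents as its own subset rather than forcing a guess.
* **Degenerate inputs.** Zero het sites degrade the pipeline to
  unphased-only images (haplotype blocks zero); empty subsets yield
  zero feature vectors; missing flanking het sites leave zero rows with
  a validity mask; mean features are defined as 0 where the
  corresponding count is 0; zero-depth columns are skipped by the
  candidate filter.
* **Determinism.** All stochastic steps (simulation, negative
  downsampling, initialisation, shuffling, expansion permutations) are
  seeded; two runs with equal seeds produce byte-identical VCFs.

## Problem sizes used by the tests

The acceptance-style study simulates a 200 kb contig at 16× (4%/1%/1%
errors), trains on the left 150 kb and scores the held-out right 50 kb
(~50 planted SNPs); it asserts final F1 >= 0.90 and that the haplotype
model's F1 is at least the pileup model's — the directional claim the
two-round design rests on. Feature extractors are checked exactly
against naive per-read recounts on 200 random windows; phasing against
exhaustive MEC enumeration on 100 random instances; determinism by
running the full pipeline twice at 60 kb. Oracle code paths
(per-read loops, exhaustive enumeration) share no code with the
vectorised implementation they check, and BAM parsing is cross-checked
against the Rsamtools pileup engine.

## Known limitations

* The desk profile's held-out F1 (~0.9 at 16×) is bounded by genuinely
  marginal sites — depth fluctuations below the candidate filter and
  het sites with extreme allele-fraction draws — the same failure modes
  that dominate real low-coverage calling.
* Quality scores saturate at the smoothing cap, so ROC-style ranking
  above the cap is flat.
* The built-in truth classifier matches exact site + genotype; it does
  not perform haplotype-aware normalisation of representations, so it
  is stricter than benchmarking tools that do.
* Multi-allelic sites are representable in the output (two
  non-reference alleles, GT 1/2) but the candidate search keys on the
  single largest alternative count.
* Phasing optimality is guaranteed only per block up to the exact-search
  limit; large blocks get a locally refined greedy solution, whose
  switch errors are harmless to the caller (the feature windows are
  local) but make global haplotype labels unreliable across long gaps.
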