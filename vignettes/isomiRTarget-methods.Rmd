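---
title: "Methods: chimeric-read interaction calling and the two-branch interaction classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chimeric-read interaction calling and the two-branch interaction classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomiRTarget)
```

## Scope

`isomiRTarget` covers the full path from chimeric sequencing reads (the
output of CLASH/CLEAR-CLIP-style crosslinking-ligation experiments, in
which a miRNA or one of its isoforms is physically ligated to the mRNA
target site it was bound to) to a trained sequence-level classifier of
small RNA-target interactions, plus two interpretation procedures for the
trained model.  Everything is testable offline: a synthetic-data module
generates references, isomiR variants of known type, planted target
sites, chimeric FASTQ reads and surrogate alignment-hit tables.

## The chimera pipeline

A chimeric read is modelled as `[small RNA portion][0-4 nt junction
insert][target-site portion]` (miRNA-first, the ligation convention; the
generator can also emit the reverse layout for robustness work).  The
pipeline applies, in order:

* **Duplicate removal.**  Exact-sequence duplicates collapse to the first
  record; the multiplicity is retained.  Read-support counting downstream
  is multiplicity-weighted, so support reflects the original read pool.
* **Hit filtering.**  Alignment hits (BLAST tabular, 12 columns) are kept
  when the e-value is at most 0.1, the hit is on the sense strand, and it
  has no gap openings.  Gapped hits are read as alignment loops and
  discarded; this keeps the later variant calling purely
  substitution/end-edit based.  Coordinates are converted once, on
  ingestion, to 0-based half-open; antisense hits are recognised by
  reversed subject coordinates.
* **Chimera calling.**  Every (miRNA hit, transcript hit) combination on
  a read with disjoint query intervals separated by at most 4 nt becomes
  a candidate.  Overlapping portions are rejected (a ligation inserts, it
  never overlaps); an optional `max_overlap` exists for users who read
  the distance rule more loosely.
* **Best-pair selection.**  Candidates are ranked by combined e-value
  (the max of the two hits -- conservative on the weaker mate), then
  combined bit score (sum), then lexicographically on identifiers so the
  ranking is a total order and output never depends on input order.  The
  top `top_k_pairs` (default 1; 5 reproduces a published sensitivity
  variant) survive per read.
* **Read support.**  A call survives only when its exact small-RNA
  portion sequence is supported by at least 10 reads.  The package
  exposes the probability model justifying that threshold:
  `supportProbability(n, L, e, k)` is the exact binomial upper tail
  `P(X >= k)` with per-read probability `e (1-e)^(L-1)` -- the chance
  that one specific single-error variant of an `L`-nt miRNA recurs `k`
  times among `n` reads.  At `n = 1000`, `L = 22`, `e = 0.001`, `k = 10`
  this is about 8.9e-08, which is why 10-fold recurrence is treated as
  biological rather than a sequencing artifact.
* **Variant calling.**  A portion identical to its reference miRNA is an
  exact miRNA call.  Otherwise the portion is anchored to the reference
  (below) and accepted as an isomiR only when the Phred quality at every
  variation position is strictly greater than 30.

### Anchored isomiR comparison and the eight types

Because gapped hits were discarded, the comparison is ungapped: the
relative offset in [-6, +6] maximising matches in the overlap is chosen
(ties prefer the smallest absolute offset, then the negative one, so the
result is deterministic).  End differences become offsets, internal
differences become mismatches, and the eight types follow directly:
5'/3' addition (negative 5' / positive 3' offset), 5'/3' deletion (the
opposite signs), 5'/3' replacement (zero offset with a terminal mismatch
run), SNP (exactly one internal mismatch) and MNP (two or more).  A
variant may carry several labels; an exact copy carries none.  Templated
and non-templated additions are not distinguished -- that would require
genome context the classification does not use.

One inherent limitation: a local aligner (ours or BLAST) trims terminal
additions out of the miRNA hit, because extending an alignment into
mismatching flanks lowers its score.  Addition isomiRs therefore surface
from the pipeline as exact-miRNA calls of the same (miRNA, site) pair,
and sequence-level recovery of addition types is only possible upstream
of alignment.  The classification itself, applied to full isomiR
sequences, recovers all eight types exactly (this round trip is tested
on 1000 generated variants).

### Type enrichment

Per (miRNA, type), a one-sided binomial test asks whether the type
occurs more often than expected among the miRNA's isomiR interactions.
The expected probability defaults to the type's pooled frequency across
all miRNAs in the dataset (a uniform 1/8 is available); the correction
is Bonferroni, the conservative reading of a "corrected" binomial test,
with Benjamini-Hochberg availble through `correction =` if preferred.

## Training pairs

Target sites are extended by 25 nt at the 3' end (clipped at the
transcript end) and dropped if still shorter than 30 nt.  Each positive
pair is matched by one negative with the same small RNA and a site of
the same length sampled uniformly from the 3'UTR of the same transcript,
at least 10 nt from every positive site, and screened by duplex energy.

Two energy backends exist.  `external_cofold` shells out to an
RNAcofold-compatible executable and parses its hybrid minimum free
energy.  The default `builtin_proxy` scores the best ungapped
complementary alignment of the small RNA against the reversed site as
`-(3 GC + 2 AU + 1 GU)`: deterministic, fast, and monotone in pairing
strength, which is all the screen requires.  The printed acceptance rule
"free folding energy < 10 kcal/mol" is ambiguous about sign (cofold
energies are typically negative, making the criterion permissive as
printed); both predicate directions are supported and the default
follows the text as printed (`energy < 10`).

The 80/20 split is stratified by label; a `by_mirna` mode partitions
miRNA identities instead, so no miRNA appears on both sides -- the
harder, generalisation-probing split.

## The classifier

Inputs are one-hot encoded: A, T, C, G map to unit columns (fixed row
order A/T/C/G), N to a uniform 0.25 column; U is read as T.  Small RNAs
are padded/trimmed at the 3' end to 30 nt and sites to 60 nt -- the 3'
end is sacrificed to preserve the 5' seed region (positions 2-7), the
most information-dense part of a miRNA.

The architecture, with every default dimension:

| stage | small-RNA branch | site branch |
|---|---|---|
| input | 4 x 30 | 4 x 60 |
| conv (10 kernels 4 x 8, valid, stride 1, ReLU) | 10 x 23 | 10 x 53 |
| max pool (size 4, stride 1) | 10 x 20 | 10 x 50 |

The two branches concatenate along the position axis (10 x 70), pass a
dropout of 0.25, a bidirectional LSTM with 10 units per direction
returning per-position states (20 x 70), dropout 0.5, a flatten (1400),
a 100-unit ReLU dense layer, dropout 0.5, and one sigmoid output.  The
binary label is `probability >= 0.5` (the threshold is configurable;
0.5 is the conventional choice).  Training minimises binary
cross-entropy with Adam (learning rate 0.001), mini-batches of 100, and
an L1 penalty of 0.01 on the convolution kernels and the dense weight
matrix (never biases).

Three numerical choices deserve explanation:

* **L1 normalisation.**  The penalty is applied as `lambda * mean(|W|)`
  per penalized matrix rather than `lambda * sum(|W|)`.  With the sum
  convention, the 1400 x 100 dense matrix contributes a constant
  subgradient of `lambda` to each of 140 000 weights -- roughly two
  orders of magnitude above typical data gradients for this
  architecture -- and in our experiments training then collapses to
  chance and stays there (the collapse is absorbing: once the dense
  pre-activations are pinned at zero, no gradient flows).  Averaging
  keeps the printed `lambda = 0.01` meaningful and commensurate across
  layers of very different sizes.
* **Initialisation.**  Glorot-uniform feed-forward weights, per-gate
  orthogonal recurrent matrices, LSTM forget-gate biases at 1 -- the
  standard recipe for this layer family.
* **Batch normalisation** after the convolutions is implemented behind a
  flag (default off), covering the alternative reading of mini-batch
  training with normalisation; in our experiments it neither harms nor
  rescues the short training schedules used in the tests.

The whole network -- forward pass, backpropagation (including the BLSTM,
overlapping stride-1 max-pooling with first-winner tie-break, inverted
dropout and optional batch normalisation) and Adam -- is implemented in
vectorised base R.  Analytic gradients are verified against central
finite differences in the test suite (relative error below 1e-4 on every
parameter class, with and without batch normalisation).  Inference is
deterministic; training is bit-reproducible under a fixed seed because
the backend is pure R.

Models serialise to a single JSON artifact with a version-stamped header
and losslessly encoded weights; `loadModel(saveModel(m))` reproduces
predictions bit-identically, and a header mismatch is rejected.

## Interpretation

**Kernel motifs.**  Each 4 x 8 convolution kernel is exported raw and as
per-column fractions (min-shift then normalise to sum 1, so a flat
column sits exactly at the 0.25 uniform baseline).  A kernel is
informative when at least half its columns put some base above
`0.25 + 0.05`; kernels whose weights are too similar across bases to
prefer a nucleotide are not.  Kernels can be matched against a JASPAR
PFM database: similarity is the maximum Pearson correlation over all
full-overlap offsets of the column-normalised matrices (zero-variance
comparisons score 0; no reverse-complement scan by default, since the
inputs are single-stranded RNA).  This is a similarity ranking, not a
calibrated motif-match p-value.

**Perturbation scan.**  Every 4-nt window of each input sequence is
replaced by Ns (after padding/trimming, so masking the padded tail
changes nothing and its deltas are exactly zero) and
`delta = p(original) - p(masked)` is recorded; positive deltas mark
regions supporting the call.  Per-position means and variances are
aggregated over pairs; per-pair delta matrices are returned for
downstream use.  miRNAs can then be clustered by their mean-delta
profiles with average-linkage agglomeration under the distance
`1 - Pearson correlation` (constant profiles get distance 1, with a
warning).

## Metrics

AUROC is computed by the midrank statistic (equivalent to concordant
pairs with half-credit for ties), AUPR by stepwise summation of
precision over recall increments with tied scores processed as blocks.
Confusion-matrix metrics report `NA` with a warning when a denominator
is zero, never a silent 0.  A stratified ten-fold cross-validation
helper mirrors the evaluation protocol used for the original method.

## What the synthetic data emulates -- and what it does not

The generator plants one target site per transcript inside its
annotated 3'UTR: the reverse complement of small RNA positions 2-7 near
the site's 3' end, optionally positions 10-16 near its 5' end
(`seed_plus_3prime`).  Reads carry per-base substitution errors at an
Illumina-like 0.001 with two-level Phred qualities (40 clean / 20
erroneous) bracketing the quality-30 variant filter.  Non-templated
terminal additions are counted against the 4-nt junction budget when
the spacer is drawn -- in a read, an addition and a junction insertion
are the same thing -- which keeps planted pairs recoverable under the
gap rule.  The generator also makes the ligation junction
alignment-unambiguous: spacer bases, and the first transcript bases
beyond them, are guaranteed to mismatch the read bases they abut, so a
local alignment cannot creep across the junction by chance and the
planted truth intervals stay well defined.  The surrogate aligner
selects each diagonal's best segment by a BLAST-like score (match +1,
mismatch -2, at most 3 mismatches, at least 16 nt) and emits
BLAST-outfmt-6-shaped tables with
a documented surrogate e-value (`L_ref * 4^-(len - 2 mm)`), monotone the
way the pipeline needs but *not* a calibrated BLAST statistic.

Real CLASH libraries differ in ways the generator does not model:
adapter remnants, indel sequencing errors, expression-driven read
abundance, paralogous miRNA families, repetitive UTRs and non-canonical
(seedless) sites.  A green test suite therefore certifies the machinery
-- filters, classification, training, interpretation -- on data whose
truth is known, not performance on any real library.

The learning sanity check uses a panel of 12 synthetic miRNAs and 2000
planted positives with 2000 sampled negatives, trained for 20 epochs: a
panel small enough that the planted motif vocabulary lies within the
default 10-kernel architecture's capacity, so the check probes
trainability of the implementation rather than the capacity limits of
the printed architecture.  Held-out AUROC/AUPR on this benchmark are
computed by the test suite itself, and the perturbation scan on the same
model shows seed-region windows moving predictions more than 3'-tail
windows, the qualitative sensitivity pattern expected of a
seed-planted dataset.  Problem sizes throughout the tests (a handful of
transcripts for pipeline round trips, thousands of pairs for training)
were chosen as the smallest sets that still exercise every filter
boundary and leave clear margins on the statistical checks.

## Known limitations

* Addition-type isomiRs are invisible to the alignment-based pipeline as
  sequence variants (see above); they are still recovered as interaction
  pairs.
* The builtin energy proxy orders candidate sites sensibly but is not a
  thermodynamic model; quantitative energy thresholds should use the
  cofold backend.
* Training the full-size default configuration for the historical 500
  epochs is possible but slow in pure R; the package targets the
  fixture-scale studies above, and nothing in the implementation depends
  on the epoch count.
* The abundance-augmented model variant (read coverage feeding the final
  logistic layer) is out of scope, as are adapter trimming and running
  an external aligner.
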