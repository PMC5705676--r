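---
title: "Species-disjoint reference proteomes and quantitative metaproteomics with ProteoTrim"
author: "ProteoTrim maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-disjoint reference proteomes and quantitative metaproteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProteoTrim)
```

## The problem

In a label-free shotgun experiment on a defined microbial community,
peptides are what the mass spectrometer sees, and a peptide whose exact
sequence occurs in the predicted proteome of two community members
cannot be attributed to either of them. For phylogenetically close
species the effect is severe: a substantial fraction of the tryptic
peptide universe can be shared, which blocks species-level protein
identification and biases quantification of the affected proteins.

`ProteoTrim` addresses this at the level of the search database. It
digests each reference proteome in silico, finds every peptide whose
string occurs in two or more species, and excises those peptides from
the protein sequences — deleting the amino-acid stretch and
concatenating the flanking fragments — so that the resulting "trimmed"
reference proteomes contain only species-unique peptide content. The
trimmed FASTA files are drop-in search databases; overlap matrices and
per-protein trim reports document what was removed. Downstream, the
package provides the matching quantitative workflow: filtering to
quantifiable proteins, two-group differential abundance with an
S0-moderated Welch statistic and permutation-based FDR, and pathway
over-representation by one-sided Fisher's exact test with
Benjamini–Hochberg correction.

## In-silico digestion

Digestion is deterministic string processing. Two tryptic rules are
provided:

* `trypsin_strict` (default): cleave C-terminal to K or R, except when
  the next residue is proline. This is the convention of the common
  digestion tools and search engines.
* `trypsin_p`: cleave after every K or R.

With zero missed cleavages the fragments partition the protein — their
concatenation in order is exactly the original sequence — which is the
invariant the trimming step relies on. `missedCleavages = k`
additionally reports every run of at most `k + 1` consecutive
fragments. Coordinates are 0-based half-open throughout the API;
reports are plain TSV where the same convention is kept and
documented, so a span `(start, end)` always satisfies
`substring(seq, start + 1, end) == peptide`.

Peptides shorter than `minLen = 7` residues are discarded before any
cross-species comparison: shorter peptides are generally not usable
for MS identification, and the seven-residue floor is the
conventional cutoff. Peptides containing ambiguity codes (B, X, Z, U,
O — all of which occur in real annotation pipelines) are excluded from
the comparable universe but tallied: an "identical string match"
against an unknown residue is meaningless, and exclusion is
conservative because it can only leave sequence in place, never remove
it. N-terminal methionine is not treated specially.

## Shared-peptide detection and trimming

`findShared()` intersects the per-species peptide indexes: a peptide is
shared when its exact uppercase string occurs in two or more species.
An optional `ilEquivalent` flag collapses isoleucine and leucine
(isobaric, indistinguishable in standard acquisitions) before
matching; it is off by default because the canonical definition is the
identical string match.

`trimProteomes()` removes every occurrence of every shared peptide
from all species, by coordinate: the digest fragment at its recorded
position is deleted and the flanks are concatenated. Substring search
is deliberately not used — a shared string embedded inside a longer,
non-shared peptide (for example behind a proline that suppressed
cleavage) is not a digest product at that locus and must stay.
Within-species repeats (the same peptide in several proteins of one
species) are not removed; that is the search engine's razor-peptide
problem, not a between-species ambiguity. Proteins trimmed to zero
length are dropped from the output FASTA (search engines reject empty
entries) but remain in the trim report with `became_empty = TRUE`.

Two modes are provided:

* `single_pass` (default): digest, detect, trim once, then verify by
  re-digesting the output; any peptides still shared are reported in
  `residualShared()` with a warning.
* `fixpoint`: repeat the cycle until the verification digest finds no
  shared peptide. This terminates because every round strictly removes
  residues.

At zero missed cleavages the two modes coincide: a removed fragment's
flanking boundaries are themselves cleavage sites (under the strict
rule a boundary additionally requires that the following fragment does
not start with proline, and both flanking boundaries retain that
property after excision), so the re-digested fragment set is always a
subset of the original and the verification digest cannot find new
peptides. With `missedCleavages > 0` the situation changes: excision
concatenates two previously non-adjacent fragments, whose run is a
*new* missed-cleavage peptide that may coincide with a peptide of
another species. `single_pass` reports such junction peptides as
residual sharing; `fixpoint` removes them. For the same reason, when
the shared universe includes missed-cleavage peptides, removal excises
all residues covered by occurrences of shared peptides (at zero missed
cleavages this is identical to deleting exactly the shared fragments).

`overlapMatrix()` reports, for every species pair, the number of
distinct peptides common to both. The count matrix is symmetric; the
percentage matrix divides each row by that species' own distinct
total, so one shared count reads as two different percentages — a
large proteome shares a smaller fraction of itself with a small one
than vice versa.

## Quantifiable proteins and differential abundance

Label-free intensities enter the statistics on the log2 scale, with
zeros and non-detections as missing values (`logTransform()`); nothing
is imputed. A protein is *quantifiable* when it has valid values in at
least a fraction `minValidFrac = 0.6` of the replicates of **each**
group — `ceiling(0.6 * n)` per group, so three of five replicates in
both conditions for the standard five-replicate design. Filtering
rather than imputing keeps every test on observed data; the cost is
that proteins detected in only one condition (on/off regulation) are
not testable, a known limitation of this design.

The test statistic is a Welch (unequal-variance) t-statistic with a
constant fudge factor in the denominator,

$$d = \frac{\bar{x} - \bar{y}}{s_0 + \sqrt{s_x^2/n_x + s_y^2/n_y}},$$

with `s0 = 1` by default. The fudge factor de-emphasises proteins
whose tiny sample variance would otherwise produce an enormous t for a
negligible fold change; `s0 = 0` recovers the classical Welch t
exactly (asserted against `t.test()` in the test suite). `s0` is on
the log2-intensity scale: at `s0 = 1` a protein needs roughly a
two-fold change to score |d| near 1 even with vanishing variance.

Significance is calibrated by permutation. Sample labels are randomly
reassigned into two groups of the original sizes; when the number of
distinct relabelings is small enough they are enumerated exhaustively
(the identity labeling is excluded), otherwise 250 seed-deterministic
random relabelings are drawn — 250 being the customary default for
this class of test. For each candidate cutoff $c$ (taken at the
observed $|d|$ values),

$$\widehat{FDR}(c) =
  \frac{\operatorname{mean}_\pi \#\{|d^*_\pi| \ge c\}}
       {\max(1,\; \#\{|d| \ge c\})},$$

clipped to $[0, 1]$ and made monotone non-increasing in $c$ by a
running minimum; the chosen cutoff is the smallest $c$ with
$\widehat{FDR}(c) \le \alpha$ (default 0.05), and proteins with
$|d| \ge c$ are flagged. The cutoff is symmetric in $|d|$; asymmetric
up/down cutoffs and a $\pi_0$ estimate, as some desktop
implementations apply, are intentionally out of scope and would only
make the estimate less conservative. If a permuted group drops below
two valid values for some protein, that permuted statistic is
undefined and never counts as an exceedance.

## Pathway over-representation

For each pathway and each direction of change (increased / decreased;
group 1 minus group 2 on the log2 scale) the package builds the 2×2
table of changed/unchanged × in-pathway/not-in-pathway and computes
the one-sided hypergeometric tail $P[X \ge a]$. The universe defaults
to every annotated protein of the reference proteome — enrichment
"relative to the size of the annotated proteome" — with
`universe = "detected"` available to restrict the background to
detected proteins, since either convention is defensible and they
answer slightly different questions. Changed proteins without any
annotation cannot enter a table; they are counted and reported
separately rather than silently dropped. BH correction is applied
across pathways within each direction; a protein in several pathways
is counted once per pathway, which makes the tests non-independent in
the usual way of subsystem annotations (BH remains valid under the
positive dependence typical here). No significance filter is applied
to the output: the full table is returned sorted by adjusted p, and
any cutoff is the analyst's decision.

## What the simulators emulate — and what they do not

`simulateProteomes()` builds each protein by concatenating random
tryptic fragments: fragment lengths are geometric with mean
`1/cleavageFreq` (default 9 residues, a realistic mean tryptic
fragment length, equivalent to a combined K/R frequency of 1/9),
residues are otherwise uniform, and fragment starts avoid proline so
that the two cleavage rules agree on the constructed boundaries.
Planted shared peptides are inserted as whole fragments at fragment
boundaries, with no internal cleavage site and a terminal K/R, so each
planted peptide is an exact tryptic product at a known span in every
species that received it. Accidental background sharing is embraced
rather than prevented — preventing it would bias the sequence
statistics — and is detected post hoc by re-digestion, so the recorded
ground truth is always the complete truth. What this generator does
not emulate: real amino-acid composition biases, homology (shared
peptides in real communities come from conserved proteins and
therefore cluster), ambiguity codes, and proteome-scale protein
counts. Passing tests therefore demonstrate correctness of the
string-level machinery, not performance on any particular pair of
real genomes.

`simulateIntensities()` draws protein baselines from
$N(25, 2^2)$ on the log2 scale (typical LFQ magnitudes), adds an
effect of `effectSize` log2 units (default 2, i.e. four times the
default within-group SD of 0.5, with random sign) to a random 10% of
proteins in group 2, adds $N(0, 0.5^2)$ noise, and applies missingness
last — completely at random by default (rate 0 unless requested), or
preferentially at low intensities to mimic left-censoring. Real LFQ
data have heavier tails, correlated proteins and normalisation
artifacts; none of these are simulated, so the FDR/power numbers from
these fixtures characterise the estimator under clean conditions.

`simulateAnnotation()` assigns random pathway memberships and can
plant one pathway enriched for a supplied changed set; it does not
model the hierarchical structure or size distribution of real
subsystem annotations.

All three generators are pure functions of their configuration
including the seed, which is what makes byte-identical reruns and
ground-truth-based testing possible.

## Numerical and design choices

* Coordinates are 0-based half-open internally; all reports carry the
  same convention (documented in the column descriptions) so spans
  can be applied directly with `substring()`.
* Ties in the permutation FDR are handled by counting exceedances
  with $\ge$ on both the observed and permuted sides, and candidate
  cutoffs are exactly the observed $|d|$ values, so the chosen cutoff
  is always attained by some protein.
* The Fisher tail is computed as `phyper(a - 1, ...)`; the test suite
  checks it against a log-space enumeration of all tables with the
  observed margins, and BH against a hand-written step-up.
* Degenerate inputs fail loudly: empty sequences, single-species
  trims, designs with a group smaller than two, unfiltered matrices
  containing untestable proteins, and out-of-range p-values are all
  errors, not silent fixes.
* Empty-after-trimming proteins: dropped from FASTA, kept in reports;
  a zero-record FASTA is still written (with a warning) so pipelines
  relying on file existence do not break.
* Default mode is `single_pass` because it reproduces the published
  single-cycle behaviour and is exact at the default zero missed
  cleavages; `fixpoint` exists for the missed-cleavage setting where
  junction peptides can arise, and its guarantee is verified by an
  independent re-digestion scan in the tests.

The test suite and the acceptance script run everything at desk
scale, chosen to exercise the asymptotics without waste: digestion
correctness on 500 random sequences up to 200 residues against a
brute-force oracle; trimming invariants on 50 simulated communities
of 2–5 species; overlap recovery on a four-species community with ~50
planted shared peptides (about 16% of one species' peptide universe);
FDR calibration on 20 replicates of 1000 proteins at five versus five
replicates with 250 permutations.

## Known limitations

* Trimming alters protein sequences; downstream tools that map
  peptides back to database coordinates must use the trim report to
  translate positions.
* Sharing is assessed on exact strings of fully tryptic,
  zero-missed-cleavage peptides by default, while search engines
  typically allow two missed cleavages; a shared missed-cleavage
  peptide can therefore survive default trimming. The
  `missedCleavages` option widens the shared universe at the cost of
  removing more sequence.
* The permutation FDR is an estimate of a global property; with very
  few proteins or very few distinct relabelings its resolution is
  coarse (with 5 relabelings the smallest attainable FDR step is
  0.2 of a protein count).
* Fisher tests across overlapping pathways are not independent, and
  BH is applied within direction only.
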