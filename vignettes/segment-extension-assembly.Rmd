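---
title: "Assembling unique and copied insertions by segment extension"
author: "segext"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling unique and copied insertions by segment extension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segext)
```

## The problem

A donor genome differs from its reference by, among other things, inserted
sequence. When the inserted content is *unique* (absent from the reference),
reads sampled from it fail to map and standard callers can flag the locus but
not reconstruct the sequence. When the content is *copied* (a duplication of
some other reference locus), its reads map — at the wrong place — and
approaches built on unmapped reads cannot see it at all. Real insertions are
frequently a mixture of both. `segext` reconstructs the nucleotide content of
unique, copied, and mixed insertions from paired-end short reads, given the
insertion breakpoints (from an SV caller, or from the built-in clustering of
one-end-anchored reads).

## Read-pair classification and the insertion read set

Fragment (outer insert) lengths are modelled Normal($\mu$, $\sigma$) and
assumed to lie in the hard interval
$[\Delta_{min}, \Delta_{max}] = [\mu - 3\sigma,\ \mu + 3\sigma]$.
Each read pair is classified by its mapping signature:

* **OEA** (one-end anchored): exactly one mate maps — the other lies in
  unique inserted sequence.
* **Orphan**: neither mate maps — both lie in unique inserted sequence.
* **Concordant**: both mates map with opposite strands in forward/reverse
  orientation and fragment span inside $[\Delta_{min}, \Delta_{max}]$.
* **Discordant**: both mates map but no placement is concordant — the
  signature of copied inserted sequence.
* **Over-coverage**: a *flag* on concordant pairs mapping into a region whose
  read depth exceeds the genome mean — the signature of a copy *source*: the
  donor carries that sequence twice, so its reference locus collects twice
  the reads. A concordant pair whose local mean depth is $\mu_{DOC[r]}$
  against a covered-genome mean of $\mu_{DOC}$ is admitted with probability
  $\max(0,\ 1 - \mu_{DOC}/\mu_{DOC[r]})$ — at twice the mean, half the reads
  are presumed to come from the copy.

The **insertion read set** (IRS) is the union of OEA, orphan, discordant and
admitted over-coverage pairs. Classification quantifies existentially over
multi-mapping location sets (one concordant placement suffices), fragment
span is measured outer-to-outer, and the depth profile places each
multi-mapped mate once, uniformly at random. $\mu_{DOC}$ is computed over
positions with nonzero depth so unsequenced gaps do not deflate it. PCR
duplicates are not removed before depth profiling.

## Segment extension

The reference is split at the insertion loci; each flank segment is grown
into its insertion one consensus column at a time. For frontier position
$pos$, a mate lying wholly inside the **anchor window**
$[pos - \ell - \Delta_{max},\ pos - \Delta_{min})$ ($\ell$ = read length) may
have sampled a partner covering $pos$: reads are *anchored* by whole-mate
match (at most $d$ substitutions) in the window, and their partner *extends*
if its longest prefix matching the assembled suffix — mismatch fraction at
most $1 - \tau$ — has length $ext$ with $\kappa < ext < \ell$. The partner's
base at index $ext$ is its vote for the new column. Votes decide the column:

* two or more bases with support fraction $\ge \varepsilon_{branch}$, each
  backed by at least `branch_min_reads` reads: a *divergence* — the
  extension forks and explores every supported base (depth-first,
  beam-capped);
* otherwise, the leading base is called when its support reaches
  $\varepsilon$, or when at most one vote dissents (a lone dissenting vote
  on a thin column is read-error noise, not a second haplotype);
* failing both: insufficient consensus, the branch terminates.

A branch also terminates *successfully* when its tail matches the opposite
flank's head over $\ell$ bases (the insertion has been crossed), or at a
safety cap. Competing hypotheses are resolved by *read accounting*: the
hypothesis matched by the greatest number of IRS pairs wins, ties going to
the first hypothesis in branch order. When the forward extension has already
reached the opposite flank the insertion is complete and the backward
extension is skipped; otherwise the right flank is extended in reverse
(reverse-complement, extend, reverse-complement back) and the two extended
segments are merged on their best ungapped overlap of at least $\ell$ bases,
a disagreeing overlap column taking the base from the side with larger
covering support. Without a qualifying overlap both fragments are reported
as a partial assembly.

The anchored search runs on an FM-index over the concatenation $R'$ of all
IRS mates — both mates of each pair, in both orientations, so the window
never needs reverse-complementing. Each column issues exactly
$|window| - \ell + 1$ index searches, independent of $|IRS|$; the naive
alternative (scan every IRS read per column) is retained as an engine option
and grows linearly in $|IRS|$ per column. Inexact search is pigeonhole-seeded:
a pattern with at most $d$ substitutions is split into $d + 1$ chunks, one of
which must match exactly; exact FM backward search per chunk plus direct
verification of the candidates returns exactly the matches a bounded
backtracking search would, much faster on 40X-duplicated read sets. Suffix
arrays are built with SA-IS; rank queries use a 2-bit-packed
Burrows-Wheeler transform with 64-symbol popcount blocks. The extension
driver caches per-substring anchored hits in a sliding window (one fresh
search per column), clones the cache on branching, and prunes competitor
branches once some branch has reached the opposite flank (a longer hypothesis
for the same insertion cannot terminate there any more). None of these
mechanics change results — the uncached, definition-level covering set and
the naive engine are kept as independent paths and the test suite asserts
their equivalence.

## Parameters

| parameter | default | meaning |
|---|---|---|
| $\mu$, $\sigma$ | estimated | fragment length model (bp); estimated from uniquely mapped proper pairs unless supplied |
| $d$ | 2 | substitution budget of mapping and anchored search (about 5.5% of $\ell = 36$) |
| $\tau$ | 0.9 | minimum identity of the ungapped overlap comparison |
| $\kappa$ | 9 | minimum informative overlap (bp) |
| $\varepsilon$ | 0.7 | consensus support fraction to call a base |
| $\varepsilon_{branch}$ | 0.25 | per-base support fraction at which a column diverges |
| `branch_min_reads` | 3 | minimum reads behind a minority base for a true divergence |
| `max_branches` | 8 | live hypotheses per endpoint |
| `max_extension` | 4275 | appended-bp cap per endpoint (twice the expected insertion length plus $\Delta_{max}$) |
| `node_budget` | 2 × `max_extension` | total columns explored per endpoint across branches |

Two defaults deserve their rationale. **$\kappa = 9$**: with roughly 150
anchored candidates per column, each tested in two orientations, an overlap
test at $\kappa = 5$ admits random prefix/suffix agreements (probability
$4^{-6}$ each) essentially every few columns — and because 40X sampling
duplicates reads exactly, such junk votes arrive in correlated pairs and can
outvote a sampling-thin column. At $\kappa = 9$ the random-agreement odds
($4^{-10}$) put expected junk below one vote per assembled insertion, while
the lost signal (true overlaps of 6–9 bp) is marginal. **$\varepsilon_{branch}
= 0.25 \le 1 - \varepsilon$**: with $\varepsilon_{branch}$ above
$1 - \varepsilon$ there is a dead zone — a 65/35 column branches but a
*stronger* 69/31 column terminates. Inside copied insertions whose source
windows collide with another insertion's, the correct base routinely sits at
0.6–0.7 support, exactly in that zone; keeping $\varepsilon_{branch}$ at or
below $1 - \varepsilon$ means every such column branches instead of dying,
and read accounting picks the right continuation. The count guard
`branch_min_reads = 3` is what makes a low $\varepsilon_{branch}$ safe: on a
two- or three-vote column any split clears a fraction threshold, so the
fraction alone cannot be "suitably large to eliminate the effect of read
errors"; requiring three reads behind the minority base confines branching
to columns with actual alternative support, while the one-dissenter call
rule keeps thin columns extending instead of terminating on a single
error vote.

## The simulator

The generator emulates the reference protocol: a uniform-random reference; a
donor carrying planted insertions of length Normal(2000, 200) bp (floored at
100 bp); paired 36 bp reads at 40X with fragment lengths Normal(200, 25)
re-drawn outside $\mu \pm 3\sigma$ (the model's hard-interval assumption);
substitution errors at rate 0.001 per base (configurable; indels and quality
profiles are deliberately out of scope since the assembler's comparisons are
mismatch-based). Unique insertions are uniform-random sequence; copied
insertions duplicate a uniformly chosen reference window; mixed insertions
split a copied segment at its midpoint and insert an equal-weight unique
segment — an insertion inside an insertion. Loci are drawn uniformly with a
minimum spacing of $2(\Delta_{max} + \ell)$ plus the largest insertion
length, guaranteeing the clean flank the extension base case assumes;
overlapping or nested loci beyond the mixed-case structure are not generated.
Each stage (reference, planting, reads) draws from its own seed offset so the
streams are independent, and every downstream stochastic step (multi-mapper
placement, over-coverage admission, N replacement) flows from the caller's
RNG, making whole runs reproducible from one seed.

What the simulator does *not* emulate matters for interpretation: a real
chromosome's repeat landscape (LINEs, SINEs, segmental duplications) is far
richer than a uniform-random background, so copied-insertion ambiguity here
arises only from collisions between the planted copies themselves; real
data would add mapping ambiguity everywhere. Accuracy on these simulations
therefore bounds what the per-insertion machinery can do under the stated
read model, not performance on a real genome.

## Evaluation

An insertion counts as correctly assembled when the best-placement
(semi-global, both strands) edit distance between the planted sequence and
the assembled contig is at most 10 bp. Contigs include reference flanks, so
local placement is the right comparison. Replicate accuracies are aggregated
as mean and sample (n − 1) standard deviation; the replicate count is five
unless stated.

At desk scale we run 50 insertions on a 1 Mb reference (and up to ~125
insertions on 2.5 Mb), which reproduces the protocol's coverage, read and
insertion geometry at roughly ten times the original insertion density —
collisions between copied-insertion source windows are correspondingly more
frequent, and they are the dominant failure mode for the mixed case here.
Conversely, pure copied insertions are easier against a uniform-random
background than against a real chromosome's repeat landscape, and desk-scale
accuracy in that case should be read as an upper bound. Problem sizes were chosen so a full replicated experiment runs in
minutes on one CPU.

```{r, eval = FALSE}
rep <- run_accuracy_experiment("case1_unique", n_insertions = 50,
                               reference_length = 1e6, seeds = 1:5)
glance(rep)
autoplot(rep)
```

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; SAM's 1-based positions are
  converted at the I/O boundary, BED breakpoints accept zero-length or 1 bp
  intervals.
* `N` never matches anything (including another `N`) in mapping, anchoring
  and overlap tests; `N`s in indexed reads are replaced by a random base at
  index time and flagged.
* Consensus ties break deterministically by base order (A < C < G < T) after
  count; hypothesis-selection ties break to the first hypothesis in branch
  order.
* A fragment-length SD of zero (degenerate estimation input) collapses the
  concordance interval to $\{\mu\}$ and is accepted.
* Reads with more than `d` mismatches everywhere are unmapped — there is no
  best-effort placement.
* An empty covering set terminates a branch; an empty hypothesis set marks
  the insertion failed (reported, not fatal).
* A single hypothesis is selected without the accounting search (there is no
  competition); its consumed-read count is reported.

## Known limitations

* Ungapped comparisons throughout: indel sequencing errors are not modelled
  and would erode consensus support.
* Copied insertions whose source windows overlap each other (or an insertion
  locus) can still divert or terminate extension; these account for
  essentially all residual failures in the mixed case at desk-scale density.
* The evaluator requires one truth record per locus; nested or overlapping
  planted insertions are out of scope.
* Per-insertion independence is preserved in the API (each locus is
  assembled in isolation from shared inputs) but no concurrency machinery is
  provided.
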