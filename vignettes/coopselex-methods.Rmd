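---
title: "Detecting TF-TF spacing preferences and composite motifs from CAP-SELEX data"
author: "coopselex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting TF-TF spacing preferences and composite motifs from CAP-SELEX data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopselex)
```

## The problem

Transcription factors (TFs) rarely act alone: two DNA-bound TFs can
interact on the DNA and prefer a particular spacing and strand
arrangement of their two sites, or can form a *composite* site whose
sequence preference differs from any concatenation of the two monomer
motifs. CAP-SELEX (consecutive affinity-purification SELEX) probes this
directly: a library of double-stranded ligands with a 40-bp random
region is incubated with two tagged TFs, both are purified in turn so
that only ligands bound by the pair survive, the bound DNA is amplified,
and the cycle is repeated (three cycles in the screen design this
package targets). The selected pools, together with single-TF HT-SELEX
pools, are the package's inputs. This vignette explains the statistical
machinery and the choices behind its implementation.

## Spacing detection by positional mutual information

Each TF is represented by a characteristic 8-mer (a locally maximal
enriched 8-mer, see below). The 8-mer and its reverse complement are
partitioned into ten indexed 4-mers: indices 1--5 are the forward
windows, indices 6--10 their reverse complements (index 6 mirroring
window 5). Two TFs' 4-mer sets are paired *forward* (index j with
index j) and *inverse* (j with 5+j, or j-5), which together cover all
four strand arrangements of the two 8-mers. 4-mers present in both sets
are excluded, because their co-occurrence reflects a single TF's site
rather than an interaction.

For every ordered pair of non-overlapping read positions
(pos2 − pos1 ≥ 4; exactly 561 position pairs per pairing on a 40-bp
read), each surviving 4-mer pair contributes the mutual information
between the indicator of "first 4-mer at pos1" and "second 4-mer at
pos2" across the reads, and the cell's score is the sum over the
(up to 20) pairs. The full 2×2 mutual information is used — both the
joint-presence term and the complementary cells — which keeps every
contribution non-negative; the joint-presence term alone can be
negative under depletion and would not represent dependence
symmetrically. Empirical frequencies are used without smoothing, with
0·log(0/x) taken as zero; smoothing would inflate MI at unobserved
cells.

Cooperative binding at a preferred arrangement concentrates high-MI
cells on few offsets (pos2 − pos1). The caller ranks the cells within
each pairing, takes the top 5% (28 of 561), and calls the pair
interacting when the top cells of **either** pairing span fewer than 6
distinct offsets. Ranking is per pairing rather than jointly across
both: the pairing orthogonal to a true arrangement carries only noise,
and its scattered top cells would otherwise always push the union past
the group limit, making the rule unable to fire at all. The preferred
arrangement is the modal (offset, pairing) group of the concentrated
pairing, reported alongside the gap between the characteristic 8-mers
(offset − 8; negative gaps mean overlapping 8-mers).

A practical consequence of the top-28 rule: an offset d has only
37 − 3 − d cells on a 40-bp read, so a single rigid arrangement can
fill the whole top set only for offsets ≤ 9 (gaps ≤ ~2). This matches
the biology — most detected interactions are short-range — but means
the binary call loses sensitivity for long gaps even when the preferred
arrangement is still identified correctly.

## k-mer relative affinities and composite discovery

Under a thermodynamic selection model, the ratio of a k-mer's frequency
in cycle r to its expected input frequency estimates its relative
binding affinity:

K_a(k) ≈ ((F_k^r / F_ref^r) / (P0(k) / P0(ref)))^(1/r),

where ref is the most abundant k-mer in the selected pool (ties broken
lexicographically; K_a(ref) = 1 exactly) and P0 is the expected input
frequency under a fifth-order Markov model fitted to the cycle-0 pool
(add-one pseudocount per context). Counts receive a pseudocount of 0.5
so unobserved k-mers get a finite small affinity; the estimator is
otherwise undefined at zero and 0.5 keeps ranks stable.

Composite candidates are 10-mers whose CAP-SELEX affinity ranks in the
top half of the observed CAP 10-mers **and** is at least 1.5× the
higher of the two HT-SELEX affinities. Percentile ranks run over
10-mers with non-zero CAP counts only — at laptop scale the 4^10 table
is dominated by unobserved 10-mers that would otherwise swamp the
denominator. Among candidates, a 10-mer becomes a seed iff no other
candidate within Hamming distance 1 has higher CAP affinity; mirrored
(reverse-complement) seeds are collapsed because a site enriches in
both read orientations.

### Seed refinement and the multinomial PWM

A seed is extended outward while the flanking position of its matches
shows base preference (most/least frequent base ratio above 2), and a
degeneracy code replaces positions where the most common base falls
below frequency 0.5 (the two- or three-base IUPAC code when the
2nd/3rd, respectively 3rd/4th, frequency ratio exceeds 2; otherwise N).
Extension additionally stops when the flank symbol would be N: with a
finite founder population the bare ratio rule fires on clone-specific
flank noise and extends seeds indefinitely, while an N column adds no
information to the seed.

The position count matrix uses the multinomial counting model: the
count column for position i is tallied from windows (both strands) that
match the seed at every position except i, with one additional mismatch
tolerated anywhere when the refined seed is longer than 10 bp
(multinomial level 2). Because each column comes from its own window
class, column totals differ by design. Background correction subtracts
the Markov-expected count of each column class (computed by dynamic
programming over the chain for the exact degenerate pattern; the
one-mismatch classes of level 2 are approximated by the exact-pattern
expectation, which dominates), floors at zero and adds a pseudocount of
one.

## Motif analytics

**Gapped k-mer similarity.** Motif similarity is the cosine of expected
gapped 10-mer occurrence vectors (one internal gap of up to 5,
placements overlapping the motif, uniform background flanks),
strand-symmetrised by averaging each motif's forward and
reverse-complement vectors. The inner product factorises over positions
into products of column inner products, so no k-mer enumeration is
performed; the brute-force enumeration at small k is kept as a test
oracle. The metric is 1 for identical motifs (and against the reverse
complement) and near 0 for disjoint sharp consensi; 0.1 is the default
edge/exclusion threshold on this scale.

**Dominating sets.** Representative motifs are a minimum dominating set
of the similarity network: every motif is a representative or similar
to one. The solver is an exact branch-and-bound over vertex subsets up
to a configurable size (default 25; verified against subset enumeration
in the tests) with the standard greedy set-cover approximation above
it; the mode used is reported.

**Core/flank divergence.** Both monomers are aligned to the composite
by exhaustive ungapped alignment maximising summed column similarity
(1 − Jensen–Shannon divergence per column, minimum overlap 4). The
composite columns covered by both monomer alignments form the
*composite overlap*; the overlap is compared with the corresponding
monomer sections by (1) total JSD in bits (distinct if > 0.5 bits
against either monomer) and (2) the Jaccard index of high-affinity
k-mer sets (k-mers of overlap length scoring ≥ 90% of each section's
maximum product-of-frequency score; distinct if < 0.5 against both),
computed for overlaps shorter than 13 columns.

**Discovery saturation.** Subsampling the tested TF pairs (300
subsamples per grid point) yields a discovery curve of distinct motif
clusters versus pairs tested. A square-root model p = A·√N + B is
fitted by least squares and evaluated at the total number of TF pairs;
a line through the ~50,000-pair point and the last point gives a lower
bound, since the concave discovery curve lies below its chords'
extension. With the published fit (A = 1.93, B = −51.57) and 1,639
human TFs, the model evaluates to 2,186 clusters.

## Genomic statistics

**Scanning.** Natural-log log-odds scanning of both strands against the
sequence base composition; the threshold is the smallest score keeping
at least the requested number of matches (default 300,000), never below
the floor of 2; when fewer matches reach the floor, all floor-passing
matches are returned with a warning.

**Region enrichment.** k of n subset regions and m of N universe
regions carry a match; the fold change is log2((k/n)/(m/N)) and the
one-sided hypergeometric tail follows its sign (upper for enrichment,
lower for depletion, p = 1 at exactly zero). The conventional call is
p < 0.01 and log2 fold change > 0.75.

**Control motifs.** For every split point leaving both halves at least
one third of the motif (rounded down), three recombinations are formed:
right+left, left+revcomp(right), revcomp(left)+right. Controls more
similar than 0.1 to the original are excluded; duplicates from
palindromic symmetry are removed and counted.

**Conservation.** True and control matches are merged; the top 10,000
non-overlapping matches by score are kept (greedy by descending score).
A motif-specific threshold on the per-match average conservation score
comes from a two-component Gaussian mixture fitted to the true matches'
averages (ten seeded random EM initialisations, best BIC; the threshold
is the smallest score whose posterior for the higher-mean component
exceeds one half; degenerate fits fall back to the median with a flag).
Conserved-match enrichment among true matches is tested one-sided by
Fisher's exact test with the conditional fold change
(k/n) / ((m−k)/(N−n)); across motifs, p-values are Holm-adjusted
(`p.adjust(..., "holm")`). Half-site coupling is tested by per-position
correlation of conservation scores across matches against a Gaussian
null fitted to control-match correlations, BH-corrected, reporting the
minimum q of the inter-half block's lower triangle. Pair conservation
by spacing/orientation counts co-occurring monomer matches (gap < 30)
in which both matches are conserved; the null distribution comes from
pairings with control motifs. Because these are counts of rare events
and a rank-based empirical p cannot fall below 1/(controls+1) — which
never clears an FDR of 0.01 — the null tail is modelled as Poisson with
the rate estimated from the control pairings.

## The simulator and what the tests show

The simulator is the package's ground truth. `simulate_library` draws
i.i.d. reads from a uniform or Markov background; `selection_model`
plants one or two position weight matrices with a cooperativity factor
ω applied when the two sites occur at the planted gap and strand
arrangement (both the arrangement and its reverse complement, since
ligands are double-stranded). Window affinity is the standard
mononucleotide product ∏ f/fmax (consensus = 1); a ligand's affinity is
the maximum over single-site and paired terms. Each round, ligand i is
captured with probability proportional to its occupancy
a_i/(a_i + K), normalised so the best ligand in the pool is always
captured — the proportionality constant is a capture efficiency, and
without it a laptop-scale pool would lose essentially all molecules in
one round. The saturation constant defaults to 10 × max(1, ω) so
selection stays approximately affinity-proportional, matching the
regime in which the relative-affinity estimator is derived. The bound
fraction is resampled with replacement to the pool size (uniform PCR).
Selection runs in index space from one affinity pass, so pools of
10^6 molecules are practical.

Default planted monomers are 8-bp motifs with a sharp 4-bp core
(consensus frequency 0.9) and soft flanks (0.3) — the information
profile of typical monomeric TF motifs. Planted composite cores use
sharper columns (0.95), as composite sites tend to be crisp. Where the
tests need a continuous affinity landscape they use graded column
frequencies, because uniform sharpness creates large exact ties.

Two scale choices matter and are deliberate:

* **Library complexity exceeds sequencing depth** (10^6 molecules,
  50,000 analysed reads for the MI tests). Real selections start from
  ~10^12 molecules; when complexity equals depth, the selected pool is
  a handful of amplified founder clones whose flanks correlate across
  *all* position pairs, producing spurious high-MI cells at arbitrary
  offsets.
* **Ground truth for affinity recovery is the effective landscape**
  (`effective_kmer_landscape`): the exact expected enrichment of each
  10-mer given the library's per-read affinities. The naive per-column
  product is not what selection rewards — a 10-mer window shifted
  against a site hitchhikes with the site's enrichment — and ~98% of
  the top 1% of 4^10 10-mers have zero expected count after three
  rounds (counts scale as affinity^r), so no estimator could rank them
  from sequence data at any scale.

What passing simulations do *not* show about real data: the simulator
has no sequencing errors, no PCR bias beyond uniform amplification, no
protein-concentration effects, rigid planted gaps, and mononucleotide-
independent energies; real pools also contain carry-over and
ligand-design context the Markov background only approximates.

## Problem sizes and numerical conventions

The shipped test suite uses: 100 seeded replicates at 50,000 reads for
the null calibration of the interaction caller; 10 replicates at
2×10^5–10^6 library molecules for power, composite recovery and
landscape recovery; 50 replicates for conservation-null calibration.
Internally, coordinates are 1-based closed (the GenomicRanges
convention), converted exactly at the BED/bedGraph boundary (0-based
half-open). k-mer tables are dense code-indexed vectors (k ≤ 12
enforced). Ties are broken deterministically everywhere:
lexicographically for reference k-mers and seeds, by (higher MI,
smaller offset, forward before inverse) for arrangement calls, and by
(smaller |offset|, same strand first) for motif alignments. EM uses 10
seeded initialisations with a BIC choice; degenerate component
collapses fall back to the median with a flag.

## Limitations

The binary interaction call needs the planted/true gap to be short
(≤ ~2 bp between 8-mers) before the top-5% rule can concentrate fully,
although the preferred arrangement is recovered for longer gaps; the
one-mismatch background-correction classes of multinomial level 2 are
approximated by the exact-pattern expectation; the motif-class
heuristic (composite vs spacing) is a consensus-embedding check, not
the expert curation used for published collections; and the exact
dominating-set solver is exponential in the worst case and hands off
to the greedy approximation beyond its size limit.
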