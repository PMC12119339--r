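# coopselex

Analysis of cooperative DNA binding by transcription-factor (TF) pairs
from CAP-SELEX and HT-SELEX sequencing data.

CAP-SELEX (consecutive affinity-purification SELEX) incubates a random
DNA library with two tagged TFs, purifies each in turn so only ligands
bound by the pair survive, amplifies and repeats. Comparing the
selected pools with single-TF HT-SELEX pools reveals two kinds of
TF–TF preference: **spacing/orientation preferences** between the two
monomer sites, and **composite motifs** whose sequence differs from any
arrangement of the monomer motifs. This package implements the full
computational machinery for both, plus the downstream motif and genome
statistics, and a thermodynamic SELEX simulator that provides planted
ground truth for every step.

## What's inside

* **Spacing detection** — each TF's characteristic 8-mer (a locally
  maximal enriched 8-mer) and its reverse complement are partitioned
  into ten indexed 4-mers; for every non-overlapping position pair
  (pos2 − pos1 ≥ 4; 561 pairs per pairing on 40-bp reads) the summed
  mutual information MI(pos1, pos2) = Σ P(4-mer+4-mer)
  log₂[P(4-mer+4-mer)/(P₁(4-mer)P₂(4-mer))] over the paired 4-mers is
  computed in the forward and inverse pairings. A pair is called
  interacting when the top 5% of cells (28 of 561) concentrate on fewer
  than 6 distinct arrangements.
* **Relative affinities** — K_a(k) ≈ ((F_k^r/F_ref^r) /
  (P₀(k)/P₀(ref)))^(1/r) per k-mer, with P₀ from a fifth-order Markov
  model of the input library.
* **Composite discovery** — 10-mers ranked in the top half of the
  CAP-SELEX table with affinity ≥ 1.5× the better HT-SELEX table seed
  composite motifs; seeds are refined to IUPAC form and expanded into
  multinomial position count matrices with Markov background
  correction.
* **Motif analytics** — gapped 10-mer similarity (closed form), motif
  alignment, core/flank divergence (Jensen–Shannon divergence and
  high-affinity k-mer Jaccard), consensus score differentials, minimum
  dominating sets (exact branch-and-bound / greedy), and
  discovery-saturation estimation (p = A·√N + B).
* **Genome statistics** — log-odds scanning to a target match count,
  hypergeometric region enrichment, recombined control motifs,
  Gaussian-mixture conservation thresholds, Fisher/Holm conserved-match
  tests, half-site conservation correlation, and pair conservation by
  spacing/orientation.
* **Simulator** — 40-bp random libraries selected by one or two planted
  PWMs with a cooperativity factor ω at a planted gap/orientation;
  affinity-proportional capture, uniform amplification, index-space
  rounds (10⁶-molecule libraries run in seconds via a small C++
  kernel).

## Worked example

Simulate a CAP-SELEX experiment for two TFs with cooperativity ω = 50
at a planted 2-bp gap, then detect the arrangement:

```r
library(coopselex)

sm <- default_sim_motifs()              # two 8-bp monomer motifs
model <- selection_model(sm$A, sm$B, cooperativity = 50, gap = 2,
                         orientation = "ff", rounds = 3)
lib <- simulate_library(1e6, 40, seed = 3)
sel <- simulate_selection(lib, model, seed = 1003, keep = "last")
set.seed(7)
pool <- read_pool_from_reads(sample(sel$pools[[3]]$reads, 50000), cycle = 3)

mi <- positional_mi(pool, build_4mer_sets(sm$a8), build_4mer_sets(sm$b8))
mi
#> MIMatrix: 561 position pairs per pairing, 50000 reads of 40 bp
#>   max MI: forward 0.3133, inverse 0.0646 bits

call_interaction(mi)
#> InteractionCall: INTERACTING (top 28 cells; 5/14 distinct offsets fwd/inv)
#>   preferred arrangement: offset 10 (8-mer gap 2), forward pairing
```

The caller ranks the 561 position-pair MI values within each pairing
and keeps the top 28. Here the forward pairing's top cells concentrate
on 5 distinct offsets (fewer than 6 → interacting) while the inverse
pairing scatters over 14 (noise), and the modal cell offset of 10
between 4-mer positions maps back to a 2-bp gap between the two
characteristic 8-mers — exactly the planted arrangement, in the
planted orientation.

The saturation arithmetic of the screen is equally direct:

```r
saturation_estimate(A = 1.93, B = -51.57, N = tf_pair_count(1639, include_self = TRUE))
#> [1] 2185.935    # ~2,186 composite-motif clusters genome-wide
round(100 * interaction_rate(2198, 58754), 1)
#> [1] 3.7         # percent of screened TF pairs interacting
```

A thin command-line interface over the same functions lives at
`inst/cli/coopselex.R` (subcommands `simulate`, `kmers`, `spacing`,
`composite`).

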