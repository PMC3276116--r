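---
title: "Line-origin inference in outbred line crosses: model, simulator, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Line-origin inference in outbred line crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineorigin)
```

## The model

An F2 individual in a cross between two outbred lines carries one
haplotype from its F1 dam and one from its F1 sire. At any genomic
position each haplotype descends from a line-1 or a line-2 founder, giving
four *line-origin states* per position, written (i, j) for maternal origin
i and paternal origin j and ordered (1,1), (1,2), (2,1), (2,2) throughout
the package. Line origin along a chromosome is a Markov chain provided
crossovers show no interference; the package therefore uses Haldane's map
function

$$r(d) = \tfrac12\left(1 - e^{-2d/100}\right), \qquad d \text{ in cM},$$

to turn an inter-position distance into a recombination fraction. Because
the two meioses are independent, the transition matrix over the four
composite states is the Kronecker product of two 2×2 single-haplotype
kernels with stay probability $1-r$ and switch probability $r$
(`transition_kernel()` accepts distinct maternal and paternal distances,
so sex-specific maps fit the same contract; by default both sexes share
the map, which is also what the simulator produces).

The observed variable is the marker genotype, which makes the chain a
hidden Markov model. The emission probability of an observed F2 genotype
under state (i, j) is *compatibility-based*:

* For each F1 parent and marker, the *transmissible-allele sets* are the
  alleles the parent could carry on its line-1 and line-2 haplotype. They
  are found by enumerating the two assignments of the parent's alleles to
  (from line-1 founder, from line-2 founder) and keeping the
  Mendelian-consistent ones; a missing genotype imposes no constraint, so
  ungenotyped founders simply marginalize out.
* A genotype is compatible with (i, j) if it can be composed from one
  allele of the dam's line-i set and one of the sire's line-j set.
  Compatible states emit 1; incompatible states emit the error floor
  $\varepsilon$; a missing F2 genotype emits 1 everywhere.

Posterior state probabilities at markers and at arbitrary test positions
come from the scaled forward–backward algorithm. Test positions are merged
into the marker sequence as pseudo-observations whose emission is 1 for
every state, so a single pass covers the whole evaluation grid; the
initial distribution is uniform (¼ per state), the expected line-origin
frequencies of an F2, and any non-degenerate choice is washed out by
flanking marker data. The per-haplotype summaries reported everywhere are
$p_{1,\text{maternal}} = p_{11} + p_{12}$ and
$p_{1,\text{paternal}} = p_{11} + p_{21}$.

`enumerate_oracle()` is the brute-force reference: it scores all $4^n$
state sequences explicitly and normalizes. It is exponential and capped at
10 positions, but on any instance it must agree with the forward–backward
result to numerical precision; the test suite asserts agreement below
1e-10 across hundreds of random instances, which is the method's central
correctness property.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `grid_step_cM` | 1 | spacing of test positions from 0 to the chromosome length |
| `error_floor` | 0.01 | emission of Mendelian-incompatible states; keeps the truth reachable under genotyping error. Any value in (0, 0.5) is accepted; results are insensitive to the exact value on clean data |
| `weighted` | `FALSE` | replaces the {1, ε} emission with the genotype probability under uniformly drawn transmissible alleles — a refinement of the documented compatibility semantics, off by default |
| `upper`, `lower` | 0.975, 0.025 | probability thresholds defining the end points of a recombination switch; attainment is inclusive (≥ / ≤) |

## Numerical choices

* **Underflow control** is by per-position rescaling (forward columns to
  sum 1, backward columns to max 1) with the cumulative log scale
  retained; the suite checks that posteriors remain normalized to 1e-12
  over 10,000-position chains.
* **Tied marker positions** (common in consensus linkage maps) are fanned
  out evenly over `x − 0.05` to `x + 0.049` cM before any computation, so
  all inter-marker distances are strictly positive. The asymmetric right
  end point is deliberate and kept verbatim from the source convention.
* **Coincident coordinates**: a test position within 1e-8 cM of a marker
  is computed once at the shared coordinate.
* **Degenerate inputs**: an emission row of all zeros (possible only with
  ε = 0) aborts with an explicit error; Mendelian-inconsistent
  parent/marker combinations do not abort inference — the constraints at
  that marker are relaxed to the parent's own alleles and the pair is
  reported in the emission table's `inconsistent` field.

## The simulator

`simulate_cross()` generates a three-generation intercross with known
truth. Its defaults are the study conditions the package is calibrated
for: a 451 cM chromosome with markers every 0.3 cM (about 1500 markers),
and a pedigree of one line-1 grandsire and three line-2 granddams, 4 F1
sires, 37 F1 dams and 773 F2 individuals assigned round-robin to
sire × dam pairs.

* **Founder haplotypes.** Per marker and per line an allele-1 frequency is
  drawn uniformly on (0, 1); founder haplotype alleles are then drawn
  independently from their line's frequency. This reproduces the mixture
  of fully informative, partially informative and uninformative markers
  that arises when the same alleles segregate in both lines. It does
  *not* reproduce within-line linkage disequilibrium: real founder
  haplotypes have correlated alleles along the chromosome, which changes
  the spatial clustering of informative markers. Passing tests under this
  generator therefore demonstrates correctness of the machinery and
  realistic average information content, not performance under any
  specific real LD structure. User-supplied frequency matrices or founder
  haplotypes override the default.
* **Meiosis** is gamete dropping: the crossover count is Poisson with
  mean the chromosome length in Morgans, positions are i.i.d. uniform on
  the chromosome, the starting haplotype is fair, and alleles switch
  haplotype at every crossover. This is exactly the no-interference model
  the Haldane transitions assume, so simulator and inference engine are
  consistent by construction. Counts-then-positions is equivalent to a
  homogeneous Poisson process on the interval.
* **Truth tracks.** F1 haplotypes inherit their line label from their
  pure-line founder, so the crossovers of an F1 meiosis translate directly
  into the F2 haplotype's piecewise-constant line-origin function; truth
  is stored as (start line, crossover positions) and expanded on demand.
* Optional genotyping error (random dosage perturbation) and missingness
  exercise the ε floor; both default to 0, matching the error-free study
  conditions.

`phase_parent()` reconstructs an F1 parent's haplotypes by line origin:
markers homozygous in the parent or pinned by a homozygous founder resolve
immediately; each remaining heterozygous marker is paired with the nearest
resolved heterozygous marker and assigned the phase that makes fewer
offspring two-marker genotypes inexplicable without a recombination
between the pair. Ties stay unresolved rather than guessed, and the
nearest-anchor choice is an interpretation — the procedure's source
description leaves the pairing order open. Newly resolved markers serve as
anchors for the rest, nearest-first.

## Evaluation statistics

For one haplotype with line-1 probability series $p_1(i)$ on the grid, the
line-origin error is $e(i) = 1 - p_1(i)$ where the true origin is line 1
and $e(i) = p_1(i)$ where it is line 2. `summarize_error()` reports the
per-position mean and standard deviation over both haplotypes of all
individuals plus the grand mean; the SD is the sample (n − 1) form, a
convention choice.

A *switch* is a traversal of the series across 0.5 that reaches ≥ `upper`
on one side and ≤ `lower` on the other before any other 0.5-crossing; its
end points are the nearest such attainments, their distance the
*imprecision* (minimum one grid step). The crossing position `cross_cM`
is the linear interpolation between the two grid points flanking the
0.5-crossing; a run of exact-0.5 values uses the centre of the run. An
alternative is to snap the crossing to the nearest grid position, but
snapping discards up to half a grid step of location information and makes
the *inaccuracy* (|crossing − true position|) bounded only by a full grid
step even on perfect data, so the interpolated crossing is used: with
ideal hard 0/1 series, every isolated interior crossover is then recovered
with imprecision exactly one grid step and inaccuracy at most half a step,
which the acceptance suite asserts. Switches truncated by the chromosome
end (one threshold side never attained) are not emitted.

`match_switches()` pairs detected switches with true crossovers of the
same haplotype and direction, greedily by distance, each side used at most
once; unmatched truths count as undetected. The matching rule is not
dictated by the statistics' definitions — greedy nearest within (haplotype,
direction) is this package's documented choice.

## Identifiability: why "all markers fully informative" is a hard case

A marker is fully informative when the two lines carry distinguishable
alleles through the pedigree. If *every* marker is fully informative
(lines fixed for alternative alleles), every F1 parent is heterozygous at
every marker, and then the likelihood is exactly invariant under swapping
the maternal and paternal labels wherever the F2 is heterozygous: states
(1,2) and (2,1) have identical emissions everywhere and the two meioses
have equal transition rates. The posterior is exactly 0.5/0.5 for the two
mixed states throughout any segment where the two true haplotype tracks
disagree — roughly half the chromosome — so the grand mean per-haplotype
error has an irreducible floor of about 0.25 in this regime, however dense
the markers. This is a property of the data, not of the algorithm: no
method using unordered genotypes and symmetric meioses can do better. The
acceptance suite keeps an aspirational check of near-exact recovery in
this regime as documentation of the gap. Real crosses (and the default
simulator) escape the symmetry because many parents are homozygous at many
markers, which anchors the maternal/paternal assignment; that is why the
mixed-informativeness default achieves sub-percent grand mean error while
the "ideal" fully informative design cannot.

## Problem sizes and scope

The worked examples and tests run on deliberately small designs (tens to
hundreds of F2, tens of cM) because every property they check is
scale-free; the acceptance script and the full-scale tests use the default
study dimensions (≈1500 markers, 773 F2, 451 cM, 9 or 3 replicates),
which complete in about a minute on a single core.

Out of scope by design: multi-chromosome batching beyond looping the
single-chromosome unit, sex-specific map *estimation* (the transition
kernel merely accepts two distances), grandparental 16-state origin
tracking, joint two-position posteriors for epistasis models, phenotype
regression/QTL scanning, and crossover-interference models in the
simulator.
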